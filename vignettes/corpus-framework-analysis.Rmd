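---
title: "Corpus framework analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corpus framework analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Peer-support forums are a naturalistic record of how people with a
long-term mental health condition talk about their lives, in their own
words and outside researcher-constructed settings. *Corpus framework
analysis* combines quantitative corpus linguistics (frequency lists,
keyword statistics, collocation) with qualitative framework analysis
(coding text into a predefined category hierarchy such as the POETIC
framework for personal recovery in bipolar disorder). `corpusframe`
implements the computational side of that workflow end to end:

1. **Cohort detection** — find users who disclose a diagnosis in the first
   person ("I was diagnosed with ...").
2. **Topical filtering** — keep posts in condition-specific subforums that
   mention the condition.
3. **Relevance ranking** — score each post's TF-IDF-weighted cosine
   similarity to a curated concept term list, sample posts by score decile
   for human calibration coding, and split posts into a concept-relevant
   *target* corpus and a low-relevance *reference* corpus.
4. **Keyness** — find lemmas used significantly more in the target corpus,
   gated by effect size and author dispersion.
5. **Concordance coding support** — extract, sort and sample key-word-in-
   context (KWIC) lines for human coding, then extrapolate coded category
   proportions to full corpus frequencies.
6. **Collocation** — rank a node lemma's content-word neighbours by cubed
   mutual information.
7. **Reliability** — Cohen's kappa for coder agreement.

Real forum datasets of this kind are typically access-restricted, so the
package ships a synthetic generator (`synth_generate()`) that emulates
user-attributed forum posts with known ground truth; every statistical
claim in the test suite is made against that ground truth.

## Normalization layer

All statistics count **lemmas** (dictionary forms: "recovering" and
"recovered" both count as "recover"). No statistical NLP stack is assumed:
`default_analyzer()` is a deterministic rule-based English analyzer — a
tokenizer that collapses URLs and user mentions to non-word placeholders,
an irregular-form dictionary plus ordered suffix rules for lemmatization,
and a coarse five-way part-of-speech tagger (`NOUN`, `VERB`, `ADJ`, `ADV`,
`OTHER`) driven by closed function-word lists and suffix heuristics. Rule
lemmatizers are imperfect on open vocabulary (e.g. some *-ed* stems
restore an "e" that was never there); what matters for the statistics is
that the mapping is deterministic, collapses inflectional variants
consistently in both corpora, and is a fixed point on its own output. The
analyzer name and version are recorded in every derived table. The
analyzer is pluggable behind the same interface should a richer
morphological model be available.

Coordinates are 0-based and end-exclusive everywhere (match spans,
concordance node spans). Multiword term matching is greedy
left-to-right longest-match over lemma sequences; non-word tokens break
multiword spans. Greediness is a documented tie rule, chosen so that term
counts are deterministic: in "take care", the phrase wins over the nested
single word "care".

## Relevance ranking

Each post is a vector over term-list entries with weight
$tf(t, p)\cdot idf(t)$, raw term frequency and smoothed inverse document
frequency $idf(t) = \ln\frac{1+N}{1+df(t)} + 1$ computed over the scored
corpus. The query vector carries the idf weights of all terms, and a
post's relevance score is the cosine of the two vectors. "TF-IDF-weighted
cosine similarity" admits many variants (log-tf, different idf smoothing,
query constructions); the package fixes this one — raw tf, the smoothed
idf above, idf-weighted binary query — and records it in the score table's
metadata, because absolute score cutoffs are only meaningful relative to a
fixed weighting. Terms with zero document frequency are dropped from the
feature space (logged): they cannot affect any score either way.

The target/reference split uses strict cutoffs ("above"/"below") and an
inclusive minimum post length of 94 words, applied at split time rather
than scoring time so that calibration sampling can still see short posts.
Post length counts title and body words together (a post's analysis text
is its title and body joined by one newline). The default cutoffs (0.025
/ 0.013) are values a real forum study of this design would use, but any
absolute cutoff is dataset- and weighting-specific, so the analysis
drivers re-calibrate them from the decile sample: `decile_sample()` partitions scores into ten equal-count
bins, merges consecutive bins whose scores are all identical (an all-zero
tail contributes one bin's worth of posts, e.g. 90 rather than 100 when
the bottom two deciles are all zero), and samples uniformly without
replacement per bin. The driver then picks the smallest upper cutoff whose
coded sample precision reaches 0.8 and the largest lower cutoff with at
most 10% relevant posts below it — the "balance precision against corpus
size" rule made explicit.

## Keyness

For a lemma with frequency $a$ in a target corpus of $c$ word tokens and
$b$ in a reference corpus of $d$ tokens, `log_likelihood()` computes the
log-likelihood statistic G² of the 2×2 contingency table
$[[a, c-a], [b, d-b]]$ (word vs all other words, target vs reference),
with the convention $0\ln 0 = 0$. Two variants are provided:

* `"4cell"` (default) — the exact likelihood-ratio statistic over all four
  cells. This is the form whose null distribution is chi-square with one
  degree of freedom, so it is the form consistent with converting a
  significance level into a G² threshold; the test suite verifies it
  against an independent entropy-form G-test oracle to 1e-9 on 10^4 random
  tables.
* `"2cell"` — the truncated two-term form
  $2\,(a \ln(a/E_1) + b \ln(b/E_2))$, $E_1 = c(a+b)/(c+d)$,
  $E_2 = d(a+b)/(c+d)$, as printed by several corpus-linguistics tools.
  It omits the "other words" cells and is slightly smaller (10.465 vs
  10.485 on $(30, 10, 10^4, 10^4)$); it is kept for comparability with
  those tools and unit-tested against its defining arithmetic.

The difference is negligible when $a, b \ll c, d$, which is the keyness
regime, but the package defaults to the exact statistic. The significance
gate at $\alpha = 10^{-4}$ is derived from the chi-square quantile at run
time (`g2_critical()`, about 15.14), never hard-coded.

A lemma is **key** iff all of: it is overused in the target
($a/c > b/d$), its overuse ratio $\frac{a/c}{b/d}$ is at least 2, its G²
exceeds the critical value, and at least 5% of the target corpus's
authors use it. The dispersion gate prevents one prolific author from
making a lemma key; its denominator is target-corpus users (the study
this generalises from leaves the denominator unstated; it is a documented
choice here and an explicit argument). When $b = 0$ the overuse ratio
alone smooths the zero cell to 0.5 (G² needs no smoothing under the
$0\ln0$ convention). Keyness is computed on the union vocabulary, one row
per lemma, sorted by G² descending with ties broken alphabetically.

**Absent terms**: a concept term is *missing* if its target frequency is
0 and *underused* if present but with lower relative frequency than in the
reference corpus. Multiword term frequencies are counts of
non-overlapping match spans, which is why this function consumes token
tables rather than lemma-keyed frequency tables.

## Concordances and extrapolation

`extract_concordances()` emits one KWIC line per occurrence with up to 20
words of context each side (word tokens only, truncated at post
boundaries). Sorting is stable and lexicographic on (node, left, right),
with the left context compared word-by-word outward from the node — the
nearest left word is the primary left key — implemented by joining words
with a separator that sorts below any printable character. Sampling for
coding is uniform without replacement, 30 lines per lemma by default,
deterministic under a seed, and returns everything (with a warning) when
fewer lines exist.

Human coding enters through a plain TSV (lemma, line id, comma-separated
labels), keeping the qualitative step an explicit file interface.
`extrapolate_category_frequencies()` scales coded proportions to corpus
frequencies: a lemma with corpus frequency $F$ and $n$ coded lines
contributes $F \cdot k_c/n$ instances to category $c$ labelled on $k_c$
lines. With single-label coding the category masses sum exactly to
$\sum F$ (a conservation law the tests assert); a line may carry several
labels, in which case each label receives full proportional mass and
totals can exceed $\sum F$ — fractional mass splitting is not attempted,
and the multi-label convention is recorded in the output metadata of the
analysis drivers.

## Collocation

`collocates()` ranks content-word neighbours (noun, verb, adjective,
adverb) of a node lemma within a symmetric window of 5 words each side,
subject to a minimum observed co-occurrence of 5, by cubed mutual
information $MI^3 = \log_2(O^3/E)$ with $E = f_1 f_2 W / N$, $W = 2
\times \text{window}$. The cube rewards frequent collocates that plain MI
would rank below rare one-off pairs. Window positions are counted over
word tokens (punctuation does not use up window slots), windows are
truncated at post boundaries, a token within reach of several node
occurrences is counted once, and node occurrences are never their own
collocates. These conventions — in particular the inclusion of $W$ in $E$
— follow common corpus-linguistics practice and are recorded with the
output; doubling a corpus by self-concatenation raises every MI³ by
exactly 2 (a property the tests assert).

## Reliability

`cohen_kappa()` computes unweighted Cohen's kappa for two equal-length
label sequences, binary or multi-class, with the full confusion table in
the result. `kappa_implied_pe()` inverts the formula to recover the
chance agreement implied by a reported (observed agreement, kappa) pair —
useful for auditing published agreement figures whose confusion-table
marginals are not printed; the algebra round-trips to machine precision.

## The synthetic generator

`synth_config()` fixes the simulation conditions used across the tests
and analysis drivers:

| parameter | default | meaning |
|---|---|---|
| `n_users` | 200 | forum users |
| `posts_per_user` | 5–15 | uniform per user |
| `words_per_post` | 50–150 | body words, uniform |
| `vocab_size` | 5000 | background pseudo-lemmas |
| `zipf_exponent` | 1.1 | background rank-frequency law |
| `relevant_fraction` | 0.2 | posts enriched in concept terms |
| `planted_terms` | 20 terms | 17 single-word + 3 multiword |
| `planted_base_rate` | 1.5e-3 | per content token, per term |
| `enrichment` | 4 | rate multiplier in relevant posts |
| `self_report_fraction` | 0.5 | users with a disclosure sentence |
| `condition_mention_rate` | 0.4 | posts naming the condition |
| `function_word_rate` | 0.35 | function-word share of tokens |

These defaults produce roughly 2000 posts and 2×10^5 words. The planted
base rate treats concept terms as moderately common content words (about
3% of background content tokens across the whole 20-term list), and half
the users disclosing a diagnosis keeps both detection classes well
represented. Posts are bags of lemmas: a Zipfian background vocabulary of
pseudo-words whose suffixes encode their part of speech, a closed
function-word set, light punctuation, planted terms at
`enrichment × base rate` in relevant posts, planted collocates inserted
adjacent to their node occurrences, and one first-person disclosure
sentence per self-reporting user. Collocates of planted nodes inherit the
node's enrichment, so the ground-truth table flags them as
planted-enriched lemmas too. Generation is byte-identical under a fixed
seed.

What the generator does *not* emulate — grammar, discourse, topic
drift, spelling noise, bursty authorship — bounds what passing tests
mean: they certify the statistical machinery (the estimators recover
planted effects at the configured sizes and control false positives under
the null), not the linguistic adequacy of any analyzer on real forum
text. Real studies of this design work with corpora of millions of words;
the package's own experiments deliberately scale down to ~2×10^5-token
corpora, a size at which every planted effect is still comfortably
detectable: the type-I study uses 200 replicate null corpora of that
size, and keyword recovery is averaged over 20 generator seeds.

## Degenerate inputs and numerical choices

* Empty target or reference corpus at split time is a hard error —
  keyness against an empty corpus is undefined.
* A term list that normalizes to nothing is a hard error; duplicate terms
  after normalization are dropped with a warning.
* G² preconditions ($c, d > 0$, $a+b \ge 1$, $a \le c$, $b \le d$) are
  hard errors; inputs are promoted to double before the four-cell terms
  to avoid integer overflow on corpus-scale products.
* Quantile bins smaller than the requested sample are taken whole with a
  warning; all randomized operations take explicit seeds and restore the
  caller's RNG state.
* TSV fields containing tabs, quotes or newlines are quoted; `#` lines
  are metadata comments.

## Limitations

The rule-based analyzer is English-only and approximates lemmas; on real
data a study would substitute a full morphological analyzer behind the
same interface and re-record the analyzer id. The self-report pattern
family shipped is a minimal first-person battery, intended as
configuration to be extended per study, not an exhaustive inventory; no
negation handling is attempted. Assigning coding-frame categories is
human work by design — the package transports, samples and extrapolates
codes, it does not classify text.
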