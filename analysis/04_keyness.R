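#!/usr/bin/env Rscript
# Contrastive keyness: frequency tables for target and reference corpora,
# key lemmas under the G2 / overuse-ratio / user-dispersion gates, and
# absent or underused concept terms.

suppressPackageStartupMessages(library(corpusframe))

target <- read_posts("results/analysis/target.jsonl", name = "target")
reference <- read_posts("results/analysis/reference.jsonl",
                        name = "reference")
terms <- read_term_list("results/analysis/pr_terms.txt")

tt <- analyze_corpus(target)
rt <- analyze_corpus(reference)
ft <- build_frequency_table(target, tt)
fr <- build_frequency_table(reference, rt)
key <- select_key_lemmas(ft, fr, alpha = 1e-4, min_ratio = 2,
                         min_user_share = 0.05)
write_table(key, "results/analysis/keyness.tsv",
            meta = c(analyzer = ft$analyzer,
                     g2_variant = attr(key, "variant")))
message(sprintf("%d of %d lemmas key (G2 >= %.2f, ratio >= 2, >= 5%% of %d users).",
                sum(key$is_key), nrow(key), g2_critical(1e-4),
                ft$total_users))
truth_lem <- read_table("results/analysis/truth_lemmas.tsv")
message(sprintf("Planted-enriched lemmas among keys: %d / %d.",
                sum(key$lemma[key$is_key] %in% truth_lem$lemma),
                sum(key$is_key)))

absent <- find_absent_terms(terms, tt, rt)
write_table(absent$missing, "results/analysis/absent_missing.tsv")
write_table(absent$underused, "results/analysis/absent_underused.tsv")
message(sprintf("Concept terms: %d missing from the target corpus, %d underused.",
                nrow(absent$missing), nrow(absent$underused)))
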