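Package: corpusframe
Title: Corpus Framework Analysis of Online Peer-Support Forum Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a concept-relevant corpus from user-attributed forum
    posts (self-reported diagnosis cohort detection, subforum and
    condition-mention filters, TF-IDF cosine relevance ranking with decile
    calibration sampling) and contrasts it against a reference corpus of
    low-relevance posts: per-lemma log-likelihood (G2) keyness with overuse
    ratio and author-dispersion gates, absent and underused concept terms,
    KWIC concordance extraction, sorting and sampling for qualitative
    coding, extrapolation of coding-frame category frequencies, cubed
    mutual information (MI3) collocation, and Cohen's kappa inter-rater
    agreement. Includes a synthetic forum-corpus generator with planted
    ground truth (Zipfian background vocabulary, enriched concept terms,
    planted collocations, self-report disclosures) so every pipeline stage
    is testable without access-restricted social-media data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    readr,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
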