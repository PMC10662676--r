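#!/usr/bin/env Rscript
# Inter-rater agreement on relevance calibration coding. Two simulated
# coders label the calibration sample's posts: both start from the
# ground-truth relevance flag and independently flip each label with a
# fixed error rate, emulating imperfect human judgement; Cohen's kappa
# summarises their agreement.

suppressPackageStartupMessages(library(corpusframe))

cal <- read_table("results/analysis/calibration_sample.tsv")
truth <- read_table("results/analysis/truth_posts.tsv")
rel <- truth$is_relevant[match(cal$post_id, truth$post_id)]

flip <- function(labels, rate, seed) {
  withr::with_seed(seed, {
    f <- runif(length(labels)) < rate
    ifelse(f, !labels, labels)
  })
}
coder_a <- ifelse(flip(rel, 0.10, 41), "relevant", "not-relevant")
coder_b <- ifelse(flip(rel, 0.10, 42), "relevant", "not-relevant")

k <- cohen_kappa(coder_a, coder_b)
print(k)
write_table(tibble::tibble(n = k$n, po = k$po, pe = k$pe, kappa = k$kappa),
            "results/analysis/kappa.tsv")
write_table(as.data.frame(k$table), "results/analysis/kappa_confusion.tsv")
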