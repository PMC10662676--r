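#!/usr/bin/env Rscript
# KWIC concordances for the top key lemmas: extract, sort by node/left/
# right context, sample 30 lines per lemma for coding, and extrapolate
# coding-frame category frequencies from a demonstration coding. Category
# assignment is a human step in real studies; here the sampled lines are
# coded by a seeded random assignment purely to exercise the
# extrapolation interface, so the category table demonstrates mechanics,
# not substance.

suppressPackageStartupMessages(library(corpusframe))

target <- read_posts("results/analysis/target.jsonl", name = "target")
tk <- analyze_corpus(target)
ft <- build_frequency_table(target, tk)
key <- read_table("results/analysis/keyness.tsv")
frame <- read_coding_frame(
  system.file("extdata", "poetic_frame.yml", package = "corpusframe"))

top <- head(key$lemma[key$is_key], 5)
if (length(top) == 0) top <- head(key$lemma, 3)

coded_all <- list()
for (lemma in top) {
  lines <- sort_concordances(extract_concordances(tk, lemma, context = 20))
  write_table(lines, sprintf("results/analysis/kwic_%s.tsv", lemma))
  sampled <- sample_for_coding(lines, n = 30, seed = 2026)
  labels <- withr::with_seed(2026, sample(
    c(frame$categories$category, "Not-frame"), nrow(sampled),
    replace = TRUE))
  coded_all[[lemma]] <- tibble::tibble(
    lemma = lemma, line_id = sampled$line_id, labels = labels)
  message(sprintf("%s: %d occurrences, %d lines sampled for coding.",
                  lemma, nrow(lines), nrow(sampled)))
}
coded <- do.call(rbind, coded_all)
write_table(coded, "results/analysis/coded_lines.tsv")

long <- read_coded_lines("results/analysis/coded_lines.tsv", frame)
cats <- extrapolate_category_frequencies(long, ft, frame)
write_table(cats$categories, "results/analysis/category_frequencies.tsv")
write_table(cats$domains, "results/analysis/domain_frequencies.tsv")
message(sprintf(
  "Extrapolated %.0f key-lemma instances; %.0f%% outside the frame.",
  sum(cats$categories$mass),
  100 * cats$domains$mass[cats$domains$domain == "Not-frame"] /
    sum(cats$domains$mass)))
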