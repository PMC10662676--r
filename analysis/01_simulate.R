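#!/usr/bin/env Rscript
# Generate the synthetic forum corpus that stands in for the
# access-restricted forum dataset, and write the raw artifacts: posts as
# JSONL, the concept term list, and the ground-truth tables used by later
# drivers to evaluate recovery.

suppressPackageStartupMessages(library(corpusframe))
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(seed = 2026)
g <- synth_generate(cfg)

write_posts(g$corpus, "results/analysis/posts.jsonl")
write_term_list(term_list(cfg$planted_terms), "results/analysis/pr_terms.txt")
write_table(g$truth$posts, "results/analysis/truth_posts.tsv")
write_table(g$truth$users, "results/analysis/truth_users.tsv")
write_table(g$truth$lemmas, "results/analysis/truth_lemmas.tsv")

st <- corpus_stats(g$corpus)
message(sprintf(
  "Simulated %d posts (%d words) by %d users; %.0f%% relevant, %.0f%% of users disclose a diagnosis.",
  st$n_posts, st$n_words, st$n_users,
  100 * mean(g$truth$posts$is_relevant),
  100 * mean(g$truth$users$is_self_reporter)))
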