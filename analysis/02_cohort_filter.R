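#!/usr/bin/env Rscript
# Corpus construction steps 1-3: detect the self-reported diagnosis
# cohort, keep only posts in condition subforums, keep only posts that
# mention the condition. Logs the flow-chart counts and checks cohort
# detection against the generator's ground truth.

suppressPackageStartupMessages(library(corpusframe))

x <- read_posts("results/analysis/posts.jsonl", name = "synthetic")
patterns <- read_self_report_patterns(
  system.file("extdata", "self_report_patterns.yml", package = "corpusframe"))

cohort <- find_self_report_users(x, patterns)
write_table(cohort, "results/analysis/cohort_users.tsv")

truth <- read_table("results/analysis/truth_users.tsv")
agree <- length(intersect(cohort$user_id,
                          truth$user_id[truth$is_self_reporter]))
message(sprintf("Cohort: %d users detected, %d planted, %d in agreement.",
                nrow(cohort), sum(truth$is_self_reporter), agree))

step1 <- filter_users(x, cohort$user_id)
step2 <- filter_subforum(step1, c("bipolar", "bipolarsupport"))
step3 <- filter_condition_mention(step2, term_list("bipolar"))
write_posts(step3, "results/analysis/filtered.jsonl")

counts <- tibble::tibble(
  stage = c("all posts", "self-reported cohort", "condition subforums",
            "condition mention"),
  n_posts = c(nrow(x), nrow(step1), nrow(step2), nrow(step3)))
write_table(counts, "results/analysis/flowchart_counts.tsv")
message(paste(sprintf("%s: %d", counts$stage, counts$n_posts),
              collapse = " -> "))
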