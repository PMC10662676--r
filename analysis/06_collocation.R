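#!/usr/bin/env Rscript
# Collocation profiles (cubed mutual information, 5-word window, content
# words only, minimum co-occurrence 5) for the planted collocation nodes,
# checked against the generator's planted pairs.

suppressPackageStartupMessages(library(corpusframe))

target <- read_posts("results/analysis/target.jsonl", name = "target")
tk <- analyze_corpus(target)

out <- list()
for (node in c("therapy", "medication")) {
  tab <- collocates(tk, node, window = 5, min_freq = 5)
  out[[node]] <- tab
  if (nrow(tab) > 0) {
    message(sprintf("%s: top collocate '%s' (O = %d, MI3 = %.2f) of %d.",
                    node, tab$collocate[1], tab$O[1], tab$mi3[1],
                    nrow(tab)))
  }
}
write_table(do.call(rbind, out), "results/analysis/collocations.tsv")
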