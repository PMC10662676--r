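# Collocation by cubed mutual information (MI3) within a symmetric word
# window, with content-word and minimum-frequency filters.

#' Rank collocates of a node lemma by cubed mutual information
#'
#' For a node lemma with corpus frequency `f1`, each candidate collocate
#' lemma with corpus frequency `f2` is scored by
#' `MI3 = log2(O^3 / E)` with `E = f1 * f2 * W / N`, where `W = 2 * window`
#' is the window size in word positions and `N` the corpus word-token
#' count. The observed count `O` is the number of word tokens of that lemma
#' lying within `window` word positions of any node occurrence (each token
#' counted once; windows are measured over word tokens, skip punctuation,
#' and are truncated at post boundaries). Node occurrences themselves are
#' never counted as their own collocates. Rows are restricted to content
#' words (`NOUN`, `VERB`, `ADJ`, `ADV`) with `O >= min_freq`, and sorted by
#' MI3 descending with ties broken by collocate lemma. MI3 favours frequent
#' collocates over rare high-MI pairs.
#'
#' @param tokens A `cfa_tokens` table from [analyze_corpus()].
#' @param node The node lemma.
#' @param window Window half-width in words on each side (default 5).
#' @param min_freq Minimum observed co-occurrence count (default 5).
#' @return Tibble `node`, `collocate`, `pos`, `O`, `f1`, `f2`, `E`, `mi3`.
#' @export
collocates <- function(tokens, node, window = 5, min_freq = 5) {
  stopifnot(length(node) == 1, window >= 1, min_freq >= 1)
  wt <- tokens[tokens$is_word, ]
  N <- nrow(wt)
  is_node <- wt$lemma == node
  f1 <- sum(is_node)
  if (f1 == 0) {
    warning("node lemma '", node, "' does not occur in the corpus",
            call. = FALSE)
    return(tibble::tibble(node = character(), collocate = character(),
                          pos = character(), O = integer(), f1 = integer(),
                          f2 = integer(), E = numeric(), mi3 = numeric()))
  }
  # distance (in word positions, within the same post) to the nearest node
  # occurrence; word tokens are stored in post order
  near <- logical(N)
  node_idx <- which(is_node)
  for (i in node_idx) {
    lo <- max(1, i - window)
    hi <- min(N, i + window)
    rng <- lo:hi
    rng <- rng[wt$post_id[rng] == wt$post_id[i]]
    near[rng] <- TRUE
  }
  near[node_idx] <- FALSE
  cand <- wt$lemma[near]
  if (length(cand) == 0) {
    return(tibble::tibble(node = character(), collocate = character(),
                          pos = character(), O = integer(), f1 = integer(),
                          f2 = integer(), E = numeric(), mi3 = numeric()))
  }
  O <- table(cand)
  f2_all <- table(wt$lemma)
  pos_map <- wt$pos[match(names(O), wt$lemma)]
  keep <- pos_map %in% base::c("NOUN", "VERB", "ADJ", "ADV") &
    as.integer(O) >= min_freq & names(O) != node
  if (!any(keep)) {
    return(tibble::tibble(node = character(), collocate = character(),
                          pos = character(), O = integer(), f1 = integer(),
                          f2 = integer(), E = numeric(), mi3 = numeric()))
  }
  coll <- names(O)[keep]
  Ov <- as.integer(O[keep])
  f2 <- as.integer(f2_all[coll])
  W <- 2 * window
  E <- f1 * as.numeric(f2) * W / N
  mi3 <- log2(Ov^3 / E)
  out <- tibble::tibble(
    node = node, collocate = coll, pos = pos_map[keep],
    O = Ov, f1 = f1, f2 = f2, E = E, mi3 = mi3
  )
  out[order(-out$mi3, out$collocate), ]
}
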