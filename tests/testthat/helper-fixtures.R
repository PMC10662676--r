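# Shared fixture builders: everything is generated in code at test time.

# Minimal corpus from raw body texts.
mini_corpus <- function(bodies, user_id = NULL, subforum = "bipolar",
                        title = "", name = "mini") {
  n <- length(bodies)
  corpus(tibble::tibble(
    post_id = sprintf("p%03d", seq_len(n)),
    user_id = user_id %||% sprintf("u%03d", seq_len(n)),
    subforum = rep_len(subforum, n),
    created = "2018-06-01T00:00:00Z",
    title = rep_len(title, n),
    body = bodies
  ), name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random well-formed posts for round-trip properties.
random_posts <- function(n, seed = 1) {
  withr::with_seed(seed, {
    words <- c("hope", "work", "sleep", "therapy", "cat", "tree", "music")
    tibble::tibble(
      post_id = sprintf("p%04d", sample(9999, n)),
      user_id = sprintf("u%03d", sample(50, n, replace = TRUE)),
      subforum = sample(c("bipolar", "offtopic"), n, replace = TRUE),
      created = "2017-03-04T12:00:00Z",
      title = vapply(seq_len(n), function(i)
        paste(sample(words, sample(0:3, 1)), collapse = " "), character(1)),
      body = vapply(seq_len(n), function(i)
        paste(sample(words, sample(5:30, 1), replace = TRUE),
              collapse = " "), character(1))
    )
  })
}

# Small, fast synthetic config for unit tests.
small_synth_config <- function(seed = 1, ...) {
  synth_config(seed = seed, n_users = 40, posts_per_user = c(3, 6),
               words_per_post = c(30, 60), vocab_size = 500, ...)
}

# Greedy longest-match reference implementation, written independently of
# the package's candidate-sweep algorithm: walk left to right, at each
# position try term lengths longest-first.
brute_force_match <- function(lemmas, is_word, terms) {
  keys <- split(terms$term, terms$n_lemmas)
  lens <- sort(unique(terms$n_lemmas), decreasing = TRUE)
  out <- list()
  i <- 1
  n <- length(lemmas)
  while (i <= n) {
    matched <- FALSE
    for (L in lens) {
      if (i + L - 1 > n) next
      span <- i:(i + L - 1)
      if (!all(is_word[span])) next
      key <- paste(lemmas[span], collapse = " ")
      if (key %in% keys[[as.character(L)]]) {
        out[[length(out) + 1]] <- data.frame(term = key, start = i - 1L,
                                             end = i + L - 1L)
        i <- i + L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1
  }
  if (length(out) == 0) {
    return(data.frame(term = character(), start = integer(),
                      end = integer()))
  }
  do.call(rbind, out)
}

# Independent G-statistic for the 2x2 table [[a, c-a], [b, d-b]] via the
# entropy (sum-of-cells) formulation rather than observed/expected ratios.
g_stat_oracle <- function(a, b, c, d) {
  xlx <- function(v) ifelse(v > 0, v * log(v), 0)
  N <- c + d
  cells <- cbind(a, c - a, b, d - b)
  rows <- cbind(c, d)
  cols <- cbind(a + b, N - a - b)
  2 * (rowSums(xlx(cells)) - rowSums(xlx(rows)) - rowSums(xlx(cols)) +
         xlx(N))
}

# Naive reference counter: per post, mark word positions within the window
# of any node occurrence, then count unique marked tokens per lemma.
naive_collocates <- function(tokens, node, window = 5, min_freq = 5) {
  wt <- tokens[tokens$is_word, ]
  counts <- list()
  N <- 0
  f1 <- 0
  for (p in unique(wt$post_id)) {
    lem <- wt$lemma[wt$post_id == p]
    pos <- wt$pos[wt$post_id == p]
    N <- N + length(lem)
    nodes <- which(lem == node)
    f1 <- f1 + length(nodes)
    near <- rep(FALSE, length(lem))
    for (i in nodes) {
      for (j in seq_along(lem)) {
        if (j != i && abs(j - i) <= window && !(lem[j] == node)) {
          near[j] <- TRUE
        }
      }
    }
    for (j in which(near)) {
      key <- paste(lem[j], pos[j])
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  if (f1 == 0) return(NULL)
  keys <- names(counts)
  lem <- sub(" [A-Z]+$", "", keys)
  pos <- sub("^.* ", "", keys)
  O <- unlist(counts, use.names = FALSE)
  f2 <- as.integer(table(wt$lemma)[lem])
  keep <- pos %in% c("NOUN", "VERB", "ADJ", "ADV") & O >= min_freq
  df <- data.frame(collocate = lem[keep], O = O[keep], f2 = f2[keep])
  df$E <- f1 * df$f2 * 2 * window / N
  df$mi3 <- log2(df$O^3 / df$E)
  df[order(-df$mi3, df$collocate), ]
}
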