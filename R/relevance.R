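# Concept-relevance ranking: TF-IDF weighted cosine similarity of each post
# to the concept term list, decile calibration sampling, and the
# target/reference corpus split.

#' Score posts' similarity to a concept term list
#'
#' Each post is represented as a vector over term-list entries weighted
#' `tf(term, post) * idf(term)`, with raw term frequencies from
#' [match_terms()] (so multiword phrases count as units) and smoothed
#' inverse document frequency `idf = ln((1 + N)/(1 + df)) + 1` computed over
#' the scored corpus. The query vector holds the idf weights of all terms;
#' the score is the cosine of the two vectors, in `[0, 1]`, and is 0 iff
#' the post shares no term with the list. Terms occurring in no post
#' (df = 0) are dropped from the feature space with a message; they cannot
#' affect any score. The tf-idf variant is recorded in the result's
#' attributes.
#'
#' @param x A `cfa_corpus`.
#' @param terms A `cfa_term_list`.
#' @param tokens Optional precomputed [analyze_corpus()] table for `x`.
#' @return Tibble `post_id`, `score`, in corpus order, with attributes
#'   `weighting` and `analyzer`.
#' @export
score_relevance <- function(x, terms, tokens = NULL) {
  stopifnot(inherits(x, "cfa_corpus"), nrow(x) > 0,
            inherits(terms, "cfa_term_list"))
  if (is.null(tokens)) tokens <- analyze_corpus(x)
  tf <- count_terms(tokens, terms)
  n_posts <- nrow(x)
  df <- table(tf$term)
  absent <- setdiff(terms$term, names(df))
  if (length(absent) > 0) {
    message(length(absent),
            " term(s) occur in no post and are dropped from scoring")
  }
  kept <- terms$term[terms$term %in% names(df)]
  idf <- log((1 + n_posts) / (1 + as.numeric(df[kept]))) + 1
  names(idf) <- kept
  q_norm <- sqrt(sum(idf^2))
  score <- stats::setNames(rep(0, n_posts), x$post_id)
  if (nrow(tf) > 0 && q_norm > 0) {
    tf <- tf[tf$term %in% kept, ]
    w <- tf$tf * idf[tf$term]
    dot <- tapply(w * idf[tf$term], tf$post_id, sum)
    d_norm <- sqrt(tapply(w^2, tf$post_id, sum))
    score[names(dot)] <- as.numeric(dot) / (as.numeric(d_norm) * q_norm)
  }
  out <- tibble::tibble(post_id = x$post_id, score = unname(score))
  attr(out, "weighting") <- "tf.idf: raw tf, idf = ln((1+N)/(1+df)) + 1, query = idf"
  attr(out, "analyzer") <- attr(tokens, "analyzer")
  out
}

#' Sample posts from score deciles for calibration coding
#'
#' Scores are partitioned into 10 equal-count quantile bins; `per_decile`
#' post ids are sampled uniformly without replacement from each bin.
#' Consecutive bins whose scores are all identical (typically an all-zero
#' tail) are merged and contribute `per_decile` ids in total, so e.g. two
#' all-zero bottom deciles yield 90 rather than 100 sampled posts. A bin
#' smaller than `per_decile` is taken whole with a warning. Deterministic
#' under `seed`.
#'
#' @param scores Tibble `post_id`, `score` from [score_relevance()].
#' @param per_decile Posts to sample per bin (>= 1).
#' @param seed Integer RNG seed.
#' @return Character vector of sampled post ids.
#' @export
decile_sample <- function(scores, per_decile = 10, seed = 1) {
  stopifnot(per_decile >= 1, nrow(scores) >= 10)
  ord <- order(scores$score, scores$post_id)
  s <- scores$score[ord]
  ids <- scores$post_id[ord]
  n <- length(s)
  bin <- ceiling(seq_len(n) * 10 / n)
  # merge consecutive constant-score bins with equal value
  binmin <- tapply(s, bin, min)
  binmax <- tapply(s, bin, max)
  const <- binmin == binmax
  grp <- integer(10)
  grp[1] <- 1L
  for (b in 2:10) {
    merge_prev <- const[b] && const[b - 1] && binmin[b] == binmin[b - 1]
    grp[b] <- if (merge_prev) grp[b - 1] else grp[b - 1] + 1L
  }
  group <- grp[bin]
  withr::with_seed(seed, {
    unlist(lapply(sort(unique(group)), function(g) {
      pool <- ids[group == g]
      if (length(pool) < per_decile) {
        warning("quantile bin has only ", length(pool), " posts; taking all",
                call. = FALSE)
        pool
      } else {
        sample(pool, per_decile)
      }
    }), use.names = FALSE)
  })
}

#' Target/reference split configuration
#'
#' Cutoffs are strict ("above"/"below"): a post enters the target corpus iff
#' `score > upper_cutoff`, the reference corpus iff `score < lower_cutoff`,
#' and in both cases only if it has at least `min_words` words; posts in
#' between belong to neither corpus.
#'
#' @param upper_cutoff Target-corpus score cutoff (default 0.025).
#' @param lower_cutoff Reference-corpus score cutoff (default 0.013).
#' @param min_words Minimum post length in words (default 94).
#' @return A `cfa_split_config`.
#' @export
split_config <- function(upper_cutoff = 0.025, lower_cutoff = 0.013,
                         min_words = 94) {
  stopifnot(0 <= lower_cutoff, lower_cutoff < upper_cutoff, min_words >= 0)
  structure(list(upper_cutoff = upper_cutoff, lower_cutoff = lower_cutoff,
                 min_words = min_words), class = "cfa_split_config")
}

#' Split a scored corpus into target and reference corpora
#'
#' @param x A `cfa_corpus`.
#' @param scores Tibble `post_id`, `score` covering every post of `x`.
#' @param cfg A [split_config()].
#' @param tokens Optional precomputed token table (for word counts).
#' @return List with `target` and `reference` corpora (disjoint). An empty
#'   target or reference corpus is a hard error, since keyness against an
#'   empty corpus is undefined.
#' @export
split_corpus <- function(x, scores, cfg = split_config(), tokens = NULL) {
  stopifnot(inherits(x, "cfa_corpus"), inherits(cfg, "cfa_split_config"))
  if (!all(x$post_id %in% scores$post_id)) {
    stop("every post must be scored before splitting", call. = FALSE)
  }
  sc <- scores$score[match(x$post_id, scores$post_id)]
  nw <- if (is.null(tokens)) {
    word_count(post_text(x))
  } else {
    wt <- table(factor(tokens$post_id[tokens$is_word], levels = x$post_id))
    as.integer(wt)
  }
  long <- nw >= cfg$min_words
  in_target <- long & sc > cfg$upper_cutoff
  in_ref <- long & sc < cfg$lower_cutoff
  if (!any(in_target)) stop("target corpus is empty", call. = FALSE)
  if (!any(in_ref)) stop("reference corpus is empty", call. = FALSE)
  list(
    target = corpus(x[in_target, ], name = paste0(corpus_name(x), "-target")),
    reference = corpus(x[in_ref, ], name = paste0(corpus_name(x), "-reference"))
  )
}
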