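# Contrastive keyness: per-lemma frequency tables, the log-likelihood (G2)
# keyword statistic, overuse ratio with zero-cell smoothing, the key-lemma
# selection gate (significance x overuse x author dispersion), and
# absent/underused concept terms.

#' Build a per-lemma frequency table
#'
#' Counts lemma occurrences over word tokens only, plus the number of posts
#' (`doc_freq`) and distinct authors (`user_freq`) using each lemma, and
#' corpus totals. The lemma is the counting unit for all keyness
#' statistics.
#'
#' @param x A `cfa_corpus`.
#' @param tokens Optional precomputed [analyze_corpus()] table for `x`.
#' @return A `cfa_freq_table`: list with `table` (tibble `lemma`, `freq`,
#'   `doc_freq`, `user_freq`), `total_tokens`, `total_posts`,
#'   `total_users`, `name`, `analyzer`.
#' @export
build_frequency_table <- function(x, tokens = NULL) {
  stopifnot(inherits(x, "cfa_corpus"))
  if (nrow(x) == 0) stop("cannot build a frequency table for an empty corpus",
                         call. = FALSE)
  if (is.null(tokens)) tokens <- analyze_corpus(x)
  wt <- tokens[tokens$is_word, c("post_id", "lemma")]
  dt <- data.table::data.table(
    lemma = wt$lemma, post_id = wt$post_id,
    user_id = x$user_id[match(wt$post_id, x$post_id)]
  )
  freq <- dt[, .(freq = .N, doc_freq = uniqueN(post_id),
                 user_freq = uniqueN(user_id)), by = lemma]
  data.table::setorder(freq, -freq, lemma)
  structure(list(
    table = tibble::as_tibble(freq),
    total_tokens = nrow(wt),
    total_posts = nrow(x),
    total_users = length(unique(x$user_id)),
    name = corpus_name(x),
    analyzer = attr(tokens, "analyzer")
  ), class = "cfa_freq_table")
}

#' @export
print.cfa_freq_table <- function(x, ...) {
  cat(sprintf(
    "<cfa_freq_table '%s'> %d lemmas, %d tokens, %d posts, %d users\n",
    x$name, nrow(x$table), x$total_tokens, x$total_posts, x$total_users))
  invisible(x)
}

#' Log-likelihood keyness statistic (G2)
#'
#' Compares the frequency `a` of a lemma in a target corpus of `c` word
#' tokens with its frequency `b` in a reference corpus of `d` word tokens.
#' The default `"4cell"` variant is the exact likelihood-ratio statistic of
#' the 2x2 contingency table `[[a, c-a], [b, d-b]]` (word vs all other
#' words, target vs reference), the form whose null distribution is
#' chi-square with 1 df. The `"2cell"` variant is the truncated two-term
#' form used by several corpus-linguistics tools,
#' `2 (a ln(a/E1) + b ln(b/E2))` with `E1 = c(a+b)/(c+d)`,
#' `E2 = d(a+b)/(c+d)`; it omits the other-words cells and is slightly
#' smaller. Both use the convention `0 ln 0 = 0`, are symmetric under
#' swapping `(a, c)` with `(b, d)`, and are 0 iff `a/c = b/d`. All
#' arguments are vectorized.
#'
#' @param a,b Lemma frequency in the target / reference corpus.
#' @param c,d Total word tokens in the target / reference corpus.
#' @param variant `"4cell"` (default) or `"2cell"`.
#' @return Numeric vector of non-negative G2 values.
#' @export
log_likelihood <- function(a, b, c, d, variant = "4cell") {
  # NB: the formal `c` masks base::c inside this function
  variant <- match.arg(variant, base::c("4cell", "2cell"))
  if (any(c <= 0) || any(d <= 0)) stop("corpus sizes must be positive",
                                       call. = FALSE)
  if (any(a + b < 1)) stop("a + b must be at least 1", call. = FALSE)
  if (any(a > c) || any(b > d)) stop("frequencies cannot exceed corpus sizes",
                                     call. = FALSE)
  if (any(a < 0) || any(b < 0)) stop("frequencies must be non-negative",
                                     call. = FALSE)
  # double arithmetic: integer inputs overflow in the other-words cells
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- c + d
  e1 <- c * (a + b) / N
  e2 <- d * (a + b) / N
  xlx <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  g <- 2 * (xlx(a, e1) + xlx(b, e2))
  if (variant == "4cell") {
    e3 <- c * (N - a - b) / N
    e4 <- d * (N - a - b) / N
    g <- g + 2 * (xlx(c - a, e3) + xlx(d - b, e4))
  }
  pmax(g, 0)
}

#' Overuse ratio (relative-frequency ratio)
#'
#' `(a/c) / (b/d)`; when the reference count `b` is 0 the zero cell alone
#' is smoothed to 0.5 so the ratio is finite: `(a/c) / (0.5/d)`. A lemma
#' absent from the target (`a = 0`) has ratio 0 and can never be key.
#' Vectorized.
#'
#' @inheritParams log_likelihood
#' @return Numeric vector of ratios.
#' @export
overuse_ratio <- function(a, b, c, d) {
  ifelse(a == 0, 0, (a / c) / (ifelse(b == 0, 0.5, b) / d))
}

#' G2 critical value for a significance level
#'
#' The chi-square(1) upper quantile: a lemma's G2 must exceed this for its
#' overuse to be significant at `alpha`.
#'
#' @param alpha Significance level (default 1e-4).
#' @return Scalar critical value (about 15.14 at alpha = 1e-4).
#' @export
g2_critical <- function(alpha = 1e-4) stats::qchisq(1 - alpha, df = 1)

#' Select key lemmas by contrastive keyness
#'
#' One result row per lemma in the union vocabulary of the two corpora. A
#' lemma is key iff it is overused in the target (`a/c > b/d`) with an
#' overuse ratio of at least `min_ratio`, its G2 exceeds the chi-square(1)
#' critical value at `alpha`, and it is used by at least `min_user_share`
#' of the target corpus' authors (dispersion gate: one prolific author
#' cannot make a lemma key).
#'
#' @param target,reference `cfa_freq_table`s built from disjoint corpora
#'   with the same analyzer.
#' @param alpha Significance level for the G2 gate (default 1e-4).
#' @param min_ratio Minimum overuse ratio (default 2).
#' @param min_user_share Minimum share of target-corpus users (default 0.05).
#' @param variant G2 variant, see [log_likelihood()].
#' @return A tibble (`cfa_keyness`) with columns `lemma`, `a`, `b`, `c`,
#'   `d`, `ratio`, `g2`, `significant`, `user_share`, `is_key`, sorted by
#'   `g2` descending with ties broken by lemma.
#' @export
select_key_lemmas <- function(target, reference, alpha = 1e-4, min_ratio = 2,
                              min_user_share = 0.05, variant = "4cell") {
  stopifnot(inherits(target, "cfa_freq_table"),
            inherits(reference, "cfa_freq_table"))
  if (!identical(target$analyzer, reference$analyzer)) {
    stop("frequency tables were built with different analyzers",
         call. = FALSE)
  }
  vocab <- union(target$table$lemma, reference$table$lemma)
  a <- target$table$freq[match(vocab, target$table$lemma)]
  a[is.na(a)] <- 0
  b <- reference$table$freq[match(vocab, reference$table$lemma)]
  b[is.na(b)] <- 0
  uf <- target$table$user_freq[match(vocab, target$table$lemma)]
  uf[is.na(uf)] <- 0
  cc <- target$total_tokens
  dd <- reference$total_tokens
  g2 <- log_likelihood(a, b, cc, dd, variant = variant)
  ratio <- overuse_ratio(a, b, cc, dd)
  user_share <- uf / target$total_users
  crit <- g2_critical(alpha)
  overused <- a / cc > b / dd
  res <- tibble::tibble(
    lemma = vocab, a = a, b = b, c = cc, d = dd,
    ratio = ratio, g2 = g2,
    significant = g2 >= crit,
    user_share = user_share,
    is_key = overused & ratio >= min_ratio & g2 >= crit &
      user_share >= min_user_share
  )
  res <- res[order(-res$g2, res$lemma), ]
  structure(res, alpha = alpha, min_ratio = min_ratio,
            min_user_share = min_user_share, variant = variant,
            analyzer = target$analyzer,
            class = c("cfa_keyness", class(tibble::tibble())))
}

#' Find absent and underused concept terms
#'
#' A term is *missing* if it never occurs in the target corpus, and
#' *underused* if it occurs but with a lower relative frequency than in the
#' reference corpus; the two lists are disjoint. Multiword term frequencies
#' are counts of non-overlapping [match_terms()] spans, so the inputs are
#' the analyzed token tables of the two corpora rather than lemma-keyed
#' frequency tables.
#'
#' @param terms A `cfa_term_list` (deduplicated by construction).
#' @param target_tokens,reference_tokens Token tables from
#'   [analyze_corpus()] for the target and reference corpora.
#' @return List with tibbles `missing` (`term`, `freq_ref`) and `underused`
#'   (`term`, `freq_target`, `freq_ref`, `rel_target`, `rel_ref`).
#' @export
find_absent_terms <- function(terms, target_tokens, reference_tokens) {
  stopifnot(inherits(terms, "cfa_term_list"))
  ct <- count_terms(target_tokens, terms)
  cr <- count_terms(reference_tokens, terms)
  ft <- tapply(ct$tf, ct$term, sum)
  fr <- tapply(cr$tf, cr$term, sum)
  f_t <- as.numeric(ft[terms$term]); f_t[is.na(f_t)] <- 0
  f_r <- as.numeric(fr[terms$term]); f_r[is.na(f_r)] <- 0
  Ct <- sum(target_tokens$is_word)
  Cr <- sum(reference_tokens$is_word)
  rel_t <- f_t / Ct
  rel_r <- f_r / Cr
  missing <- terms$term[f_t == 0]
  under <- f_t > 0 & rel_t < rel_r
  list(
    missing = tibble::tibble(term = missing,
                             freq_ref = f_r[f_t == 0]),
    underused = tibble::tibble(
      term = terms$term[under], freq_target = f_t[under],
      freq_ref = f_r[under], rel_target = rel_t[under],
      rel_ref = rel_r[under]
    )
  )
}
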