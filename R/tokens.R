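# Corpus-level token layer and multiword term matching.

#' Analyze every post of a corpus
#'
#' Runs the analyzer over each post's analysis text (title + newline +
#' body) and stacks the results. Token indices are 0-based within each
#' post; `word_idx` numbers word tokens only (0-based, NA for non-words)
#' and is the coordinate used by concordance and collocation windows.
#'
#' @param x A `cfa_corpus`.
#' @param analyzer Analyzer, see [default_analyzer()].
#' @return A `cfa_tokens` tibble: `post_id`, `token_idx`, `word_idx`,
#'   `surface`, `lemma`, `pos`, `is_word`.
#' @export
analyze_corpus <- function(x, analyzer = default_analyzer()) {
  stopifnot(inherits(x, "cfa_corpus"))
  texts <- post_text(x)
  raw <- stringr::str_extract_all(texts, .token_pattern)
  nt <- lengths(raw)
  flat <- classify_tokens(unlist(raw, use.names = FALSE))
  post_id <- rep(x$post_id, nt)
  token_idx <- sequence(nt) - 1L
  word_idx <- rep(NA_integer_, nrow(flat))
  if (nrow(flat) > 0) {
    w <- flat$is_word
    word_idx[w] <- as.integer(
      stats::ave(rep(1L, sum(w)), post_id[w], FUN = cumsum)) - 1L
  }
  out <- tibble::tibble(
    post_id = post_id, token_idx = token_idx, word_idx = word_idx,
    surface = flat$surface, lemma = flat$lemma, pos = flat$pos,
    is_word = flat$is_word
  )
  structure(out, analyzer = analyzer_id(analyzer),
            corpus_name = corpus_name(x),
            class = c("cfa_tokens", class(tibble::tibble())))
}

# Restrict a token table to the posts of a (sub)corpus, preserving attrs.
subset_tokens <- function(tokens, post_ids) {
  out <- tokens[tokens$post_id %in% post_ids, ]
  attributes(out)$analyzer <- attr(tokens, "analyzer")
  out
}

#' Match concept terms in a token sequence
#'
#' Greedy left-to-right longest-match of term lemma sequences over the
#' token stream: at each position the longest matching term wins and
#' matching resumes after its span, so matched spans never overlap.
#' Multiword spans must consist of contiguous word tokens; any intervening
#' non-word token breaks the span.
#'
#' @param tokens A token table from [analyze()] or [analyze_corpus()].
#' @param terms A `cfa_term_list`.
#' @return Tibble with `post_id` (if present in input), `term`, `start`,
#'   `end`: 0-based, end-exclusive token indices into the post's token
#'   sequence.
#' @export
match_terms <- function(tokens, terms) {
  stopifnot(inherits(terms, "cfa_term_list"))
  single <- !("post_id" %in% names(tokens))
  if (single) {
    tokens <- tibble::tibble(
      post_id = "<post>", token_idx = seq_len(nrow(tokens)) - 1L,
      lemma = tokens$lemma, is_word = tokens$is_word
    )
  }
  out <- match_terms_impl(tokens, terms)
  if (single) out$post_id <- NULL
  out
}

match_terms_impl <- function(tokens, terms) {
  n <- nrow(tokens)
  empty <- tibble::tibble(post_id = character(), term = character(),
                          start = integer(), end = integer())
  if (n == 0) return(empty)
  lens <- sort(unique(terms$n_lemmas))
  lem <- tokens$lemma
  isw <- tokens$is_word
  pid <- tokens$post_id
  cand <- list()
  for (L in lens) {
    keys_L <- terms$term[terms$n_lemmas == L]
    if (L == 1) {
      hit <- which(isw & lem %in% keys_L)
      if (length(hit) > 0) {
        cand[[length(cand) + 1]] <- data.frame(
          row = hit, len = 1L, term = lem[hit], stringsAsFactors = FALSE)
      }
    } else {
      if (n < L) next
      idx <- seq_len(n - L + 1)
      ok <- rep(TRUE, length(idx))
      key <- lem[idx]
      for (k in 1:(L - 1)) {
        ok <- ok & isw[idx + k] & (pid[idx + k] == pid[idx])
        key <- paste(key, lem[idx + k])
      }
      ok <- ok & isw[idx]
      hit <- which(ok & key %in% keys_L)
      if (length(hit) > 0) {
        cand[[length(cand) + 1]] <- data.frame(
          row = hit, len = L, term = key[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$row, -cand$len), , drop = FALSE]
  # greedy sweep, restarted at post boundaries
  keep <- logical(nrow(cand))
  cur_post <- ""
  cur_end <- 0L
  for (i in seq_len(nrow(cand))) {
    p <- pid[cand$row[i]]
    if (p != cur_post) { cur_post <- p; cur_end <- 0L }
    if (cand$row[i] >= cur_end) {
      keep[i] <- TRUE
      cur_end <- cand$row[i] + cand$len[i]
    }
  }
  cand <- cand[keep, , drop = FALSE]
  tibble::tibble(
    post_id = pid[cand$row],
    term = cand$term,
    start = tokens$token_idx[cand$row],
    end = tokens$token_idx[cand$row] + cand$len
  )
}

#' Per-post concept term counts
#'
#' Counts non-overlapping term matches ([match_terms()]) per post; the
#' term-frequency input to relevance scoring and absent-term analysis.
#'
#' @inheritParams match_terms
#' @return Tibble `post_id`, `term`, `tf` (one row per post-term pair with
#'   tf > 0).
#' @export
count_terms <- function(tokens, terms) {
  m <- match_terms_impl(tokens, terms)
  if (nrow(m) == 0) {
    return(tibble::tibble(post_id = character(), term = character(),
                          tf = integer()))
  }
  dt <- data.table::as.data.table(m)[, .(tf = .N), by = .(post_id, term)]
  tibble::as_tibble(dt)
}
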