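# Core containers: corpus of posts, term lists, coding frames.

.post_fields <- c("post_id", "user_id", "subforum", "created", "title", "body")

#' Construct a corpus of forum posts
#'
#' A corpus is a tibble of posts with the six required columns `post_id`,
#' `user_id`, `subforum`, `created` (ISO-8601 UTC string, provenance only),
#' `title` (may be empty) and `body`, carrying a corpus name attribute. The
#' analysis text of a post is its title and body joined by a single newline,
#' title first.
#'
#' @param posts Data frame with the six post columns.
#' @param name Corpus name used in derived tables.
#' @return A `cfa_corpus` (tibble subclass).
#' @export
corpus <- function(posts, name = "corpus") {
  posts <- tibble::as_tibble(posts)
  missing_cols <- setdiff(.post_fields, names(posts))
  if (length(missing_cols) > 0) {
    stop("corpus is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  posts <- posts[, .post_fields]
  for (col in .post_fields) posts[[col]] <- as.character(posts[[col]])
  if (anyDuplicated(posts$post_id)) {
    stop("duplicate post_id values in corpus", call. = FALSE)
  }
  if (any(is.na(posts$user_id) | posts$user_id == "")) {
    stop("every post must have a non-empty user_id", call. = FALSE)
  }
  structure(posts, name = name,
            class = c("cfa_corpus", class(tibble::tibble())))
}

corpus_name <- function(x) attr(x, "name") %||% "corpus"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analysis text of each post (title + newline + body)
#' @param x A `cfa_corpus`.
#' @return Character vector, one element per post.
#' @export
post_text <- function(x) paste(x$title, x$body, sep = "\n")

#' Corpus summary counts
#'
#' Word count is the sum of per-post word counts (words as defined by the
#' analyzer); user count is the number of distinct authors. Both are pure
#' functions of content, independent of post order.
#'
#' @param x A `cfa_corpus`.
#' @param tokens Optional precomputed token table from [analyze_corpus()].
#' @return A tibble with `name`, `n_posts`, `n_words`, `n_users`.
#' @export
corpus_stats <- function(x, tokens = NULL) {
  n_words <- if (is.null(tokens)) {
    sum(word_count(post_text(x)))
  } else {
    sum(tokens$is_word)
  }
  tibble::tibble(
    name = corpus_name(x), n_posts = nrow(x),
    n_words = n_words, n_users = length(unique(x$user_id))
  )
}

#' @export
print.cfa_corpus <- function(x, ...) {
  cat(sprintf("<cfa_corpus '%s'> %d posts by %d users\n",
              corpus_name(x), nrow(x), length(unique(x$user_id))))
  NextMethod()
}

#' Build a concept term list
#'
#' Terms (single words or multiword phrases) are lowercased and
#' lemma-normalized with the analyzer; terms that collapse to the same lemma
#' sequence after normalization (spelling or inflectional variants) are
#' dropped with a warning, keeping the first occurrence.
#'
#' @param terms Character vector, one term per element.
#' @param analyzer Analyzer, see [default_analyzer()].
#' @return A `cfa_term_list`: tibble with `term` (original string), `lemmas`
#'   (list of lemma vectors) and `n_lemmas`.
#' @export
term_list <- function(terms, analyzer = default_analyzer()) {
  terms <- trimws(terms)
  terms <- terms[terms != ""]
  if (length(terms) == 0) stop("term list is empty", call. = FALSE)
  lemmas <- lapply(terms, function(t) {
    tk <- analyze(t, analyzer)
    tk$lemma[tk$is_word]
  })
  ok <- lengths(lemmas) > 0
  terms <- terms[ok]; lemmas <- lemmas[ok]
  key <- vapply(lemmas, paste, character(1), collapse = " ")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate term(s) after lemma normalization dropped: ",
            paste(unique(terms[dup]), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    term = key[!dup],
    lemmas = lemmas[!dup],
    n_lemmas = lengths(lemmas[!dup])
  )
  structure(out, analyzer = analyzer_id(analyzer),
            class = c("cfa_term_list", class(tibble::tibble())))
}

#' @export
print.cfa_term_list <- function(x, ...) {
  cat(sprintf("<cfa_term_list> %d terms (%d multiword)\n",
              nrow(x), sum(x$n_lemmas > 1)))
  NextMethod()
}

#' Construct a coding frame
#'
#' A two-level category hierarchy: ordered first-level domains, each owning
#' one or more second-level categories. Concordance lines that do not fit
#' the frame may be labelled with the reserved category `"Not-frame"`.
#'
#' @param domains Named list: domain name -> character vector of categories.
#' @return A `cfa_coding_frame` with `domains` and a `categories` tibble.
#' @export
coding_frame <- function(domains) {
  stopifnot(is.list(domains), length(domains) > 0, !is.null(names(domains)))
  cats <- tibble::tibble(
    category = unlist(domains, use.names = FALSE),
    domain = rep(names(domains), lengths(domains))
  )
  if (anyDuplicated(cats$category)) {
    stop("each category must belong to exactly one domain", call. = FALSE)
  }
  structure(list(domains = names(domains), categories = cats),
            class = "cfa_coding_frame")
}

#' @export
print.cfa_coding_frame <- function(x, ...) {
  cat(sprintf("<cfa_coding_frame> %d domains, %d categories\n",
              length(x$domains), nrow(x$categories)))
  invisible(x)
}

frame_labels <- function(frame) c(frame$categories$category, "Not-frame")
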