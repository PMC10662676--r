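# Cohort construction: self-reported diagnosis detection, subforum and
# condition-mention filters. The three filters have set-intersection
# semantics: each is idempotent, order-stable, and they commute.

#' Self-report pattern set
#'
#' Templates contain a `{DX}` slot filled with each diagnosis synonym;
#' matching is surface-level, case-insensitive, whitespace-flexible, and
#' anchored at word boundaries, so a first-person template like
#' `"I was diagnosed with {DX}"` does not fire on
#' `"my friend was diagnosed with ..."`.
#'
#' @param templates Character vector of templates with a `{DX}` slot.
#' @param dx_synonyms Character vector of diagnosis synonyms.
#' @return A `cfa_self_report_patterns` object.
#' @export
self_report_patterns <- function(templates, dx_synonyms) {
  stopifnot(length(templates) >= 1, length(dx_synonyms) >= 1)
  expanded <- unlist(lapply(templates, function(tpl) {
    vapply(dx_synonyms, function(dx) sub("{DX}", dx, tpl, fixed = TRUE),
           character(1))
  }), use.names = FALSE)
  regex <- vapply(expanded, function(p) {
    words <- strsplit(trimws(p), "\\s+")[[1]]
    paste0("(?i)\\b", paste(vapply(words, escape_regex, character(1)),
                            collapse = "\\s+"), "\\b")
  }, character(1), USE.NAMES = FALSE)
  structure(list(templates = templates, dx_synonyms = dx_synonyms,
                 phrases = expanded, regex = regex),
            class = "cfa_self_report_patterns")
}

escape_regex <- function(x) gsub("([][^$.|?*+(){}\\\\])", "\\\\\\1", x)

#' Default self-report pattern family
#'
#' A small first-person disclosure family ("I was diagnosed with
#' <condition>" and close variants). The full pattern battery used to build
#' large self-reported-diagnosis cohorts is study-specific configuration;
#' supply your own via [self_report_patterns()].
#'
#' @param dx_synonyms Diagnosis synonyms; defaults to bipolar disorder.
#' @return A `cfa_self_report_patterns` object.
#' @export
default_self_report_patterns <- function(
    dx_synonyms = c("bipolar disorder", "bipolar", "bd", "manic depression")) {
  self_report_patterns(
    templates = c(
      "I was diagnosed with {DX}",
      "I have been diagnosed with {DX}",
      "I am diagnosed with {DX}",
      "I got diagnosed with {DX}",
      "my {DX} diagnosis"
    ),
    dx_synonyms = dx_synonyms
  )
}

#' Read self-report patterns from a YAML config
#'
#' The file has two keys, `templates` (with `{DX}` slots) and
#' `dx_synonyms`. The package ships a default at
#' `system.file("extdata", "self_report_patterns.yml", package =
#' "corpusframe")`.
#'
#' @param path Path to a YAML pattern config.
#' @return A `cfa_self_report_patterns` object.
#' @export
read_self_report_patterns <- function(path) {
  cfg <- yaml::read_yaml(path)
  self_report_patterns(cfg$templates, cfg$dx_synonyms)
}

#' Identify users with a self-reported diagnosis
#'
#' A user is included iff at least one of their posts matches at least one
#' pattern. The first matching span per user is recorded as audit evidence.
#'
#' @param x A `cfa_corpus`.
#' @param patterns A `cfa_self_report_patterns` object.
#' @return Tibble with one row per included user: `user_id`, `post_id`,
#'   `phrase` (the pattern that fired) and `evidence` (matched text).
#' @export
find_self_report_users <- function(x, patterns) {
  stopifnot(inherits(x, "cfa_corpus"))
  if (!inherits(patterns, "cfa_self_report_patterns") ||
      length(patterns$regex) == 0) {
    stop("a non-empty self-report pattern set is required", call. = FALSE)
  }
  texts <- post_text(x)
  seen <- character(0)
  rows <- list()
  for (j in seq_along(patterns$regex)) {
    hits <- which(stringr::str_detect(texts, patterns$regex[j]))
    hits <- hits[!(x$user_id[hits] %in% seen)]
    if (length(hits) == 0) next
    first <- hits[!duplicated(x$user_id[hits])]
    ev <- stringr::str_extract(texts[first], patterns$regex[j])
    rows[[length(rows) + 1]] <- tibble::tibble(
      user_id = x$user_id[first], post_id = x$post_id[first],
      phrase = patterns$phrases[j], evidence = ev
    )
    seen <- c(seen, x$user_id[first])
  }
  if (length(rows) == 0) {
    return(tibble::tibble(user_id = character(), post_id = character(),
                          phrase = character(), evidence = character()))
  }
  out <- do.call(rbind, rows)
  out[order(match(out$user_id, x$user_id)), ]
}

#' Keep only posts by the given users
#' @param x A `cfa_corpus`.
#' @param user_ids Character vector of user ids to keep.
#' @return Filtered `cfa_corpus`, order preserved.
#' @export
filter_users <- function(x, user_ids) {
  corpus(x[x$user_id %in% user_ids, ], name = corpus_name(x))
}

#' Keep only posts in the given subforums
#' @param x A `cfa_corpus`.
#' @param allowed Non-empty character vector of subforum names.
#' @return Filtered `cfa_corpus`, order preserved.
#' @export
filter_subforum <- function(x, allowed) {
  stopifnot(inherits(x, "cfa_corpus"))
  if (length(allowed) == 0) {
    stop("'allowed' subforum set must be non-empty", call. = FALSE)
  }
  corpus(x[x$subforum %in% allowed, ], name = corpus_name(x))
}

#' Keep only posts mentioning the condition
#'
#' A post is kept iff it has at least one [match_terms()] hit against the
#' condition term list (lemma-level, so inflected mentions count).
#'
#' @param x A `cfa_corpus`.
#' @param condition_terms A `cfa_term_list` naming the condition.
#' @param tokens Optional precomputed [analyze_corpus()] table for `x`.
#' @return Filtered `cfa_corpus`, order preserved.
#' @export
filter_condition_mention <- function(x, condition_terms, tokens = NULL) {
  stopifnot(inherits(x, "cfa_corpus"), nrow(condition_terms) > 0)
  if (is.null(tokens)) tokens <- analyze_corpus(x)
  m <- match_terms_impl(tokens, condition_terms)
  corpus(x[x$post_id %in% unique(m$post_id), ], name = corpus_name(x))
}
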