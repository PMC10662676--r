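# Pipeline artifact I/O: posts as JSONL, term lists as plain text, coding
# frames as YAML, all tabular outputs as TSV with '#' metadata comments.

#' Read posts from a JSONL file
#'
#' One JSON object per line with keys `post_id`, `user_id`, `subforum`,
#' `created`, `title`, `body`; unknown keys are ignored. Input order is
#' preserved. A record missing a required field is a hard error naming the
#' field and line number.
#'
#' @param path Path to a JSONL file.
#' @param name Corpus name; defaults to the file name.
#' @return A `cfa_corpus`.
#' @export
read_posts <- function(path, name = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty posts file: ", path, call. = FALSE)
    empty <- stats::setNames(
      as.data.frame(matrix(character(), 0, length(.post_fields))),
      .post_fields)
    return(corpus(empty, name = name))
  }
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) {
                      stop("malformed JSON on line ", i, " of ", path, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    absent <- setdiff(.post_fields, names(rec))
    if (length(absent) > 0) {
      stop("record on line ", i, " of ", path, " is missing field(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    recs[[i]] <- vapply(.post_fields, function(f) as.character(rec[[f]]),
                        character(1))
  }
  df <- tibble::as_tibble(do.call(rbind, recs))
  corpus(df, name = name)
}

#' Write posts to a JSONL file
#'
#' Inverse of [read_posts()]: one JSON object per line with exactly the six
#' post keys, UTF-8, newline-terminated.
#'
#' @param x A `cfa_corpus`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_posts <- function(x, path) {
  stopifnot(inherits(x, "cfa_corpus"))
  lines <- vapply(seq_len(nrow(x)), function(i) {
    as.character(jsonlite::toJSON(as.list(x[i, .post_fields]),
                                  auto_unbox = TRUE))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a concept term list from plain text
#'
#' One term per line; `#` starts a comment line; blank lines ignored. Terms
#' are lowercased and lemma-normalized, duplicates after normalization
#' dropped with a warning ([term_list()]).
#'
#' @inheritParams read_posts
#' @param analyzer Analyzer used for normalization.
#' @return A `cfa_term_list`.
#' @export
read_term_list <- function(path, analyzer = default_analyzer()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    stop("term list file has no terms: ", path, call. = FALSE)
  }
  tl <- term_list(lines, analyzer)
  message(nrow(tl), " unique terms read from ", path)
  tl
}

#' Write a term list
#' @param x A `cfa_term_list`.
#' @param path Output path.
#' @export
write_term_list <- function(x, path) {
  writeLines(x$term, path, useBytes = TRUE)
  invisible(path)
}

#' Write a table as TSV
#'
#' Header row first, UTF-8, newline-terminated; fields containing tabs,
#' quotes or newlines are quoted. Optional metadata (e.g. the analyzer id)
#' is written as leading `#` comment lines that [read_table()] skips.
#'
#' @param records Data frame.
#' @param path Output path.
#' @param meta Optional named character vector written as `# key: value`.
#' @export
write_table <- function(records, path, meta = NULL) {
  records <- as.data.frame(records)
  listish <- vapply(records, is.list, logical(1))
  for (col in names(records)[listish]) {
    records[[col]] <- vapply(records[[col]], paste, character(1),
                             collapse = " ")
  }
  # quote character fields containing the delimiter, quotes or newlines
  chr <- vapply(records, is.character, logical(1))
  for (col in names(records)[chr]) {
    v <- records[[col]]
    bad <- !is.na(v) & grepl("[\t\n\"]", v)
    v[bad] <- paste0('"', gsub('"', '""', v[bad]), '"')
    records[[col]] <- v
  }
  if (!is.null(meta)) {
    writeLines(paste0("# ", names(meta), ": ", unname(meta)), path,
               useBytes = TRUE)
    readr::write_tsv(records, path, append = TRUE, col_names = TRUE,
                     quote = "none", escape = "none")
  } else {
    readr::write_tsv(records, path, quote = "none", escape = "none")
  }
  invisible(path)
}

#' Read a TSV table written by [write_table()]
#' @param path Input path.
#' @return A tibble; `#` comment lines are skipped.
#' @export
read_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read a coding frame from YAML
#'
#' The file maps each first-level domain to a list of second-level
#' categories.
#'
#' @inheritParams read_posts
#' @return A `cfa_coding_frame`.
#' @export
read_coding_frame <- function(path) {
  coding_frame(yaml::read_yaml(path))
}

#' Read coded concordance labels
#'
#' TSV interface for the human coding step: columns `lemma`, `line_id` and
#' `labels` (comma-separated category names). Returns one row per
#' (lemma, line, label).
#'
#' @inheritParams read_posts
#' @param frame Optional `cfa_coding_frame`; if given, labels are validated
#'   against it (`"Not-frame"` always allowed).
#' @return Tibble with columns `lemma`, `line_id`, `label`.
#' @export
read_coded_lines <- function(path, frame = NULL) {
  df <- read_table(path)
  stopifnot(all(c("lemma", "line_id", "labels") %in% names(df)))
  labs <- strsplit(as.character(df$labels), ",[ ]*")
  out <- tibble::tibble(
    lemma = rep(df$lemma, lengths(labs)),
    line_id = rep(df$line_id, lengths(labs)),
    label = trimws(unlist(labs))
  )
  if (!is.null(frame)) {
    bad <- setdiff(unique(out$label), frame_labels(frame))
    if (length(bad) > 0) {
      stop("coded labels not in the coding frame: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  out
}
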