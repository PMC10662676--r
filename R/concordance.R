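# KWIC concordancing: extraction, node/left/right sorting, random sampling
# for qualitative coding, and extrapolation of coding-frame category
# frequencies from the coded sample to full corpus frequencies.

#' Extract KWIC concordance lines for a lemma
#'
#' One line per occurrence of the lemma among word tokens, with up to
#' `context` words of left and right context (word tokens only,
#' truncated at post boundaries). Line ids are stable identifiers
#' `<post_id>:<token_idx>`.
#'
#' @param tokens A `cfa_tokens` table from [analyze_corpus()].
#' @param lemma The node lemma to search for.
#' @param context Context width in words on each side (default 20).
#' @return Tibble (`cfa_concordance`): `line_id`, `post_id`, `node_lemma`,
#'   `node_surface`, `node_start`, `node_end` (0-based, end-exclusive token
#'   indices), `left`, `right` (space-joined word surfaces).
#' @export
extract_concordances <- function(tokens, lemma, context = 20) {
  stopifnot(length(lemma) == 1, context >= 0)
  wt <- tokens[tokens$is_word, ]
  hit <- which(wt$lemma == lemma)
  if (length(hit) == 0) {
    warning("lemma '", lemma, "' does not occur in the corpus",
            call. = FALSE)
    out <- tibble::tibble(
      line_id = character(), post_id = character(), node_lemma = character(),
      node_surface = character(), node_start = integer(),
      node_end = integer(), left = character(), right = character()
    )
    return(structure(out, class = base::c("cfa_concordance",
                                          class(tibble::tibble()))))
  }
  # word tokens are stored in post order, so a same-post window is a
  # contiguous slice of wt
  lines <- lapply(hit, function(i) {
    p <- wt$post_id[i]
    lo <- max(1, i - context)
    hi <- min(nrow(wt), i + context)
    lw <- if (i - 1 >= lo) {
      idx <- seq(lo, i - 1)
      wt$surface[idx][wt$post_id[idx] == p]
    } else character(0)
    rw <- if (i + 1 <= hi) {
      idx <- seq(i + 1, hi)
      wt$surface[idx][wt$post_id[idx] == p]
    } else character(0)
    tibble::tibble(
      line_id = paste0(p, ":", wt$token_idx[i]),
      post_id = p,
      node_lemma = lemma,
      node_surface = wt$surface[i],
      node_start = wt$token_idx[i],
      node_end = wt$token_idx[i] + 1L,
      left = paste(lw, collapse = " "),
      right = paste(rw, collapse = " ")
    )
  })
  out <- do.call(rbind, lines)
  structure(out, context = context,
            class = base::c("cfa_concordance", class(tibble::tibble())))
}

#' Sort concordance lines by node, left and right context
#'
#' Stable lexicographic sort on the node lemma, then the left context read
#' word-by-word outward from the node (nearest word first), then the right
#' context left-to-right. Comparison is case-insensitive.
#'
#' @param lines A `cfa_concordance`.
#' @return The same lines, reordered.
#' @export
sort_concordances <- function(lines) {
  if (nrow(lines) == 0) return(lines)
  sep <- "\u0001" # separator below printable chars (radix = C order)
  key_left <- vapply(strsplit(tolower(lines$left), " ", fixed = TRUE),
                     function(w) paste(rev(w), collapse = sep), character(1))
  key_right <- gsub(" ", sep, tolower(lines$right), fixed = TRUE)
  ord <- order(tolower(lines$node_lemma), key_left, key_right,
               method = "radix")
  lines[ord, ]
}

#' Randomly sample concordance lines for coding
#'
#' Uniform sample without replacement; if fewer than `n` lines exist, all
#' are returned with a warning. Deterministic under `seed`.
#'
#' @param lines A `cfa_concordance`.
#' @param n Sample size (default 30).
#' @param seed Integer RNG seed.
#' @return A subset of `lines`.
#' @export
sample_for_coding <- function(lines, n = 30, seed = 1) {
  stopifnot(n >= 1)
  if (nrow(lines) <= n) {
    if (nrow(lines) < n) {
      warning("only ", nrow(lines), " concordance lines available; ",
              "returning all of them", call. = FALSE)
    }
    return(lines)
  }
  idx <- withr::with_seed(seed, sample(nrow(lines), n))
  lines[idx, ]
}

#' Extrapolate coding-frame category frequencies
#'
#' For each coded lemma with corpus frequency `F` and a coded sample of
#' `n` lines, every category gains `F * (lines labelled with it) / n`
#' instances; domain totals are the sums of their categories. With
#' single-label coding the category masses of a lemma sum exactly to `F`,
#' so the grand total equals the summed key-lemma frequencies
#' (conservation). Multi-label lines give each of their labels full
#' proportional mass, so totals can exceed that sum.
#'
#' @param coded Tibble `lemma`, `line_id`, `label` (one row per label), as
#'   from [read_coded_lines()].
#' @param freq A `cfa_freq_table` for the corpus the lines came from; every
#'   coded lemma must be present.
#' @param frame A `cfa_coding_frame`; labels must be frame categories or
#'   `"Not-frame"`.
#' @return List with tibbles `categories` (`domain`, `category`, `mass`,
#'   zero-mass categories included) and `domains` (`domain`, `mass`), plus
#'   `per_lemma` (`lemma`, `freq`, `n_coded`).
#' @export
extrapolate_category_frequencies <- function(coded, freq, frame) {
  stopifnot(inherits(freq, "cfa_freq_table"),
            inherits(frame, "cfa_coding_frame"))
  coded <- tibble::as_tibble(coded)[, base::c("lemma", "line_id", "label")]
  bad <- setdiff(unique(coded$label), frame_labels(frame))
  if (length(bad) > 0) {
    stop("labels not in the coding frame: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lemmas <- unique(coded$lemma)
  fl <- freq$table$freq[match(lemmas, freq$table$lemma)]
  if (anyNA(fl)) {
    stop("coded lemma(s) absent from the frequency table: ",
         paste(lemmas[is.na(fl)], collapse = ", "), call. = FALSE)
  }
  dt <- data.table::as.data.table(coded)
  n_coded <- dt[, .(n_lines = uniqueN(line_id)), by = lemma]
  n_map <- stats::setNames(n_coded$n_lines, n_coded$lemma)
  f_map <- stats::setNames(as.numeric(fl), lemmas)
  hits <- dt[, .(n_hits = .N), by = .(lemma, label)]
  hits[, mass := f_map[lemma] * n_hits / n_map[lemma]]
  cat_mass <- hits[, .(mass = sum(mass)), by = label]
  all_cats <- tibble::tibble(
    category = frame_labels(frame),
    domain = base::c(frame$categories$domain, "Not-frame")
  )
  all_cats$mass <- cat_mass$mass[match(all_cats$category, cat_mass$label)]
  all_cats$mass[is.na(all_cats$mass)] <- 0
  dom <- tapply(all_cats$mass, all_cats$domain, sum)
  dom_order <- base::c(frame$domains, "Not-frame")
  domains <- tibble::tibble(domain = dom_order,
                            mass = as.numeric(dom[dom_order]))
  domains$mass[is.na(domains$mass)] <- 0
  list(
    categories = all_cats[, base::c("domain", "category", "mass")],
    domains = domains,
    per_lemma = tibble::tibble(lemma = lemmas, freq = as.numeric(fl),
                               n_coded = as.integer(n_map[lemmas]))
  )
}
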