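# Inter-rater agreement for the relevance-calibration coding.

#' Cohen's kappa between two coders
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)`, where `po` is
#' the observed fraction of items with identical labels and
#' `pe = sum_label marginal_a * marginal_b` the agreement expected by
#' chance from the two coders' label marginals. Binary and multi-class
#' labels are supported; no weighting. `kappa = 1` when both `po` and `pe`
#' are 1 (degenerate perfect agreement).
#'
#' @param labels_a,labels_b Equal-length label sequences (coercible to
#'   character), one element per coded item.
#' @return A `cfa_kappa`: list with `n`, `po`, `pe`, `kappa` and the
#'   per-label confusion `table` (rows = coder A, columns = coder B).
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label sequences have different lengths (",
         length(labels_a), " vs ", length(labels_b), ")", call. = FALSE)
  }
  n <- length(labels_a)
  if (n < 1) stop("at least one coded item is required", call. = FALSE)
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  levels <- sort(unique(base::c(labels_a, labels_b)))
  tab <- table(factor(labels_a, levels), factor(labels_b, levels))
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  structure(list(n = n, po = po, pe = pe, kappa = kappa, table = tab),
            class = "cfa_kappa")
}

#' @export
print.cfa_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (po = %.3f, pe = %.3f, n = %d)\n",
              x$kappa, x$po, x$pe, x$n))
  invisible(x)
}

#' Chance agreement implied by observed agreement and kappa
#'
#' Inverts the kappa formula: given `po` and `kappa`, returns
#' `pe = (po - kappa) / (1 - kappa)`, which round-trips through
#' `(po - pe) / (1 - pe)` back to `kappa`. Useful for checking reported
#' agreement statistics whose confusion-table marginals are not published.
#'
#' @param po Observed agreement in `[0, 1]`.
#' @param kappa Reported kappa (< 1).
#' @return The implied chance agreement `pe`.
#' @export
kappa_implied_pe <- function(po, kappa) {
  stopifnot(kappa < 1)
  (po - kappa) / (1 - kappa)
}
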