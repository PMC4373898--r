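#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with fixed margins. The two-sided p-value is
#' the sum of the probabilities of all tables (with the observed margins)
#' whose probability does not exceed that of the observed table — the
#' probability-mass rule, the convention used by most software. The odds
#' ratio reported is the sample odds ratio `a*d / (b*c)` (infinite when
#' the denominator is zero, `NaN` for 0/0), not the conditional MLE.
#'
#' @param a,b,c,d Non-negative integer cell counts; rows are
#'   sensitive/non-sensitive, columns motif present/absent. A 2x2 matrix
#'   may be passed as `a`.
#' @return List with `p_value`, `odds_ratio` and the `table`.
#' @examples
#' fisher_exact(12, 0, 5, 138)$p_value   # < 1e-4
#' fisher_exact(5, 5, 5, 5)$p_value      # exactly 1
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  if (sum(cells) == 0) stop("all-zero table: test undefined")
  m <- a + b   # row 1 margin
  n <- c + d   # row 2 margin
  k <- a + c   # column 1 margin
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- probs[support == a]
  # relative tolerance guards against ties broken by floating-point noise
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * c > 0) (a * d) / (b * c) else if (a * d > 0) Inf else NaN
  list(p_value = p, odds_ratio = or,
       table = matrix(cells, 2L, 2L, byrow = TRUE,
                      dimnames = list(c("sensitive", "non_sensitive"),
                                      c("motif", "no_motif"))))
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Arithmetic mean of the per-residue hydropathy values of a sequence,
#' Kyte-Doolittle by default. Residues absent from the scale (e.g. `X`)
#' are excluded from both numerator and denominator.
#'
#' @param sequence Amino-acid string.
#' @param scale Named numeric hydropathy scale (default [KYTE_DOOLITTLE]).
#' @return GRAVY value (dimensionless).
#' @examples
#' gravy("AL")  # (1.8 + 3.8) / 2
#' @export
gravy <- function(sequence, scale = KYTE_DOOLITTLE) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a non-empty string")
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  vals <- scale[chars]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("no residues with defined hydropathy in sequence")
  mean(vals)
}

#' Bin values into a percentage frequency profile
#'
#' Histogram with half-open bins `[edge, edge + width)` whose counts are
#' expressed as percent of the cohort, optionally after mapping the values
#' through a linear rescale (used e.g. to place GRAVY values from
#' \[-4.5, 4.5\] onto a 0-100 axis before binning in steps of 4). Values
#' falling outside the range are counted in the boundary bins and flagged.
#'
#' @param values Numeric vector (non-empty).
#' @param bin_width Positive bin width.
#' @param range `c(lo, hi)` axis range, `hi > lo`.
#' @param rescale Optional `c(from_lo, from_hi, to_lo, to_hi)` linear map
#'   applied to the values before binning.
#' @param cohort_label Label carried into the result.
#' @return A `frequency_profile`: data.frame with `bin_lo`, `bin_hi`,
#'   `count`, `percent`; attributes `cohort_label` and `n_outside`.
#' @examples
#' frequency_profile(c(20, 21, 22, 23), 4, c(0, 50))
#' @export
frequency_profile <- function(values, bin_width, range,
                              rescale = NULL, cohort_label = "") {
  if (length(values) == 0L) stop("no values to profile")
  stopifnot(bin_width > 0, length(range) == 2L, range[2] > range[1])
  if (!is.null(rescale)) {
    stopifnot(length(rescale) == 4L, rescale[2] != rescale[1])
    values <- rescale[3] +
      (values - rescale[1]) * (rescale[4] - rescale[3]) / (rescale[2] - rescale[1])
  }
  edges <- seq(range[1], range[2], by = bin_width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  nb <- length(edges) - 1L
  idx <- findInterval(values, edges, rightmost.closed = FALSE, left.open = FALSE)
  n_outside <- sum(idx < 1L | idx > nb)
  idx[idx < 1L] <- 1L
  idx[idx > nb] <- nb
  count <- tabulate(idx, nbins = nb)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    count = count, percent = 100 * count / length(values))
  attr(out, "cohort_label") <- cohort_label
  attr(out, "n_outside") <- n_outside
  class(out) <- c("frequency_profile", "data.frame")
  out
}

#' Motif-by-sensitivity enrichment report
#'
#' Assembles the 2x2 contingency table — sensitive signal anchors with and
#' without the motif versus non-sensitive signal anchors with and without —
#' from a cohort screen and the matching sensitivity calls, and attaches
#' Fisher's exact test. Only signal anchor (SAS) records present in both
#' inputs enter the table; up-regulated and resistant calls both count as
#' non-sensitive.
#'
#' @param screen A `ccm_screen` from [screen_cohort()].
#' @param calls A `silac_calls` from [classify_table()], or a data.frame
#'   with columns `accession`, `label`.
#' @param signal_type Stratum to test (default `"SAS"`).
#' @return List with `table` (2x2 matrix), `p_value`, `odds_ratio`, `n`.
#' @export
enrichment_report <- function(screen, calls, signal_type = "SAS") {
  stopifnot(inherits(screen, "ccm_screen"))
  if (inherits(calls, "silac_calls")) calls <- calls$calls
  per <- screen$per_record
  per <- per[!per$skipped & per$signal_type == signal_type, , drop = FALSE]
  lab <- calls$label[match(per$accession, calls$accession)]
  keep <- !is.na(lab) & lab != "incomplete"
  if (!any(keep)) stop("no classified ", signal_type, " records to test")
  per <- per[keep, , drop = FALSE]
  lab <- lab[keep]
  sens <- lab == "sensitive"
  a <- sum(sens & per$has_motif)
  b <- sum(sens & !per$has_motif)
  cc <- sum(!sens & per$has_motif)
  dd <- sum(!sens & !per$has_motif)
  ft <- fisher_exact(a, b, cc, dd)
  list(table = ft$table, p_value = ft$p_value, odds_ratio = ft$odds_ratio,
       n = a + b + cc + dd)
}
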