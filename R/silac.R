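#' Classify one protein from its label-swap ratio pair
#'
#' A protein is called cotransin-*sensitive* when its DMSO/cotransin
#' expression ratio exceeds the threshold in both the forward (heavy/light)
#' and the label-swapped reverse (light/heavy) experiment. Both ratios
#' strictly below the reciprocal threshold indicate *up-regulation* under
#' treatment; anything else is *resistant*. A missing ratio yields
#' *incomplete*. Comparisons are strict ("higher than"), so a ratio equal
#' to the threshold is resistant.
#'
#' @param forward_ratio,reverse_ratio Positive DMSO/cotransin ratios
#'   (`NA` allowed).
#' @param threshold Sensitivity cutoff, must be > 1. Default 1.65.
#' @return One of `"sensitive"`, `"resistant"`, `"up_regulated"`,
#'   `"incomplete"` (vectorised over the ratio pair).
#' @examples
#' classify_protein(2.0, 1.8)        # sensitive
#' classify_protein(2.0, 1.2)        # resistant
#' classify_protein(0.50, 0.55)      # up_regulated
#' @export
classify_protein <- function(forward_ratio, reverse_ratio, threshold = 1.65) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 1) {
    stop("threshold must be a single number > 1")
  }
  if (any(forward_ratio <= 0, na.rm = TRUE) ||
      any(reverse_ratio <= 0, na.rm = TRUE)) {
    stop("ratios must be positive")
  }
  n <- max(length(forward_ratio), length(reverse_ratio))
  f <- rep_len(forward_ratio, n)
  r <- rep_len(reverse_ratio, n)
  out <- rep("resistant", n)
  out[f > threshold & r > threshold] <- "sensitive"
  out[f < 1 / threshold & r < 1 / threshold] <- "up_regulated"
  out[is.na(f) | is.na(r)] <- "incomplete"
  out
}

#' Classify a ratio table and summarise by category
#'
#' Applies [classify_protein()] row-wise and tabulates the calls by
#' protein class and signal-sequence type. Records with unspecified
#' signal type are kept in an `"unspecified"` stratum; cell counts always
#' sum to the number of input records.
#'
#' @param ratios data.frame from [read_ratio_table()] or
#'   [generate_silac_table()]: columns `accession`, `forward_ratio`,
#'   `reverse_ratio`, optionally `protein_class`, `signal_type`.
#' @param threshold Sensitivity cutoff (> 1). Default 1.65.
#' @return A `silac_calls` list: `calls` (per-record data.frame with
#'   `label` and `threshold_used`), `summary` (counts by protein_class x
#'   signal_type x label), `threshold`.
#' @export
classify_table <- function(ratios, threshold = 1.65) {
  label <- classify_protein(ratios$forward_ratio, ratios$reverse_ratio,
                            threshold)
  calls <- data.frame(accession = ratios$accession, label = label,
                      threshold_used = rep(threshold, length(label)),
                      stringsAsFactors = FALSE)
  cls <- if ("protein_class" %in% names(ratios)) ratios$protein_class
         else rep("unspecified", nrow(ratios))
  typ <- if ("signal_type" %in% names(ratios)) ratios$signal_type
         else rep("unspecified", nrow(ratios))
  calls$protein_class <- cls
  calls$signal_type <- typ
  summary <- if (nrow(calls)) {
    stats::aggregate(list(n = rep(1L, nrow(calls))),
                     by = list(protein_class = cls, signal_type = typ,
                               label = label),
                     FUN = sum)
  } else {
    data.frame(protein_class = character(), signal_type = character(),
               label = character(), n = integer())
  }
  structure(list(calls = calls, summary = summary, threshold = threshold),
            class = "silac_calls")
}

#' @export
print.silac_calls <- function(x, ...) {
  cat("SILAC sensitivity calls (dual DMSO/cotransin ratio >",
      x$threshold, "in forward and reverse):\n")
  tab <- table(x$calls$label)
  for (nm in names(tab)) cat(" ", nm, ":", tab[[nm]], "\n")
  invisible(x)
}

#' Form expression ratios from channel intensities
#'
#' Computes per-protein heavy/light (or DMSO/cotransin) ratios from raw
#' channel intensities, optionally median-normalising each channel first.
#' Median normalisation makes the resulting ratios — and hence all
#' sensitivity calls — invariant to rescaling either whole channel (e.g.
#' different total label incorporation or loading).
#'
#' @param numerator,denominator Positive intensity vectors (DMSO channel
#'   and cotransin channel, respectively).
#' @param normalize `"none"` (plain ratio) or `"median"` (divide each
#'   channel by its median before forming ratios).
#' @return Numeric ratio vector.
#' @export
ratios_from_intensities <- function(numerator, denominator,
                                    normalize = c("none", "median")) {
  normalize <- match.arg(normalize)
  if (any(numerator <= 0, na.rm = TRUE) || any(denominator <= 0, na.rm = TRUE)) {
    stop("intensities must be positive")
  }
  if (normalize == "median") {
    numerator <- numerator / stats::median(numerator, na.rm = TRUE)
    denominator <- denominator / stats::median(denominator, na.rm = TRUE)
  }
  numerator / denominator
}
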