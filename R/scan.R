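.empty_matches <- function() {
  data.frame(pattern_id = character(), start = integer(), end = integer(),
             patch1_start = integer(), patch1_end = integer(),
             sep_start = integer(), sep_end = integer(),
             patch2_start = integer(), patch2_end = integer(),
             left_flank = integer(), right_flank = integer(),
             stringsAsFactors = FALSE)
}

.check_region <- function(region, n) {
  if (is.null(region)) return(c(1L, n))
  region <- as.integer(region)
  if (length(region) != 2L || anyNA(region) ||
      region[1] < 1L || region[2] > n || region[1] > region[2]) {
    stop("scan region out of bounds for sequence of length ", n)
  }
  region
}

#' Scan a sequence for the conformational consensus motif
#'
#' Scans N- to C-terminally for the two-cavity motif: a first patch of two
#' small residues, a separator of two or three bulky residues, a second
#' patch of one or two small residues, and at least one flanking residue
#' immediately adjacent to a patch (depending on the family's flank rule).
#' Alternative parses sharing the same first-patch start are collapsed to
#' one match, preferring the shorter separator and then the longer second
#' patch; set `all_parses = TRUE` to see every valid parse.
#'
#' A generic [compile_pattern()] object (or list of them) may be given
#' instead of a motif family; such matches report `start`/`end` only, with
#' variable repeats resolved to the longest valid widths at each start.
#'
#' @param sequence Amino-acid string.
#' @param patterns A `ccm_family` (default), a `compiled_pattern`, or a
#'   list of `compiled_pattern`s.
#' @param region Optional `c(from, to)` 1-based inclusive window; matches
#'   (including flanks) must lie entirely inside it. Positions are always
#'   reported in full-sequence coordinates.
#' @param all_parses Report uncollapsed alternative motif parses.
#' @return data.frame of matches with columns `pattern_id`, `start`, `end`
#'   and, for motif-family scans, the element spans `patch1_start/end`,
#'   `sep_start/end`, `patch2_start/end`, `left_flank`, `right_flank`
#'   (`NA` when the corresponding flank is absent).
#' @examples
#' scan_sequence("KGGLLA")
#' @export
scan_sequence <- function(sequence, patterns = ccm_pattern_family(),
                          region = NULL, all_parses = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("sequence must be a single string")
  }
  if (!nzchar(sequence)) stop("cannot scan an empty sequence")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  region <- .check_region(region, length(chars))
  if (inherits(patterns, "ccm_family")) {
    .scan_ccm(chars, patterns, region, all_parses)
  } else {
    if (inherits(patterns, "compiled_pattern")) patterns <- list(patterns)
    do.call(rbind, c(list(.empty_matches()[, c("pattern_id", "start", "end")]),
                     lapply(patterns, .scan_generic, chars = chars,
                            region = region)))
  }
}

.scan_ccm <- function(chars, family, region, all_parses) {
  lo <- region[1]; hi <- region[2]
  sch <- family$scheme
  in_small <- chars %in% sch$small
  in_bulky <- chars %in% sch$bulky
  in_flank <- chars %in% sch$flank
  rule <- family$flank_rule
  rows <- list()
  for (p1 in lo:hi) {
    if (p1 + 1L > hi || !(in_small[p1] && in_small[p1 + 1L])) next
    # parse preference: shorter separator first, then longer second patch
    found <- FALSE
    for (sep_len in 2:3) {
      for (p2_len in 2:1) {
        sep_start <- p1 + 2L
        sep_end <- sep_start + sep_len - 1L
        p2_start <- sep_end + 1L
        p2_end <- p2_start + p2_len - 1L
        if (p2_end > hi) next
        if (!all(in_bulky[sep_start:sep_end])) next
        if (!all(in_small[p2_start:p2_end])) next
        left_ok <- p1 - 1L >= lo && in_flank[p1 - 1L]
        right_ok <- p2_end + 1L <= hi && in_flank[p2_end + 1L]
        ok <- switch(rule,
                     either_required = left_ok || right_ok,
                     left_required = left_ok,
                     right_required = right_ok,
                     both_required = left_ok && right_ok)
        if (!ok) next
        side <- if (left_ok && right_ok) "both" else if (left_ok) "left" else "right"
        lf <- if (left_ok) p1 - 1L else NA_integer_
        rf <- if (right_ok) p2_end + 1L else NA_integer_
        rows[[length(rows) + 1L]] <- data.frame(
          pattern_id = sprintf("ccm/s%dp%d/%s", sep_len, p2_len, side),
          start = if (left_ok) p1 - 1L else p1,
          end = if (right_ok) p2_end + 1L else p2_end,
          patch1_start = p1, patch1_end = p1 + 1L,
          sep_start = sep_start, sep_end = sep_end,
          patch2_start = p2_start, patch2_end = p2_end,
          left_flank = lf, right_flank = rf,
          stringsAsFactors = FALSE)
        found <- TRUE
        if (!all_parses) break
      }
      if (found && !all_parses) break
    }
  }
  out <- do.call(rbind, c(list(.empty_matches()), rows))
  rownames(out) <- NULL
  out
}

.scan_generic <- function(pattern, chars, region) {
  lo <- region[1]; hi <- region[2]
  els <- pattern$elements
  member <- lapply(els, function(el) chars %in% el$set)
  widths <- lapply(els, function(el) seq(el$max, el$min)) # longest first
  grid <- as.matrix(expand.grid(rev(widths), KEEP.OUT.ATTRS = FALSE))
  grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
  # order by total width descending so the first valid hit per start is maximal
  grid <- grid[order(-rowSums(grid)), , drop = FALSE]
  rows <- list()
  for (s in lo:hi) {
    for (g in seq_len(nrow(grid))) {
      w <- grid[g, ]
      e <- s + sum(w) - 1L
      if (e > hi) next
      pos <- s
      ok <- TRUE
      for (k in seq_along(els)) {
        if (w[k] > 0L && !all(member[[k]][pos:(pos + w[k] - 1L)])) {
          ok <- FALSE
          break
        }
        pos <- pos + w[k]
      }
      if (ok) {
        rows[[length(rows) + 1L]] <-
          data.frame(pattern_id = pattern$id, start = s, end = e,
                     stringsAsFactors = FALSE)
        break
      }
    }
  }
  do.call(rbind, c(list(data.frame(pattern_id = character(), start = integer(),
                                   end = integer(), stringsAsFactors = FALSE)),
                   rows))
}

#' Screen a cohort of signal sequences for the motif
#'
#' Scans each record's annotated signal region, widened by `margin`
#' residues on both sides so that flanking residues just outside the
#' transmembrane span still count. Records with missing boundaries are
#' flagged skipped and counted separately.
#'
#' @param cohort data.frame from [join_cohort()] (or the generators):
#'   columns `accession`, `sequence`, `protein_class`, `signal_type`,
#'   `signal_start`, `signal_end`.
#' @param patterns A `ccm_family` (default scheme if `NULL`).
#' @param margin Non-negative integer widening of the signal window
#'   (default 2).
#' @param calls Optional per-protein sensitivity calls
#'   (data.frame `accession`, `label`, e.g. from [classify_table()]); when
#'   given, summary counts are additionally stratified by sensitivity.
#' @return A `ccm_screen` list: `per_record` (accession, has_motif,
#'   n_matches, skipped), `matches` (all match rows with accession),
#'   `summary` (counts by protein_class x signal_type (x label) x motif
#'   status), `n_skipped`.
#' @export
screen_cohort <- function(cohort, patterns = NULL, margin = 2L, calls = NULL) {
  if (is.null(patterns)) patterns <- ccm_pattern_family()
  stopifnot(inherits(patterns, "ccm_family"), margin >= 0L)
  n <- nrow(cohort)
  has_motif <- logical(n)
  n_matches <- integer(n)
  skipped <- logical(n)
  match_rows <- list()
  for (i in seq_len(n)) {
    st <- cohort$signal_start[i]
    en <- cohort$signal_end[i]
    len <- nchar(cohort$sequence[i])
    if (is.na(st) || is.na(en) || st < 1L || en > len || st > en) {
      skipped[i] <- TRUE
      next
    }
    region <- c(max(1L, st - margin), min(len, en + margin))
    m <- scan_sequence(cohort$sequence[i], patterns, region = region)
    has_motif[i] <- nrow(m) > 0L
    n_matches[i] <- nrow(m)
    if (nrow(m)) {
      m$accession <- cohort$accession[i]
      match_rows[[length(match_rows) + 1L]] <- m
    }
  }
  per_record <- data.frame(accession = cohort$accession,
                           protein_class = cohort$protein_class,
                           signal_type = cohort$signal_type,
                           has_motif = has_motif, n_matches = n_matches,
                           skipped = skipped, stringsAsFactors = FALSE)
  keep <- !skipped
  strata <- per_record[keep, c("protein_class", "signal_type"), drop = FALSE]
  if (!is.null(calls)) {
    lab <- calls$label[match(per_record$accession, calls$accession)]
    per_record$label <- lab
    strata$label <- lab[keep]
  }
  summary <- if (any(keep)) {
    stats::aggregate(list(n = integer(sum(keep)) + 1L),
                     by = c(strata, list(has_motif = has_motif[keep])),
                     FUN = sum)
  } else {
    data.frame()
  }
  structure(list(per_record = per_record, summary = summary,
                 matches = do.call(rbind, c(list(NULL), match_rows)),
                 n_skipped = sum(skipped)),
            class = "ccm_screen")
}

#' @export
print.ccm_screen <- function(x, ...) {
  n <- nrow(x$per_record)
  cat("Motif screen over", n, "records:",
      sum(x$per_record$has_motif), "with motif,",
      sum(!x$per_record$has_motif & !x$per_record$skipped), "without,",
      x$n_skipped, "skipped\n")
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}
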