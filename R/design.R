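#' Parse point mutations in protein notation
#'
#' Converts strings like `"F25G"` (Phe25 to Gly) into a mutation table.
#'
#' @param x Character vector of mutations in `<from><position><to>` form.
#' @return data.frame with columns `position`, `from`, `to`.
#' @examples
#' parse_mutations(c("F25G", "F26G", "G27L", "Q33K"))
#' @export
parse_mutations <- function(x) {
  m <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z])$", toupper(x)))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed mutation string: ", x[bad][1])
  out <- data.frame(position = as.integer(vapply(m, `[`, "", 3L)),
                    from = vapply(m, `[`, "", 2L),
                    to = vapply(m, `[`, "", 4L),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$position)) stop("duplicate mutation positions")
  out
}

#' Format a mutation table in protein notation
#'
#' @param mutations data.frame with `position`, `from`, `to`.
#' @return Character vector like `"F25G"`.
#' @export
format_mutations <- function(mutations) {
  if (is.null(mutations) || nrow(mutations) == 0L) return(character())
  paste0(mutations$from, mutations$position, mutations$to)
}

#' Apply point substitutions to a sequence
#'
#' Every `from` residue must match the sequence at its position; a
#' mismatch is an error naming the position, never silently overwritten.
#'
#' @param sequence Amino-acid string.
#' @param mutations data.frame (`position`, `from`, `to`) or character
#'   vector in `"F25G"` notation.
#' @return The mutated sequence (same length).
#' @examples
#' apply_mutations("KFFGLA", c("F2G", "F3G"))
#' @export
apply_mutations <- function(sequence, mutations) {
  if (is.character(mutations)) mutations <- parse_mutations(mutations)
  if (is.null(mutations) || nrow(mutations) == 0L) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (anyDuplicated(mutations$position)) stop("duplicate mutation positions")
  for (i in seq_len(nrow(mutations))) {
    p <- mutations$position[i]
    if (p < 1L || p > length(chars)) {
      stop("mutation position ", p, " outside sequence of length ",
           length(chars))
    }
    if (chars[p] != mutations$from[i]) {
      stop("mutation ", format_mutations(mutations[i, , drop = FALSE]),
           ": sequence has ", chars[p], " at position ", p)
    }
    chars[p] <- mutations$to[i]
  }
  paste(chars, collapse = "")
}

.rep_residue <- function(set, preferred) {
  if (preferred %in% set) preferred else sort(set)[1]
}

#' Propose a minimal mutation set introducing the consensus motif
#'
#' Searches for the smallest set of point substitutions that creates a
#' conformational-consensus-motif match lying entirely inside `window`.
#' The search is exact: every concrete motif variant is laid at every
#' offset in the window and the substitutions needed to satisfy its
#' residue classes are counted (a position already in the required class
#' costs nothing). Replacement residues default to one representative per
#' class — Gly for small, Leu for bulky, Lys for flank — the
#' minimal-perturbation choice; cardinality is unaffected by this
#' restriction. Ties are broken by fewest mutations, then leftmost match
#' start, then lexicographically smallest substitution strings.
#'
#' @param sequence Amino-acid string.
#' @param window `c(from, to)` 1-based inclusive search window (default
#'   whole sequence); the created match, flank included, must fit inside.
#' @param scheme A [residue_scheme()].
#' @param max_mutations Maximum substitutions to allow (0-5; larger
#'   budgets are refused rather than approximated).
#' @param allow_flank_mutations May substitutions create the flanking
#'   residue itself (default `TRUE`)?
#' @return A `motif_design` list: `found`, `mutations` (data.frame,
#'   zero rows when the window already contains a match), `match`
#'   (the created match row), `mutated_sequence`, `window`; or
#'   `found = FALSE` when no set within budget exists.
#' @examples
#' propose_motif_insertion("KLLLLLL", max_mutations = 3)
#' @export
propose_motif_insertion <- function(sequence, window = NULL,
                                    scheme = residue_scheme(),
                                    max_mutations = 4L,
                                    allow_flank_mutations = TRUE) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty sequence")
  if (is.null(window)) window <- c(1L, n)
  window <- as.integer(window)
  if (length(window) != 2L || window[1] < 1L || window[2] > n ||
      window[1] > window[2]) {
    stop("window out of bounds for sequence of length ", n)
  }
  if (max_mutations < 0L) stop("max_mutations must be >= 0")
  if (max_mutations > 5L) {
    stop("exact search supports max_mutations <= 5; refusing to approximate")
  }
  fam <- ccm_pattern_family(scheme)
  reps <- c(patch1 = .rep_residue(scheme$small, "G"),
            separator = .rep_residue(scheme$bulky, "L"),
            patch2 = .rep_residue(scheme$small, "G"),
            flank = .rep_residue(scheme$flank, "K"))
  class_sets <- list(patch1 = scheme$small, separator = scheme$bulky,
                     patch2 = scheme$small, flank = scheme$flank)

  best <- NULL
  for (v in fam$variants) {
    roles <- vapply(v$elements, `[[`, "", "role")
    lens <- vapply(v$elements, `[[`, 1L, "min")
    total <- sum(lens)
    if (window[2] - window[1] + 1L < total) next
    for (s in window[1]:(window[2] - total + 1L)) {
      pos <- s
      muts <- list()
      ok <- TRUE
      for (k in seq_along(roles)) {
        span <- pos:(pos + lens[k] - 1L)
        set <- class_sets[[roles[k]]]
        for (p in span) {
          if (!chars[p] %in% set) {
            if (roles[k] == "flank" && !allow_flank_mutations) {
              ok <- FALSE
              break
            }
            muts[[length(muts) + 1L]] <-
              data.frame(position = p, from = chars[p], to = reps[[roles[k]]],
                         stringsAsFactors = FALSE)
          }
        }
        if (!ok) break
        pos <- pos + lens[k]
      }
      if (!ok) next
      mdf <- do.call(rbind, c(list(data.frame(position = integer(),
                                              from = character(),
                                              to = character())), muts))
      if (nrow(mdf) > max_mutations) next
      cand <- list(cost = nrow(mdf), start = s, mutations = mdf,
                   key = paste(sort(format_mutations(mdf)), collapse = ","))
      if (is.null(best) ||
          cand$cost < best$cost ||
          (cand$cost == best$cost && cand$start < best$start) ||
          (cand$cost == best$cost && cand$start == best$start &&
             cand$key < best$key)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(found = FALSE, mutations = NULL, match = NULL,
                          mutated_sequence = NULL, window = window),
                     class = "motif_design"))
  }
  mutated <- apply_mutations(paste(chars, collapse = ""), best$mutations)
  match <- scan_sequence(mutated, fam, region = window)
  stopifnot(nrow(match) >= 1L)  # soundness of the exact search
  structure(list(found = TRUE, mutations = best$mutations,
                 match = match[1, , drop = FALSE],
                 mutated_sequence = mutated, window = window),
            class = "motif_design")
}

#' Verify that a user-supplied mutation set creates the motif
#'
#' Applies the mutations and scans the window; mirrors the mutagenesis
#' workflow where a combined substitution set (e.g. F25G, F26G, G27L,
#' Q33K in an aquaporin signal anchor) is designed by hand and then
#' checked for motif creation.
#'
#' @inheritParams propose_motif_insertion
#' @param mutations Mutation table or `"F25G"`-style strings.
#' @return List: `creates_motif` (logical), `matches` (scan result on the
#'   mutated sequence), `mutated_sequence`.
#' @export
verify_motif_insertion <- function(sequence, mutations, window = NULL,
                                   scheme = residue_scheme()) {
  mutated <- apply_mutations(toupper(sequence), mutations)
  if (is.null(window)) window <- c(1L, nchar(mutated))
  m <- scan_sequence(mutated, ccm_pattern_family(scheme), region = window)
  list(creates_motif = nrow(m) > 0L, matches = m, mutated_sequence = mutated)
}

#' @export
print.motif_design <- function(x, ...) {
  if (!x$found) {
    cat("No mutation set within budget creates the motif in window [",
        x$window[1], ",", x$window[2], "]\n")
    return(invisible(x))
  }
  cat("Motif introduced by ", nrow(x$mutations), " substitution(s): ",
      paste(format_mutations(x$mutations), collapse = ", "), "\n", sep = "")
  invisible(x)
}
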