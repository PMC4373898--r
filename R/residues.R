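#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter residue codes. Non-standard codes (B, Z, U, X)
#' may appear in sequences but belong to no residue class, so they can never
#' satisfy a small/bulky/flank position of a motif pattern.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values used by [gravy()]. Positive values are
#' hydrophobic, negative hydrophilic.
#'
#' @format Named numeric vector over the 20 standard residues.
#' @references Kyte J, Doolittle RF (1982) J Mol Biol 157:105-132.
#' @export
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Residue class scheme for the conformational consensus motif
#'
#' The consensus motif in cotransin-sensitive signal anchor sequences is
#' built from three residue classes: a *small* class forming the two
#' helix-surface cavities (Gly, Ala, Ser, Thr, Cys by default), a *bulky*
#' class separating the cavities, and a *flank* class of large charged,
#' large polar or aromatic residues bordering the motif.
#'
#' The default bulky class is the complement of the small class over the
#' 20 standard residues; a hydrophobic-only alternative can be supplied
#' (e.g. `c("L","I","V","F","M","W","Y","P")`). A residue may not belong
#' to both the small and the bulky class; flank residues may overlap with
#' the bulky class (they are large by definition).
#'
#' @param small Character vector of small (cavity-forming) residues.
#' @param bulky Character vector of separator residues, or `NULL` for the
#'   complement of `small` over the standard alphabet.
#' @param flank Character vector of flanking residues. Default: charged
#'   (D, E, K, R, H), large polar (N, Q) and aromatic (F, W, Y).
#' @param name Label carried into pattern ids and reports.
#'
#' @return An object of class `residue_scheme`: a list with elements
#'   `small`, `bulky`, `flank`, `name`.
#' @examples
#' sch <- residue_scheme()
#' sch$small
#' @export
residue_scheme <- function(small = c("G", "A", "S", "T", "C"),
                           bulky = NULL,
                           flank = c("D", "E", "K", "R", "H",
                                     "N", "Q", "F", "W", "Y"),
                           name = "default") {
  small <- unique(toupper(small))
  flank <- unique(toupper(flank))
  if (is.null(bulky)) bulky <- setdiff(AA_STANDARD, small)
  bulky <- unique(toupper(bulky))
  for (set in list(small, bulky, flank)) {
    bad <- setdiff(set, AA_STANDARD)
    if (length(bad)) {
      stop("residue scheme contains non-standard letters: ",
           paste(bad, collapse = ", "))
    }
  }
  if (length(small) == 0L || length(bulky) == 0L || length(flank) == 0L) {
    stop("residue scheme classes must be non-empty")
  }
  overlap <- intersect(small, bulky)
  if (length(overlap)) {
    stop("residues may not be both small and bulky: ",
         paste(overlap, collapse = ", "))
  }
  structure(list(small = small, bulky = bulky, flank = flank, name = name),
            class = "residue_scheme")
}

#' @export
print.residue_scheme <- function(x, ...) {
  cat("Residue class scheme '", x$name, "'\n", sep = "")
  cat("  small (cavity): ", paste(x$small, collapse = ""), "\n", sep = "")
  cat("  bulky (separator): ", paste(x$bulky, collapse = ""), "\n", sep = "")
  cat("  flank: ", paste(x$flank, collapse = ""), "\n", sep = "")
  invisible(x)
}
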