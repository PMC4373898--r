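#' Project a sequence onto ideal alpha-helix geometry
#'
#' Assigns each residue the azimuth it would occupy on an ideal
#' alpha-helical wheel: residue *i* sits at `(i - 1) * degrees_per_residue`
#' modulo 360, i.e. 100 degrees per residue (3.6 residues per turn) by
#' default. This is a wheel abstraction, not a 3D model.
#'
#' @param sequence Amino-acid string.
#' @param degrees_per_residue Helical twist per residue (default 100).
#' @return A `helix_projection` data.frame: `position`, `residue`,
#'   `azimuth` (degrees in \[0, 360)).
#' @examples
#' project_helix("MAVLG")$azimuth   # 0 100 200 300 40
#' @export
project_helix <- function(sequence, degrees_per_residue = 100) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a non-empty string")
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  pos <- seq_along(chars)
  out <- data.frame(position = pos, residue = chars,
                    azimuth = ((pos - 1) * degrees_per_residue) %% 360,
                    stringsAsFactors = FALSE)
  attr(out, "degrees_per_residue") <- degrees_per_residue
  class(out) <- c("helix_projection", "data.frame")
  out
}

#' Circular mean of angles in degrees
#'
#' @param degrees Numeric vector of angles.
#' @return Mean direction in \[0, 360).
#' @export
circular_mean <- function(degrees) {
  rad <- degrees * pi / 180
  ang <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  ang %% 360
}

#' Annotate the two helix-surface cavities of a motif match
#'
#' On an ideal helix the two small-residue patches of the motif cluster
#' into two surface cavities. This reports the member positions and
#' azimuths of each cavity, the circular-mean centroid azimuths, and the
#' angular separation between the centroids. The annotation is a pure
#' function of the match positions and the projection.
#'
#' @param sequence Amino-acid string the match refers to.
#' @param match One row of a motif-family [scan_sequence()] result.
#' @param projection Optional [project_helix()] result for `sequence`.
#' @return A `cavity_annotation` list: `cavity1_positions`,
#'   `cavity2_positions`, `cavity1_azimuths`, `cavity2_azimuths`,
#'   `cavity1_centroid`, `cavity2_centroid`, `angular_separation`
#'   (degrees in \[0, 180\]).
#' @export
annotate_cavities <- function(sequence, match, projection = NULL) {
  if (is.null(projection)) projection <- project_helix(sequence)
  if (is.data.frame(match)) {
    if (nrow(match) != 1L) stop("match must be a single row")
    match <- as.list(match)
  }
  need <- c("patch1_start", "patch1_end", "patch2_start", "patch2_end")
  if (!all(need %in% names(match)) || anyNA(unlist(match[need]))) {
    stop("match lacks patch spans; scan with a motif family first")
  }
  n <- nrow(projection)
  if (match$patch2_end > n || match$patch1_start < 1L) {
    stop("match out of bounds for sequence of length ", n)
  }
  p1 <- match$patch1_start:match$patch1_end
  p2 <- match$patch2_start:match$patch2_end
  az1 <- projection$azimuth[p1]
  az2 <- projection$azimuth[p2]
  c1 <- circular_mean(az1)
  c2 <- circular_mean(az2)
  sep <- abs(c1 - c2) %% 360
  if (sep > 180) sep <- 360 - sep
  structure(list(cavity1_positions = p1, cavity2_positions = p2,
                 cavity1_azimuths = az1, cavity2_azimuths = az2,
                 cavity1_centroid = c1, cavity2_centroid = c2,
                 angular_separation = sep),
            class = "cavity_annotation")
}

#' @export
print.cavity_annotation <- function(x, ...) {
  cat("Helix-surface cavities of motif match\n")
  cat("  cavity 1: positions ", paste(x$cavity1_positions, collapse = ","),
      " centroid ", round(x$cavity1_centroid, 1), "°\n", sep = "")
  cat("  cavity 2: positions ", paste(x$cavity2_positions, collapse = ","),
      " centroid ", round(x$cavity2_centroid, 1), "°\n", sep = "")
  cat("  angular separation ", round(x$angular_separation, 1), "°\n",
      sep = "")
  invisible(x)
}
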