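#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()]. Sequences are
#' upper-cased and records with empty bodies are rejected by name, so the
#' result is safe to join against an annotation table.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `accession` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  acc <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    stop("empty sequence for FASTA record(s): ",
         paste(acc[empty], collapse = ", "))
  }
  if (anyNA(acc) || any(acc == "")) stop("FASTA record with empty header")
  data.frame(accession = acc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param x data.frame with columns `accession`, `sequence` (as returned by
#'   [read_fasta()]), or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) {
    seqs <- x$sequence
    names(seqs) <- x$accession
  } else {
    seqs <- x
  }
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

.PROTEIN_CLASSES <- c("secretory", "membrane")
.SIGNAL_TYPES <- c("SP", "SAS", "unspecified")
.TOPOLOGIES <- c("Nc", "Ne", "unspecified")

.map_unspecified <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x %in% c("n/s", "ns", "NA", "", ".")] <- "unspecified"
  x
}

#' Read a signal-sequence annotation table
#'
#' Expects a tab-separated file with header columns `accession`, `class`
#' (secretory/membrane), `signal_type` (SP/SAS or `n/s`), `signal_start`,
#' `signal_end` (1-based inclusive residue coordinates) and `topology`
#' (Nc/Ne or `n/s` for a signal anchor's N-tail orientation). `n/s` and
#' empty cells map to `"unspecified"`.
#'
#' Coordinate sanity against the actual sequences is enforced later by
#' [join_cohort()]; here only `1 <= signal_start <= signal_end` is checked.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `accession`, `protein_class`,
#'   `signal_type`, `signal_start`, `signal_end`, `topology`.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("accession", "class", "signal_type", "signal_start",
            "signal_end", "topology")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  }
  out <- data.frame(
    accession = df$accession,
    protein_class = as.character(df$class),
    signal_type = .map_unspecified(df$signal_type),
    signal_start = suppressWarnings(as.integer(df$signal_start)),
    signal_end = suppressWarnings(as.integer(df$signal_end)),
    topology = .map_unspecified(df$topology),
    stringsAsFactors = FALSE
  )
  bad <- which(!out$protein_class %in% .PROTEIN_CLASSES)
  if (length(bad)) {
    stop("row ", bad[1], ": unknown protein class '",
         out$protein_class[bad[1]], "'")
  }
  bad <- which(!out$signal_type %in% .SIGNAL_TYPES)
  if (length(bad)) {
    stop("row ", bad[1], ": unknown signal type '", out$signal_type[bad[1]], "'")
  }
  bad <- which(!out$topology %in% .TOPOLOGIES)
  if (length(bad)) {
    stop("row ", bad[1], ": unknown topology '", out$topology[bad[1]], "'")
  }
  bad <- which(is.na(out$signal_start) | is.na(out$signal_end) |
                 out$signal_start < 1L | out$signal_end < out$signal_start)
  if (length(bad)) {
    stop("row ", bad[1], ": invalid signal coordinates (need 1 <= start <= end)")
  }
  # secretory proteins carry cleavable signal peptides, never signal anchors
  bad <- which(out$protein_class == "secretory" & out$signal_type == "SAS")
  if (length(bad)) {
    stop("row ", bad[1], ": secretory protein annotated with a signal anchor")
  }
  out
}

#' Write a signal-sequence annotation table
#'
#' Inverse of [read_annotation_table()]; `"unspecified"` is written as `n/s`.
#'
#' @param x Annotation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(x, path) {
  out <- data.frame(
    accession = x$accession,
    class = x$protein_class,
    signal_type = ifelse(x$signal_type == "unspecified", "n/s", x$signal_type),
    signal_start = x$signal_start,
    signal_end = x$signal_end,
    topology = ifelse(x$topology == "unspecified", "n/s", x$topology),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Join sequences and annotations into a validated cohort
#'
#' Inner-joins a FASTA frame and an annotation frame on `accession` and
#' enforces the coordinate invariant
#' `1 <= signal_start <= signal_end <= nchar(sequence)`. Violations are
#' errors, never clamped.
#'
#' @param fasta data.frame from [read_fasta()].
#' @param annotation data.frame from [read_annotation_table()].
#' @return Cohort data.frame: annotation columns plus `sequence`.
#' @export
join_cohort <- function(fasta, annotation) {
  merged <- merge(annotation, fasta, by = "accession", sort = FALSE)
  bad <- which(merged$signal_end > nchar(merged$sequence))
  if (length(bad)) {
    stop("signal_end beyond sequence length for accession(s): ",
         paste(merged$accession[bad], collapse = ", "))
  }
  merged
}

#' Read a label-swap SILAC ratio table
#'
#' Expects a tab-separated file with header columns `accession`,
#' `forward_ratio`, `reverse_ratio` and optionally `class` and
#' `signal_type`. Both ratios are DMSO/cotransin expression ratios: the
#' forward experiment reports heavy/light, the label-swapped reverse
#' experiment light/heavy. Empty ratio cells yield `NA` (the record is
#' classified `incomplete`); non-positive ratios are validation errors.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `accession`, `forward_ratio`,
#'   `reverse_ratio`, and `protein_class`/`signal_type` when present.
#' @export
read_ratio_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("accession", "forward_ratio", "reverse_ratio")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("ratio table missing column(s): ", paste(miss, collapse = ", "))
  }
  out <- data.frame(
    accession = as.character(df$accession),
    forward_ratio = as.numeric(df$forward_ratio),
    reverse_ratio = as.numeric(df$reverse_ratio),
    stringsAsFactors = FALSE
  )
  if ("class" %in% names(df)) out$protein_class <- as.character(df$class)
  if ("signal_type" %in% names(df)) {
    out$signal_type <- .map_unspecified(df$signal_type)
  }
  for (col in c("forward_ratio", "reverse_ratio")) {
    bad <- which(!is.na(out[[col]]) & out[[col]] <= 0)
    if (length(bad)) {
      stop("row ", bad[1], ": non-positive ", col, " (", out[[col]][bad[1]], ")")
    }
  }
  out
}

#' Write a SILAC ratio table
#'
#' Ratios are written with [format()] at full precision (15 significant
#' digits) so that a write/read round trip preserves values exactly as
#' decimal text.
#'
#' @param x Ratio data.frame (see [read_ratio_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratio_table <- function(x, path) {
  out <- x
  if ("protein_class" %in% names(out)) {
    names(out)[names(out) == "protein_class"] <- "class"
  }
  for (col in c("forward_ratio", "reverse_ratio")) {
    out[[col]] <- vapply(out[[col]], function(v) {
      if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE)
    }, character(1))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dose-response table
#'
#' Tab-separated columns `concentration` (micromolar) and `response`
#' (percent of the DMSO control); an optional `replicate` column is kept.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `concentration`, `response` (and
#'   `replicate` if present).
#' @export
read_dose_response <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("concentration", "response")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("dose-response table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(df$concentration < 0)) stop("negative concentration")
  df
}
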