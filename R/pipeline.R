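.file_hash <- function(path) {
  if (is.null(path) || !file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}

.df_hash <- function(df) {
  if (is.null(df)) return(NA_character_)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full sensitivity/motif analysis pipeline
#'
#' Chains the stages of the analysis: sensitivity classification of the
#' ratio table, motif screening of the signal-sequence cohort, the
#' motif-by-sensitivity enrichment test on signal anchors, and GRAVY /
#' length frequency profiles per category. Stages whose inputs are absent
#' are marked skipped rather than failing; any stage error aborts with
#' the stage name.
#'
#' @param ratios Ratio data.frame (see [read_ratio_table()]), or `NULL`.
#' @param cohort Cohort data.frame (see [join_cohort()]), or `NULL`.
#' @param threshold Sensitivity cutoff (default 1.65).
#' @param scheme A [residue_scheme()].
#' @param margin Signal-window widening for the motif screen (default 2).
#' @param gravy_rescale Linear map applied to GRAVY values before binning
#'   (default from \[-4.5, 4.5\] to \[0, 100\], binned in steps of 4).
#' @return A `ccm_report` list with elements `classification`, `screen`,
#'   `enrichment`, `profiles` (each `NULL` when skipped) and `provenance`
#'   (thresholds, scheme, package version, input hashes).
#' @export
run_pipeline <- function(ratios = NULL, cohort = NULL, threshold = 1.65,
                         scheme = residue_scheme(), margin = 2L,
                         gravy_rescale = c(-4.5, 4.5, 0, 100)) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  classification <- if (!is.null(ratios)) {
    stage("classify", classify_table(ratios, threshold))
  }
  screen <- enrichment <- profiles <- NULL
  if (!is.null(cohort)) {
    fam <- ccm_pattern_family(scheme)
    screen <- stage("screen",
                    screen_cohort(cohort, fam, margin = margin,
                                  calls = if (!is.null(classification))
                                    classification$calls))
    if (!is.null(classification)) {
      enrichment <- stage("enrich",
                          enrichment_report(screen, classification))
    }
    profiles <- stage("profile", {
      sig <- substring(cohort$sequence, cohort$signal_start, cohort$signal_end)
      groups <- split(seq_len(nrow(cohort)),
                      paste(cohort$protein_class, cohort$signal_type))
      lapply(groups, function(idx) {
        gv <- vapply(sig[idx], gravy, 0, USE.NAMES = FALSE)
        list(
          gravy = frequency_profile(gv, 4, c(0, 100),
                                    rescale = gravy_rescale),
          length = frequency_profile(nchar(sig[idx]), 4, c(0, 52)))
      })
    })
  }
  provenance <- list(
    package = "ccmscan",
    version = as.character(utils::packageVersion("ccmscan")),
    threshold = threshold,
    margin = margin,
    scheme = scheme[c("small", "bulky", "flank", "name")],
    gravy_rescale = gravy_rescale,
    ratios_hash = .df_hash(ratios),
    cohort_hash = .df_hash(cohort),
    timestamp = NA_character_  # kept NA so reports are byte-reproducible
  )
  structure(list(classification = classification, screen = screen,
                 enrichment = enrichment, profiles = profiles,
                 provenance = provenance),
            class = "ccm_report")
}

#' @export
print.ccm_report <- function(x, ...) {
  cat("== Cotransin sensitivity / consensus motif report ==\n")
  if (!is.null(x$classification)) {
    print(x$classification)
  } else cat("classification: skipped (no ratio table)\n")
  if (!is.null(x$screen)) {
    print(x$screen)
  } else cat("motif screen: skipped (no sequence cohort)\n")
  if (!is.null(x$enrichment)) {
    cat(sprintf(
      "enrichment (signal anchors): motif %d/%d sensitive vs %d/%d non-sensitive, Fisher p = %.3g, OR = %.3g\n",
      x$enrichment$table[1, 1], sum(x$enrichment$table[1, ]),
      x$enrichment$table[2, 1], sum(x$enrichment$table[2, ]),
      x$enrichment$p_value, x$enrichment$odds_ratio))
  }
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' @param report A `ccm_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  x <- list(
    provenance = report$provenance,
    classification = if (!is.null(report$classification)) list(
      threshold = report$classification$threshold,
      summary = report$classification$summary,
      calls = report$classification$calls),
    screen = if (!is.null(report$screen)) list(
      summary = report$screen$summary,
      n_skipped = report$screen$n_skipped,
      per_record = report$screen$per_record),
    enrichment = if (!is.null(report$enrichment)) list(
      table = as.vector(t(report$enrichment$table)),
      p_value = report$enrichment$p_value,
      odds_ratio = report$enrichment$odds_ratio,
      n = report$enrichment$n)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
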