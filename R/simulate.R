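#' Configuration for the synthetic-data generators
#'
#' Defaults mirror the structure of the cotransin SILAC screen: 217
#' proteins, 53 of them secretory; signal anchors of 18-25 residues;
#' sensitive proteins carry the consensus motif with probability 1 and
#' resistant ones with probability 5/143; true DMSO/cotransin effect
#' ratios of sensitive proteins span 2-10 with 10% lognormal measurement
#' noise, independently in the forward and reverse experiment.
#'
#' @param seed Integer seed making every generator reproducible.
#' @param n_proteins Cohort size.
#' @param fraction_secretory Fraction of secretory proteins.
#' @param fraction_sensitive Overall fraction of cotransin-sensitive
#'   proteins.
#' @param motif_prevalence_sensitive_sas,motif_prevalence_resistant_sas
#'   Probability that a sensitive / resistant signal anchor carries a
#'   planted motif.
#' @param ratio_effect_range `c(lo, hi)`, `lo > 1`: true DMSO/cotransin
#'   ratio of sensitive proteins is drawn uniformly from this range.
#' @param ratio_noise_cv Coefficient of variation of the multiplicative
#'   lognormal ratio noise.
#' @param sas_length_range Hydrophobic-core length range of signal
#'   anchors (residues).
#' @param sp_length_range Total signal-peptide length range implied by the
#'   tripartite n/h/c architecture (informational).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_proteins = 217L,
                             fraction_secretory = 53 / 217,
                             fraction_sensitive = 71 / 217,
                             motif_prevalence_sensitive_sas = 1.0,
                             motif_prevalence_resistant_sas = 5 / 143,
                             ratio_effect_range = c(2, 10),
                             ratio_noise_cv = 0.1,
                             sas_length_range = c(18L, 25L),
                             sp_length_range = c(11L, 27L)) {
  stopifnot(n_proteins >= 0,
            fraction_secretory >= 0, fraction_secretory <= 1,
            fraction_sensitive >= 0, fraction_sensitive <= 1,
            motif_prevalence_sensitive_sas >= 0,
            motif_prevalence_sensitive_sas <= 1,
            motif_prevalence_resistant_sas >= 0,
            motif_prevalence_resistant_sas <= 1,
            ratio_effect_range[1] > 1,
            ratio_effect_range[2] >= ratio_effect_range[1],
            ratio_noise_cv >= 0,
            sas_length_range[1] >= 10, sas_length_range[2] >= sas_length_range[1])
  structure(as.list(environment()), class = "generator_config")
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

# fixed multinomials for sequence composition; transmembrane cores are
# drawn from the bulky class only, so every small-residue cavity present
# in a synthetic signal anchor is a planted one
.CORE_RES <- c(L = 0.30, I = 0.18, V = 0.18, F = 0.14, M = 0.10,
               W = 0.05, Y = 0.05)
.TAIL_RES <- c(K = 0.2, R = 0.15, E = 0.15, D = 0.1, Q = 0.15,
               N = 0.1, P = 0.1, H = 0.05)
.SPC_RES <- c(P = 0.25, Q = 0.25, N = 0.2, E = 0.15, D = 0.1, H = 0.05)

.sample_res <- function(n, freq) {
  if (n <= 0) return(character(0))
  sample(names(freq), n, replace = TRUE, prob = freq)
}

.plant_motif <- function(chars, core_start, core_end, scheme) {
  variant <- list(sep_len = sample(2:3, 1), p2_len = sample(1:2, 1),
                  side = sample(c("left", "right", "both"), 1))
  has_l <- variant$side %in% c("left", "both")
  has_r <- variant$side %in% c("right", "both")
  total <- has_l + 2L + variant$sep_len + variant$p2_len + has_r
  lo <- core_start
  hi <- core_end - total + 1L
  if (hi < lo) stop("core too short to plant motif")
  s <- if (hi > lo) sample(lo:hi, 1) else lo
  pos <- s
  if (has_l) {
    chars[pos] <- sample(scheme$flank, 1)
    pos <- pos + 1L
  }
  p1_start <- pos
  chars[pos:(pos + 1L)] <- sample(scheme$small, 2L, replace = TRUE)
  pos <- pos + 2L
  chars[pos:(pos + variant$sep_len - 1L)] <-
    .sample_res(variant$sep_len, .CORE_RES)
  pos <- pos + variant$sep_len
  chars[pos:(pos + variant$p2_len - 1L)] <-
    sample(scheme$small, variant$p2_len, replace = TRUE)
  pos <- pos + variant$p2_len
  if (has_r) chars[pos] <- sample(scheme$flank, 1)
  list(chars = chars, patch1_start = p1_start)
}

.one_sas <- function(config, prevalence, scheme) {
  core_len <- sample(config$sas_length_range[1]:config$sas_length_range[2], 1)
  n_len <- sample(4:10, 1)
  c_len <- sample(4:10, 1)
  chars <- c("M", .sample_res(n_len - 1L, .TAIL_RES),
             .sample_res(core_len, .CORE_RES),
             .sample_res(c_len, .TAIL_RES))
  core_start <- n_len + 1L
  core_end <- n_len + core_len
  planted <- NA_integer_
  if (stats::runif(1) < prevalence) {
    pl <- .plant_motif(chars, core_start, core_end, scheme)
    chars <- pl$chars
    planted <- pl$patch1_start
  }
  list(sequence = paste(chars, collapse = ""),
       signal_start = core_start, signal_end = core_end,
       planted_patch1_start = planted)
}

#' Generate synthetic signal-anchor records
#'
#' Emulates first-transmembrane-domain signal anchors: a hydrophobic core
#' (drawn from the bulky residue class so that small-residue cavities
#' occur only where planted) embedded between polar/charged N- and
#' C-terminal context. With probability `prevalence` a consensus-motif
#' instance — variant drawn uniformly from the 12 concrete alternatives —
#' is written into the core at a recorded position.
#'
#' @param n Number of records.
#' @param config A [generator_config()].
#' @param prevalence Planting probability (default
#'   `config$motif_prevalence_sensitive_sas`).
#' @param scheme Residue scheme used for planting.
#' @param seed Seed (`NULL` to use the current RNG stream; default
#'   `config$seed`).
#' @param prefix Accession prefix.
#' @return Cohort data.frame with `accession`, `sequence`,
#'   `protein_class`, `signal_type`, `signal_start`, `signal_end`,
#'   `topology`, plus truth columns `motif_planted` and
#'   `planted_patch1_start`.
#' @export
generate_sas <- function(n, config = generator_config(),
                         prevalence = config$motif_prevalence_sensitive_sas,
                         scheme = residue_scheme(),
                         seed = config$seed, prefix = "SAS") {
  stopifnot(n >= 0)
  .with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) .one_sas(config, prevalence, scheme))
    data.frame(
      accession = sprintf("%s%04d", prefix, seq_len(n)),
      sequence = vapply(rows, `[[`, "", "sequence"),
      protein_class = rep("membrane", n),
      signal_type = rep("SAS", n),
      signal_start = vapply(rows, `[[`, 1L, "signal_start"),
      signal_end = vapply(rows, `[[`, 1L, "signal_end"),
      topology = if (n) sample(c("Nc", "Ne", "unspecified"), n,
                               replace = TRUE, prob = c(10, 1, 1) / 12)
                 else character(0),
      motif_planted = !is.na(vapply(rows, `[[`, 1L, "planted_patch1_start")),
      planted_patch1_start = vapply(rows, `[[`, 1L, "planted_patch1_start"),
      stringsAsFactors = FALSE)
  })
}

.one_sp <- function(config) {
  n_len <- sample(1:5, 1)
  h_len <- sample(7:15, 1)
  c_len <- sample(3:7, 1)
  sig <- c("M", .sample_res(n_len - 1L, c(K = 0.5, R = 0.5)),
           .sample_res(h_len, .CORE_RES),
           .sample_res(max(0L, c_len - 3L), .SPC_RES), "A", "Q", "A")
  mature <- .sample_res(8L, .TAIL_RES)
  list(sequence = paste(c(sig, mature), collapse = ""),
       signal_start = 1L, signal_end = length(sig))
}

#' Generate synthetic signal-peptide records
#'
#' Emulates cleavable signal peptides with the classic tripartite
#' architecture: a short positively charged n-region (1-5 residues), a
#' hydrophobic h-region (7-15 residues, bulky class only) and a polar
#' c-region (3-7 residues) ending in an Ala-X-Ala cleavage context. No
#' motif is planted: adjacent small-residue pairs cannot arise, matching
#' the observation that the motif is a signal-anchor feature.
#'
#' @inheritParams generate_sas
#' @param protein_class `"secretory"` (default) or `"membrane"`.
#' @return Cohort data.frame (same columns as [generate_sas()]).
#' @export
generate_sp <- function(n, config = generator_config(),
                        protein_class = "secretory",
                        seed = config$seed, prefix = "SP") {
  stopifnot(n >= 0)
  .with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) .one_sp(config))
    data.frame(
      accession = sprintf("%s%04d", prefix, seq_len(n)),
      sequence = vapply(rows, `[[`, "", "sequence"),
      protein_class = rep(protein_class, n),
      signal_type = rep("SP", n),
      signal_start = vapply(rows, `[[`, 1L, "signal_start"),
      signal_end = vapply(rows, `[[`, 1L, "signal_end"),
      topology = rep("unspecified", n),
      motif_planted = rep(FALSE, n),
      planted_patch1_start = rep(NA_integer_, n),
      stringsAsFactors = FALSE)
  })
}

.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate a label-swap SILAC ratio table with known truth
#'
#' Sensitive proteins receive a true DMSO/cotransin effect ratio drawn
#' uniformly from `ratio_effect_range`; resistant proteins have true
#' ratio 1. Observed forward and reverse ratios are the true ratio times
#' independent lognormal noise of coefficient of variation
#' `ratio_noise_cv`. Channel intensities consistent with the ratios are
#' emitted as well, so normalisation invariances can be exercised.
#'
#' @param config A [generator_config()].
#' @param n Number of proteins (default `config$n_proteins`).
#' @param seed Seed (default `config$seed`; `NULL` for current stream).
#' @return data.frame with `accession`, `forward_ratio`, `reverse_ratio`,
#'   `truth` (`"sensitive"`/`"resistant"`), `true_ratio`, and intensity
#'   columns `fwd_dmso`, `fwd_cotransin`, `rev_dmso`, `rev_cotransin`
#'   (forward: DMSO heavy, reverse: DMSO light).
#' @export
generate_silac_table <- function(config = generator_config(),
                                 n = config$n_proteins,
                                 seed = config$seed) {
  .with_seed(seed, {
    n_sens <- round(config$fraction_sensitive * n)
    sens <- rep(FALSE, n)
    if (n_sens > 0) sens[sample.int(n, n_sens)] <- TRUE
    true_ratio <- ifelse(sens,
                         stats::runif(n, config$ratio_effect_range[1],
                                      config$ratio_effect_range[2]),
                         1)
    fwd <- true_ratio * .lognoise(n, config$ratio_noise_cv)
    rev <- true_ratio * .lognoise(n, config$ratio_noise_cv)
    base_f <- exp(stats::rnorm(n, log(1e6), 0.8))
    base_r <- exp(stats::rnorm(n, log(1e6), 0.8))
    data.frame(
      accession = sprintf("PROT%04d", seq_len(n)),
      forward_ratio = fwd, reverse_ratio = rev,
      truth = ifelse(sens, "sensitive", "resistant"),
      true_ratio = true_ratio,
      fwd_dmso = base_f * fwd, fwd_cotransin = base_f,
      rev_dmso = base_r * rev, rev_cotransin = base_r,
      stringsAsFactors = FALSE)
  })
}

#' Generate synthetic concentration-response data
#'
#' Samples the sigmoidal inhibition curve at the given concentrations
#' (by default eight points log-spaced over the 1-50 micromolar assay
#' range) and multiplies each replicate by lognormal noise.
#'
#' @param ic50,hill,top,bottom Generating curve parameters (see
#'   [dose_response()]).
#' @param concentrations Micromolar concentrations (default
#'   `10^seq(log10(1), log10(50), length.out = 8)`).
#' @param replicates Replicates per concentration (default 3).
#' @param cv Coefficient of variation of the lognormal noise (default 0.1).
#' @param seed Seed (`NULL` for current stream).
#' @return data.frame with `concentration`, `replicate`, `response`.
#' @export
generate_dose_response <- function(ic50 = 6.5, hill = 1, top = 100,
                                   bottom = 0,
                                   concentrations =
                                     10^seq(log10(1), log10(50),
                                            length.out = 8),
                                   replicates = 3L, cv = 0.1, seed = NULL) {
  stopifnot(all(concentrations > 0), replicates >= 1)
  .with_seed(seed, {
    conc <- rep(concentrations, each = replicates)
    mu <- dose_response(conc, ic50, hill, top, bottom)
    data.frame(concentration = conc,
               replicate = rep(seq_len(replicates), length(concentrations)),
               response = mu * .lognoise(length(conc), cv))
  })
}

#' Deterministic synthetic stand-in for the screen's protein-level table
#'
#' The study's protein-level ratio table is published only as a PDF
#' supplement, so this function builds a *synthetic* stand-in with the
#' same stratum structure and classification outcome: 217 proteins — 53
#' secretory (all SP, 50 sensitive), 164 membrane (56 SP with 9
#' sensitive, 105 SAS with 11 sensitive, 3 unspecified with 1 sensitive)
#' — with deterministic ratio values placed on the sensitive (>1.65 both
#' experiments) or resistant side of the criterion. One non-sensitive
#' secretory protein is given reciprocal ratios (0.50/0.55), mimicking
#' the single up-regulated protein observed. No random numbers are used.
#'
#' @return Ratio data.frame with `accession`, `forward_ratio`,
#'   `reverse_ratio`, `protein_class`, `signal_type`.
#' @export
simulate_s1_table <- function() {
  strata <- data.frame(
    protein_class = c("secretory", "membrane", "membrane", "membrane"),
    signal_type = c("SP", "SP", "SAS", "unspecified"),
    total = c(53L, 56L, 105L, 3L),
    sensitive = c(50L, 9L, 11L, 1L),
    stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    ns <- strata$sensitive[i]
    nr <- strata$total[i] - ns
    f_s <- seq(2, 10, length.out = max(ns, 1L))[seq_len(ns)]
    r_s <- rev(f_s) * 0.95 + 0.4   # stays comfortably above the threshold
    f_r <- seq(0.75, 1.50, length.out = max(nr, 1L))[seq_len(nr)]
    r_r <- rev(f_r)
    rows[[i]] <- data.frame(
      protein_class = strata$protein_class[i],
      signal_type = strata$signal_type[i],
      forward_ratio = c(f_s, f_r), reverse_ratio = c(r_s, r_r),
      sensitive = rep(c(TRUE, FALSE), c(ns, nr)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  # one resistant secretory protein is up-regulated under treatment
  up <- which(out$protein_class == "secretory" & !out$sensitive)[1]
  out$forward_ratio[up] <- 0.50
  out$reverse_ratio[up] <- 0.55
  out$sensitive <- NULL
  out <- data.frame(accession = sprintf("SYN%04d", seq_len(nrow(out))), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a complete, linked set of pipeline inputs
#'
#' Builds a cohort (sequences plus annotations) and a matching ratio
#' table whose accessions agree, with the paper-shaped strata of
#' [generator_config()]: sensitive signal anchors carry the motif with
#' probability `motif_prevalence_sensitive_sas`, resistant ones with
#' probability `motif_prevalence_resistant_sas`, and ratio noise follows
#' the config. Ground truth is returned alongside, never only implied.
#'
#' @param config A [generator_config()].
#' @return List: `cohort` (sequence records with truth columns), `ratios`
#'   (ratio table with `truth`), `config`.
#' @export
simulate_inputs <- function(config = generator_config()) {
  .with_seed(config$seed, {
    n <- config$n_proteins
    n_secr <- round(config$fraction_secretory * n)
    n_mem <- n - n_secr
    n_sas <- round(n_mem * 105 / 164)
    n_msp <- round(n_mem * 56 / 164)
    n_uns <- n_mem - n_sas - n_msp
    # sensitivity truth per stratum, paper-shaped overall fraction
    sens_secr <- round(n_secr * 50 / 53)
    sens_sas <- round(n_sas * 11 / 105)
    sens_msp <- round(n_msp * 9 / 56)
    sens_uns <- min(n_uns, 1L)

    secr <- generate_sp(n_secr, config, seed = NULL, prefix = "SEC")
    msp <- generate_sp(n_msp, config, protein_class = "membrane",
                       seed = NULL, prefix = "MSP")
    sas_sens <- generate_sas(sens_sas, config,
                             prevalence = config$motif_prevalence_sensitive_sas,
                             seed = NULL, prefix = "SASS")
    sas_res <- generate_sas(n_sas - sens_sas, config,
                            prevalence = config$motif_prevalence_resistant_sas,
                            seed = NULL, prefix = "SASR")
    uns <- generate_sas(n_uns, config, prevalence = 0, seed = NULL,
                        prefix = "UNS")
    uns$signal_type <- rep("unspecified", nrow(uns))
    cohort <- rbind(secr, msp, sas_sens, sas_res, uns)
    truth <- c(rep(c(TRUE, FALSE), c(sens_secr, n_secr - sens_secr)),
               rep(c(TRUE, FALSE), c(sens_msp, n_msp - sens_msp)),
               rep(TRUE, sens_sas), rep(FALSE, n_sas - sens_sas),
               rep(c(TRUE, FALSE), c(sens_uns, n_uns - sens_uns)))
    cohort$truth <- ifelse(truth, "sensitive", "resistant")

    true_ratio <- ifelse(truth,
                         stats::runif(nrow(cohort),
                                      config$ratio_effect_range[1],
                                      config$ratio_effect_range[2]),
                         1)
    ratios <- data.frame(
      accession = cohort$accession,
      forward_ratio = true_ratio * .lognoise(nrow(cohort),
                                             config$ratio_noise_cv),
      reverse_ratio = true_ratio * .lognoise(nrow(cohort),
                                             config$ratio_noise_cv),
      protein_class = cohort$protein_class,
      signal_type = cohort$signal_type,
      truth = cohort$truth,
      stringsAsFactors = FALSE)
    list(cohort = cohort, ratios = ratios, config = config)
  })
}
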