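test_that("generators are pure functions of seed and config", {
  cfg <- generator_config(seed = 33)
  a <- generate_sas(20, cfg)
  b <- generate_sas(20, cfg)
  expect_identical(a, b)
  t1 <- withr::local_tempfile(fileext = ".fasta")
  t2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(a[, c("accession", "sequence")], t1)
  write_fasta(b[, c("accession", "sequence")], t2)
  expect_identical(readLines(t1), readLines(t2))  # byte-identical FASTA

  expect_identical(generate_sp(15, cfg), generate_sp(15, cfg))
  expect_identical(generate_silac_table(cfg), generate_silac_table(cfg))
  expect_identical(generate_dose_response(seed = 4),
                   generate_dose_response(seed = 4))
  expect_identical(simulate_inputs(cfg)$ratios, simulate_inputs(cfg)$ratios)

  expect_equal(nrow(generate_sas(0, cfg)), 0L)
  expect_equal(nrow(generate_sp(0, cfg)), 0L)
})

test_that("planted ground truth is emitted and honoured by the scanner", {
  cfg <- generator_config(seed = 60)
  full <- generate_sas(100, cfg, prevalence = 1)
  expect_true(all(full$motif_planted))
  scr <- screen_cohort(full)
  expect_true(all(scr$per_record$has_motif))
  # matched at the planted position, not just anywhere
  hit_at_planted <- vapply(seq_len(100), function(i) {
    m <- scan_sequence(full$sequence[i],
                       region = c(max(1, full$signal_start[i] - 2),
                                  min(nchar(full$sequence[i]),
                                      full$signal_end[i] + 2)))
    full$planted_patch1_start[i] %in% m$patch1_start
  }, TRUE)
  expect_true(all(hit_at_planted))

  none <- generate_sas(100, cfg, prevalence = 0)
  expect_false(any(none$motif_planted))
  expect_false(any(screen_cohort(none)$per_record$has_motif))
})

test_that("synthetic signal peptides are motif-free by construction", {
  sp <- generate_sp(50, generator_config(seed = 71))
  scr <- screen_cohort(sp)
  n_oracle <- vapply(seq_len(50), function(i) {
    region <- c(1L, min(nchar(sp$sequence[i]), sp$signal_end[i] + 2L))
    o <- oracle_scan_ccm(sp$sequence[i], region = region)
    if (is.null(o)) 0L else nrow(o)
  }, 1L)
  # scanner and independent oracle agree record by record...
  expect_equal(scr$per_record$n_matches, n_oracle)
  # ...and the empirical false-positive rate is zero: the generator's
  # c-regions cannot form an adjacent small-residue pair
  expect_equal(sum(scr$per_record$has_motif), 0L)
})

test_that("silac generator hits its stated noise and effect structure", {
  cfg <- generator_config(seed = 5, n_proteins = 1000, ratio_noise_cv = 0.2,
                          fraction_sensitive = 0.25)
  tab <- generate_silac_table(cfg)
  expect_equal(sum(tab$truth == "sensitive"), 250L)
  expect_true(all(tab$true_ratio[tab$truth == "resistant"] == 1))
  expect_true(all(tab$true_ratio[tab$truth == "sensitive"] >= 2))
  # observed/true ratio noise has roughly the configured CV
  noise <- tab$forward_ratio / tab$true_ratio
  expect_equal(sd(noise), 0.2, tolerance = 0.05)
  # fixed seed makes recovered sensitivity/specificity reproducible
  lab <- classify_protein(tab$forward_ratio, tab$reverse_ratio)
  sens1 <- mean(lab[tab$truth == "sensitive"] == "sensitive")
  tab2 <- generate_silac_table(cfg)
  lab2 <- classify_protein(tab2$forward_ratio, tab2$reverse_ratio)
  expect_identical(sens1, mean(lab2[tab2$truth == "sensitive"] == "sensitive"))

  none <- generate_silac_table(generator_config(seed = 6, n_proteins = 50,
                                                fraction_sensitive = 0,
                                                ratio_noise_cv = 0))
  expect_equal(sum(classify_protein(none$forward_ratio,
                                    none$reverse_ratio) == "sensitive"), 0L)
})

test_that("dose-response generator reduces to the closed form at cv 0", {
  d <- generate_dose_response(ic50 = 6.5, hill = 1.2, bottom = 5,
                              cv = 0, seed = 3)
  expect_equal(d$response,
               dose_response(d$concentration, 6.5, 1.2, 100, 5))
})

test_that("the synthetic screen-table stand-in carries the stated strata", {
  s1 <- simulate_s1_table()
  expect_equal(nrow(s1), 217L)
  expect_equal(sum(s1$protein_class == "secretory"), 53L)
  expect_equal(sum(s1$protein_class == "membrane"), 164L)
  expect_equal(sum(s1$protein_class == "membrane" & s1$signal_type == "SAS"),
               105L)
  expect_identical(s1, simulate_s1_table())  # deterministic, no RNG
})

test_that("linked simulation keeps cohort and ratio table consistent", {
  sim <- simulate_inputs(generator_config(seed = 9))
  expect_equal(sim$cohort$accession, sim$ratios$accession)
  expect_equal(nrow(sim$cohort), 217L)
  expect_equal(sum(sim$cohort$protein_class == "secretory"), 53L)
  expect_equal(sum(sim$cohort$signal_type == "SAS"), 105L)
  # sensitive signal anchors all carry the motif; resistant ones rarely
  sas <- sim$cohort[sim$cohort$signal_type == "SAS", ]
  expect_true(all(sas$motif_planted[sas$truth == "sensitive"]))
  expect_lt(mean(sas$motif_planted[sas$truth == "resistant"]), 0.2)
})
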