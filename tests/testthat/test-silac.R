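test_that("the dual-ratio criterion classifies as specified", {
  expect_equal(classify_protein(2.0, 1.8), "sensitive")
  expect_equal(classify_protein(2.0, 1.2), "resistant")
  expect_equal(classify_protein(0.50, 0.55), "up_regulated")
  expect_equal(classify_protein(0.50, 0.65), "resistant")  # 0.65 > 1/1.65
  expect_equal(classify_protein(NA, 2.0), "incomplete")
  # strict inequality: a tie at the threshold is resistant
  expect_equal(classify_protein(1.65, 3.0), "resistant")
  expect_equal(classify_protein(1.65 + 1e-9, 1.66), "sensitive")
  expect_error(classify_protein(2, 2, threshold = 1), "> 1")
  expect_error(classify_protein(-2, 2), "positive")
})

test_that("summary counts are conserved and strata are kept", {
  tab <- generate_silac_table(generator_config(seed = 2, n_proteins = 150))
  tab$protein_class <- rep(c("secretory", "membrane"), length.out = 150)
  tab$signal_type <- rep(c("SP", "SAS", "unspecified"), length.out = 150)
  res <- classify_table(tab)
  expect_equal(sum(res$summary$n), 150L)
  expect_equal(nrow(res$calls), 150L)
  expect_true("unspecified" %in% res$summary$signal_type)
  empty <- classify_table(tab[0, ])
  expect_equal(nrow(empty$summary), 0L)
})

test_that("dual filter is stricter than either single-experiment filter", {
  tab <- generate_silac_table(generator_config(seed = 8, n_proteins = 400,
                                               ratio_noise_cv = 0.4))
  lab <- classify_protein(tab$forward_ratio, tab$reverse_ratio)
  dual <- lab == "sensitive"
  fwd_only <- tab$forward_ratio > 1.65
  rev_only <- tab$reverse_ratio > 1.65
  expect_true(all(dual <= fwd_only))
  expect_true(all(dual <= rev_only))
})

test_that("truth is recovered exactly at zero noise", {
  cfg <- generator_config(seed = 4, n_proteins = 300, ratio_noise_cv = 0)
  tab <- generate_silac_table(cfg)
  lab <- classify_protein(tab$forward_ratio, tab$reverse_ratio)
  expect_equal(lab == "sensitive", tab$truth == "sensitive")
})

test_that("noisy recovery agrees with a row-by-row re-check", {
  cfg <- generator_config(seed = 31, n_proteins = 200, ratio_noise_cv = 0.1)
  tab <- generate_silac_table(cfg)
  res <- classify_table(tab)
  # independent per-row re-check of the rule
  manual <- ifelse(tab$forward_ratio > 1.65 & tab$reverse_ratio > 1.65,
                   "sensitive",
            ifelse(tab$forward_ratio < 1 / 1.65 & tab$reverse_ratio < 1 / 1.65,
                   "up_regulated", "resistant"))
  expect_identical(res$calls$label, manual)
  sens <- sum(manual == "sensitive" & tab$truth == "sensitive") /
    sum(tab$truth == "sensitive")
  spec <- sum(manual != "sensitive" & tab$truth == "resistant") /
    sum(tab$truth == "resistant")
  expect_gt(sens, 0.9)   # CV 10% with effects >= 2 misses few proteins
  expect_gt(spec, 0.99)
})

test_that("calls are invariant to rescaling one intensity channel", {
  tab <- generate_silac_table(generator_config(seed = 13, n_proteins = 120))
  r1 <- ratios_from_intensities(tab$fwd_dmso, tab$fwd_cotransin, "median")
  r2 <- ratios_from_intensities(tab$fwd_dmso * 7.3, tab$fwd_cotransin, "median")
  expect_equal(r1, r2)
  rr1 <- ratios_from_intensities(tab$rev_dmso, tab$rev_cotransin, "median")
  rr2 <- ratios_from_intensities(tab$rev_dmso, tab$rev_cotransin * 0.01,
                                 "median")
  expect_equal(classify_protein(r1, rr1), classify_protein(r2, rr2))
  # without normalisation the plain ratio reproduces the table
  expect_equal(ratios_from_intensities(tab$fwd_dmso, tab$fwd_cotransin),
               tab$forward_ratio)
})
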