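test_that("Fisher exact test matches enumeration on pinned tables", {
  # perfectly balanced table
  expect_equal(fisher_exact(5, 5, 5, 5)$p_value, 1.0)
  # margins (2,2)x(2,2): 3 possible tables, two as extreme as observed
  expect_equal(fisher_exact(2, 0, 0, 2)$p_value, 1 / 3, tolerance = 1e-12)
  # the screen's table: motif in 12/12 sensitive vs 5/143 non-sensitive
  # signal anchors; p pinned by the pre-build enumeration oracle
  res <- fisher_exact(12, 0, 5, 138)
  expect_equal(res$p_value, 2.3855194195e-14, tolerance = 1e-9)
  expect_true(is.infinite(res$odds_ratio))
  expect_error(fisher_exact(0, 0, 0, 0), "all-zero")
  expect_equal(fisher_exact(3, 1, 2, 4)$odds_ratio, 6)
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(7)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p_value,
                 stats::fisher.test(tab)$p.value,
                 tolerance = 1e-10,
                 label = paste("table", paste(tab, collapse = ",")))
  }
})

test_that("Fisher p is invariant under simultaneous row and column swaps", {
  set.seed(21)
  for (i in 1:100) {
    x <- rpois(4, 5)
    if (sum(x) == 0) next
    p1 <- fisher_exact(x[1], x[2], x[3], x[4])$p_value
    p2 <- fisher_exact(x[4], x[3], x[2], x[1])$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("GRAVY is the mean Kyte-Doolittle hydropathy", {
  expect_equal(gravy("AAAA"), 1.8)
  expect_equal(gravy("AL"), 2.8)
  expect_equal(gravy("ALX"), 2.8)   # X excluded from both sums
  expect_error(gravy(""), "non-empty")
  expect_error(gravy("XXX"), "hydropathy")
  # length-weighted mean property over random pairs
  set.seed(12)
  for (i in 1:50) {
    s1 <- random_seq(sample(1:30, 1), AA_STANDARD)
    s2 <- random_seq(sample(1:30, 1), AA_STANDARD)
    w <- nchar(c(s1, s2))
    expect_equal(gravy(paste0(s1, s2)),
                 sum(w * c(gravy(s1), gravy(s2))) / sum(w))
  }
})

test_that("frequency profiles use half-open bins and sum to 100", {
  p <- frequency_profile(c(20, 21, 22, 23), 4, c(0, 50))
  expect_equal(p$percent[p$bin_lo == 20], 100)
  expect_equal(sum(p$percent), 100)

  p2 <- frequency_profile(c(0, 4), 4, c(0, 8))
  expect_equal(p2$percent, c(50, 50))

  expect_error(frequency_profile(numeric(), 4, c(0, 50)), "no values")

  # GRAVY values of synthetic signal anchors rescaled to the 0-100 axis
  cohort <- generate_sas(12, seed = 5)
  gv <- vapply(substring(cohort$sequence, cohort$signal_start,
                         cohort$signal_end), gravy, 0)
  p3 <- frequency_profile(gv, 4, c(0, 100), rescale = c(-4.5, 4.5, 0, 100))
  expect_equal(sum(p3$percent), 100, tolerance = 1e-9)
  expect_equal(attr(p3, "n_outside"), 0L)

  # out-of-range values land in boundary bins and are flagged
  p4 <- frequency_profile(c(-5, 2, 200), 4, c(0, 100))
  expect_equal(sum(p4$percent), 100, tolerance = 1e-9)
  expect_equal(attr(p4, "n_outside"), 2L)
  set.seed(3)
  for (i in 1:20) {
    pr <- frequency_profile(runif(sample(1:50, 1), -3, 3), 0.5, c(-4, 4))
    expect_equal(sum(pr$percent), 100, tolerance = 1e-9)
  }
})

test_that("enrichment assembles the sensitive-by-motif table correctly", {
  cfg <- generator_config(seed = 17)
  sens <- generate_sas(12, cfg, prevalence = 1, seed = 41, prefix = "SEN")
  res <- generate_sas(30, cfg, prevalence = 0, seed = 42, prefix = "RES")
  cohort <- rbind(sens, res)
  calls <- data.frame(accession = cohort$accession,
                      label = rep(c("sensitive", "resistant"), c(12, 30)))
  scr <- screen_cohort(cohort, calls = calls)
  er <- enrichment_report(scr, calls)
  expect_equal(as.vector(er$table), c(12L, 0L, 0L, 30L))
  expect_equal(er$n, 42L)
  expect_equal(er$p_value, oracle_fisher_p(12, 0, 0, 30), tolerance = 1e-12)
  expect_true(is.infinite(er$odds_ratio))
})

test_that("null Fisher p-values are conservative (never super-uniform)", {
  # exact tests on discrete tables are conservative: the null cdf of p
  # must not exceed the uniform cdf beyond one-sided KS fluctuation
  set.seed(19)
  n_sim <- 500
  p <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    a <- rbinom(1, 12, 0.3)
    c_ <- rbinom(1, 143, 0.3)
    p[i] <- fisher_exact(a, 12 - a, c_, 143 - c_)$p_value
  }
  grid <- seq(0.01, 0.99, by = 0.01)
  excess <- max(vapply(grid, function(t) mean(p <= t) - t, 0))
  expect_lt(excess, 1.22 / sqrt(n_sim))  # one-sided KS ~1% bound
})
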