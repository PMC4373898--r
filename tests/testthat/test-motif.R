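test_that("PROSITE-dialect patterns compile as written", {
  p <- compile_pattern("[GASTC](2)-x(2,3)-[GASTC](1,2)")
  expect_length(p$elements, 3L)
  expect_equal(vapply(p$elements, `[[`, 1L, "min"), c(2L, 2L, 1L))
  expect_equal(vapply(p$elements, `[[`, 1L, "max"), c(2L, 3L, 2L))
  expect_setequal(p$elements[[1]]$set, c("G", "A", "S", "T", "C"))
  expect_setequal(p$elements[[2]]$set, AA_STANDARD)

  # negation is the complement over the 20 standard residues
  q <- compile_pattern("{GASTC}(2)")
  expect_length(q$elements[[1]]$set, 15L)
  expect_length(intersect(q$elements[[1]]$set, c("G", "A", "S", "T", "C")), 0L)

  expect_error(compile_pattern("[GASTC](3,2)"), "1 <= m <= n")
  expect_error(compile_pattern("[GASTC"), "unbalanced")
  expect_error(compile_pattern("[GAB]"), "position 4")
  expect_error(compile_pattern("[GA]-"), "trailing")
})

test_that("generic pattern scans report maximal matches at each start", {
  p <- compile_pattern("[GASTC](2)-x(2,3)-[GASTC](1,2)")
  m <- scan_sequence("KGGLLAA", p)
  expect_equal(m$start, 2L)
  expect_equal(m$end, 7L)  # widths resolved to the longest valid parse
  expect_equal(nrow(scan_sequence("KLLLLLL", p)), 0L)
})

test_that("the motif family enumerates 12 concrete variants", {
  fam <- ccm_pattern_family()
  expect_length(fam$variants, 12L)
  key <- vapply(fam$variants, `[[`, "", "id")
  expect_equal(anyDuplicated(key), 0L)
  seps <- vapply(fam$variants, `[[`, 1L, "sep_len")
  p2s <- vapply(fam$variants, `[[`, 1L, "p2_len")
  sides <- vapply(fam$variants, `[[`, "", "flank_side")
  expect_setequal(unique(seps), 2:3)
  expect_setequal(unique(p2s), 1:2)
  expect_setequal(unique(sides), c("left", "right", "both"))
  expect_error(residue_scheme(flank = character()), "non-empty")
})

test_that("motif scan reproduces the hand-derived example matches", {
  m <- scan_sequence("KGGLLA")
  expect_equal(nrow(m), 1L)
  expect_equal(m$left_flank, 1L)
  expect_equal(c(m$patch1_start, m$patch1_end), c(2L, 3L))
  expect_equal(c(m$sep_start, m$sep_end), c(4L, 5L))
  expect_equal(c(m$patch2_start, m$patch2_end), c(6L, 6L))
  expect_true(is.na(m$right_flank))

  # no flank on either side -> no match
  expect_equal(nrow(scan_sequence("GGLLA")), 0L)
  expect_error(scan_sequence(""), "empty")
  expect_error(scan_sequence("KGGLLA", region = c(2, 9)), "region")
})

test_that("alternative parses collapse per first-patch start", {
  # both separator lengths fit: the shorter one is preferred, and the
  # longer second patch is taken when consistent
  m <- scan_sequence("KGGLLGGK")
  expect_equal(nrow(m), 1L)
  expect_equal(m$sep_end - m$sep_start + 1L, 2L)
  expect_equal(m$patch2_end - m$patch2_start + 1L, 2L)
  expect_equal(m$left_flank, 1L)
  expect_equal(m$right_flank, 8L)
  all_p <- scan_sequence("KGGLLGGK", all_parses = TRUE)
  expect_gt(nrow(all_p), nrow(m))
})

test_that("scanner agrees exactly with the brute-force oracle", {
  sch <- residue_scheme()
  # exhaustive over the reduced alphabet up to length 5
  for (len in 1:5) {
    grid <- do.call(expand.grid,
                    rep(list(c("G", "L", "K", "A")), len))
    seqs <- do.call(paste0, grid)
    for (s in seqs) expect_scan_agrees(s, sch)
  }
  # seeded random sample of longer sequences (caps the 4^12 space)
  set.seed(424242)
  for (i in 1:2000) {
    expect_scan_agrees(random_seq(sample(6:12, 1)), sch)
  }
})

test_that("enlarging the small set never loses matched sequences", {
  base <- residue_scheme(small = c("G", "A", "S", "T", "C"),
                         bulky = c("L", "I", "V", "F", "M", "W", "P"))
  wider <- residue_scheme(small = c("G", "A", "S", "T", "C", "N", "Y"),
                          bulky = c("L", "I", "V", "F", "M", "W", "P"))
  set.seed(99)
  seqs <- replicate(300, random_seq(sample(8:20, 1), AA_STANDARD))
  hit <- function(scheme) {
    fam <- ccm_pattern_family(scheme)
    vapply(seqs, function(s) nrow(scan_sequence(s, fam)) > 0, TRUE)
  }
  h1 <- hit(base)
  h2 <- hit(wider)
  expect_true(all(h2[h1]))          # subset relation, sequence by sequence
  expect_gte(sum(h2), sum(h1))
})

test_that("cohort screening restricts to the widened signal window", {
  cfg <- generator_config(seed = 5)
  cohort <- rbind(generate_sas(2, cfg, prevalence = 1, seed = 21),
                  generate_sas(1, cfg, prevalence = 0, seed = 22,
                               prefix = "NEG"))
  scr <- screen_cohort(cohort)
  expect_equal(sum(scr$per_record$has_motif), 2L)
  expect_equal(sum(!scr$per_record$has_motif), 1L)
  expect_equal(scr$n_skipped, 0L)
  expect_equal(sum(scr$summary$n), 3L)

  # empty cohort -> all-zero summary
  scr0 <- screen_cohort(cohort[0, ])
  expect_equal(nrow(scr0$per_record), 0L)
  expect_equal(scr0$n_skipped, 0L)

  # no small patch can exist in poly-L, K flank or not
  polyL <- data.frame(accession = "L1", sequence = "KLLLLLLLLLL",
                      protein_class = "membrane", signal_type = "SAS",
                      signal_start = 2L, signal_end = 11L,
                      topology = "Nc", stringsAsFactors = FALSE)
  expect_equal(sum(screen_cohort(polyL)$per_record$has_motif), 0L)

  # records with missing boundaries are skipped, not matched
  broken <- cohort
  broken$signal_start[1] <- NA_integer_
  scrb <- screen_cohort(broken)
  expect_equal(scrb$n_skipped, 1L)
  expect_true(scrb$per_record$skipped[1])

  # a motif outside the signal window does not count: the planted match
  # disappears when the window is moved to the N-tail
  shifted <- cohort[1, ]
  shifted$signal_end <- shifted$signal_start - 1L + 4L
  shifted$signal_start <- 1L
  pl <- cohort$planted_patch1_start[1]
  if (pl > shifted$signal_end + 4L) {
    expect_equal(sum(screen_cohort(shifted)$per_record$has_motif), 0L)
  }
})
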