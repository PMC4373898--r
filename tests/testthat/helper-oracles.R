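# Independent oracles used to pin expected values. These deliberately use
# different machinery (regex lookahead, choose()-arithmetic, exhaustive
# enumeration) than the package implementation they check.

# Brute-force consensus-motif matcher built on PCRE lookahead regexes.
# Enumerates every concrete variant at every offset, then collapses
# alternative parses per first-patch start with the documented preference
# (shorter separator, then longer second patch).
oracle_scan_ccm <- function(sequence, scheme = residue_scheme(),
                            region = NULL) {
  n <- nchar(sequence)
  if (is.null(region)) region <- c(1L, n)
  sub <- substr(sequence, region[1], region[2])
  cls <- function(set) paste0("[", paste(set, collapse = ""), "]")
  cand <- list()
  for (s in 2:3) {
    for (p in 1:2) {
      for (side in c("left", "right", "both")) {
        core <- paste0(cls(scheme$small), "{2}", cls(scheme$bulky),
                       "{", s, "}", cls(scheme$small), "{", p, "}")
        rx <- switch(side,
                     left = paste0(cls(scheme$flank), core),
                     right = paste0(core, cls(scheme$flank)),
                     both = paste0(cls(scheme$flank), core, cls(scheme$flank)))
        hits <- gregexpr(paste0("(?=", rx, ")"), sub, perl = TRUE)[[1]]
        if (hits[1] == -1) next
        for (h in as.integer(hits)) {
          p1 <- region[1] + h - 1L + (side %in% c("left", "both"))
          cand[[length(cand) + 1L]] <-
            data.frame(p1 = p1, s = s, p = p, side = side)
        }
      }
    }
  }
  if (!length(cand)) return(NULL)
  cand <- do.call(rbind, cand)
  out <- list()
  for (p1 in sort(unique(cand$p1))) {
    cc <- cand[cand$p1 == p1, , drop = FALSE]
    cc <- cc[order(cc$s, -cc$p), , drop = FALSE]
    pick <- cc[1, ]
    same <- cc[cc$s == pick$s & cc$p == pick$p, , drop = FALSE]
    left_ok <- any(same$side %in% c("left", "both"))
    right_ok <- any(same$side %in% c("right", "both"))
    p2_end <- p1 + 1L + pick$s + pick$p
    out[[length(out) + 1L]] <- data.frame(
      patch1_start = p1, sep_len = pick$s, p2_len = pick$p,
      left_flank = if (left_ok) p1 - 1L else NA_integer_,
      right_flank = if (right_ok) p2_end + 1L else NA_integer_)
  }
  do.call(rbind, out)
}

# Fisher two-sided p by direct enumeration with exact binomial-coefficient
# arithmetic (no dhyper); probability-mass rule.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  pr <- exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  min(1, sum(pr[pr <= pr[x == a] * (1 + 1e-7)]))
}

# Exhaustive minimal-mutation oracle: tries every subset of window
# positions up to max_k with every assignment of the representative
# replacements, and returns the smallest cardinality that creates a
# motif match inside the window (Inf if none).
oracle_min_mutations <- function(sequence, window = NULL,
                                 scheme = residue_scheme(), max_k = 4,
                                 allow_flank_mutations = TRUE) {
  n <- nchar(sequence)
  if (is.null(window)) window <- c(1L, n)
  fam <- ccm_pattern_family(scheme)
  has_match <- function(seq) {
    nrow(scan_sequence(seq, fam, region = window)) > 0
  }
  reps <- c("G", "L", "K")
  if (!allow_flank_mutations) reps <- c("G", "L")
  if (has_match(sequence)) return(0L)
  positions <- window[1]:window[2]
  chars <- strsplit(sequence, "")[[1]]
  for (k in seq_len(max_k)) {
    subsets <- utils::combn(positions, k, simplify = FALSE)
    grid <- as.matrix(expand.grid(rep(list(reps), k),
                                  stringsAsFactors = FALSE))
    for (ss in subsets) {
      for (g in seq_len(nrow(grid))) {
        mut <- chars
        mut[ss] <- grid[g, ]
        if (has_match(paste(mut, collapse = ""))) return(k)
      }
    }
  }
  Inf
}

# Random sequence over an alphabet (used by property tests).
random_seq <- function(len, alphabet = c("G", "L", "K", "A")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Compare implementation scan against the regex oracle on one sequence.
expect_scan_agrees <- function(sequence, scheme = residue_scheme(),
                               region = NULL) {
  got <- scan_sequence(sequence, ccm_pattern_family(scheme), region = region)
  exp <- oracle_scan_ccm(sequence, scheme, region)
  if (is.null(exp)) {
    expect_identical(nrow(got), 0L, label = paste("matches in", sequence))
    return(invisible())
  }
  expect_identical(got$patch1_start, exp$patch1_start,
                   label = paste("patch1 starts in", sequence))
  expect_identical(got$sep_end - got$sep_start + 1L, exp$sep_len,
                   label = paste("separator lengths in", sequence))
  expect_identical(got$patch2_end - got$patch2_start + 1L, exp$p2_len,
                   label = paste("patch2 lengths in", sequence))
  expect_identical(got$left_flank, exp$left_flank,
                   label = paste("left flanks in", sequence))
  expect_identical(got$right_flank, exp$right_flank,
                   label = paste("right flanks in", sequence))
}
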