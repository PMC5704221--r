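test_that("regularize_pwm applies the background-weighted pseudocount", {
  p <- pwm("M", "T", matrix(c(1, 0, 0, 0, 0.5, 0.5, 0, 0), nrow = 2, byrow = TRUE))
  cfg0 <- scan_config(pseudocount = 0)
  expect_equal(regularize_pwm(p, cfg0)$prob, p$prob)
  cfg <- scan_config(pseudocount = 0.01)
  reg <- regularize_pwm(p, cfg)
  expect_equal(unname(reg$prob[1, ]), c(1.0025, 0.0025, 0.0025, 0.0025) / 1.01)
  set.seed(21)
  for (w in c(1, 4, 9)) {
    r <- regularize_pwm(random_pwm(w), cfg)
    expect_equal(unname(rowSums(r$prob)), rep(1, w))
    expect_true(all(r$prob > 0))
  }
})

test_that("log-odds scoring satisfies its algebraic identities", {
  cfg <- scan_config(pseudocount = 0)
  # PWM equal to the background scores zero everywhere
  flat <- pwm("F", "T", matrix(0.25, nrow = 3, ncol = 4))
  expect_equal(unname(pwm_log_odds(flat, cfg)), matrix(0, 3, 4))
  # a certain base under uniform background scores log2(1/0.25) = 2 bits
  pm <- pwm("P", "T", matrix(c(1, 0, 0, 0), nrow = 1))
  expect_error(pwm_log_odds(pm, cfg), "positive")
  reg <- regularize_pwm(pm, scan_config(pseudocount = 1e-12))
  expect_equal(unname(pwm_log_odds(reg, cfg)[1, 1]), 2, tolerance = 1e-9)
  # sum_x b[x] * 2^s[i,x] = 1 for every position
  set.seed(22)
  bg <- c(0.3, 0.2, 0.2, 0.3)
  cfg_bg <- scan_config(background = bg)
  s <- pwm_log_odds(regularize_pwm(random_pwm(6), cfg_bg), cfg_bg)
  expect_equal(unname(rowSums(sweep(2^s, 2, bg, `*`))), rep(1, 6))
})

test_that("the exact score distribution matches single-position enumeration", {
  # width 1, uniform background: point-mass regularised with a tiny
  # pseudocount puts probability 0.25 on the top score
  s <- matrix(c(2, -5, -7, -9), nrow = 1)
  d <- score_distribution(s, rep(0.25, 4), granularity = 0.001)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  expect_equal(score_pvalue(d, 2), 0.25)
  expect_equal(score_pvalue(d, -9), 1)          # minimum achievable score
  expect_equal(score_pvalue(d, 2.5), 0)         # above the maximum
  expect_equal(score_pvalue(d, -5), 0.5)
})

test_that("DP p-values equal exhaustive enumeration for random PWMs", {
  set.seed(23)
  cfg <- scan_config()
  for (trial in 1:6) {
    w <- sample(4:6, 1)
    sc <- grnrewire:::motif_scorer(random_pwm(w), cfg)
    en <- bf_enumerate_scores(sc$dist$int_matrix, cfg$background)
    expect_equal(sum(sc$dist$prob), 1, tolerance = 1e-9)
    for (t in sample(unique(en$tot), min(25, length(unique(en$tot))))) {
      expect_equal(score_pvalue(sc$dist, t, integer_score = TRUE),
                   bf_tail_pvalue(en, t), tolerance = 1e-9)
    }
    # p-value at the minimum achievable score is 1
    expect_equal(score_pvalue(sc$dist, min(en$tot), integer_score = TRUE), 1,
                 tolerance = 1e-9)
  }
})

test_that("the score grid cap rejects over-fine granularities", {
  s <- matrix(rep(c(2, -12, -12, -12), 10), nrow = 10, byrow = TRUE)
  expect_error(score_distribution(s, granularity = 1e-7, max_grid = 1e6),
               "granularity")
})

test_that("scanning the consensus of a width-8 point-mass motif yields one hit", {
  pm <- point_pwm("GGATCCTT")  # non-palindromic consensus
  cfg <- scan_config(alpha = 1e-4)
  h <- scan_peak(pwm_consensus(pm), pm, cfg, peak_id = "pk")
  expect_equal(nrow(h), 1L)
  expect_equal(h$offset, 0L)
  expect_equal(h$strand, "+")
  expect_equal(h$pvalue, 4^-8, tolerance = 1e-12)
  # the reverse complement reports the same hit on the minus strand
  h2 <- scan_peak(grnrewire:::revcomp(pwm_consensus(pm)), pm, cfg)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$offset, 0L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$pvalue, h$pvalue)
})

test_that("scan_peak skips N windows and handles degenerate input", {
  pm <- point_pwm("AAACGTCC")  # deliberately non-palindromic
  cfg <- scan_config()
  expect_equal(nrow(scan_peak(strrep("N", 50), pm, cfg)), 0L)
  expect_equal(nrow(scan_peak("ACG", pm, cfg)), 0L)  # shorter than the motif
  # an N inside the only matching window suppresses the hit
  seq_n <- paste0("AAACGNCC", strrep("A", 20))
  expect_equal(nrow(scan_peak(seq_n, pm, cfg)), 0L)
  with_hit <- paste0("AAACGTCC", strrep("N", 20))
  expect_equal(nrow(scan_peak(with_hit, pm, cfg)), 1L)
})

test_that("scan is strand-symmetric and monotone in alpha", {
  set.seed(25)
  seq_r <- random_dna(400)
  p <- random_pwm(7)
  loose <- scan_peak(seq_r, p, scan_config(alpha = 0.05))
  tight <- scan_peak(seq_r, p, scan_config(alpha = 0.001))
  expect_true(all(paste(tight$offset, tight$strand) %in%
                  paste(loose$offset, loose$strand)))
  expect_true(all(loose$pvalue <= 0.05))
  # mirror-image hit lists on the reverse complement
  rc <- scan_peak(grnrewire:::revcomp(seq_r), p, scan_config(alpha = 0.05))
  expect_equal(nrow(rc), nrow(loose))
  mirrored <- data.frame(offset = 400L - 7L - loose$offset,
                         strand = ifelse(loose$strand == "+", "-", "+"),
                         score = loose$score)
  mirrored <- mirrored[order(mirrored$offset, mirrored$strand), ]
  expect_equal(rc$offset, mirrored$offset)
  expect_equal(rc$strand, mirrored$strand)
  expect_equal(rc$score, mirrored$score, tolerance = 1e-9)
})

test_that("background scanning is calibrated to the analytic expectation", {
  set.seed(26)
  L <- 2e5
  alpha <- 1e-3
  p <- random_pwm(8)
  hits <- scan_peak(random_dna(L), p, scan_config(alpha = alpha))
  expected <- expected_background_hits(L, alpha, 8)
  expect_lt(abs(nrow(hits) - expected), 4 * sqrt(expected))
})

test_that("scan_all extracts peak sequences and keeps deterministic order", {
  set.seed(27)
  genome <- Biostrings::DNAStringSet(c(chr1 = random_dna(4000)))
  pm <- point_pwm("ACGTACGTAC", id = "M1", tfs = "T1")
  # plant the consensus at a known position inside a peak
  gs <- as.character(genome[[1]])
  substr(gs, 1021, 1030) <- pwm_consensus(pm)
  genome <- Biostrings::DNAStringSet(c(chr1 = gs))
  peaks <- data.frame(chrom = "chr1", start = c(1000L, 2000L), end = c(1200L, 2200L),
                      peak_id = c("p1", "p2"), summit_offset = NA_integer_,
                      stringsAsFactors = FALSE)
  hits <- scan_all(peaks, genome, list(pm), scan_config())
  expect_true(any(hits$peak_id == "p1" & hits$offset == 20L & hits$strand == "+"))
  expect_identical(hits, scan_all(peaks, genome, list(pm), scan_config()))
  # unknown chromosome and out-of-bounds peaks are rejected
  bad <- peaks; bad$chrom <- "chrZ"
  expect_error(scan_all(bad, genome, list(pm), scan_config()), "chrZ")
  oob <- peaks; oob$end[2] <- 10000L
  expect_error(scan_all(oob, genome, list(pm), scan_config()), "past the end")
})
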