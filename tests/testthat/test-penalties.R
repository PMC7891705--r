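test_that("GC-content penalty reproduces its anchor values", {
  expect_equal(p_gcc(50), 0)
  expect_equal(p_gcc(c(40, 60)), c(0, 0))
  expect_equal(p_gcc(c(0, 100)), c(1e6, 1e6))
  expect_equal(round(gcc_norm_score(0)), 4023)
  # direct evaluation of the closed form at an interior point
  f <- function(g) 22662.54 * exp(-(g - 50)^2 / (2 * 14.74996^2))
  gbar25 <- f(25) / f(40) * 1e6
  expect_equal(p_gcc(25), (1e6 - gbar25) / (1e6 - f(0) / f(40) * 1e6) * 1e6)
  # Gaussian symmetry about the center
  g <- seq(0, 50, by = 2.5)
  expect_equal(p_gcc(g), p_gcc(100 - g))
  expect_error(p_gcc(101), "0, 100")
})

test_that("homopolymer and repeat penalties follow the exponential curves", {
  expect_equal(p_hp(c(1, 2)), c(2, 2))
  expect_equal(p_hp(3), 1e6 * (1 - exp(-1.31322)) + 2)
  expect_equal(p_sr(c(1, 2)), c(6, 6))
  expect_equal(p_sr(3), 1e6 * (1 - exp(-3.010114)) + 6)
  # strictly increasing beyond 2, bounded
  hp_vals <- p_hp(2:12)
  sr_vals <- p_sr(2:6)
  expect_true(all(diff(hp_vals) > 0))
  expect_true(all(diff(sr_vals) > 0))
  expect_true(all(hp_vals <= 1e6 + 2) && all(sr_vals <= 1e6 + 6))
  expect_error(p_hp(0), ">= 1")
})

test_that("mismatch penalty follows the sequencing-error ladder", {
  expect_equal(p_hd(1), 1e6, tolerance = 1e-9)
  expect_equal(p_hd(2), 1e3, tolerance = 1e-9)
  expect_equal(p_hd(3), 1, tolerance = 1e-9)
  expect_identical(p_hd(c(4, 5, 12)), c(0, 0, 0))
  expect_equal(p_hd(1) / p_hd(2), 1e3, tolerance = 1e-9)
  expect_equal(p_hd(2) / p_hd(3), 1e3, tolerance = 1e-9)
  expect_equal(p_hd(0), 1e9)  # duplicate barcodes dominate everything
  expect_true(all(diff(p_hd(0:6)) <= 0))
})

test_that("complementarity penalty steps by 100 per extra base pair", {
  expect_equal(p_cp(8:12, l = 12), c(1, 1e2, 1e4, 1e6, 1e8),
               tolerance = 5e-3)
  expect_identical(p_cp(0:7, l = 12), rep(0, 8))
  expect_equal(p_cp(6, l = 8), 1e2, tolerance = 5e-3)  # rescaled cp = 9
  expect_true(all(diff(p_cp(0:12, l = 12)) >= 0))
  expect_error(p_cp(5, l = 0), "positive")
  expect_error(p_cp(9, l = 8), "in \\[0, l\\]")
})

test_that("weighted totals combine components linearly", {
  expect_equal(barcode_total_penalty(rep(0, 5)), 0)
  expect_equal(barcode_total_penalty(1:5, barcode_weights(1, 1, 1, 1, 1)), 15)
  expect_equal(barcode_total_penalty(rep(10, 5)), 620)
  expect_error(barcode_weights(0, 0, 0, 0, 0), "at least one")
  expect_error(barcode_weights(-1, 1, 1, 1, 1), "non-negative")
})

test_that("parameter validation rejects inconsistent penalty constants", {
  expect_error(penalty_params(gcc_amp = -1), "positive")
  expect_error(penalty_params(gcc_best_lo = 55), "gcc_best_lo")
  expect_error(penalty_params(hp_c = 0.5), "negative")
})

test_that("set scoring matches a brute-force all-pairs recomputation", {
  barcodes <- c("AGCTAAGCTACC", "GGGGCAGTCGGG", "ACACACACACAC",
                "TTTTTTTTTTTT", "AGTCCGATAGCT")
  params <- penalty_params()
  w <- barcode_weights()
  scored <- score_barcode_set(barcodes, params, w)
  ref <- oracle_set_totals(barcodes, params, w)
  expect_equal(scored$totals, ref$totals, tolerance = 1e-10)
  expect_equal(scored$p_wt, ref$p_wt, tolerance = 1e-10)
  expect_equal(scored$table$P_T, ref$p_t, tolerance = 1e-10)
  # the two routes to the objective agree: sum of P_T vs weighted totals
  expect_equal(sum(scored$table$P_T), scored$p_wt, tolerance = 1e-6)
})

test_that("set scoring handles degenerate sets", {
  one <- score_barcode_set("ACGTACGTACGT")
  expect_equal(unname(one$totals[c("P_HDt", "P_CPt")]), c(0, 0))
  # each unordered pair contributes to both members' components
  two <- score_barcode_set(c("ACGTACGTACGT", "ACGTACGTACGA"))
  s <- p_hd(hamming("ACGTACGTACGT", "ACGTACGTACGA"))
  expect_equal(unname(two$totals["P_HDt"]), 2 * s)
  # duplicated user input is scored at the duplicate penalty, not dropped
  dup <- score_barcode_set(c("ACGTACGTACGT", "ACGTACGTACGT"))
  expect_equal(unname(dup$totals["P_HDt"]), 2 * penalty_params()$hd_amp)
})

test_that("zero-weight pairwise factors can be skipped without changing the objective", {
  set.seed(99)
  b <- random_seqs(40, 12)
  w <- barcode_weights(20, 20, 20, 0, 0)
  full <- score_barcode_set(b, weights = w)
  skim <- score_barcode_set(b, weights = w, skip_zero_weight_pairs = TRUE)
  expect_equal(skim$p_wt, full$p_wt)
  expect_equal(unname(skim$totals[c("P_HDt", "P_CPt")]), c(0, 0))
})
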