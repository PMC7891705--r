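test_that("random-barcode characterization is reproducible and calibrated", {
  ch1 <- characterize_random(12, n_barcodes = 1000, pair_sample = 2e4,
                             seed = 8)
  ch2 <- characterize_random(12, n_barcodes = 1000, pair_sample = 2e4,
                             seed = 8)
  expect_identical(as.data.frame(ch1), as.data.frame(ch2))
  # uniform barcodes: mean GC near 50%, mean pairwise distance near 3/4 l
  expect_lt(abs(ch1$gcc$mean - 50), 1)
  expect_lt(abs(ch1$hd$mean - 0.75 * 12), 0.05 * 12)
  # histogram counts account for every evaluated item
  expect_equal(sum(ch1$gcc$histogram$count), 1000)
  expect_equal(sum(ch1$hd$histogram$count), 2e4)
})

test_that("histogram modes break ties toward the smaller value", {
  s <- oligobarcodes:::distribution_summary(
    "hd", data.frame(value = c(3, 5, 7), count = c(4, 4, 1)),
    n_items = 9, n_sets = 1, l = 8, stat = "sum")
  expect_equal(s$mode, 3)
})

test_that("curve refitting recovers generating parameters exactly on model data", {
  gcc_hist <- data.frame(value = seq(0, 100, length.out = 13))
  gcc_hist$count <- 1200 * exp(-(gcc_hist$value - 48)^2 / (2 * 13^2))
  hp_hist <- data.frame(value = 2:8)
  hp_hist$count <- 5e5 * exp(-1.25 * hp_hist$value)
  sr_hist <- data.frame(value = 2:6)
  sr_hist$count <- 2e6 * exp(-2.9 * sr_hist$value)
  fake <- list(gcc = list(histogram = gcc_hist),
               hp = list(histogram = hp_hist),
               sr = list(histogram = sr_hist))
  fit <- fit_penalty_curves(fake)
  expect_equal(unname(fit$gcc), c(1200, 48, 13), tolerance = 1e-3)
  expect_equal(unname(fit$hp), c(5e5, -1.25), tolerance = 1e-3)
  expect_equal(unname(fit$sr), c(2e6, -2.9), tolerance = 1e-3)
  expect_error(fit_penalty_curves(list(gcc = list(histogram =
    data.frame(value = c(40, 50), count = c(1, 2))))), "degenerate")
})

test_that("refitting on fresh random 12-mers reproduces the shipped Gaussian", {
  ch <- characterize_random(12, n_barcodes = 5000, n_sets = 8,
                            pair_sample = 1000, seed = 42)
  fit <- fit_penalty_curves(ch)
  expect_lt(abs(fit$gcc[["mu"]] - 50), 1)
  expect_lt(abs(fit$gcc[["sigma"]] - 14.74996), 0.5)
})

test_that("heavier intrinsic weights do not hurt the percent decrease", {
  grid <- data.frame(w1 = c(1, 20), w2 = c(1, 20), w3 = c(1, 20),
                     w4 = c(1, 1), w5 = c(1, 1))
  res <- grid_search_weights(grid, l = 12, n = 300, runs = 3, seed = 2)
  expect_equal(nrow(res), 2)
  expect_gte(res$median_p_dec[2], res$median_p_dec[1])
  expect_equal(attr(res, "best"), 2L)
})

test_that("the alpha sweep reports one deterministic row per condition", {
  res1 <- alpha_sweep(alphas = c(0.1, 0.3), l = 12, n = 150, runs = 2,
                      seed = 6)
  res2 <- alpha_sweep(alphas = c(0.1, 0.3), l = 12, n = 150, runs = 2,
                      seed = 6)
  expect_identical(res1, res2)
  expect_equal(res1$alpha, c(0.1, 0.3))
  expect_true(all(res1$min_p_wtb <= res1$median_p_wtb))
})

test_that("set comparison is symmetric-fair and directionally sound", {
  set.seed(12)
  random_set <- generate_random_set(12, 400)
  self <- compare_sets(random_set, random_set, pair_sample = 5000, seed = 1)
  expect_equal(as.data.frame(self)$count[as.data.frame(self)$set == "set_a"],
               as.data.frame(self)$count[as.data.frame(self)$set == "set_b"])
  expect_error(compare_sets(random_set, generate_random_set(10, 50)),
               "same barcode length")

  fit <- optimize_barcode_set(optimizer_config(l = 12, n = 400, seed = 33))
  cmp <- compare_sets(fit$best$barcodes, random_set, pair_sample = 5000,
                      seed = 2, set_names = c("optimized", "random"))
  hist_of <- function(set, fac) {
    h <- cmp$summaries[[set]][[fac]]$histogram
    setNames(h$count, h$value)
  }
  count_ge <- function(h, x) sum(h[as.numeric(names(h)) >= x])
  count_le <- function(h, x) sum(h[as.numeric(names(h)) <= x])
  # optimization suppresses long homopolymers and near-identical pairs
  # (hd <= 1, the pairs the mismatch penalty is built to eliminate)
  expect_lt(count_ge(hist_of("optimized", "hp"), 4),
            count_ge(hist_of("random", "hp"), 4))
  expect_lte(count_le(hist_of("optimized", "hd"), 1),
             count_le(hist_of("random", "hd"), 1))
  # and pushes GC content into the preferred band
  gcc_pen <- function(set) {
    h <- cmp$summaries[[set]]$gcc$histogram
    stats::median(rep(p_gcc(h$value), times = h$count))
  }
  expect_lte(gcc_pen("optimized"), gcc_pen("random"))
})
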