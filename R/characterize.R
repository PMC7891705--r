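#' @title Distribution summaries of barcode factors
#' @description Internal constructor for a factor distribution: histogram,
#'   mode (ties broken toward the smaller value), median and mean.
#' @noRd
distribution_summary <- function(factor, hist, n_items, n_sets, l, stat) {
  hist <- hist[order(hist$value), , drop = FALSE]
  pos <- hist$count > 0
  mode <- if (any(pos)) hist$value[pos][which.max(hist$count[pos])] else NA_real_
  expand <- rep(hist$value, times = pmax(0L, round(hist$count)))
  structure(list(factor = factor, histogram = hist, mode = mode,
                 median = if (length(expand)) stats::median(expand) else NA,
                 mean = sum(hist$value * hist$count) / sum(hist$count),
                 n_items = n_items, n_sets = n_sets, l = l, stat = stat),
            class = "factor_distribution")
}

#' @export
print.factor_distribution <- function(x, ...) {
  cat("Distribution of ", x$factor, " (l = ", x$l, ", ", x$n_items,
      " items, ", x$n_sets, " set(s), ", x$stat, " counts)\n", sep = "")
  cat("mode = ", x$mode, ", median = ", x$median, ", mean = ",
      signif(x$mean, 5), "\n", sep = "")
  invisible(x)
}

# counts of `values` aligned on a common support
count_on <- function(values, support) {
  as.numeric(table(factor(values, levels = support)))
}

# sample `k` unordered pairs of 1..n uniformly; enumerates all pairs when
# the space is no larger than the request
sample_pairs <- function(n, k) {
  total <- n * (n - 1) / 2
  if (k > total)
    stop("pair_sample exceeds the number of unordered pairs", call. = FALSE)
  if (k == total && total <= 5e6) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    return(list(i = idx[, 1], j = idx[, 2]))
  }
  i <- sample.int(n, k, replace = TRUE)
  j <- sample.int(n, k, replace = TRUE)
  while (any(eq <- i == j)) j[eq] <- sample.int(n, sum(eq), replace = TRUE)
  list(i = i, j = j)
}

# per-set raw factor values; pairwise factors on sampled pairs
factor_values <- function(barcodes, pair_sample, min_overlap) {
  enc <- encode_barcodes(barcodes)
  l <- ncol(enc)
  pr <- sample_pairs(nrow(enc), pair_sample)
  list(gcc = 100 * rowSums(enc == 1L | enc == 2L) / l,
       hp = hp_lengths_c(enc),
       sr = sr_repeats_c(enc),
       hd = hd_index_pairs_c(enc, pr$i, pr$j),
       cp = cp_index_pairs_c(enc, pr$i, pr$j, as.integer(min_overlap)),
       ld = ld_index_pairs_c(enc, pr$i, pr$j))
}

#' Characterize uniform random barcodes
#'
#' Generates `n_sets` independent sets of `n_barcodes` uniform random
#' barcodes of length `l` and summarizes the distributions of the six
#' factors. The per-barcode factors (gcc, hp, sr) are evaluated on every
#' barcode; the pairwise factors (hd, cp, ld) on a uniform random sample of
#' `pair_sample` unordered pairs per set. Histogram counts are aggregated
#' across sets as the mean count per value for gcc, the median count for hp
#' and sr (the statistics used to calibrate the penalty curves) and the
#' pooled sum for the pairwise factors.
#'
#' @param l barcode length.
#' @param n_barcodes barcodes per set.
#' @param n_sets number of independent random sets.
#' @param pair_sample unordered pairs sampled per set for hd/cp/ld.
#' @param seed optional integer seed; results are reproducible given a seed.
#' @param min_overlap minimum sliding overlap for complementarity.
#' @return an object of class `barcode_characterization`: a list of
#'   `factor_distribution` objects keyed `gcc`, `hp`, `sr`, `hd`, `cp`,
#'   `ld`.
#' @examples
#' ch <- characterize_random(12, n_barcodes = 500, pair_sample = 2000,
#'                           seed = 1)
#' ch$hd$mode  # random 12-mers differ at about 3/4 of positions
#' @export
characterize_random <- function(l = 12, n_barcodes = 1e4, n_sets = 1,
                                pair_sample = 1e6, seed = NULL,
                                min_overlap = 3) {
  stopifnot(n_barcodes >= 2, n_sets >= 1, pair_sample >= 1)
  if (!is.null(seed)) set.seed(seed)
  per_set <- lapply(seq_len(n_sets), function(s) {
    factor_values(random_distinct_barcodes(l, n_barcodes), pair_sample,
                  min_overlap)
  })
  aggregate_one <- function(fac, stat) {
    vals <- lapply(per_set, `[[`, fac)
    support <- sort(unique(unlist(vals)))
    counts <- vapply(vals, count_on, numeric(length(support)),
                     support = support)
    counts <- matrix(counts, nrow = length(support))
    agg <- switch(stat,
                  mean = rowMeans(counts),
                  median = apply(counts, 1L, stats::median),
                  sum = rowSums(counts))
    distribution_summary(fac, data.frame(value = support, count = agg),
                         n_items = length(vals[[1L]]), n_sets = n_sets,
                         l = l, stat = stat)
  }
  stats <- c(gcc = "mean", hp = "median", sr = "median",
             hd = "sum", cp = "sum", ld = "sum")
  out <- lapply(names(stats), function(f) aggregate_one(f, stats[[f]]))
  names(out) <- names(stats)
  structure(out, class = "barcode_characterization",
            l = l, n_barcodes = n_barcodes, n_sets = n_sets,
            pair_sample = pair_sample, seed = seed)
}

#' @export
as.data.frame.barcode_characterization <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(s)
    data.frame(factor = s$factor, s$histogram, row.names = NULL)))
}

#' Refit the penalty curves from random-barcode distributions
#'
#' Re-derives the curve constants used by [penalty_params()] from a
#' [characterize_random()] result: a Gaussian `a * exp(-(x - mu)^2 /
#' (2 sigma^2))` for the GC-content histogram (mean counts) and
#' exponentials `b * exp(c * x)` for the homopolymer and dinucleotide
#' repeat histograms (median counts, values >= 2; the additive constant of
#' the exponential model is dropped so the fitted curve stays
#' non-negative). Intended for re-derivation studies; default scoring uses
#' the shipped constants.
#'
#' @param char a `barcode_characterization` (or any list with `gcc`, `hp`,
#'   `sr` elements of class `factor_distribution`).
#' @return list with elements `gcc` (`a`, `mu`, `sigma`), `hp` (`b`, `c`)
#'   and `sr` (`b`, `c`).
#' @export
fit_penalty_curves <- function(char) {
  fit_gauss <- function(h) {
    if (nrow(h) < 4)
      stop("degenerate gcc histogram: too few points to fit", call. = FALSE)
    fit <- minpack.lm::nlsLM(
      count ~ a * exp(-(value - mu)^2 / (2 * sigma^2)), data = h,
      start = list(a = max(h$count), mu = 50, sigma = 15))
    setNames(coef(fit), c("a", "mu", "sigma"))
  }
  fit_exp <- function(h, fac) {
    h <- h[h$value >= 2 & h$count > 0, , drop = FALSE]
    if (nrow(h) < 3)
      stop("degenerate ", fac, " histogram: too few points to fit",
           call. = FALSE)
    lm0 <- stats::lm(log(count) ~ value, data = h)
    fit <- minpack.lm::nlsLM(count ~ b * exp(c * value), data = h,
                             start = list(b = exp(coef(lm0)[1]),
                                          c = coef(lm0)[2]))
    setNames(coef(fit), c("b", "c"))
  }
  list(gcc = fit_gauss(char$gcc$histogram),
       hp = fit_exp(char$hp$histogram, "hp"),
       sr = fit_exp(char$sr$histogram, "sr"))
}

# deterministic sub-seeds for repeated optimizer runs
derive_seeds <- function(seed, k) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Full-factorial weight grid
#'
#' @param values weight values per axis (applied to all five axes).
#' @return data frame of all weight combinations, columns `w1` ... `w5`.
#' @export
weight_grid <- function(values = c(1, 5, 10, 20)) {
  g <- expand.grid(w1 = values, w2 = values, w3 = values, w4 = values,
                   w5 = values)
  g[, c("w1", "w2", "w3", "w4", "w5")]
}

#' Grid search over factor weights
#'
#' Runs the optimizer repeatedly at each weight vector and records the
#' median percent decrease of the objective (`P_DEC` of `P_WT`). Intended
#' for calibration studies at reduced scale; the attribute `"best"` holds
#' the row index of the arg-max vector.
#'
#' @param grid data frame with columns `w1` ... `w5` (see [weight_grid()]),
#'   or a list coercible to one.
#' @param l,n,alpha,params,patience,max_cycles,min_overlap optimizer
#'   settings shared across grid points.
#' @param runs optimizer repetitions per grid point.
#' @param seed integer seed from which per-run sub-seeds are derived.
#' @return data frame with the weight columns and `median_p_dec`; attribute
#'   `"best"` is the index of the best row.
#' @export
grid_search_weights <- function(grid = weight_grid(), l = 12, n = 500,
                                alpha = 0.2, runs = 10, seed = 1,
                                params = penalty_params(), patience = 5,
                                max_cycles = 200, min_overlap = 3) {
  grid <- as.data.frame(grid)
  stopifnot(all(c("w1", "w2", "w3", "w4", "w5") %in% names(grid)), runs >= 1)
  seeds <- matrix(derive_seeds(seed, nrow(grid) * runs), nrow = nrow(grid))
  med <- vapply(seq_len(nrow(grid)), function(g) {
    w <- barcode_weights(grid$w1[g], grid$w2[g], grid$w3[g], grid$w4[g],
                         grid$w5[g])
    dec <- vapply(seq_len(runs), function(r) {
      fit <- optimize_barcode_set(optimizer_config(
        l = l, n = n, alpha = alpha, weights = w, params = params,
        seed = seeds[g, r], patience = patience, max_cycles = max_cycles,
        min_overlap = min_overlap))
      percent_decrease(fit$p_wta, fit$p_wtb)
    }, numeric(1))
    stats::median(dec)
  }, numeric(1))
  out <- cbind(grid, median_p_dec = med)
  attr(out, "best") <- which.max(med)
  out
}

#' Sweep the per-cycle replacement fraction
#'
#' Runs the optimizer repeatedly at each `alpha` and reports the minimum
#' and median best objective (`P_WTb`) and the median percent decrease.
#'
#' @param alphas replacement fractions to test.
#' @param l,n,weights,params,patience,max_cycles,min_overlap optimizer
#'   settings shared across conditions.
#' @param runs optimizer repetitions per alpha.
#' @param seed integer seed from which per-run sub-seeds are derived.
#' @return data frame with columns `alpha`, `min_p_wtb`, `median_p_wtb`,
#'   `median_p_dec`.
#' @export
alpha_sweep <- function(alphas = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5), l = 12,
                        n = 500, runs = 10, seed = 1,
                        weights = barcode_weights(),
                        params = penalty_params(), patience = 5,
                        max_cycles = 200, min_overlap = 3) {
  stopifnot(all(alphas > 0 & alphas <= 1), runs >= 1)
  seeds <- matrix(derive_seeds(seed, length(alphas) * runs),
                  nrow = length(alphas))
  rows <- lapply(seq_along(alphas), function(a) {
    fits <- lapply(seq_len(runs), function(r)
      optimize_barcode_set(optimizer_config(
        l = l, n = n, alpha = alphas[a], weights = weights, params = params,
        seed = seeds[a, r], patience = patience, max_cycles = max_cycles,
        min_overlap = min_overlap)))
    p_wtb <- vapply(fits, `[[`, numeric(1), "p_wtb")
    dec <- vapply(fits, function(f) percent_decrease(f$p_wta, f$p_wtb),
                  numeric(1))
    data.frame(alpha = alphas[a], min_p_wtb = min(p_wtb),
               median_p_wtb = stats::median(p_wtb),
               median_p_dec = stats::median(dec))
  })
  do.call(rbind, rows)
}

#' Compare two barcode sets on six criteria
#'
#' Summarizes both sets on GCC, HP, SR, HD, LD and CP under identical
#' sampling parameters and seed (the pairwise factors are evaluated on the
#' same number of uniformly sampled pairs in each set).
#'
#' @param set_a,set_b character vectors of barcodes; all barcodes must
#'   share one length.
#' @param pair_sample unordered pairs sampled per set (capped at the number
#'   of pairs available in the smaller set).
#' @param seed optional integer seed.
#' @param min_overlap minimum sliding overlap for complementarity.
#' @param set_names labels for the two sets.
#' @return an object of class `barcode_comparison`: list with `sets` (the
#'   labels) and `summaries` (per set, a list of `factor_distribution`
#'   objects). `as.data.frame()` yields a long table (set, factor, value,
#'   count) suitable for TSV export.
#' @export
compare_sets <- function(set_a, set_b, pair_sample = 1e5, seed = NULL,
                         min_overlap = 3,
                         set_names = c("set_a", "set_b")) {
  set_a <- validate_barcodes(set_a, same_length = TRUE)
  set_b <- validate_barcodes(set_b, same_length = TRUE)
  if (nchar(set_a[1L]) != nchar(set_b[1L]))
    stop("sets must have the same barcode length", call. = FALSE)
  l <- nchar(set_a[1L])
  k <- min(pair_sample,
           length(set_a) * (length(set_a) - 1) / 2,
           length(set_b) * (length(set_b) - 1) / 2)
  summarize <- function(bc) {
    if (!is.null(seed)) set.seed(seed)
    fv <- factor_values(bc, k, min_overlap)
    out <- lapply(names(fv), function(f) {
      support <- sort(unique(fv[[f]]))
      distribution_summary(f, data.frame(value = support,
                                         count = count_on(fv[[f]], support)),
                           n_items = length(fv[[f]]), n_sets = 1L, l = l,
                           stat = "sum")
    })
    names(out) <- names(fv)
    out
  }
  out <- list(sets = set_names,
              summaries = setNames(list(summarize(set_a), summarize(set_b)),
                                   set_names),
              pair_sample = k, l = l, seed = seed)
  structure(out, class = "barcode_comparison")
}

#' @export
as.data.frame.barcode_comparison <- function(x, ...) {
  do.call(rbind, lapply(x$sets, function(s) {
    do.call(rbind, lapply(x$summaries[[s]], function(d)
      data.frame(set = s, factor = d$factor, d$histogram, row.names = NULL)))
  }))
}

#' @export
print.barcode_comparison <- function(x, ...) {
  cat("Comparison of barcode sets (l = ", x$l, ", ", x$pair_sample,
      " sampled pairs per set)\n", sep = "")
  for (s in x$sets) {
    modes <- vapply(x$summaries[[s]], `[[`, numeric(1), "mode")
    cat(" ", s, ": modes ",
        paste(names(modes), modes, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
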