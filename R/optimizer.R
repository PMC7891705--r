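#' Optimizer configuration
#'
#' Bundles all run parameters of the barcode-set optimizer: barcode length,
#' set size, the expected replaced fraction per cycle (`alpha`), factor
#' weights, penalty constants, RNG seed and the stopping rule (`patience`
#' cycles without improving the best objective, bounded by `max_cycles`).
#'
#' @param l barcode length (default 12).
#' @param n set size N (default `10^5`); must not exceed `4^l`.
#' @param alpha expected fraction of the set replaced per cycle, in (0, 1]
#'   (default 0.2).
#' @param weights a [barcode_weights()] vector.
#' @param params a [penalty_params()] object.
#' @param seed optional integer RNG seed; one seeded generator drives the
#'   initial set, the exclusion draws and the replacements, in that order.
#' @param patience consecutive non-improving cycles before stopping
#'   (default 5).
#' @param max_cycles safety cap on the number of cycles (default 200).
#' @param min_overlap minimum sliding overlap for complementarity.
#' @return an object of class `optimizer_config`.
#' @export
optimizer_config <- function(l = 12, n = 1e5, alpha = 0.2,
                             weights = barcode_weights(),
                             params = penalty_params(), seed = NULL,
                             patience = 5, max_cycles = 200,
                             min_overlap = 3) {
  stopifnot(l >= 4, n >= 1, patience >= 1, max_cycles >= 1)
  if (n > 4^l)
    stop("infeasible: n exceeds the barcode space 4^l", call. = FALSE)
  if (alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]", call. = FALSE)
  structure(list(l = as.integer(l), n = as.integer(n), alpha = alpha,
                 weights = weights, params = params, seed = seed,
                 patience = as.integer(patience),
                 max_cycles = as.integer(max_cycles),
                 min_overlap = as.integer(min_overlap)),
            class = "optimizer_config")
}

#' Per-barcode exclusion probabilities
#'
#' Each cycle a barcode is excluded with probability proportional to its
#' share of the set objective: `P_EX = P_T / P_WT * N * alpha`, clipped to
#' at most 1. The pre-clip values sum to `N * alpha` by construction.
#'
#' @param p_t per-barcode weighted penalty totals (numeric vector), or a
#'   [score_barcode_set()] result from which they are taken.
#' @param alpha expected replaced fraction per cycle.
#' @return a list with `raw` (pre-clip values) and `prob` (clipped to
#'   `[0, 1]`).
#' @export
exclusion_probabilities <- function(p_t, alpha) {
  if (inherits(p_t, "barcode_set_score")) p_t <- p_t$table$P_T
  stopifnot(is.numeric(p_t), alpha > 0, alpha <= 1)
  p_wt <- sum(p_t)
  if (p_wt == 0)
    stop("set already optimal (P_WT = 0); no exclusion round", call. = FALSE)
  raw <- p_t / p_wt * length(p_t) * alpha
  list(raw = raw, prob = pmin(raw, 1))
}

# i.i.d. uniform barcodes distinct from `avoid` and from each other
draw_replacements <- function(l, need, avoid) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  while (length(out) < need) {
    k <- need - length(out)
    cand <- apply(matrix(sample(bases, k * l, replace = TRUE), k, l),
                  1L, paste, collapse = "")
    cand <- unique(cand[!(cand %in% avoid) & !(cand %in% out)])
    out <- c(out, cand)
  }
  out
}

#' Run one exclusion/replacement cycle
#'
#' Draws an independent Bernoulli exclusion per barcode from
#' [exclusion_probabilities()], replaces excluded barcodes with fresh
#' uniform random barcodes distinct from all retained ones and from each
#' other, and rescores the set.
#'
#' @param state a [score_barcode_set()] result.
#' @param config an [optimizer_config()]. Uses the current RNG stream; seed
#'   handling is the caller's job.
#' @return the rescored `barcode_set_score` after replacement.
#' @export
run_cycle <- function(state, config) {
  stopifnot(inherits(state, "barcode_set_score"))
  if (state$p_wt == 0) return(state)  # terminal: nothing to exclude
  pex <- exclusion_probabilities(state$table$P_T, config$alpha)
  excl <- runif(state$n) < pex$prob
  if (!any(excl)) return(state)
  retained <- state$barcodes[!excl]
  fresh <- draw_replacements(state$l, sum(excl), retained)
  score_barcode_set(c(retained, fresh), config$params, config$weights,
                    config$min_overlap, skip_zero_weight_pairs = TRUE)
}

#' Optimize a barcode set
#'
#' Two-step stochastic refinement: (i) generate a uniform random initial
#' set of `n` distinct barcodes; (ii) repeat cycles of penalty scoring,
#' probabilistic exclusion and replacement, tracking the minimum weighted
#' objective `P_WT` ever seen. Stops once `patience` consecutive cycles
#' fail to improve that minimum (or at `max_cycles`, or when the objective
#' reaches 0). The best state seen - not the last - is returned, rescored
#' with all five factors regardless of weights.
#'
#' @param config an [optimizer_config()].
#' @param verbose emit per-cycle totals via `message()`?
#' @param per_cycle_file if non-`NULL`, a directory into which each cycle's
#'   set (including the initial state as cycle 0) is written with
#'   [write_barcode_set()], as `cycle_000.txt`, `cycle_001.txt`, ...
#' @return an object of class `barcode_opt`: list with `best` (the best
#'   scored set), `trace` (per-cycle data frame of the six totals),
#'   `best_cycle`, `p_wta` (initial objective), `p_wtb` (best objective),
#'   `cycles` and `config`.
#' @examples
#' fit <- optimize_barcode_set(optimizer_config(l = 12, n = 50, seed = 1))
#' fit$p_wtb < fit$p_wta
#' @export
optimize_barcode_set <- function(config = optimizer_config(),
                                 verbose = FALSE, per_cycle_file = NULL) {
  stopifnot(inherits(config, "optimizer_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  state <- score_barcode_set(random_distinct_barcodes(config$l, config$n),
                             config$params, config$weights,
                             config$min_overlap,
                             skip_zero_weight_pairs = TRUE)
  trace_row <- function(cycle, s)
    data.frame(cycle = cycle, as.list(s$totals), P_WT = s$p_wt)
  emit <- function(cycle, s) {
    if (verbose)
      message(sprintf("cycle %d: P_WT = %.6g", cycle, s$p_wt))
    if (!is.null(per_cycle_file)) {
      dir.create(per_cycle_file, showWarnings = FALSE, recursive = TRUE)
      write_barcode_set(s, file.path(per_cycle_file,
                                     sprintf("cycle_%03d.txt", cycle)))
    }
  }
  trace <- trace_row(0L, state)
  emit(0L, state)
  best <- state
  best_cycle <- 0L
  p_wta <- state$p_wt
  since_improve <- 0L
  cycle <- 0L

  while (cycle < config$max_cycles && best$p_wt > 0 &&
         since_improve < config$patience) {
    cycle <- cycle + 1L
    state <- run_cycle(state, config)
    trace <- rbind(trace, trace_row(cycle, state))
    emit(cycle, state)
    if (state$p_wt < best$p_wt) {
      best <- state
      best_cycle <- cycle
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
    }
  }

  # rescore the winner with every factor so reported components are complete
  best_full <- score_barcode_set(best$barcodes, config$params, config$weights,
                                 config$min_overlap,
                                 skip_zero_weight_pairs = FALSE)
  structure(list(best = best_full, trace = trace, best_cycle = best_cycle,
                 p_wta = p_wta, p_wtb = best$p_wt, cycles = cycle,
                 config = config),
            class = "barcode_opt")
}

#' @export
print.barcode_opt <- function(x, ...) {
  cat("Barcode set optimization (l = ", x$config$l, ", N = ", x$config$n,
      ", alpha = ", x$config$alpha, ")\n", sep = "")
  cat("cycles run: ", x$cycles, "; best cycle: ", x$best_cycle, "\n", sep = "")
  cat("P_WT initial ", format(x$p_wta, digits = 7), " -> best ",
      format(x$p_wtb, digits = 7), " (decrease ",
      format(percent_decrease(x$p_wta, x$p_wtb), digits = 4), "%)\n",
      sep = "")
  invisible(x)
}

#' Percent decrease of a penalty score
#'
#' `(p_a - p_b) / p_a * 100`, the performance measure comparing an initial
#' penalty `p_a` with the best (lowest) penalty `p_b`.
#'
#' @param p_a initial value (> 0).
#' @param p_b best value.
#' @return percent decrease.
#' @export
percent_decrease <- function(p_a, p_b) {
  if (any(p_a <= 0))
    stop("percent decrease undefined for p_a <= 0", call. = FALSE)
  (p_a - p_b) / p_a * 100
}
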