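#' Penalty-curve parameters
#'
#' Constants of the per-factor penalty curves. Defaults are the values
#' calibrated on uniform random 12-mer barcodes:
#'
#' * GCC: a Gaussian `f(gcc) = a * exp(-(gcc - mu)^2 / (2 sigma^2))` fitted
#'   to the random GC-content distribution; the normalized score is flat at
#'   its maximum (`10^6`) on the preferred range `[best_lo, best_hi]` and
#'   the penalty is the inverted, rescaled score.
#' * HP / SR: exponentials `b * exp(c * x)` fitted to random homopolymer /
#'   dinucleotide-repeat count distributions; values below 2 share the
#'   minimum penalty (`offset`).
#' * HD: `amp * exp(rate * hd) - shift` for `hd < zero_from`, else 0. The
#'   rate is `-log(10^3)`: each additional mismatch divides the penalty by
#'   the per-base sequencing error odds (error rate 1/10^3), giving the
#'   ladder `10^6, 10^3, 1` at `hd = 1, 2, 3`.
#' * CP: `amp * exp(rate * cp~) - shift` for `cp~ >= threshold`, else 0,
#'   where `cp~ = cp * ref_len / l` rescales complementarity to the
#'   reference length 12. The rate is `log(10^2)`: one extra base pair
#'   multiplies the penalty by 100.
#'
#' @param gcc_amp,gcc_mu,gcc_sigma Gaussian amplitude, center and width of
#'   the GC-content curve.
#' @param gcc_best_lo,gcc_best_hi preferred GC-content range (percent) on
#'   which the penalty is 0.
#' @param gcc_scale maximum GC-content penalty.
#' @param hp_b,hp_c,hp_offset exponential constants and minimum penalty for
#'   homopolymers.
#' @param sr_b,sr_c,sr_offset exponential constants and minimum penalty for
#'   dinucleotide repeats.
#' @param hd_amp,hd_rate,hd_shift,hd_zero_from Hamming-distance curve;
#'   penalties are 0 from `hd_zero_from` mismatches on.
#' @param cp_amp,cp_rate,cp_shift,cp_ref_len,cp_threshold complementarity
#'   curve; `cp_threshold` applies on the rescaled (`cp~`) scale.
#' @return an object of class `penalty_params` (a validated named list).
#' @export
penalty_params <- function(gcc_amp = 22662.54, gcc_mu = 50,
                           gcc_sigma = 14.74996, gcc_best_lo = 40,
                           gcc_best_hi = 60, gcc_scale = 1e6,
                           hp_b = 461428, hp_c = -1.31322, hp_offset = 2,
                           sr_b = 15642980, sr_c = -3.010114, sr_offset = 6,
                           hd_amp = 1e9, hd_rate = -log(1e3),
                           hd_shift = 7.524427e-16, hd_zero_from = 4,
                           cp_amp = 9.999999e-17, cp_rate = log(1e2),
                           cp_shift = 0.0009216598, cp_ref_len = 12,
                           cp_threshold = 8) {
  p <- list(gcc_amp = gcc_amp, gcc_mu = gcc_mu, gcc_sigma = gcc_sigma,
            gcc_best_lo = gcc_best_lo, gcc_best_hi = gcc_best_hi,
            gcc_scale = gcc_scale,
            hp_b = hp_b, hp_c = hp_c, hp_offset = hp_offset,
            sr_b = sr_b, sr_c = sr_c, sr_offset = sr_offset,
            hd_amp = hd_amp, hd_rate = hd_rate, hd_shift = hd_shift,
            hd_zero_from = hd_zero_from,
            cp_amp = cp_amp, cp_rate = cp_rate, cp_shift = cp_shift,
            cp_ref_len = cp_ref_len, cp_threshold = cp_threshold)
  stopifnot(all(vapply(p, is.numeric, logical(1))),
            all(lengths(p) == 1L))
  if (gcc_amp <= 0 || gcc_sigma <= 0 || gcc_scale <= 0 || hp_b <= 0 ||
      sr_b <= 0 || hd_amp <= 0 || cp_amp <= 0)
    stop("penalty amplitudes must be positive", call. = FALSE)
  if (!(gcc_best_lo < gcc_mu && gcc_mu < gcc_best_hi))
    stop("need gcc_best_lo < gcc_mu < gcc_best_hi", call. = FALSE)
  if (hp_c >= 0 || sr_c >= 0)
    stop("hp_c and sr_c must be negative (decaying counts)", call. = FALSE)
  if (cp_ref_len <= 0 || hd_zero_from < 1)
    stop("invalid cp_ref_len or hd_zero_from", call. = FALSE)
  structure(p, class = "penalty_params")
}

#' Barcode factor weights
#'
#' Multipliers applied to the five factor penalties (GCC, HP, SR, HD, CP)
#' in per-barcode totals and the set objective. The defaults
#' (20, 20, 20, 1, 1) favor the intrinsic factors over the pairwise ones.
#'
#' @param w1,w2,w3,w4,w5 non-negative weights for GCC, HP, SR, HD and CP.
#' @return named numeric vector of length 5.
#' @export
barcode_weights <- function(w1 = 20, w2 = 20, w3 = 20, w4 = 1, w5 = 1) {
  w <- c(w1 = w1, w2 = w2, w3 = w3, w4 = w4, w5 = w5)
  if (any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite and non-negative", call. = FALSE)
  if (all(w == 0))
    stop("at least one weight must be positive", call. = FALSE)
  w
}

#' Normalized GC-content score
#'
#' The Gaussian curve fitted to random GC-content counts, normalized to
#' `10^6` at the edge of the preferred range and held flat at `10^6` inside
#' it. Its minimum (attained at `gcc` 0 or 100) rounds to 4023 with the
#' default constants.
#'
#' @param gcc GC content in percent, in `[0, 100]`.
#' @param params a [penalty_params()] object.
#' @return numeric vector of normalized scores.
#' @export
gcc_norm_score <- function(gcc, params = penalty_params()) {
  if (any(gcc < 0 | gcc > 100)) stop("gcc must be in [0, 100]", call. = FALSE)
  f <- function(g) params$gcc_amp *
    exp(-(g - params$gcc_mu)^2 / (2 * params$gcc_sigma^2))
  ref <- f(params$gcc_best_lo)
  ifelse(gcc >= params$gcc_best_lo & gcc <= params$gcc_best_hi,
         1e6, f(gcc) / ref * 1e6)
}

#' Per-factor penalty scores
#'
#' Map factor values to penalty scores with the curves described in
#' [penalty_params()]. All functions are vectorized and monotone in the
#' direction that penalizes undesirable barcodes: `p_gcc` is 0 on the
#' preferred GC range and maximal at 0/100% GC; `p_hp` and `p_sr` grow with
#' run length; `p_hd` shrinks (to exactly 0 from `hd_zero_from` on) as
#' barcodes grow apart; `p_cp` grows with complementarity and is 0 below
#' the threshold.
#'
#' @param gcc,hp,sr,hd,cp factor values (see [barcode_factors]).
#' @param l barcode length, used to rescale `cp` to the reference length.
#' @param params a [penalty_params()] object.
#' @return numeric vector of non-negative penalty scores.
#' @examples
#' p_gcc(c(0, 50, 100))  # 1e6, 0, 1e6
#' p_hd(1:4)             # 1e6, 1e3, 1, 0
#' p_cp(8:12, l = 12)    # approx 1, 1e2, 1e4, 1e6, 1e8
#' @name penalty_scores
NULL

#' @rdname penalty_scores
#' @export
p_gcc <- function(gcc, params = penalty_params()) {
  bar <- gcc_norm_score(gcc, params)
  min_bar <- gcc_norm_score(0, params)
  (1e6 - bar) / (1e6 - min_bar) * params$gcc_scale
}

#' @rdname penalty_scores
#' @export
p_hp <- function(hp, params = penalty_params()) {
  if (any(hp < 1)) stop("hp must be >= 1", call. = FALSE)
  bar <- ifelse(hp <= 2, 1e6, exp(params$hp_c * hp) / exp(params$hp_c * 2) * 1e6)
  1e6 - bar + params$hp_offset
}

#' @rdname penalty_scores
#' @export
p_sr <- function(sr, params = penalty_params()) {
  if (any(sr < 1)) stop("sr must be >= 1", call. = FALSE)
  bar <- ifelse(sr <= 2, 1e6, exp(params$sr_c * sr) / exp(params$sr_c * 2) * 1e6)
  1e6 - bar + params$sr_offset
}

#' @rdname penalty_scores
#' @export
p_hd <- function(hd, params = penalty_params()) {
  if (any(hd < 0)) stop("hd must be >= 0", call. = FALSE)
  # hd = 0 only arises from duplicated user-supplied barcodes; penalized at
  # the curve amplitude so duplicates dominate any mismatch penalty.
  ifelse(hd == 0, params$hd_amp,
         ifelse(hd >= params$hd_zero_from, 0,
                params$hd_amp * exp(params$hd_rate * hd) - params$hd_shift))
}

#' @rdname penalty_scores
#' @export
p_cp <- function(cp, l, params = penalty_params()) {
  if (any(l <= 0)) stop("l must be positive", call. = FALSE)
  if (any(cp < 0 | cp > l)) stop("cp must be in [0, l]", call. = FALSE)
  cpt <- cp * params$cp_ref_len / l
  ifelse(cpt < params$cp_threshold, 0,
         pmax(0, params$cp_amp * exp(params$cp_rate * cpt) - params$cp_shift))
}

#' Weighted per-barcode penalty total
#'
#' `P_T = w1 P_GCC + w2 P_HP + w3 P_SR + w4 P_HD + w5 P_CP`.
#'
#' @param components numeric vector of the five factor penalties (in GCC,
#'   HP, SR, HD, CP order) or a matrix / data frame with those five columns,
#'   one row per barcode.
#' @param weights a [barcode_weights()] vector.
#' @return numeric vector of weighted totals.
#' @export
barcode_total_penalty <- function(components, weights = barcode_weights()) {
  if (is.data.frame(components)) components <- as.matrix(components)
  if (is.null(dim(components))) components <- matrix(components, nrow = 1L)
  if (ncol(components) != 5L)
    stop("expected five penalty components per barcode", call. = FALSE)
  if (any(components < 0)) stop("components must be non-negative", call. = FALSE)
  drop(components %*% unname(weights))
}

# value-indexed penalty lookup vectors for hd, cp in 0..l
hd_penalty_lookup <- function(l, params) p_hd(0:l, params)
cp_penalty_lookup <- function(l, params) p_cp(0:l, l, params)

#' Score a barcode set
#'
#' Computes all factor values and penalty components for a set of
#' equal-length barcodes, the per-barcode weighted totals `P_T`, the
#' per-factor set totals and the weighted set objective `P_WT`. For the
#' pairwise factors (HD, CP) the component of barcode i is the sum of pair
#' penalties over its N-1 partners, so every unordered pair contributes to
#' both members; self-pairing (self-dimers) is excluded.
#'
#' @param barcodes character vector of equal-length barcodes.
#' @param params a [penalty_params()] object.
#' @param weights a [barcode_weights()] vector.
#' @param min_overlap minimum sliding overlap for complementarity.
#' @param skip_zero_weight_pairs if `TRUE`, pairwise factors whose weight is
#'   0 are not computed (their components are reported as 0); used by the
#'   optimizer to avoid O(N^2) work that cannot affect the objective.
#' @return an object of class `barcode_set_score`: a list with elements
#'   `barcodes`, `l`, `n`, `table` (per-barcode factors, components and
#'   `P_T`), `totals` (named vector `P_GCCt` ... `P_CPt`), and `p_wt`.
#' @export
score_barcode_set <- function(barcodes, params = penalty_params(),
                              weights = barcode_weights(), min_overlap = 3,
                              skip_zero_weight_pairs = FALSE) {
  barcodes <- validate_barcodes(barcodes, same_length = TRUE)
  n <- length(barcodes)
  l <- nchar(barcodes[1L])
  enc <- encode_barcodes(barcodes)

  gcc <- 100 * rowSums(enc == 1L | enc == 2L) / l
  hp <- if (l == 1L) rep(1L, n) else hp_lengths_c(enc)
  sr <- if (l < 2L) rep(1L, n) else sr_repeats_c(enc)

  comp <- cbind(P_GCC = p_gcc(gcc, params),
                P_HP = p_hp(hp, params),
                P_SR = p_sr(sr, params),
                P_HD = 0, P_CP = 0)
  do_hd <- !(skip_zero_weight_pairs && weights[["w4"]] == 0)
  do_cp <- !(skip_zero_weight_pairs && weights[["w5"]] == 0)
  if (n > 1L && (do_hd || do_cp)) {
    pc <- pair_components_c(enc, hd_penalty_lookup(l, params),
                            cp_penalty_lookup(l, params),
                            as.integer(min_overlap), do_hd, do_cp)
    comp[, "P_HD"] <- pc$p_hd
    comp[, "P_CP"] <- pc$p_cp
  }
  p_t <- barcode_total_penalty(comp, weights)
  totals <- setNames(colSums(comp),
                     c("P_GCCt", "P_HPt", "P_SRt", "P_HDt", "P_CPt"))
  p_wt <- sum(unname(weights) * totals)

  structure(list(barcodes = barcodes, l = l, n = n,
                 table = data.frame(barcode = barcodes, gcc = gcc, hp = hp,
                                    sr = sr, comp, P_T = p_t),
                 totals = totals, p_wt = p_wt, weights = weights,
                 params = params, min_overlap = min_overlap,
                 pair_factors = c(hd = do_hd, cp = do_cp)),
            class = "barcode_set_score")
}

#' @export
print.barcode_set_score <- function(x, ...) {
  cat("Scored barcode set: ", x$n, " barcodes of length ", x$l, "\n", sep = "")
  cat("Per-factor totals:\n")
  print(signif(x$totals, 6))
  cat("Weighted set penalty P_WT =", format(x$p_wt, digits = 7), "\n")
  invisible(x)
}
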