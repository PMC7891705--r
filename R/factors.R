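#' Barcode sequence factors
#'
#' Five sequence factors drive barcode-set selection: GC content (`gcc`),
#' homopolymer length (`hp`), dinucleotide simple-sequence-repeat count
#' (`sr`), pairwise Hamming distance (`hd`) and pairwise complementarity
#' (`cp`). The Levenshtein distance (`ld`) is computed for set-comparison
#' reports only. `gcc`, `hp` and `sr` are per-barcode; `hd`, `cp` and `ld`
#' are per-pair and symmetric.
#'
#' @param x,y character vectors of barcode sequences. Pairwise functions
#'   recycle the shorter of `x`/`y` and operate elementwise.
#' @return numeric or integer vector of factor values.
#' @name barcode_factors
NULL

#' @describeIn barcode_factors percentage of G and C bases,
#'   `100 * (n_G + n_C) / l`, in `[0, 100]`.
#' @examples
#' gc_content("AGCTAAGCTACC")        # 50
#' homopolymer_length("GTAAACGGGGGC") # 5
#' ssr_repeats("TATCTCTCTCGA")        # 4 copies of "TC"
#' hamming("AAAAC", "AGAAG")          # 2
#' complementarity("AGACAT", "GTGTCC") # 4
#' @export
gc_content <- function(x) {
  x <- validate_barcodes(x)
  gc <- nchar(gsub("[AT]", "", x))
  100 * gc / nchar(x)
}

#' @describeIn barcode_factors length of the longest single-base run
#'   (always at least 1).
#' @export
homopolymer_length <- function(x) {
  x <- validate_barcodes(x)
  out <- integer(length(x))
  for (l in unique(nchar(x))) {
    idx <- nchar(x) == l
    out[idx] <- if (l == 1L) 1L else hp_lengths_c(encode_barcodes(x[idx]))
  }
  out
}

#' @describeIn barcode_factors maximum number of consecutive tandem copies
#'   of any dinucleotide unit, scanning every start position; single-base
#'   runs count as copies of the XX unit (a run of length r contributes
#'   `floor(r / 2)` copies). Minimum reported value is 1.
#' @export
ssr_repeats <- function(x) {
  x <- validate_barcodes(x)
  out <- integer(length(x))
  for (l in unique(nchar(x))) {
    idx <- nchar(x) == l
    out[idx] <- if (l < 2L) 1L else sr_repeats_c(encode_barcodes(x[idx]))
  }
  out
}

recycle_pair <- function(x, y) {
  n <- max(length(x), length(y))
  list(x = rep_len(x, n), y = rep_len(y, n))
}

#' @describeIn barcode_factors Hamming distance: number of mismatching
#'   positions in the ungapped alignment of two equal-length barcodes.
#' @export
hamming <- function(x, y) {
  p <- recycle_pair(validate_barcodes(x), validate_barcodes(y))
  if (any(nchar(p$x) != nchar(p$y)))
    stop("hamming distance requires equal-length sequences", call. = FALSE)
  out <- integer(length(p$x))
  for (l in unique(nchar(p$x))) {
    idx <- nchar(p$x) == l
    out[idx] <- hd_rows_c(encode_barcodes(p$x[idx]), encode_barcodes(p$y[idx]))
  }
  out
}

#' @describeIn barcode_factors maximum count of Watson-Crick (A-T / G-C)
#'   base pairs over all ungapped antiparallel offsets of the two sequences
#'   with overlap at least `min_overlap`; pairs need not be contiguous.
#'   Symmetric in its arguments; `complementarity(b, reverse_complement(b))`
#'   equals the barcode length.
#' @param min_overlap minimum number of overlapping positions considered
#'   when sliding one sequence along the other (default 3).
#' @export
complementarity <- function(x, y, min_overlap = 3) {
  stopifnot(min_overlap >= 1)
  x <- validate_barcodes(x); y <- validate_barcodes(y)
  if (any(nchar(x) < min_overlap) || any(nchar(y) < min_overlap))
    stop("sequences shorter than min_overlap have no valid offset",
         call. = FALSE)
  p <- recycle_pair(x, y)
  out <- integer(length(p$x))
  key <- paste(nchar(p$x), nchar(p$y))
  for (k in unique(key)) {
    idx <- key == k
    out[idx] <- cp_rows_c(encode_barcodes(p$x[idx]), encode_barcodes(p$y[idx]),
                          as.integer(min_overlap))
  }
  out
}

#' @describeIn barcode_factors unit-cost edit distance (substitutions,
#'   insertions, deletions); never exceeds the Hamming distance on
#'   equal-length pairs.
#' @export
levenshtein <- function(x, y) {
  p <- recycle_pair(validate_barcodes(x), validate_barcodes(y))
  out <- integer(length(p$x))
  key <- paste(nchar(p$x), nchar(p$y))
  for (k in unique(key)) {
    idx <- key == k
    out[idx] <- ld_rows_c(encode_barcodes(p$x[idx]), encode_barcodes(p$y[idx]))
  }
  out
}

#' Precomputed Hamming-distance look-up tables
#'
#' Dense tables of Hamming distances between all ordered pairs of k-mers for
#' k = 2, 3 and 4, used to evaluate the distance of longer barcodes by block
#' decomposition (see [hamming_lut()]). Each table is a vector of length
#' `4^(2k)` indexed by `code1 * 4^k + code2 + 1` with the 2-bit base
#' encoding A=0, C=1, G=2, T=3.
#'
#' @return an object of class `hd_luts`: a list with elements `k2`, `k3`,
#'   `k4`.
#' @export
build_hd_luts <- function() {
  if (!is.null(.obc_cache$luts)) return(.obc_cache$luts)
  one <- function(k) {
    codes <- 0:(4^k - 1)
    digits <- sapply(seq_len(k), function(p) codes %/% 4^(k - p) %% 4)
    if (k == 1L) digits <- matrix(digits, ncol = 1L)
    mism <- Reduce(`+`, lapply(seq_len(k), function(p)
      outer(digits[, p], digits[, p], `!=`)))
    # row index = code1, column = code2; flatten with code1 major
    as.integer(t(mism))
  }
  luts <- structure(list(k2 = one(2L), k3 = one(3L), k4 = one(4L)),
                    class = "hd_luts")
  .obc_cache$luts <- luts
  luts
}

# Greedy largest-first tiling of l into blocks of size 4, 3, 2:
# as many 4s as possible, the remainder covered by one 3 and/or one 2
# (l = 9 -> 4+3+2, l = 10 -> 4+4+2).  l = 1 cannot be tiled.
block_tiling <- function(l) {
  if (l < 2) stop("block decomposition requires length >= 2", call. = FALSE)
  r <- l %% 4
  n4 <- l %/% 4
  blocks <- switch(as.character(r),
    "0" = rep(4L, n4),
    "1" = c(rep(4L, n4 - 1L), 3L, 2L),
    "2" = c(rep(4L, n4), 2L),
    "3" = c(rep(4L, n4), 3L))
  blocks
}

#' Hamming distance via k-mer look-up tables
#'
#' Computes the same value as [hamming()] by splitting each barcode into
#' blocks of length 4, 3 and 2 (longer blocks preferred) and summing
#' precomputed sub-distances from [build_hd_luts()].
#'
#' @inheritParams barcode_factors
#' @param luts tables from [build_hd_luts()] (built and cached on demand).
#' @return integer vector of Hamming distances.
#' @export
hamming_lut <- function(x, y, luts = build_hd_luts()) {
  p <- recycle_pair(validate_barcodes(x), validate_barcodes(y))
  if (any(nchar(p$x) != nchar(p$y)))
    stop("hamming distance requires equal-length sequences", call. = FALSE)
  out <- integer(length(p$x))
  for (l in unique(nchar(p$x))) {
    idx <- which(nchar(p$x) == l)
    ex <- encode_barcodes(p$x[idx])
    ey <- encode_barcodes(p$y[idx])
    blocks <- block_tiling(l)
    off <- 0L
    acc <- integer(length(idx))
    for (k in blocks) {
      w <- 4^((k - 1):0)
      cx <- as.vector(ex[, off + seq_len(k), drop = FALSE] %*% w)
      cy <- as.vector(ey[, off + seq_len(k), drop = FALSE] %*% w)
      lut <- luts[[paste0("k", k)]]
      acc <- acc + lut[cx * 4^k + cy + 1L]
      off <- off + k
    }
    out[idx] <- acc
  }
  out
}
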