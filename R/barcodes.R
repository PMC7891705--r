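#' Validate barcode sequences
#'
#' Barcodes are oligonucleotide sequences over the alphabet {A, C, G, T}.
#' Input is uppercased; any other character (including N or U) is rejected
#' rather than coerced.
#'
#' @param x character vector of sequences.
#' @param same_length require all sequences to have equal length?
#' @return the validated (uppercased) character vector, invisibly usable.
#' @export
validate_barcodes <- function(x, same_length = FALSE) {
  if (!is.character(x) || length(x) == 0)
    stop("barcodes must be a non-empty character vector", call. = FALSE)
  x <- toupper(x)
  bad <- !grepl("^[ACGT]+$", x)
  if (any(bad))
    stop("invalid barcode sequence(s) (alphabet is A/C/G/T): ",
         paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
  if (same_length && length(unique(nchar(x))) != 1L)
    stop("barcodes must all have the same length", call. = FALSE)
  x
}

#' Encode barcodes as a 2-bit integer matrix
#'
#' One row per barcode, values A=0, C=1, G=2, T=3. All computational kernels
#' operate on this encoding; Watson-Crick partners satisfy a + b == 3.
#'
#' @param x character vector of equal-length barcodes.
#' @return integer matrix with `length(x)` rows and `nchar(x[1])` columns.
#' @export
encode_barcodes <- function(x) {
  x <- validate_barcodes(x, same_length = TRUE)
  l <- nchar(x[1L])
  codes <- match(unlist(strsplit(x, "", fixed = TRUE)),
                 c("A", "C", "G", "T")) - 1L
  matrix(codes, nrow = length(x), ncol = l, byrow = TRUE)
}

#' @rdname encode_barcodes
#' @param m integer matrix in the 2-bit encoding.
#' @export
decode_barcodes <- function(m) {
  bases <- c("A", "C", "G", "T")
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  apply(m, 1L, function(r) paste(bases[r + 1L], collapse = ""))
}

#' Reverse complement
#'
#' @param x character vector of sequences over A/C/G/T.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  x <- validate_barcodes(x)
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# n distinct uniform random barcodes of length l, as character vector.
# Uses the current RNG stream.  For dense requests (n close to 4^l) the
# whole space is enumerated and sampled without replacement, which induces
# the same distribution as i.i.d. draws with rejection of duplicates.
random_distinct_barcodes <- function(l, n) {
  space <- 4^l
  if (n > space)
    stop("infeasible: ", n, " barcodes requested but only 4^", l, " = ",
         space, " exist", call. = FALSE)
  if (n > 0.5 * space) {
    if (l > 12)
      stop("dense sampling (n > 0.5 * 4^l) is only supported for l <= 12",
           call. = FALSE)
    codes <- sample.int(space, n) - 1L
    m <- matrix(0L, nrow = n, ncol = l)
    for (p in seq_len(l)) {  # base-4 digits, most significant first
      m[, p] <- codes %/% 4^(l - p) %% 4
    }
    return(decode_barcodes(m))
  }
  bases <- c("A", "C", "G", "T")
  draw <- function(k) {
    m <- matrix(sample(bases, k * l, replace = TRUE), nrow = k, ncol = l)
    apply(m, 1L, paste, collapse = "")
  }
  out <- unique(draw(n))
  while (length(out) < n) {
    out <- unique(c(out, draw(n - length(out))))
  }
  out[seq_len(n)]
}

#' Generate a random barcode set
#'
#' Draws `n` distinct barcodes of length `l` uniformly at random (each base
#' i.i.d. uniform over the four bases, duplicates rejected and redrawn).
#' Deterministic for a given seed.
#'
#' @param l barcode length.
#' @param n number of distinct barcodes; must not exceed `4^l`.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (so callers can manage reproducibility themselves).
#' @return character vector of `n` distinct barcodes.
#' @examples
#' generate_random_set(1, 4, seed = 1)  # the full space A, C, G, T
#' @export
generate_random_set <- function(l, n, seed = NULL) {
  stopifnot(l >= 1, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  random_distinct_barcodes(l, n)
}
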