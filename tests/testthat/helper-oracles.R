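# Brute-force reference implementations, kept independent of the package's
# computational kernels: plain R loops over string characters.

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

oracle_hd <- function(s1, s2) sum(chars(s1) != chars(s2))

oracle_hp <- function(s) max(rle(chars(s))$lengths)

# max tandem copies of any dinucleotide unit, any start position
oracle_sr <- function(s) {
  x <- chars(s)
  l <- length(x)
  if (l < 2) return(1L)
  best <- 1L
  for (st in 1:(l - 1)) {
    u <- x[st:(st + 1)]
    k <- 1L
    pos <- st + 2
    while (pos + 1 <= l && all(x[pos:(pos + 1)] == u)) {
      k <- k + 1L
      pos <- pos + 2
    }
    best <- max(best, k)
  }
  best
}

# enumerate every antiparallel offset and count Watson-Crick pairs
oracle_cp <- function(s1, s2, min_ov = 3) {
  code <- function(s) match(chars(s), c("A", "C", "G", "T")) - 1L
  a <- code(s1); b <- code(s2)
  l1 <- length(a); l2 <- length(b)
  best <- 0L
  for (o in (-(l1 - min_ov)):(l2 - min_ov)) {
    i <- 0:(l1 - 1)
    keep <- (i + o) >= 0 & (i + o) <= l2 - 1
    if (sum(keep) < min_ov) next
    ii <- i[keep]
    best <- max(best, sum(a[ii + 1] + b[l2 - ii - o] == 3))
  }
  best
}

# O(N^2) recomputation of per-barcode components and set totals
oracle_set_totals <- function(barcodes, params, weights, min_ov = 3) {
  n <- length(barcodes)
  l <- nchar(barcodes[1])
  p_hd_i <- p_cp_i <- numeric(n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      s_hd <- p_hd(oracle_hd(barcodes[i], barcodes[j]), params)
      s_cp <- p_cp(oracle_cp(barcodes[i], barcodes[j], min_ov), l, params)
      p_hd_i[i] <- p_hd_i[i] + s_hd; p_hd_i[j] <- p_hd_i[j] + s_hd
      p_cp_i[i] <- p_cp_i[i] + s_cp; p_cp_i[j] <- p_cp_i[j] + s_cp
    }
  }
  comp <- cbind(p_gcc(sapply(barcodes, function(s)
                  100 * sum(chars(s) %in% c("G", "C")) / nchar(s)), params),
                p_hp(sapply(barcodes, oracle_hp), params),
                p_sr(sapply(barcodes, oracle_sr), params),
                p_hd_i, p_cp_i)
  comp <- unname(comp)
  totals <- colSums(comp)
  list(totals = setNames(totals, c("P_GCCt", "P_HPt", "P_SRt", "P_HDt",
                                   "P_CPt")),
       p_wt = sum(unname(weights) * totals),
       p_t = drop(comp %*% unname(weights)))
}

random_seqs <- function(n, l) {
  apply(matrix(sample(c("A", "C", "G", "T"), n * l, replace = TRUE), n, l),
        1, paste, collapse = "")
}
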