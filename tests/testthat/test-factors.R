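test_that("per-barcode factors match their definitions on worked examples", {
  expect_equal(gc_content("AGCTAAGCTACC"), 50)
  expect_equal(gc_content(c("AAAA", "GGCC")), c(0, 100))
  expect_equal(homopolymer_length("GTAAACGGGGGC"), 5L)
  expect_equal(homopolymer_length(c("ACGT", "AATTCCC")), c(1L, 3L))
  expect_equal(ssr_repeats("GGGGGG"), 3L)        # 3 copies of "GG"
  expect_equal(ssr_repeats("TATCTCTCTCGA"), 4L)  # 4 copies of "TC"
  expect_equal(ssr_repeats(c("ACGT", "AG")), c(1L, 1L))
  # lowercase input is canonicalized, other letters rejected
  expect_equal(gc_content("acgt"), 50)
  expect_error(gc_content("ACGTN"), "invalid barcode")
  expect_error(homopolymer_length("ACGU"), "invalid barcode")
})

test_that("pairwise factors match their definitions on worked examples", {
  expect_equal(hamming("AAAAC", "AGAAG"), 2L)
  expect_equal(hamming("ACGTACGTA", "ACGTACGTA"), 0L)
  expect_error(hamming("ACGT", "ACG"), "equal-length")

  expect_equal(complementarity("AGACAT", "GTGTCC"), 4L)
  expect_equal(complementarity("GTGTCC", "AGACAT"), 4L)
  expect_error(complementarity("AC", "ACGT"), "min_overlap")

  expect_equal(levenshtein("AAAAC", "AGAAG"), 2L)
  expect_equal(levenshtein("ACGT", "ACGT"), 0L)
  expect_equal(levenshtein("ACGT", "CGT"), 1L)
})

test_that("factor invariances hold on random barcodes", {
  set.seed(101)
  for (l in c(5, 8, 12)) {
    b <- random_seqs(50, l)
    rev_b <- vapply(strsplit(b, ""), function(s) paste(rev(s), collapse = ""),
                    character(1))
    expect_equal(gc_content(rev_b), gc_content(b))
    expect_equal(homopolymer_length(rev_b), homopolymer_length(b))
    expect_equal(ssr_repeats(rev_b), ssr_repeats(b))
    # homopolymer runs are XX-unit repeats
    expect_true(all(ssr_repeats(b) >= floor(homopolymer_length(b) / 2)))
    # full duplex with the reverse complement
    expect_equal(complementarity(b, reverse_complement(b)), rep(l, 50))
    # symmetry of the pairwise factors
    b2 <- random_seqs(50, l)
    expect_equal(complementarity(b, b2), complementarity(b2, b))
    expect_equal(hamming(b, b2), hamming(b2, b))
    expect_true(all(levenshtein(b, b2) <= hamming(b, b2)))
  }
})

test_that("per-barcode factors agree with brute-force string scans", {
  set.seed(7)
  b <- random_seqs(200, 12)
  expect_equal(homopolymer_length(b), vapply(b, oracle_hp, 1L,
                                             USE.NAMES = FALSE))
  expect_equal(ssr_repeats(b), vapply(b, oracle_sr, 1L, USE.NAMES = FALSE))
})

test_that("complementarity agrees with exhaustive offset enumeration", {
  set.seed(31)
  a <- random_seqs(100, 8)
  b <- random_seqs(100, 8)
  expect_equal(complementarity(a, b),
               mapply(oracle_cp, a, b, USE.NAMES = FALSE))
  # mixed lengths and a different overlap floor
  a6 <- random_seqs(40, 6)
  b9 <- random_seqs(40, 9)
  expect_equal(complementarity(a6, b9, min_overlap = 4),
               mapply(oracle_cp, a6, b9, MoreArgs = list(min_ov = 4),
                      USE.NAMES = FALSE))
})

test_that("levenshtein agrees with the generalized edit-distance oracle", {
  set.seed(13)
  a <- random_seqs(80, 10)
  b <- c(random_seqs(40, 10), random_seqs(40, 7))
  expect_equal(levenshtein(a, b),
               as.integer(mapply(function(x, y) utils::adist(x, y), a, b)))
})

test_that("look-up tables are complete, zero on the diagonal and exact", {
  luts <- build_hd_luts()
  expect_equal(lengths(unclass(luts)),
               c(k2 = 256L, k3 = 4096L, k4 = 65536L))
  for (k in 2:4) {
    tab <- luts[[paste0("k", k)]]
    same <- (0:(4^k - 1)) * 4^k + (0:(4^k - 1)) + 1
    expect_true(all(tab[same] == 0L))
    expect_true(all(tab >= 0L & tab <= k))
  }
  # random spot checks against a per-position scan
  set.seed(5)
  for (rep in 1:50) {
    k <- sample(2:4, 1)
    s1 <- random_seqs(1, k); s2 <- random_seqs(1, k)
    c1 <- oligobarcodes:::kmer_codes(s1, k)
    c2 <- oligobarcodes:::kmer_codes(s2, k)
    expect_identical(luts[[paste0("k", k)]][c1 * 4^k + c2 + 1],
                     oracle_hd(s1, s2))
  }
})

test_that("block-decomposed Hamming distance equals the direct distance", {
  # exhaustive over the full 4-mer space against sampled partners at 2..6
  set.seed(23)
  for (l in 2:6) {
    a <- random_seqs(300, l)
    b <- random_seqs(300, l)
    expect_equal(hamming_lut(a, b), hamming(a, b))
  }
  for (l in c(8, 9, 10, 12)) {
    a <- random_seqs(500, l)
    b <- random_seqs(500, l)
    expect_equal(hamming_lut(a, b), hamming(a, b))
  }
  expect_error(hamming_lut("A", "C"), "length >= 2")
  # greedy largest-first tiling
  expect_equal(oligobarcodes:::block_tiling(8), c(4L, 4L))
  expect_equal(oligobarcodes:::block_tiling(9), c(4L, 3L, 2L))
  expect_equal(oligobarcodes:::block_tiling(10), c(4L, 4L, 2L))
})
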