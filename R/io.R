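# parameter-file dialect: one "key = value" per line, '#' starts a comment.
# Unknown keys and duplicate keys are rejected with the file and key named.

param_file_keys <- list(
  param_general = c("l", "N"),
  param_alpha = "alpha",
  param_weights = c("w1", "w2", "w3", "w4", "w5"),
  param_GCC = c("amp", "mu", "sigma", "best_lo", "best_hi", "scale"),
  param_HP = c("b", "c", "offset"),
  param_SR = c("b", "c", "offset"),
  param_HD = c("amp", "rate", "shift", "zero_from"),
  param_CP = c("amp", "rate", "shift", "ref_len", "threshold"))

parse_kv_file <- function(path, allowed) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  if (any(bad <- !grepl("=", lines, fixed = TRUE)))
    stop("malformed line in ", basename(path), ": '", lines[bad][1L], "'",
         call. = FALSE)
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  if (any(unknown <- !(keys %in% allowed)))
    stop("unknown key '", keys[unknown][1L], "' in ", basename(path),
         call. = FALSE)
  if (anyDuplicated(keys))
    stop("duplicate key '", keys[duplicated(keys)][1L], "' in ",
         basename(path), call. = FALSE)
  num <- suppressWarnings(as.numeric(vals))
  if (any(is.na(num)))
    stop("non-numeric value for key '", keys[is.na(num)][1L], "' in ",
         basename(path), call. = FALSE)
  setNames(as.list(num), keys)
}

#' Read run parameters from a parameter-file directory
#'
#' Reads the plain-text files `param_general` (`l`, `N`), `param_alpha`
#' (`alpha`), `param_weights` (`w1` ... `w5`) and `param_GCC` / `param_HP` /
#' `param_SR` / `param_HD` / `param_CP` (penalty constants). Missing files
#' fall back to the built-in defaults; explicit `overrides` (e.g. from
#' command-line flags) win over file values.
#'
#' @param dir directory containing parameter files; `NULL` for defaults
#'   only.
#' @param overrides named list of [optimizer_config()] arguments taking
#'   precedence over file values.
#' @return an [optimizer_config()] object.
#' @export
read_params <- function(dir = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(dir)) {
    if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
    for (f in names(param_file_keys)) {
      path <- file.path(dir, f)
      if (file.exists(path))
        vals[[f]] <- parse_kv_file(path, param_file_keys[[f]])
      else
        message("parameter file ", f, " not found; using defaults")
    }
  }
  take <- function(file, key, default) {
    v <- vals[[file]][[key]]
    if (is.null(v)) default else v
  }
  pp_args <- list()
  for (spec in list(c("param_GCC", "gcc"), c("param_HP", "hp"),
                    c("param_SR", "sr"), c("param_HD", "hd"),
                    c("param_CP", "cp"))) {
    for (key in param_file_keys[[spec[1L]]]) {
      v <- vals[[spec[1L]]][[key]]
      if (!is.null(v)) pp_args[[paste0(spec[2L], "_", key)]] <- v
    }
  }
  params <- do.call(penalty_params, pp_args)
  weights <- barcode_weights(take("param_weights", "w1", 20),
                             take("param_weights", "w2", 20),
                             take("param_weights", "w3", 20),
                             take("param_weights", "w4", 1),
                             take("param_weights", "w5", 1))
  args <- list(l = take("param_general", "l", 12),
               n = take("param_general", "N", 1e5),
               alpha = take("param_alpha", "alpha", 0.2),
               weights = weights, params = params)
  args[names(overrides)] <- overrides
  do.call(optimizer_config, args)
}

#' Write run parameters as a parameter-file directory
#'
#' Inverse of [read_params()]: writes all parameter files so that reading
#' the directory back reproduces the configuration.
#'
#' @param config an [optimizer_config()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_params <- function(config, dir) {
  stopifnot(inherits(config, "optimizer_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(file, values) {
    writeLines(c(paste("#", file),
                 paste(names(values), "=",
                       vapply(values, format, character(1), digits = 17))),
               file.path(dir, file))
  }
  p <- config$params
  wr("param_general", list(l = config$l, N = config$n))
  wr("param_alpha", list(alpha = config$alpha))
  wr("param_weights", as.list(config$weights))
  wr("param_GCC", list(amp = p$gcc_amp, mu = p$gcc_mu, sigma = p$gcc_sigma,
                       best_lo = p$gcc_best_lo, best_hi = p$gcc_best_hi,
                       scale = p$gcc_scale))
  wr("param_HP", list(b = p$hp_b, c = p$hp_c, offset = p$hp_offset))
  wr("param_SR", list(b = p$sr_b, c = p$sr_c, offset = p$sr_offset))
  wr("param_HD", list(amp = p$hd_amp, rate = p$hd_rate, shift = p$hd_shift,
                      zero_from = p$hd_zero_from))
  wr("param_CP", list(amp = p$cp_amp, rate = p$cp_rate, shift = p$cp_shift,
                      ref_len = p$cp_ref_len, threshold = p$cp_threshold))
  invisible(dir)
}

#' Write and read Hamming look-up-table files
#'
#' Serializes the k-mer Hamming tables of [build_hd_luts()] as plain-text
#' files `hd2_table`, `hd3_table`, `hd4_table` (lines `kmer1 kmer2 hd`) and
#' reads them back. The files are an optional cache: tables are rebuilt in
#' milliseconds when absent.
#'
#' @param luts an `hd_luts` object.
#' @param dir directory for the table files.
#' @return `write_hd_luts()` returns `dir` invisibly; `read_hd_luts()`
#'   returns an `hd_luts` object.
#' @export
write_hd_luts <- function(luts = build_hd_luts(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in 2:4) {
    codes <- 0:(4^k - 1)
    kmers <- decode_barcodes(sapply(seq_len(k),
                                    function(p) codes %/% 4^(k - p) %% 4))
    grid <- expand.grid(c2 = codes, c1 = codes)  # c1-major flattening
    writeLines(paste(kmers[grid$c1 + 1L], kmers[grid$c2 + 1L],
                     luts[[paste0("k", k)]][grid$c1 * 4^k + grid$c2 + 1L]),
               file.path(dir, paste0("hd", k, "_table")))
  }
  invisible(dir)
}

#' @rdname write_hd_luts
#' @export
read_hd_luts <- function(dir) {
  out <- list()
  for (k in 2:4) {
    path <- file.path(dir, paste0("hd", k, "_table"))
    if (!file.exists(path)) stop("missing table file: ", path, call. = FALSE)
    fields <- strsplit(readLines(path, warn = FALSE), " ", fixed = TRUE)
    if (length(fields) != 4^(2 * k) ||
        any(lengths(fields) != 3L))
      stop("corrupt look-up table ", basename(path), ": expected ",
           4^(2 * k), " 'kmer1 kmer2 hd' lines", call. = FALSE)
    m <- do.call(rbind, fields)
    c1 <- kmer_codes(m[, 1L], k)
    c2 <- kmer_codes(m[, 2L], k)
    vals <- suppressWarnings(as.integer(m[, 3L]))
    if (any(is.na(c1)) || any(is.na(c2)) || any(is.na(vals)) ||
        any(vals < 0 | vals > k))
      stop("corrupt look-up table ", basename(path), call. = FALSE)
    tab <- integer(4^(2 * k))
    tab[c1 * 4^k + c2 + 1L] <- vals
    out[[paste0("k", k)]] <- tab
  }
  structure(out, class = "hd_luts")
}

kmer_codes <- function(kmers, k) {
  enc <- match(unlist(strsplit(kmers, "", fixed = TRUE)),
               c("A", "C", "G", "T")) - 1L
  m <- matrix(enc, ncol = k, byrow = TRUE)
  as.integer(m %*% 4^((k - 1):0))
}

#' Write a scored barcode set to a text file
#'
#' The output carries the barcode length, the set size, the six penalty
#' totals of the set and the barcodes sorted lexicographically
#' (A < C < G < T), one per line.
#'
#' @param state a [score_barcode_set()] result or a [optimize_barcode_set()]
#'   fit (its best set is written).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_barcode_set <- function(state, path) {
  if (inherits(state, "barcode_opt")) state <- state$best
  stopifnot(inherits(state, "barcode_set_score"))
  header <- c("# oligobarcodes barcode set v1",
              paste("length =", state$l),
              paste("count =", state$n),
              paste(names(state$totals), "=",
                    sprintf("%.17g", state$totals)),
              paste("P_WT =", sprintf("%.17g", state$p_wt)))
  writeLines(c(header, sort(state$barcodes, method = "radix")), path)
  invisible(path)
}

#' Read a barcode list
#'
#' Accepts three plain-text formats, detected from the first non-blank
#' line: the [write_barcode_set()] output format (header then sorted
#' barcodes), FASTA (read with Biostrings), and bare one-barcode-per-line
#' lists. Invalid sequence lines are reported with their line number.
#'
#' @param path input file.
#' @return character vector of barcodes; for the set format, the header
#'   values are attached as attribute `"header"`.
#' @export
read_barcode_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- trimws(lines[nzchar(trimws(lines))])
  if (!length(nonblank)) stop("empty barcode file: ", path, call. = FALSE)
  first <- nonblank[1L]

  if (startsWith(first, ">")) {
    seqs <- as.character(Biostrings::readDNAStringSet(path))
    bad <- !grepl("^[ACGTacgt]+$", seqs)
    if (any(bad))
      stop("FASTA record ", which(bad)[1L],
           " contains characters outside A/C/G/T", call. = FALSE)
    return(setNames(toupper(seqs), names(seqs)))
  }

  keep <- nzchar(trimws(lines))
  is_header <- startsWith(trimws(lines), "#") |
    grepl("=", lines, fixed = TRUE)
  seq_lines <- which(keep & !is_header)
  if (!length(seq_lines)) stop("no barcode lines in ", path, call. = FALSE)
  bc <- trimws(lines[seq_lines])
  bad <- !grepl("^[ACGTacgt]+$", bc)
  if (any(bad))
    stop("invalid barcode at line ", seq_lines[bad][1L], " of ",
         basename(path), ": '", bc[bad][1L], "'", call. = FALSE)
  bc <- toupper(bc)
  if (any(keep & is_header)) {
    hdr <- lines[keep & is_header]
    hdr <- hdr[!startsWith(trimws(hdr), "#")]
    keysv <- trimws(sub("=.*$", "", hdr))
    valsv <- suppressWarnings(as.numeric(trimws(sub("^[^=]*=", "", hdr))))
    attr(bc, "header") <- setNames(valsv, keysv)
    cnt <- valsv[keysv == "count"]
    if (length(cnt) && !is.na(cnt) && cnt != length(bc))
      stop("header count (", cnt, ") does not match number of barcodes (",
           length(bc), ") in ", basename(path), call. = FALSE)
  }
  bc
}
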