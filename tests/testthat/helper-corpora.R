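# shared helpers: tiny corpora, byte comparison, round-trip driver

file_bytes <- function(path) readBin(path, "raw", n = file.size(path))

tmp_path <- function(ext = "") tempfile(fileext = ext)

# write a record set to FASTQ, compress, decompress, compare bytes
expect_lossless_files <- function(f1, f2 = NULL, xz = TRUE, chunk_kb = 1000,
                                  gzip_out = FALSE, info = NULL) {
  out <- tmp_path(if (xz) ".rfq.xz" else ".rfq")
  o1 <- tmp_path(".fastq")
  o2 <- if (!is.null(f2)) tmp_path(".fastq")
  on.exit(unlink(c(out, o1, o2)))
  rfq_compress(f1, f2, out, chunk_kb = chunk_kb, xz = xz)
  rfq_decompress(out, o1, o2, gzip = gzip_out)
  if (gzip_out) {
    # compare decompressed content instead of container bytes
    r1 <- readBin(gzfile(o1, "rb"), "raw", n = 2 * file.size(f1) + 1e4)
    expect_identical(r1, file_bytes(f1), info = info)
  } else {
    expect_identical(file_bytes(o1), file_bytes(f1), info = info)
    if (!is.null(f2)) expect_identical(file_bytes(o2), file_bytes(f2), info = info)
  }
  invisible(TRUE)
}

# random quality stream with run structure and a given bin count
random_qual_stream <- function(len, n_bins, run_mean = 4) {
  chars <- rawToChar(as.raw(32 + sample.int(94, n_bins)), multiple = TRUE)
  probs <- stats::rexp(n_bins) + 0.05
  k <- ceiling(2 * len / run_mean) + 20
  runs <- 1 + stats::rgeom(k, 1 / run_mean)
  while (sum(runs) < len) runs <- c(runs, 1 + stats::rgeom(k, 1 / run_mean))
  cum <- cumsum(runs)
  keep <- seq_len(which(cum >= len)[1])
  runs <- runs[keep]
  runs[length(runs)] <- runs[length(runs)] - (sum(runs) - len)
  runs <- runs[runs > 0]
  scores <- sample(chars, length(runs), replace = TRUE, prob = probs)
  paste(strrep(scores, runs), collapse = "")
}

random_bases <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# independent R oracle for the 2-bit packer
pack_bases_oracle <- function(s) {
  codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T")) - 1L
  n <- length(codes)
  pad <- (4L - n %% 4L) %% 4L
  codes <- c(codes, rep(0L, pad))
  m <- matrix(codes, nrow = 4L)
  as.raw(m[1, ] + 4L * m[2, ] + 16L * m[3, ] + 64L * m[4, ])
}

# brute-force overlap scan: try all offsets, largest overlap first
find_overlap_oracle <- function(r1, r2, min_overlap, max_mismatch) {
  len1 <- nchar(r1); len2 <- nchar(r2)
  rc2 <- rev_comp_oracle(r2)
  a <- strsplit(r1, "")[[1]]
  b <- strsplit(rc2, "")[[1]]
  for (off in max(0, len1 - len2):(len1 - min_overlap)) {
    if (off < max(0, len1 - len2)) next
    ov <- len1 - off
    if (ov < min_overlap) next
    mism <- sum(a[(off + 1):len1] != b[1:ov])
    if (mism <= min(max_mismatch, ov %/% 8)) return(off)
  }
  NULL
}

rev_comp_oracle <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
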