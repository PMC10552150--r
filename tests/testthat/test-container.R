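test_that("chunk boundaries follow the accumulated-base-count rule", {
  # 10 pairs of 2x150 bases with k=1: chunks close after 4, 4, 2 pairs
  expect_identical(chunk_assignment(rep(300, 10), chunk_kb = 1),
                   rep(c(1L, 2L, 3L), c(4L, 4L, 3L))[1:10])
  # a single record larger than the budget forms its own chunk
  expect_identical(chunk_assignment(c(5000, 10), chunk_kb = 1), c(1L, 2L))
  # k = 1000 default on a 500-base file: one chunk
  expect_identical(chunk_assignment(rep(100, 5)), rep(1L, 5))
})

test_that("written archives reflect the chunking rule frame by frame", {
  f1 <- tmp_path(".fastq"); f2 <- tmp_path(".fastq")
  out <- tmp_path(".rfq")
  on.exit(unlink(c(f1, f2, out)))
  n <- 10
  write_fastq(f1, paste0("p", 1:n), rep(strrep("A", 150), n), rep(strrep("F", 150), n))
  write_fastq(f2, paste0("p", 1:n), rep(strrep("T", 150), n), rep(strrep("F", 150), n))
  rfq_compress(f1, f2, out, chunk_kb = 1, xz = FALSE)
  info <- rfq_info(out)
  expect_identical(info$chunks$records, c(4, 4, 2))
  expect_identical(info$chunks$bases, c(1200, 1200, 600))
  expect_identical(info$total_records, 10)
  expect_true(info$header$paired)
})

test_that("flipping a payload byte is caught by the frame CRC with its index", {
  f1 <- tmp_path(".fastq"); out <- tmp_path(".rfq")
  o1 <- tmp_path(".fastq")
  on.exit(unlink(c(f1, out, o1)))
  write_fastq(f1, paste0("r", 1:30), replicate(30, random_bases(100)),
              replicate(30, strrep("F", 100)))
  rfq_compress(f1, NULL, out, xz = FALSE)
  bytes <- file_bytes(out)
  # corrupt a byte well inside the chunk frame payload
  k <- length(bytes) - 40L
  bytes[k] <- xor(bytes[k], as.raw(0xFF))
  writeBin(bytes, out)
  expect_error(rfq_decompress(out, o1), "CRC mismatch in frame")
})

test_that("bad magic and future versions are rejected", {
  f <- tmp_path(".rfq"); o <- tmp_path(".fastq")
  on.exit(unlink(c(f, o)))
  writeBin(charToRaw("NOPE....junk"), f)
  expect_error(rfq_decompress(f, o), "bad magic")
  f1 <- tmp_path(".fastq")
  write_fastq(f1, "r", "ACGT", "FFFF")
  rfq_compress(f1, NULL, f, xz = FALSE)
  bytes <- file_bytes(f)
  bytes[5] <- as.raw(99)  # version byte
  writeBin(bytes, f)
  expect_error(rfq_decompress(f, o), "unsupported rfq format version")
  unlink(f1)
})

test_that("empty FASTQ input round-trips to an empty file", {
  f1 <- tmp_path(".fastq"); out <- tmp_path(".rfq.xz"); o1 <- tmp_path(".fastq")
  on.exit(unlink(c(f1, out, o1)))
  file.create(f1)
  st <- rfq_compress(f1, NULL, out)
  expect_identical(st$records, 0)
  rfq_decompress(out, o1)
  expect_identical(file.size(o1), 0)
})

test_that("N bases are elided exactly when the chunk's N-score is consistent", {
  cases <- edge_case_corpora()
  f <- tmp_path(".fastq"); out <- tmp_path(".rfq"); o <- tmp_path(".fastq")
  on.exit(unlink(c(f, out, o)))
  # every N carries '#' and no other base does: positions recoverable from
  # qualities alone, so the chunk sets the elision flag
  write_edge_case(cases$all_n_consistent, f)
  rfq_compress(f, NULL, out, xz = FALSE)
  info <- rfq_info(out)
  expect_identical(info$header$n_score, "#")
  expect_true(all(info$chunks$n_elision))
  rfq_decompress(out, o)
  expect_identical(file_bytes(o), file_bytes(f))
  # a non-N base carrying '#': the shortcut must switch off, still lossless
  write_edge_case(cases$all_n_inconsistent, f)
  rfq_compress(f, NULL, out, xz = FALSE)
  expect_false(any(rfq_info(out)$chunks$n_elision))
  rfq_decompress(out, o)
  expect_identical(file_bytes(o), file_bytes(f))
})

test_that("a failed compression leaves no partial output behind", {
  f1 <- tmp_path(".fastq"); out <- tmp_path(".rfq")
  on.exit(unlink(f1))
  writeLines(c("@r", "ACGT", "+", "FF"), f1)  # malformed: length mismatch
  expect_error(rfq_compress(f1, NULL, out, xz = FALSE))
  expect_false(file.exists(out))
  expect_length(list.files(dirname(out), pattern = basename(out)), 0)
})
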