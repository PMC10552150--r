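test_that("reader parses records and pairs in file order", {
  f1 <- tmp_path(".fastq"); f2 <- tmp_path(".fastq")
  on.exit(unlink(c(f1, f2)))
  write_fastq(f1, "r1", "ACGT", "FFFF")
  write_fastq(f2, "r1b", "TTTT", ",,,,")
  rd <- fastq_reader(f1, f2)
  ch <- rd$read_chunk()
  rd$close()
  expect_identical(ch$ids1, "r1")
  expect_identical(ch$seqs2, "TTTT")
  expect_identical(ch$quals2, ",,,,")
  expect_true(ch$paired)
  expect_identical(ch$bases, 8L)
})

test_that("unequal R1/R2 record counts raise a pairing error", {
  f1 <- tmp_path(".fastq"); f2 <- tmp_path(".fastq")
  on.exit(unlink(c(f1, f2)))
  write_fastq(f1, c("a", "b"), c("ACGT", "ACGT"), c("FFFF", "FFFF"))
  write_fastq(f2, "a", "ACGT", "FFFF")
  rd <- fastq_reader(f1, f2)
  expect_error(rd$read_chunk(), "record counts differ")
  rd$close()
})

test_that("gzip input yields the same records as plain input", {
  f <- tmp_path(".fastq"); fgz <- tmp_path(".fastq.gz")
  on.exit(unlink(c(f, fgz)))
  ids <- paste0("r", 1:20)
  seqs <- replicate(20, random_bases(40))
  quals <- replicate(20, strrep("F", 40))
  write_fastq(f, ids, seqs, quals)
  write_fastq(fgz, ids, seqs, quals, gzip = TRUE)
  rd1 <- fastq_reader(f); rd2 <- fastq_reader(fgz)
  c1 <- rd1$read_chunk(); c2 <- rd2$read_chunk()
  rd1$close(); rd2$close()
  expect_identical(c1[c("ids1", "seqs1", "quals1")], c2[c("ids1", "seqs1", "quals1")])
})

test_that("malformed records are reported with their index", {
  f <- tmp_path(".fastq")
  on.exit(unlink(f))
  writeLines(c("@ok", "ACGT", "+", "FFFF", "@bad", "ACGT", "+", "FFF"), f)
  rd <- fastq_reader(f)
  expect_error(rd$read_chunk(), "record 2.*lengths differ")
  rd$close()
  writeLines(c("@ok", "ACGT", "+", "FFFF", "@trunc", "ACGT"), f)
  rd <- fastq_reader(f)
  expect_error(rd$read_chunk(), "truncated")
  rd$close()
})

test_that("CRLF input is rejected with a clear error", {
  f <- tmp_path(".fastq")
  on.exit(unlink(f))
  writeBin(charToRaw("@r\r\nACGT\r\n+\r\nFFFF\r\n"), f)
  rd <- fastq_reader(f)
  expect_error(rd$read_chunk(), "CRLF")
  rd$close()
})

test_that("trailing-newline state is tracked through the reader", {
  f <- tmp_path(".fastq")
  on.exit(unlink(f))
  writeBin(charToRaw("@r\nACGT\n+\nFFFF"), f)  # no final newline
  rd <- fastq_reader(f)
  ch <- rd$read_chunk()
  expect_null(rd$read_chunk())
  expect_false(rd$trailing_newline()[["file1"]])
  expect_identical(ch$quals1, "FFFF")
  rd$close()
  write_fastq(f, "r", "ACGT", "FFFF")
  rd <- fastq_reader(f)
  rd$read_chunk(); rd$read_chunk()
  expect_true(rd$trailing_newline()[["file1"]])
  rd$close()
})

test_that("reader streams one chunk at a time at record boundaries", {
  f <- tmp_path(".fastq")
  on.exit(unlink(f))
  n <- 50
  write_fastq(f, paste0("r", 1:n), rep(strrep("A", 100), n), rep(strrep("F", 100), n))
  rd <- fastq_reader(f, chunk_kb = 1)  # 1000 bases: 10 records per chunk
  sizes <- integer(0)
  repeat {
    ch <- rd$read_chunk()
    if (is.null(ch)) break
    sizes <- c(sizes, length(ch$ids1))
  }
  rd$close()
  expect_identical(sizes, rep(10L, 5))
})
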