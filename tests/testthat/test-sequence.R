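test_that("2-bit packing uses the fixed mapping and bit order", {
  expect_identical(pack_bases("ACGT"), as.raw(0xE4))
  expect_identical(pack_bases("AAAA"), as.raw(0x00))
  expect_identical(pack_bases("TTTT"), as.raw(0xFF))
  expect_identical(pack_bases("A"), as.raw(0x00))  # zero-padded partial byte
  expect_error(pack_bases("ACGN"), "non-ACGT")
})

test_that("packer agrees with an independent arithmetic oracle and round-trips", {
  set.seed(11)
  for (i in 1:200) {
    s <- random_bases(sample(1:97, 1))
    expect_identical(pack_bases(s), pack_bases_oracle(s))
    expect_identical(unpack_bases(pack_bases(s), nchar(s)), s)
  }
  # vector input packs as one concatenated stream
  expect_identical(pack_bases(c("AC", "GT")), pack_bases("ACGT"))
})

test_that("overlap detection matches the worked example and the brute-force scan", {
  d <- find_overlap("ACGGTTCA", "GATCTGAA", min_overlap = 4)
  expect_identical(d$offset, 4L)
  expect_identical(d$merged_length, 12L)
  expect_identical(length(d$mismatch_pos), 0L)
  expect_identical(merge_pair("ACGGTTCA", "GATCTGAA", d), "ACGGTTCAGATC")
  expect_null(find_overlap("AAAAAAAA", "GGGGGGGG", min_overlap = 4))
  # full overlap: reverse-complement mates, offset 0, merged == read1
  r1 <- "ACGTTGCAACGTTGCAACGTTGCAACGTTGCA"
  d0 <- find_overlap(r1, rev_comp_oracle(r1), min_overlap = 8)
  expect_identical(d0$offset, 0L)
  expect_identical(merge_pair(r1, rev_comp_oracle(r1), d0), r1)
  # randomized agreement with the brute-force offset scan
  set.seed(21)
  for (i in 1:100) {
    frag <- random_bases(sample(60:120, 1))
    len <- 50
    r1 <- substr(frag, 1, len)
    r2 <- rev_comp_oracle(substr(frag, nchar(frag) - len + 1, nchar(frag)))
    d <- find_overlap(r1, r2, min_overlap = 10, max_mismatch = 2)
    oracle <- find_overlap_oracle(r1, r2, 10, 2)
    if (is.null(oracle)) expect_null(d)
    else expect_identical(d$offset, as.integer(oracle))
  }
})

test_that("merge and split are exact inverses, including mismatches and N", {
  set.seed(31)
  for (i in 1:200) {
    flen <- sample(60:140, 1)
    frag <- random_bases(flen)
    len <- 50
    r1 <- substr(frag, 1, len)
    r2 <- rev_comp_oracle(substr(frag, flen - len + 1, flen))
    # inject disagreements and Ns into both mates
    mutate <- function(s, k) {
      v <- strsplit(s, "")[[1]]
      pos <- sample(len, k)
      v[pos] <- sample(c("A", "C", "G", "T", "N"), k, replace = TRUE)
      paste(v, collapse = "")
    }
    r1m <- mutate(r1, sample(0:2, 1))
    r2m <- mutate(r2, sample(0:2, 1))
    d <- find_overlap(r1m, r2m, min_overlap = 10, max_mismatch = 4)
    if (is.null(d)) next
    merged <- merge_pair(r1m, r2m, d)
    expect_identical(nchar(merged), d$merged_length)
    expect_lte(d$merged_length, nchar(r1m) + nchar(r2m))
    back <- split_pair(merged, d, nchar(r1m), nchar(r2m))
    expect_identical(back$read1, r1m)
    expect_identical(back$read2, r2m)
  }
})

test_that("corrupt overlap descriptors are rejected", {
  d <- find_overlap("ACGGTTCA", "GATCTGAA", min_overlap = 4)
  expect_error(split_pair("ACGGTTCAGATC", list(offset = 9, mismatch_pos = integer(0),
                                               mismatch_base = ""), 8, 8),
               "corrupt")
  expect_error(split_pair("ACGGTTCAGATC", list(offset = 4, mismatch_pos = 20L,
                                               mismatch_base = "A"), 8, 8),
               "out of range|corrupt")
})

test_that("length coding is fixed-width from the maximum and round-trips", {
  p <- encode_lengths(c(100L, 300L))
  expect_identical(p, as.raw(c(0x02, 0x64, 0x00, 0x2C, 0x01)))  # width byte + LE values
  expect_identical(decode_lengths(p, 2L), c(100L, 300L))
  for (lens in list(c(150L, 150L, 150L), 0L, c(1L, 255L, 256L, 65536L))) {
    expect_identical(decode_lengths(encode_lengths(lens), length(lens)), lens)
  }
})

test_that("merged storage never exceeds separate storage in stored bases", {
  co <- simulate_pe_corpus(corpus_spec(n_pairs = 300, insert_mean = 220,
                                       insert_sd = 40, seed = 13))
  ov <- rfqpack:::rp_find_overlaps(co$seqs1, co$seqs2, 30L, 4L)
  merged <- which(ov$offset >= 0)
  expect_gt(length(merged), 0)
  ml <- ov$offset[merged] + nchar(co$seqs2[merged])
  expect_true(all(ml <= nchar(co$seqs1[merged]) + nchar(co$seqs2[merged])))
  expect_true(all((ml == nchar(co$seqs1[merged]) + nchar(co$seqs2[merged])) ==
                    (ov$offset[merged] == nchar(co$seqs1[merged]))))
})
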