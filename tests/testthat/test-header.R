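make_chunk <- function(seqs, quals, ids = NULL, paired = FALSE) {
  n <- length(seqs)
  list(ids1 = if (is.null(ids)) paste0("r", seq_len(n)) else ids,
       seqs1 = seqs, quals1 = quals, plus1 = rep("", n), paired = paired)
}

test_that("major quality score is the argmax of the table, ties to lowest code", {
  ch <- make_chunk(c(strrep("A", 115)),
                   c(paste0(strrep("F", 100), strrep(",", 10), strrep("#", 5))))
  h <- build_header(ch)
  expect_identical(h$major_q, "F")
  expect_true(all(h$quality_table$count[h$quality_table$score == "F"] >=
                    h$quality_table$count))
  # tie: ',' (44) vs 'F' (70) both 5 -> lower character code wins
  ch2 <- make_chunk("AAAAAAAAAA", ",,,,,FFFFF")
  expect_identical(build_header(ch2)$major_q, ",")
})

test_that("N-score is the unique quality over N bases, absent otherwise", {
  ch <- make_chunk(c("ANNA", "ACGT"), c("F##F", "FFFF"))
  expect_identical(build_header(ch)$n_score, "#")
  # two distinct N qualities -> absent
  ch2 <- make_chunk(c("ANNA"), c("F#!F"))
  expect_true(is.na(build_header(ch2)$n_score))
  # no N bases -> absent
  ch3 <- make_chunk("ACGT", "FFFF")
  expect_true(is.na(build_header(ch3)$n_score))
})

test_that("identifier dialect detection recognizes Casava 1.8 and falls back", {
  expect_identical(detect_dialect("A00001:15:HXXX:1:1101:1000:2000 1:N:0:ACGT"),
                   "ILLUMINA_CASAVA_1_8")
  expect_identical(detect_dialect("read_42"), "GENERIC")
  expect_identical(detect_dialect("SRR000001.7"), "GENERIC")
  expect_identical(detect_dialect("a:b:c 1:N:0:X"), "GENERIC")
})

test_that("header round-trips through serialization bit-exactly", {
  co <- simulate_pe_corpus(corpus_spec(n_pairs = 50, seed = 3))
  ch <- list(ids1 = co$ids1, seqs1 = co$seqs1, quals1 = co$quals1,
             ids2 = co$ids2, seqs2 = co$seqs2, quals2 = co$quals2,
             paired = TRUE)
  h <- build_header(ch)
  h2 <- rfqpack:::parse_header(rfqpack:::serialize_header(h))
  expect_identical(h2, h)
  expect_identical(h$dialect, "ILLUMINA_CASAVA_1_8")
  expect_identical(h$read_length, 150L)
  # empty-input header also survives
  h0 <- build_header(NULL, paired = TRUE)
  expect_identical(rfqpack:::parse_header(rfqpack:::serialize_header(h0)), h0)
})

test_that("empty first chunk is rejected upstream but header has a defined fallback", {
  h <- build_header(NULL, paired = FALSE)
  expect_false(h$paired)
  expect_identical(nrow(h$quality_table), 0L)
})
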