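test_that("tokenization splits digit runs and concatenates back to the input", {
  tk <- tokenize_identifier("A00001:15:1101:1000")
  expect_identical(tk$tokens, c("A", "00001", ":", "15", ":", "1101", ":", "1000"))
  expect_identical(tk$digit, c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
  for (id in c("read", "7", "a1b2c3", ":::", "x007y", "99bottles")) {
    tk <- tokenize_identifier(id)
    expect_identical(paste(tk$tokens, collapse = ""), id)
  }
})

test_that("layout derivation classifies constant, numeric and literal fields", {
  lay <- derive_layout(c("L1:100", "L1:103", "L1:107"))
  expect_false(lay$degraded)
  # "L1:" is constant (as three tokens), the trailing digit run is the field
  expect_identical(lay$kind, c("constant", "constant", "constant", "numeric"))
  expect_identical(lay$baseline[4], 100)
  # pure text variation -> literal
  lay2 <- derive_layout(c("a", "b"))
  expect_identical(lay2$kind, "literal")
  # differing token shapes -> whole-chunk degradation
  expect_true(derive_layout(c("a:1", "no_digits"))$degraded)
  # same shape with different text: still layout-coded, fields literal
  expect_identical(derive_layout(c("a:1", "b2"))$kind, c("literal", "numeric"))
  # leading zeros: same width stays numeric (zero-padded), mixed width degrades the field
  expect_identical(derive_layout(c("x007", "x008"))$kind[2], "numeric")
  expect_identical(derive_layout(c("x007", "x008"))$width[2], 3L)
  expect_identical(derive_layout(c("x007", "x18"))$kind[2], "literal")
  # digit runs too long for exact doubles stay literal
  expect_identical(derive_layout(c(strrep("9", 16), strrep("8", 16)))$kind, "literal")
})

test_that("progressive-difference coding emits the stated zigzag varint bytes", {
  expect_identical(encode_numeric_series(c(1101, 1102, 1105), 1101),
                   as.raw(c(0x02, 0x06)))
  expect_identical(encode_numeric_series(5, 5), raw(0))
  expect_identical(encode_numeric_series(c(10, 7), 10), as.raw(0x05))
  # round trip including multi-byte varints and sign changes
  set.seed(42)
  for (i in 1:25) {
    v <- cumsum(sample(c(-500, -3, -1, 0, 1, 2, 300, 70000), 40, replace = TRUE))
    v <- v - min(v)
    expect_identical(decode_numeric_series(encode_numeric_series(v, v[1]),
                                           length(v), v[1]), as.numeric(v))
  }
})

test_that("meta block round-trips arbitrary identifiers byte-exactly", {
  set.seed(7)
  rand_id <- function() {
    parts <- replicate(sample(1:6, 1), {
      if (runif(1) < 0.5) strrep("0", sample(0:2, 1))  # leading zeros
      else ""
    })
    paste0(sample(c("x", ":", "07", "tile", "0", "9981", " ", "..", "A"),
                  sample(1:8, 1), replace = TRUE), collapse = "")
  }
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    ids <- vapply(seq_len(n), function(i) rand_id(), "")
    ids[ids == ""] <- "x"
    blk <- encode_meta_block(ids)
    out <- decode_meta_block(blk, n, paired = FALSE)
    expect_identical(out$ids1, ids)
  }
})

test_that("read2 identifiers are derived from read1 when only the read-number differs", {
  co <- simulate_pe_corpus(corpus_spec(n_pairs = 200, seed = 5))
  blk <- encode_meta_block(co$ids1, co$ids2)
  out <- decode_meta_block(blk, 200, paired = TRUE)
  expect_identical(out$ids1, co$ids1)
  expect_identical(out$ids2, co$ids2)
  # brute-force check of the premise on the generated corpus
  expect_identical(sub(" 1:", " 2:", co$ids1, fixed = TRUE), co$ids2)
  # the derived form must be much smaller than storing read2 independently
  blk_indep <- encode_meta_block(co$ids1, paste0(co$ids2, "Z"))
  expect_lt(length(blk), length(blk_indep) * 0.7)
  # identical read2 ids and fully independent read2 ids also round-trip
  for (ids2 in list(co$ids1, rev(co$ids2))) {
    out <- decode_meta_block(encode_meta_block(co$ids1, ids2), 200, TRUE)
    expect_identical(out$ids2, ids2)
  }
})

test_that("delta coding on monotone coordinates never loses more than a byte per record", {
  co <- simulate_pe_corpus(corpus_spec(n_pairs = 500, seed = 9))
  lay <- derive_layout(co$ids1)
  for (j in which(lay$kind == "numeric")) {
    vals <- as.numeric(lay$tokens[, j])
    delta_bytes <- length(encode_numeric_series(vals, vals[1]))
    raw_bytes <- length(rfqpack:::rp_varint_encode(vals))
    expect_lte(delta_bytes, raw_bytes + length(vals))
  }
})

test_that("truncated meta payloads raise a corruption error", {
  ids <- sprintf("L1:%d", 1:50)
  blk <- encode_meta_block(ids)
  expect_error(decode_meta_block(blk[1:(length(blk) - 3)], 50, FALSE),
               "exhausted|corrupt")
  expect_error(decode_meta_block(blk, 60, FALSE), "exhausted|corrupt")
})
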