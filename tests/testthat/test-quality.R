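test_that("strategy selection follows the 64-bin rule", {
  expect_identical(select_strategy(4), "column")
  expect_identical(select_strategy(1), "column")
  expect_identical(select_strategy(63), "column")
  expect_identical(select_strategy(64), "rle")
  expect_identical(select_strategy(70), "rle")
})

test_that("stream segmentation matches a run-length oracle and tiles the stream", {
  s <- segment_stream("FFFF,,FF")
  expect_identical(s$score, c("F", ",", "F"))
  expect_identical(s$pos, c(0, 4, 6))
  expect_identical(s$len, c(4, 2, 2))
  expect_identical(segment_stream("A"),
                   data.frame(score = "A", pos = 0, len = 1))
  set.seed(5)
  for (i in 1:50) {
    q <- random_qual_stream(sample(1:400, 1), sample(1:10, 1))
    s <- segment_stream(q)
    o <- rle(strsplit(q, "")[[1]])
    expect_identical(s$score, o$values)
    expect_identical(s$len, as.numeric(o$lengths))
    expect_identical(sum(s$len), as.numeric(nchar(q)))
  }
})

test_that("column combos use the documented byte layouts", {
  # single segment: offset 4, len 2 -> one size-1 combo 0b00_100_010
  p <- encode_column("FFFF,,FF", "F")
  # block: n_scores=1, score ',', count 1, combo 0x22
  expect_identical(p, c(as.raw(1), charToRaw(","), as.raw(1), as.raw(0x22)))
  # offset 500, len 3 needs the 3-byte layout and round-trips
  q <- paste0(strrep("F", 500), ":::", strrep("F", 100))
  expect_identical(decode_column(encode_column(q, "F"), nchar(q), "F"), q)
  # all-major stream: empty segment payload
  expect_identical(encode_column("FFFFFF", "F"), as.raw(0))
  expect_identical(decode_column(as.raw(0), 6, "F"), "FFFFFF")
})

test_that("column codec handles long runs and gaps past the 15-bit capacity", {
  # gap of 70000 needs skip combos; run of 70000 needs continuation combos
  q <- paste0(strrep("F", 70000), strrep("#", 70000), "F",
              strrep("#", 3), strrep("F", 40000), "#")
  expect_identical(decode_column(encode_column(q, "F"), nchar(q), "F"), q)
})

test_that("rle codec emits frequency-ranked one-byte combos and splits long runs", {
  # "FFFF,,FF" with table [F, ","]: combos (F,4),(",",2),(F,2)
  p <- encode_rle("FFFF,,FF", c("F", ","))
  expect_identical(p, as.raw(c(0x03, 0x41, 0x01)))
  expect_identical(decode_rle(p, 8, c("F", ",")), "FFFF,,FF")
  # run of 1000 of the top score: 16 combos (15 x 64 + 40)
  p2 <- encode_rle(strrep("F", 1000), "F")
  expect_identical(length(p2), 16L)
  expect_identical(decode_rle(p2, 1000, "F"), strrep("F", 1000))
  # low-rank scores encode one position per byte; escape beyond the code space
  tab <- rawToChar(as.raw(33:112), multiple = TRUE)  # 80 ranks
  q <- paste(rev(tab), collapse = "")
  expect_identical(decode_rle(encode_rle(q, tab), nchar(q), tab), q)
})

test_that("both codecs are exact inverses on fuzzed streams across the bin range", {
  set.seed(17)
  for (i in 1:300) {
    nb <- sample(1:70, 1)
    q <- random_qual_stream(sample(1:2000, 1), nb)
    tab <- rfqpack:::rp_qual_table(q)
    strat <- select_strategy(length(tab$score))
    if (strat == "column") {
      major <- tab$score[which.max(tab$count)]
      expect_identical(decode_column(encode_column(q, major), nchar(q), major), q)
    }
    # rle must round-trip regardless of bin count
    ord <- order(-tab$count, tab$score)
    expect_identical(decode_rle(encode_rle(q, tab$score[ord]), nchar(q),
                                tab$score[ord]), q)
  }
})

test_that("column payload shrinks as the major-score fraction grows", {
  set.seed(23)
  n <- 20000
  fracs <- seq(0.5, 0.95, by = 0.05)
  sizes <- vapply(fracs, function(f) {
    q <- paste(sample(c("F", ",", ":"), n, replace = TRUE,
                      prob = c(f, (1 - f) * 0.7, (1 - f) * 0.3)), collapse = "")
    length(encode_column(q, "F"))
  }, 0)
  expect_lt(stats::cor(fracs, sizes, method = "spearman"), -0.9)
  expect_lt(sizes[length(sizes)], sizes[1])
})

test_that("corrupt quality payloads are rejected", {
  q <- "FFFF,,FF"
  p <- encode_column(q, "F")
  expect_error(decode_column(p[1:2], 8, "F"), "exhausted|corrupt")
  expect_error(decode_column(c(p, as.raw(9)), 8, "F"), "corrupt")
  p2 <- encode_rle(q, c("F", ","))
  expect_error(decode_rle(p2[1:2], 8, c("F", ",")), "exhausted|corrupt")
  expect_error(decode_rle(p2, 5, c("F", ",")), "corrupt")
})
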