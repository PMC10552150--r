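test_that("generation is deterministic given the seed", {
  a <- simulate_pe_corpus(corpus_spec(n_pairs = 100, seed = 42))
  b <- simulate_pe_corpus(corpus_spec(n_pairs = 100, seed = 42))
  expect_identical(a, b)
  c2 <- simulate_pe_corpus(corpus_spec(n_pairs = 100, seed = 43))
  expect_false(identical(a$seqs1, c2$seqs1))
})

test_that("quality marginals match the configured bins within one percent", {
  bins <- c("F" = 0.85, "," = 0.08, ":" = 0.05, "#" = 0.02)
  co <- simulate_pe_corpus(corpus_spec(n_pairs = 4000, n_rate = 0,
                                       quality_bins = bins, seed = 8))
  q <- paste(c(co$quals1, co$quals2), collapse = "")
  n <- nchar(q)
  expect_gte(n, 1e6)
  tab <- rfqpack:::rp_qual_table(q)
  freq <- tab$count / n
  names(freq) <- tab$score
  for (ch in names(bins)) expect_lt(abs(freq[[ch]] - bins[[ch]]), 0.01)
})

test_that("mates overlap exactly when the insert is under twice the read length", {
  co <- simulate_pe_corpus(corpus_spec(n_pairs = 200, insert_mean = 200,
                                       insert_sd = 30, error_rate = 0,
                                       n_rate = 0, seed = 12))
  expect_true(all(co$truth$overlap == pmax(2 * 150 - co$truth$insert, 0)))
  # noiseless limit: the detected offset equals the true offset everywhere
  ov <- rfqpack:::rp_find_overlaps(co$seqs1, co$seqs2, 30L, 4L)
  has <- co$truth$overlap >= 30
  expect_true(all(ov$offset[has] == co$truth$offset[has]))
  # by construction read2 is the reverse complement of the fragment suffix
  i <- which(co$truth$insert == 300)[1]
  if (!is.na(i)) expect_identical(nchar(co$seqs2[i]), 150L)
})

test_that("edge-case corpora cover the degradation paths they claim", {
  cases <- edge_case_corpora()
  expect_true(all(c("empty_file", "one_record", "variable_lengths",
                    "many_quality_bins", "non_acgtn_bases",
                    "no_trailing_newline", "plus_repeats_identifier",
                    "paired_mixed") %in% names(cases)))
  # the 70-bin case must select the run-length strategy
  q <- cases$many_quality_bins$quals1
  expect_gte(length(rfqpack:::rp_qual_table(q)$score), 64)
  expect_identical(select_strategy(length(rfqpack:::rp_qual_table(q)$score)), "rle")
  # quality strings always match sequence lengths
  for (cs in cases) {
    expect_identical(nchar(cs$seqs1), nchar(cs$quals1))
    if (isTRUE(cs$paired)) expect_identical(nchar(cs$seqs2), nchar(cs$quals2))
  }
})
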