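#' Describe a synthetic paired-end corpus
#'
#' Defines the statistical structure of a simulated sequencing run:
#' fragments are drawn from a finite random genome (so reads share sequence
#' at realistic depth), read1 is the fragment prefix and read2 the reverse
#' complement of the fragment suffix, mates overlap whenever the insert is
#' shorter than twice the read length, and qualities follow a binned scheme
#' with run structure along the read. The defaults emulate a NovaSeq-like
#' run: 150 bp reads, 4 quality bins dominated by one score, per-base error
#' 1e-3, N rate 2e-3.
#'
#' @param n_pairs number of read pairs.
#' @param read_length read length in bases.
#' @param insert_mean,insert_sd normal insert-size distribution.
#' @param insert_min lower truncation of the insert (default: read length,
#'   so reads never run past the fragment end).
#' @param error_rate per-base substitution error rate.
#' @param n_rate per-base N rate (N bases receive the `n_score` quality).
#' @param quality_bins named numeric vector: quality characters and their
#'   marginal probabilities.
#' @param quality_run_mean mean length of constant-quality runs.
#' @param n_score quality character assigned to N bases.
#' @param genome_size size of the synthetic genome fragments are drawn
#'   from; smaller genomes mean higher depth and more cross-read
#'   redundancy.
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return a `corpus_spec` list.
#' @export
corpus_spec <- function(n_pairs = 1000L, read_length = 150L,
                        insert_mean = 300, insert_sd = 50,
                        insert_min = NULL,
                        error_rate = 0.001, n_rate = 0.002,
                        quality_bins = c("F" = 0.85, "," = 0.08,
                                         ":" = 0.05, "#" = 0.02),
                        quality_run_mean = 8,
                        n_score = "#",
                        genome_size = 2e6,
                        seed = 1L) {
  if (is.null(insert_min)) insert_min <- read_length
  stopifnot(n_pairs >= 1, read_length >= 1, insert_min >= read_length,
            abs(sum(quality_bins) - 1) < 1e-8)
  structure(list(n_pairs = as.integer(n_pairs),
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 insert_min = insert_min, error_rate = error_rate,
                 n_rate = n_rate, quality_bins = quality_bins,
                 quality_run_mean = quality_run_mean, n_score = n_score,
                 genome_size = genome_size, seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Simulate a paired-end FASTQ corpus
#'
#' Deterministic given `spec$seed`. Identifiers are Casava 1.8-style with
#' monotone tile coordinates; read1 and read2 identifiers differ only in
#' the read-number field. The returned ground truth records each pair's
#' insert size and, for overlapping pairs, the true merge offset
#' (`insert - read_length`) and overlap length (`2 * read_length - insert`).
#'
#' @param spec a [corpus_spec()].
#' @return list with `ids1`, `seqs1`, `quals1`, `ids2`, `seqs2`, `quals2`
#'   and a `truth` data.frame (`insert`, `offset`, `overlap`).
#' @export
simulate_pe_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  n <- spec$n_pairs
  rl <- spec$read_length
  max_frag <- max(ceiling(spec$insert_mean + 6 * spec$insert_sd), rl + 1)
  genome_size <- max(spec$genome_size, max_frag + 1)
  genome <- rp_random_bases(genome_size)
  frag <- pmin(pmax(round(rnorm(n, spec$insert_mean, spec$insert_sd)),
                    spec$insert_min), max_frag)
  starts <- sample.int(genome_size - max_frag, n, replace = TRUE)
  reads <- rp_simulate_reads(genome, starts, as.integer(frag), rl,
                             spec$error_rate, spec$n_rate,
                             paste(names(spec$quality_bins), collapse = ""),
                             unname(spec$quality_bins),
                             spec$quality_run_mean, spec$n_score)
  tile <- 1101L + (seq_len(n) - 1L) %/% 10000L
  x <- cumsum(sample.int(30L, n, replace = TRUE))
  y <- cumsum(sample.int(30L, n, replace = TRUE))
  head_part <- sprintf("A00001:15:HXFQPACKXX:1:%d:%d:%d", tile, x, y)
  ids1 <- paste0(head_part, " 1:N:0:ACGTACGT")
  ids2 <- paste0(head_part, " 2:N:0:ACGTACGT")
  overlap <- 2L * rl - frag
  list(ids1 = ids1, seqs1 = reads$seq1, quals1 = reads$qual1,
       ids2 = ids2, seqs2 = reads$seq2, quals2 = reads$qual2,
       truth = data.frame(insert = frag,
                          offset = ifelse(overlap > 0, frag - rl, NA),
                          overlap = pmax(overlap, 0L)))
}

#' Write a simulated corpus to FASTQ files
#'
#' @param corpus result of [simulate_pe_corpus()].
#' @param path1,path2 output paths (`path2` `NULL` writes read1 only).
#' @param gzip write gzip-compressed FASTQ.
#' @return invisibly, the paths.
#' @export
write_corpus <- function(corpus, path1, path2 = NULL, gzip = FALSE) {
  write_fastq(path1, corpus$ids1, corpus$seqs1, corpus$quals1, gzip = gzip)
  if (!is.null(path2))
    write_fastq(path2, corpus$ids2, corpus$seqs2, corpus$quals2, gzip = gzip)
  invisible(c(path1, path2))
}

#' Adversarial edge-case corpora
#'
#' Small hand-built inputs exercising the container's degradation paths:
#' empty file, single record, variable read lengths, all-N reads with and
#' without a consistent N-score, 70 distinct quality bins (forcing the
#' run-length codec), non-ACGTN bases, identifiers with leading zeros and
#' mixed shapes, a missing trailing newline, and plus lines repeating the
#' identifier. Each element carries the record columns plus `paired` and
#' `trailing_newline`.
#'
#' @return named list of edge-case corpora.
#' @export
edge_case_corpora <- function() {
  se <- function(ids, seqs, quals, plus = "", trailing = TRUE) {
    list(paired = FALSE, ids1 = ids, seqs1 = seqs, quals1 = quals,
         plus1 = rep_len(plus, length(ids)), trailing_newline = trailing)
  }
  cases <- list(
    empty_file = se(character(0), character(0), character(0)),
    one_record = se("read_1", "ACGTACGTAA", "FFFFFFFF,,"),
    variable_lengths = se(
      paste0("var_", 1:6),
      c("ACGT", "ACGTACGTACGTACGTACGTACGTACGT", "A", "TTTTTTTTTT",
        "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT", "GG"),
      c("FFFF", "FFFFFFFFFFFFFFFF,,,,,,,,,,,,", "#", ":::::,,,,,",
        paste(rep("F", 56), collapse = ""), "FF")),
    all_n_consistent = se(
      c("n_1", "n_2", "n_3"),
      c("NNNNNNNNNN", "ACGTACGTAC", "ACNNTACGTA"),
      c("##########", "FFFFFFFFFF", "FF##FFFFFF")),
    all_n_inconsistent = se(
      c("n_1", "n_2"),
      c("NNNNNNNNNN", "ACGTACGTAC"),
      c("##########", "FF#FFFFFFF")),  # '#' on a non-N base: elision off
    many_quality_bins = se(
      "bins_70",
      paste(rep("ACGT", 18), collapse = ""),
      rawToChar(as.raw(33:104))),      # 72 distinct printable scores
    non_acgtn_bases = se(
      c("iupac_1", "iupac_2"),
      c("ACGRYSWKMacgtNNT", "ACGTACGTACGTACGT"),
      c("FFFFFFFFFFFFFFFF", "FFFF,,,,::::####")),
    leading_zeros_mixed = se(
      c("tile:007:x", "tile:008:x", "tile:0009:x", "other_shape", "tile:010:x"),
      rep("ACGTACGT", 5),
      rep("FFFFFFFF", 5)),
    no_trailing_newline = se(
      c("t_1", "t_2"), c("ACGTACGT", "TTTTACGT"),
      c("FFFFFFFF", ",,,,FFFF"), trailing = FALSE),
    plus_repeats_identifier = se(
      c("p_1", "p_2"), c("ACGTACGT", "GGGGACGT"),
      c("FFFFFFFF", "FFFF,,,,"), plus = NA)
  )
  cases$plus_repeats_identifier$plus1 <- cases$plus_repeats_identifier$ids1
  # a paired case with mates that fully overlap and one that does not
  r1 <- c("ACGGTTCAGGATCCTA", "ACGTACGTACGTACGT")
  cases$paired_mixed <- list(
    paired = TRUE,
    ids1 = c("pair:1 1:N:0:AC", "pair:2 1:N:0:AC"),
    seqs1 = r1,
    quals1 = c("FFFFFFFFFFFFFFFF", "FFFFFFFF,,,,,,,,"),
    plus1 = c("", ""),
    ids2 = c("pair:1 2:N:0:AC", "pair:2 2:N:0:AC"),
    seqs2 = c(rp_revcomp(r1[1]), "TTTTTTTTGGGGGGGG"),
    quals2 = c("::::::::FFFFFFFF", "FFFFFFFFFFFFFFFF"),
    plus2 = c("", ""),
    trailing_newline = TRUE)
  cases
}

#' Write an edge-case corpus to FASTQ
#'
#' @param case one element of [edge_case_corpora()].
#' @param path1,path2 output paths (`path2` used for paired cases).
#' @return invisibly, the paths written.
#' @export
write_edge_case <- function(case, path1, path2 = NULL) {
  write_fastq(path1, case$ids1, case$seqs1, case$quals1,
              plus = if (length(case$ids1)) case$plus1 else "",
              trailing_newline = case$trailing_newline)
  if (isTRUE(case$paired)) {
    stopifnot(!is.null(path2))
    write_fastq(path2, case$ids2, case$seqs2, case$quals2,
                plus = if (length(case$ids2)) case$plus2 else "",
                trailing_newline = case$trailing_newline)
    return(invisible(c(path1, path2)))
  }
  invisible(path1)
}
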