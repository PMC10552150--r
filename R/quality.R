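#' Choose the quality codec for a chunk
#'
#' Column-based `<OFFSET, LEN>` coding is used when the chunk has fewer
#' than 64 distinct quality characters (the common case for modern binned
#' schemes); otherwise interleaved `<SCORE, LEN>` run-length coding.
#'
#' @param distinct_bins number of distinct quality characters (>= 1).
#' @return `"column"` or `"rle"`.
#' @export
select_strategy <- function(distinct_bins) {
  stopifnot(distinct_bins >= 1)
  if (distinct_bins < 64) "column" else "rle"
}

#' Segment a quality stream into per-score runs
#'
#' @param qualities the chunk's concatenated quality string.
#' @return data.frame with `score`, `pos` (0-based start) and `len`, in
#'   stream order; the segments tile the stream exactly.
#' @export
segment_stream <- function(qualities) {
  s <- rp_segment_stream(qualities)
  data.frame(score = s$score, pos = s$pos, len = s$len)
}

#' Column-based quality encoding
#'
#' Stores, per non-major score, its run segments as `<OFFSET, LEN>` combos
#' of 1 to 4 whole bytes (2-bit size tag, then equally split offset/length
#' fields of 3, 7, 11 or 15 bits). OFFSET is the gap from the previous
#' segment's end; LEN is stored verbatim with 0 reserved as a skip combo
#' (the escape for gaps beyond 15 bits). Segments of the major score are
#' not stored: the decoder fills uncovered positions with it.
#'
#' @param qualities concatenated quality string.
#' @param major_q the chunk's major quality character.
#' @return raw payload.
#' @export
encode_column <- function(qualities, major_q) {
  rp_encode_column(qualities, utf8ToInt(major_q))
}

#' Decode a column-based quality payload
#'
#' @param payload raw payload from [encode_column()].
#' @param stream_length length of the original stream.
#' @param major_q the major quality character.
#' @return the quality string.
#' @export
decode_column <- function(payload, stream_length, major_q) {
  rp_decode_column(payload, stream_length, utf8ToInt(major_q))
}

#' Run-length quality encoding
#'
#' Every maximal run becomes one or more single-byte `<SCORE, LEN>` combos.
#' Scores ranked by descending frequency receive shorter codes and hence
#' more length bits: the top two scores run up to 64 per combo, ranks 3-10
#' up to 8, further ranks encode single positions, and scores beyond the
#' one-byte code space use a two-byte `0xFF` + literal escape.
#'
#' @param qualities concatenated quality string.
#' @param score_table distinct scores in descending frequency order
#'   (character vector or one string).
#' @return raw payload.
#' @export
encode_rle <- function(qualities, score_table) {
  rp_encode_rle(qualities, paste(score_table, collapse = ""))
}

#' Decode a run-length quality payload
#'
#' @param payload raw payload from [encode_rle()].
#' @param stream_length length of the original stream.
#' @param score_table the score table used for encoding.
#' @return the quality string.
#' @export
decode_rle <- function(payload, stream_length, score_table) {
  rp_decode_rle(payload, stream_length, paste(score_table, collapse = ""))
}

# Per-chunk quality block. The strategy, score table and major score are
# re-derived from the chunk's own data (the header's table is only a hint).
# Layout: varint stream length, then
#   column: u8 major, payload
#   rle:    varint n_scores, score bytes in rank order, payload
encode_quality_block <- function(qstream) {
  tab <- rp_qual_table(qstream)
  distinct <- length(tab$score)
  slen <- rp_varint_encode(nchar(qstream, type = "bytes"))
  if (distinct == 0) {
    return(list(block = c(slen, charToRaw("!")), strategy = "column"))
  }
  strategy <- select_strategy(distinct)
  if (strategy == "column") {
    major <- tab$score[which.max(tab$count)]
    block <- c(slen, charToRaw(major), encode_column(qstream, major))
  } else {
    ord <- order(-tab$count, tab$score)
    table_str <- paste(tab$score[ord], collapse = "")
    block <- c(slen, rp_varint_encode(nchar(table_str)), charToRaw(table_str),
               rp_encode_rle(qstream, table_str))
  }
  list(block = block, strategy = strategy)
}

decode_quality_block <- function(block, strategy) {
  r <- rp_varint_decode_at(block, 1L, 0)
  slen <- r$values
  pos <- r$pos
  rest <- function() if (pos < length(block)) block[(pos + 1):length(block)] else raw(0)
  if (strategy == "column") {
    major <- rawToChar(block[pos + 1]); pos <- pos + 1
    if (slen == 0) return("")
    rp_decode_column(rest(), slen, utf8ToInt(major))
  } else {
    r <- rp_varint_decode_at(block, 1L, pos)
    nt <- r$values; pos <- r$pos
    table_str <- rawToChar(block[pos + seq_len(nt)]); pos <- pos + nt
    if (slen == 0) return("")
    rp_decode_rle(rest(), slen, table_str)
  }
}
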