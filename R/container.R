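# .rfq container: magic "RFQ2", one version byte, a header frame, chunk
# frames, and an end marker. Every frame is
#   u8 type (1 = chunk, 0 = end, 2 = header)
#   u32 payload length (little-endian)
#   payload
#   u32 CRC32 of the payload
# The end marker carries the trailing-newline flags, the total record
# count, and a running CRC32 over all chunk payloads. Full byte-level
# layout in FORMAT.md.

FRAME_HEADER <- 2L
FRAME_CHUNK <- 1L
FRAME_END <- 0L

CHUNK_FLAG_NELISION <- 1L
CHUNK_FLAG_CONSTLEN <- 2L
CHUNK_FLAG_META_DEGRADED <- 4L
CHUNK_FLAG_RLE <- 8L
# bits 4-5: plus style file1; bits 6-7: plus style file2
# style 0 = bare '+', 1 = '+' repeats the identifier, 2 = literal per record

#' Assign records to chunks by accumulated base count
#'
#' A chunk closes at the first record boundary where the accumulated base
#' count reaches `chunk_kb * 1000`; records are never split, and the last
#' chunk may be smaller.
#'
#' @param bases per-record base counts (both mates for paired data).
#' @param chunk_kb chunk size in kilobases.
#' @return integer vector of 1-based chunk indices, one per record.
#' @export
chunk_assignment <- function(bases, chunk_kb = 1000) {
  stopifnot(chunk_kb >= 1)
  budget <- chunk_kb * 1000
  id <- integer(length(bases))
  cur <- 1L
  acc <- 0
  for (i in seq_along(bases)) {
    acc <- acc + bases[i]
    id[i] <- cur
    if (acc >= budget) {
      cur <- cur + 1L
      acc <- 0
    }
  }
  id
}

plus_style <- function(plus, ids) {
  if (all(plus == "")) 0L
  else if (all(plus == ids)) 1L
  else 2L
}

write_frame <- function(con, type, payload) {
  writeBin(as.raw(type), con)
  writeBin(rp_u32_raw(length(payload)), con)
  if (length(payload)) writeBin(payload, con)
  writeBin(rp_u32_raw(rp_crc32(payload, 0)), con)
  invisible(8L + length(payload))
}

# encode one chunk into a frame payload
encode_chunk <- function(chunk, header, min_overlap = 30L, max_mismatch = 4L) {
  n <- length(chunk$ids1)
  paired <- isTRUE(chunk$paired)

  style1 <- plus_style(chunk$plus1, chunk$ids1)
  style2 <- if (paired) plus_style(chunk$plus2, chunk$ids2) else 0L

  n_elision <- FALSE
  if (!is.na(header$n_score)) {
    ns <- utf8ToInt(header$n_score) + 1L
    st <- rp_base_qual_stats(chunk$seqs1, chunk$quals1)
    qcount <- st$qtable[ns]; ncount <- st$ntable[ns]; ntot <- st$n_bases
    if (paired) {
      st2 <- rp_base_qual_stats(chunk$seqs2, chunk$quals2)
      qcount <- qcount + st2$qtable[ns]
      ncount <- ncount + st2$ntable[ns]
      ntot <- ntot + st2$n_bases
    }
    # consistent: every N carries the N-score and no non-N base does
    n_elision <- (ncount == ntot) && (qcount == ncount)
  }

  lens <- nchar(chunk$seqs1, type = "bytes")
  if (paired) lens <- c(lens, nchar(chunk$seqs2, type = "bytes"))
  const_len <- !is.na(header$read_length) && all(lens == header$read_length)

  if (paired) {
    ov <- rp_find_overlaps(chunk$seqs1, chunk$seqs2,
                           as.integer(min_overlap), as.integer(max_mismatch))
    offsets <- ov$offset
    mm_pos <- ov$mismatch_pos
    mm_base <- ov$mismatch_base
  } else {
    offsets <- NULL
    mm_pos <- list()
    mm_base <- character(0)
  }

  meta <- encode_meta_block(
    chunk$ids1,
    if (paired) chunk$ids2 else NULL,
    if (style1 == 2L) chunk$plus1 else NULL,
    if (paired && style2 == 2L) chunk$plus2 else NULL)
  meta_degraded <- bitwAnd(as.integer(meta[1]), 1L) > 0

  seqb <- rp_encode_sequence_block(
    chunk$seqs1, if (paired) chunk$seqs2 else NULL, offsets,
    mm_pos, mm_base, n_elision, const_len,
    if (const_len) header$read_length else 0L)

  qstream <- rp_concat_interleave(chunk$quals1, if (paired) chunk$quals2 else NULL)
  qb <- encode_quality_block(qstream)

  flags <- 0L
  if (n_elision) flags <- bitwOr(flags, CHUNK_FLAG_NELISION)
  if (const_len) flags <- bitwOr(flags, CHUNK_FLAG_CONSTLEN)
  if (meta_degraded) flags <- bitwOr(flags, CHUNK_FLAG_META_DEGRADED)
  if (qb$strategy == "rle") flags <- bitwOr(flags, CHUNK_FLAG_RLE)
  flags <- bitwOr(flags, bitwShiftL(style1, 4L))
  flags <- bitwOr(flags, bitwShiftL(style2, 6L))

  c(rp_varint_encode(c(n, sum(lens))),
    as.raw(flags),
    rp_u32_raw(length(meta)), meta,
    rp_u32_raw(length(seqb$block)), seqb$block,
    qb$block)
}

# decode one chunk frame payload back into records
decode_chunk <- function(payload, header) {
  r <- rp_varint_decode_at(payload, 2L, 0)
  n <- as.integer(r$values[1])
  base_count <- r$values[2]
  pos <- r$pos
  flags <- as.integer(payload[pos + 1]); pos <- pos + 1
  n_elision <- bitwAnd(flags, CHUNK_FLAG_NELISION) > 0
  const_len <- bitwAnd(flags, CHUNK_FLAG_CONSTLEN) > 0
  rle <- bitwAnd(flags, CHUNK_FLAG_RLE) > 0
  style1 <- bitwAnd(bitwShiftR(flags, 4L), 3L)
  style2 <- bitwAnd(bitwShiftR(flags, 6L), 3L)
  paired <- header$paired

  meta_len <- rp_raw_u32(payload, pos); pos <- pos + 4
  meta <- payload[pos + seq_len(meta_len)]; pos <- pos + meta_len
  seq_len_ <- rp_raw_u32(payload, pos); pos <- pos + 4
  seqb <- payload[pos + seq_len(seq_len_)]; pos <- pos + seq_len_
  qblock <- if (pos < length(payload)) payload[(pos + 1):length(payload)] else raw(0)

  m <- decode_meta_block(meta, n, paired)
  qstream <- decode_quality_block(qblock, if (rle) "rle" else "column")
  sq <- rp_decode_sequence_block(
    seqb, n, paired, n_elision, const_len,
    if (const_len) header$read_length else 0L,
    qstream,
    if (is.na(header$n_score)) -1L else utf8ToInt(header$n_score))

  if (sum(sq$len1) + sum(sq$len2) != base_count)
    stop("corrupt chunk: base count mismatch")
  if (nchar(qstream, type = "bytes") != base_count)
    stop("corrupt chunk: quality stream length mismatch")

  # split the quality stream back into per-record strings
  pair_len <- sq$len1 + if (paired) sq$len2 else 0L
  start1 <- c(0, cumsum(pair_len))[seq_len(n)] + 1
  quals1 <- substring(qstream, start1, start1 + sq$len1 - 1)
  out <- list(
    ids1 = m$ids1, seqs1 = sq$seqs1,
    plus1 = switch(as.character(style1), "0" = rep.int("", n),
                   "1" = m$ids1, "2" = m$plus1),
    quals1 = quals1, paired = paired)
  if (paired) {
    start2 <- start1 + sq$len1
    out$ids2 <- m$ids2
    out$seqs2 <- sq$seqs2
    out$plus2 <- switch(as.character(style2), "0" = rep.int("", n),
                        "1" = m$ids2, "2" = m$plus2)
    out$quals2 <- substring(qstream, start2, start2 + sq$len2 - 1)
  }
  out
}
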