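#' Compress FASTQ files into an .rfq or .rfq.xz archive
#'
#' Two-step compression: records are repacked chunk by chunk into the
#' byte-aligned `.rfq` container, and (optionally, default) the repacked
#' stream is further compressed with LZMA into a standard xz container.
#' Paired-end files should be compressed together: shared identifier
#' content is stored once and overlapping mate sequences are merged, which
#' single-file compression cannot exploit.
#'
#' The output is written to a temporary file in the target directory and
#' renamed on success, so a failed run never leaves a partial archive
#' behind.
#'
#' @param input1 FASTQ path (plain or gzip).
#' @param input2 optional mate FASTQ for paired-end data.
#' @param output output path; when `xz` is `NULL` the `.xz` suffix decides
#'   whether the LZMA stage runs.
#' @param chunk_kb chunk size in kilobases (default 1000 = 1 Mb of bases).
#' @param xz run the LZMA stage (default: inferred from `output`).
#' @param preset,dict_mib,threads,block_mib LZMA settings, see
#'   [xz_compress()].
#' @param min_overlap,max_mismatch overlap acceptance parameters, see
#'   [find_overlap()].
#' @param verbose log per-chunk progress to standard error.
#' @return invisibly, a list with `records`, `bases`, `input_bytes`,
#'   `output_bytes` and `ratio` (input over output).
#' @export
rfq_compress <- function(input1, input2 = NULL, output,
                         chunk_kb = 1000, xz = NULL, preset = 6L,
                         dict_mib = 64, threads = 1L, block_mib = 0,
                         min_overlap = 30L, max_mismatch = 4L,
                         verbose = FALSE) {
  if (!file.exists(input1)) stop("input file not found: ", input1)
  if (!is.null(input2) && !file.exists(input2)) stop("input file not found: ", input2)
  if (is.null(xz)) xz <- grepl("\\.xz$", output)

  tmp <- paste0(output, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, "wb")
  con_open <- TRUE
  on.exit(if (con_open) close(con), add = TRUE)

  reader <- fastq_reader(input1, input2, chunk_kb = chunk_kb)
  on.exit(reader$close(), add = TRUE)

  first <- reader$read_chunk()
  header <- build_header(first, paired = !is.null(input2))
  writeBin(RFQ_MAGIC, con)
  writeBin(as.raw(RFQ_VERSION), con)
  write_frame(con, FRAME_HEADER, serialize_header(header))

  total_records <- 0
  total_bases <- 0
  running_crc <- 0
  chunk <- first
  i <- 0L
  while (!is.null(chunk)) {
    i <- i + 1L
    payload <- encode_chunk(chunk, header, min_overlap, max_mismatch)
    write_frame(con, FRAME_CHUNK, payload)
    running_crc <- rp_crc32(payload, running_crc)
    total_records <- total_records + length(chunk$ids1)
    total_bases <- total_bases + chunk$bases
    if (verbose)
      message(sprintf("chunk %d: %d records, %d bases, %d packed bytes",
                      i, length(chunk$ids1), chunk$bases, length(payload)))
    chunk <- reader$read_chunk()
  }
  tnl <- reader$trailing_newline()
  end_flags <- 0L
  if (isTRUE(tnl[["file1"]])) end_flags <- bitwOr(end_flags, 1L)
  if (isTRUE(tnl[["file2"]])) end_flags <- bitwOr(end_flags, 2L)
  write_frame(con, FRAME_END,
              c(as.raw(end_flags), rp_varint_encode(total_records),
                rp_u32_raw(running_crc)))
  close(con)
  con_open <- FALSE

  if (xz) {
    rfq <- readBin(tmp, "raw", n = file.size(tmp))
    compressed <- xz_compress(rfq, preset = preset, dict_mib = dict_mib,
                              threads = threads, block_mib = block_mib)
    writeBin(compressed, tmp)
  }
  if (!file.rename(tmp, output)) {
    file.copy(tmp, output, overwrite = TRUE)
    unlink(tmp)
  }
  in_bytes <- file.size(input1) + if (is.null(input2)) 0 else file.size(input2)
  out_bytes <- file.size(output)
  if (verbose)
    message(sprintf("%d records, %.0f bases: %.0f -> %.0f bytes (ratio %.2f)",
                    total_records, total_bases, in_bytes, out_bytes,
                    in_bytes / out_bytes))
  invisible(list(records = total_records, bases = total_bases,
                 input_bytes = in_bytes, output_bytes = out_bytes,
                 ratio = in_bytes / out_bytes))
}

#' Inspect an .rfq or .rfq.xz archive
#'
#' Reads the archive structure without reconstructing any FASTQ: the
#' header, and per chunk the record count, base count and frame flags.
#'
#' @param input archive path.
#' @return list with `header`, `chunks` (data.frame with `records`,
#'   `bases`, `n_elision`, `const_len`, `strategy`) and `total_records`.
#' @export
rfq_info <- function(input) {
  data <- readBin(input, "raw", n = file.size(input))
  xz_magic <- as.raw(c(0xfd, 0x37, 0x7a, 0x58, 0x5a, 0x00))
  if (length(data) >= 6 && identical(data[1:6], xz_magic))
    data <- xz_decompress(data)
  if (length(data) < 5 || !identical(data[1:4], RFQ_MAGIC))
    stop("not an rfq archive: bad magic bytes")
  pos <- 5
  header <- NULL
  records <- bases <- numeric(0)
  nel <- cl <- logical(0)
  strat <- character(0)
  total_records <- NA_real_
  repeat {
    type <- as.integer(data[pos + 1])
    len <- rp_raw_u32(data, pos + 1)
    payload <- if (len > 0) data[pos + 5 + seq_len(len)] else raw(0)
    pos <- pos + 9 + len
    if (type == FRAME_HEADER) {
      header <- parse_header(payload)
    } else if (type == FRAME_CHUNK) {
      r <- rp_varint_decode_at(payload, 2L, 0)
      flags <- as.integer(payload[r$pos + 1])
      records <- c(records, r$values[1])
      bases <- c(bases, r$values[2])
      nel <- c(nel, bitwAnd(flags, CHUNK_FLAG_NELISION) > 0)
      cl <- c(cl, bitwAnd(flags, CHUNK_FLAG_CONSTLEN) > 0)
      strat <- c(strat, if (bitwAnd(flags, CHUNK_FLAG_RLE) > 0) "rle" else "column")
    } else {
      r <- rp_varint_decode_at(payload, 1L, 1)
      total_records <- r$values
      break
    }
  }
  list(header = header,
       chunks = data.frame(records = records, bases = bases,
                           n_elision = nel, const_len = cl,
                           strategy = strat),
       total_records = total_records)
}

#' Decompress an .rfq or .rfq.xz archive back to FASTQ
#'
#' Reconstructs the original FASTQ file(s) byte-exactly, including plus
#' lines and the presence or absence of a final newline. The container
#' type is auto-detected from the leading magic bytes; frame CRCs are
#' verified and corruption is reported with the failing frame index.
#'
#' @param input archive path (`.rfq` or `.rfq.xz`).
#' @param output1 output FASTQ path.
#' @param output2 output path for the mate file (required for paired
#'   archives).
#' @param gzip write gzip-compressed FASTQ.
#' @return invisibly, a list with `records` and `paired`.
#' @export
rfq_decompress <- function(input, output1, output2 = NULL, gzip = FALSE) {
  if (!file.exists(input)) stop("input file not found: ", input)
  data <- readBin(input, "raw", n = file.size(input))
  xz_magic <- as.raw(c(0xfd, 0x37, 0x7a, 0x58, 0x5a, 0x00))
  if (length(data) >= 6 && identical(data[1:6], xz_magic))
    data <- xz_decompress(data)
  if (length(data) < 5 || !identical(data[1:4], RFQ_MAGIC))
    stop("not an rfq archive: bad magic bytes")
  version <- as.integer(data[5])
  if (version > RFQ_VERSION)
    stop("unsupported rfq format version ", version)

  pos <- 5
  read_frame <- function(index) {
    if (pos + 9 > length(data)) stop("corrupt archive: truncated frame ", index)
    type <- as.integer(data[pos + 1])
    len <- rp_raw_u32(data, pos + 1)
    if (pos + 9 + len > length(data)) stop("corrupt archive: truncated frame ", index)
    payload <- if (len > 0) data[pos + 5 + seq_len(len)] else raw(0)
    crc <- rp_raw_u32(data, pos + 5 + len)
    if (rp_crc32(payload, 0) != crc)
      stop("corrupt archive: CRC mismatch in frame ", index)
    pos <<- pos + 9 + len
    list(type = type, payload = payload)
  }

  fr <- read_frame(0L)
  if (fr$type != FRAME_HEADER) stop("corrupt archive: missing header frame")
  header <- parse_header(fr$payload)
  paired <- header$paired
  if (paired && is.null(output2))
    stop("paired-end archive: an output path for the mate file is required")

  tmp1 <- paste0(output1, ".tmp", Sys.getpid())
  tmp2 <- if (paired) paste0(output2, ".tmp", Sys.getpid())
  on.exit({
    if (file.exists(tmp1)) unlink(tmp1)
    if (!is.null(tmp2) && file.exists(tmp2)) unlink(tmp2)
  }, add = TRUE)
  con1 <- if (gzip) gzfile(tmp1, "wb") else file(tmp1, "wb")
  con2 <- if (paired) (if (gzip) gzfile(tmp2, "wb") else file(tmp2, "wb"))
  on.exit({
    if (!is.null(con1)) close(con1)
    if (!is.null(con2)) close(con2)
  }, add = TRUE)

  nl <- charToRaw("\n")
  total_records <- 0
  running_crc <- 0
  first_rec <- TRUE
  idx <- 0L
  repeat {
    idx <- idx + 1L
    fr <- read_frame(idx)
    if (fr$type == FRAME_END) {
      end_flags <- as.integer(fr$payload[1])
      r <- rp_varint_decode_at(fr$payload, 1L, 1)
      if (r$values != total_records)
        stop("corrupt archive: record count mismatch in end marker")
      if (rp_raw_u32(fr$payload, r$pos) != running_crc)
        stop("corrupt archive: whole-file CRC mismatch")
      if (total_records > 0) {
        if (bitwAnd(end_flags, 1L) > 0) writeBin(nl, con1)
        if (paired && bitwAnd(end_flags, 2L) > 0) writeBin(nl, con2)
      }
      break
    }
    if (fr$type != FRAME_CHUNK) stop("corrupt archive: unexpected frame type ", fr$type)
    running_crc <- rp_crc32(fr$payload, running_crc)
    ch <- decode_chunk(fr$payload, header)
    txt1 <- paste(paste0("@", ch$ids1), ch$seqs1, paste0("+", ch$plus1),
                  ch$quals1, sep = "\n")
    blob1 <- charToRaw(paste(txt1, collapse = "\n"))
    if (!first_rec) writeBin(nl, con1)
    writeBin(blob1, con1)
    if (paired) {
      txt2 <- paste(paste0("@", ch$ids2), ch$seqs2, paste0("+", ch$plus2),
                    ch$quals2, sep = "\n")
      if (!first_rec) writeBin(nl, con2)
      writeBin(charToRaw(paste(txt2, collapse = "\n")), con2)
    }
    first_rec <- FALSE
    total_records <- total_records + length(ch$ids1)
  }
  close(con1)
  if (paired) close(con2)
  con1 <- con2 <- NULL
  if (!file.rename(tmp1, output1)) {
    file.copy(tmp1, output1, overwrite = TRUE); unlink(tmp1)
  }
  if (paired && !file.rename(tmp2, output2)) {
    file.copy(tmp2, output2, overwrite = TRUE); unlink(tmp2)
  }
  invisible(list(records = total_records, paired = paired))
}
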