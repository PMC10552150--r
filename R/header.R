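#' Build the file-level header from the first chunk
#'
#' Traverses the first chunk to collect the quality table, the major quality
#' score (most frequent quality character; ties broken by lowest character
#' code), the N-score (the unique quality character observed over N bases,
#' when one exists), the identifier dialect, and whether the read length is
#' constant. The header is a hint for the encoder and a compatibility record
#' for the decoder: every chunk re-derives its own quality table, so
#' losslessness never depends on the first chunk being representative.
#'
#' @param chunk a chunk as produced by [fastq_reader()]; for an empty input
#'   pass `NULL` together with `paired`.
#' @param paired logical; only consulted when `chunk` is `NULL`.
#' @return an object of class `rfq_header`.
#' @export
build_header <- function(chunk, paired = FALSE) {
  if (is.null(chunk) || length(chunk$ids1) == 0) {
    return(structure(list(version = RFQ_VERSION, paired = paired,
                          major_q = "!", n_score = NA_character_,
                          dialect = "GENERIC", read_length = NA_integer_,
                          quality_table = data.frame(score = character(0),
                                                     count = numeric(0))),
                     class = "rfq_header"))
  }
  st1 <- rp_base_qual_stats(chunk$seqs1, chunk$quals1)
  qtab <- st1$qtable
  ntab <- st1$ntable
  if (isTRUE(chunk$paired)) {
    st2 <- rp_base_qual_stats(chunk$seqs2, chunk$quals2)
    qtab <- qtab + st2$qtable
    ntab <- ntab + st2$ntable
  }
  present <- which(qtab > 0)
  major_q <- rawToChar(as.raw(present[which.max(qtab[present])] - 1L))
  ncars <- which(ntab > 0)
  n_score <- if (length(ncars) == 1L) rawToChar(as.raw(ncars - 1L)) else NA_character_
  lens <- nchar(chunk$seqs1, type = "bytes")
  if (isTRUE(chunk$paired)) lens <- c(lens, nchar(chunk$seqs2, type = "bytes"))
  read_length <- if (length(unique(lens)) == 1L) lens[1] else NA_integer_
  structure(list(
    version = RFQ_VERSION,
    paired = isTRUE(chunk$paired),
    major_q = major_q,
    n_score = n_score,
    dialect = detect_dialect(chunk$ids1[1]),
    read_length = read_length,
    quality_table = data.frame(
      score = vapply(present - 1L, function(i) rawToChar(as.raw(i)), ""),
      count = qtab[present])
  ), class = "rfq_header")
}

#' Detect the identifier dialect
#'
#' Recognizes Illumina Casava 1.8-style identifiers
#' (`instrument:run:flowcell:lane:tile:x:y read:filter:control:index`,
#' i.e. a 7-field colon block, a space, and a 4-field colon block);
#' everything else is `GENERIC`.
#'
#' @param identifier a FASTQ identifier without the leading `@`.
#' @return `"ILLUMINA_CASAVA_1_8"` or `"GENERIC"`.
#' @export
detect_dialect <- function(identifier) {
  stopifnot(length(identifier) == 1L, nchar(identifier) > 0)
  pat <- "^[^:[:space:]]+:[0-9]+:[^:[:space:]]+:[0-9]+:[0-9]+:[0-9]+:[0-9]+ [0-9]+:[YN]:[0-9]+:[^[:space:]]*$"
  if (grepl(pat, identifier)) "ILLUMINA_CASAVA_1_8" else "GENERIC"
}

DIALECT_CODES <- c(GENERIC = 0L, ILLUMINA_CASAVA_1_8 = 1L)

serialize_header <- function(h) {
  flags <- 0L
  if (h$paired) flags <- bitwOr(flags, 1L)
  if (!is.na(h$read_length)) flags <- bitwOr(flags, 2L)
  if (!is.na(h$n_score)) flags <- bitwOr(flags, 4L)
  parts <- list(
    as.raw(flags),
    as.raw(DIALECT_CODES[[h$dialect]]),
    charToRaw(h$major_q))
  if (!is.na(h$n_score)) parts <- c(parts, list(charToRaw(h$n_score)))
  if (!is.na(h$read_length)) parts <- c(parts, list(rp_varint_encode(h$read_length)))
  parts <- c(parts, list(rp_varint_encode(nrow(h$quality_table))))
  if (nrow(h$quality_table) > 0) {
    parts <- c(parts, list(
      charToRaw(paste(h$quality_table$score, collapse = "")),
      rp_varint_encode(h$quality_table$count)))
  }
  do.call(c, parts)
}

parse_header <- function(payload) {
  pos <- 0
  u8 <- function() {
    pos <<- pos + 1
    as.integer(payload[pos])
  }
  vint <- function(n) {
    r <- rp_varint_decode_at(payload, n, pos)
    pos <<- r$pos
    r$values
  }
  flags <- u8()
  dialect_code <- u8()
  major_q <- rawToChar(payload[pos + 1]); pos <- pos + 1
  n_score <- NA_character_
  if (bitwAnd(flags, 4L) > 0) {
    n_score <- rawToChar(payload[pos + 1]); pos <- pos + 1
  }
  read_length <- NA_integer_
  if (bitwAnd(flags, 2L) > 0) read_length <- as.integer(vint(1))
  nq <- vint(1)
  qtab <- data.frame(score = character(0), count = numeric(0))
  if (nq > 0) {
    chars <- payload[pos + seq_len(nq)]
    pos <- pos + nq
    counts <- vint(nq)
    qtab <- data.frame(score = vapply(seq_len(nq), function(i) rawToChar(chars[i]), ""),
                       count = counts)
  }
  structure(list(version = RFQ_VERSION,
                 paired = bitwAnd(flags, 1L) > 0,
                 major_q = major_q, n_score = n_score,
                 dialect = names(DIALECT_CODES)[match(dialect_code, DIALECT_CODES)],
                 read_length = read_length, quality_table = qtab),
            class = "rfq_header")
}

#' @export
print.rfq_header <- function(x, ...) {
  cat("rfq header (format version ", x$version, ")\n", sep = "")
  cat("  mode:        ", if (x$paired) "paired-end" else "single-end", "\n", sep = "")
  cat("  dialect:     ", x$dialect, "\n", sep = "")
  cat("  major Q:     '", x$major_q, "'\n", sep = "")
  cat("  N-score:     ", if (is.na(x$n_score)) "absent" else paste0("'", x$n_score, "'"), "\n", sep = "")
  cat("  read length: ", if (is.na(x$read_length)) "variable" else x$read_length, "\n", sep = "")
  cat("  quality bins (first chunk): ", nrow(x$quality_table), "\n", sep = "")
  invisible(x)
}
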