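#' Tokenize a FASTQ identifier
#'
#' Splits an identifier into maximal runs of decimal digits (candidate
#' numeric fields) and the text between them. Concatenating the tokens
#' reproduces the identifier exactly; leading zeros are preserved verbatim.
#'
#' @param identifier a non-empty identifier string.
#' @return a list with `tokens` (character vector) and `digit` (logical,
#'   `TRUE` for digit-run tokens).
#' @export
tokenize_identifier <- function(identifier) {
  stopifnot(length(identifier) == 1L, nchar(identifier) > 0)
  rp_tokenize_id(identifier)
}

#' Derive the per-chunk identifier layout
#'
#' Tokenizes every identifier of a chunk; when all identifiers share one
#' token shape, each token column becomes CONSTANT (identical everywhere,
#' stored once in the chunk head), NUMERIC (a digit run that can be
#' delta-coded: at most 15 digits, and either no leading zeros or one fixed
#' width), or LITERAL (stored per record). Identifiers with differing shapes
#' degrade the whole chunk to literal per-record storage.
#'
#' @param identifiers character vector of chunk identifiers.
#' @return a list describing the layout; `degraded = TRUE` when shapes
#'   differ. Otherwise `kind` is one of `"constant"`, `"numeric"`,
#'   `"literal"` per token, with `baseline` and `width` for numeric tokens
#'   (`width` 0 means no leading-zero padding).
#' @export
derive_layout <- function(identifiers) {
  tk <- rp_tokenize_chunk(identifiers)
  if (!tk$ok) return(list(degraded = TRUE))
  toks <- tk$tokens
  k <- ncol(toks)
  kind <- character(k)
  width <- integer(k)
  baseline <- numeric(k)
  text <- character(k)
  for (j in seq_len(k)) {
    col <- toks[, j]
    if (all(col == col[1])) {
      kind[j] <- "constant"
      text[j] <- col[1]
    } else if (tk$digit[j]) {
      wid <- nchar(col)
      if (any(wid > 15L)) {
        kind[j] <- "literal"
      } else if (!any(wid > 1L & startsWith(col, "0"))) {
        kind[j] <- "numeric"
        width[j] <- 0L
        baseline[j] <- as.numeric(col[1])
      } else if (all(wid == wid[1])) {
        kind[j] <- "numeric"
        width[j] <- wid[1]
        baseline[j] <- as.numeric(col[1])
      } else {
        kind[j] <- "literal"
      }
    } else {
      kind[j] <- "literal"
    }
  }
  list(degraded = FALSE, kind = kind, width = width, baseline = baseline,
       text = text, tokens = toks, digit = tk$digit)
}

#' Delta-encode a numeric identifier field
#'
#' Successive differences `v[i] - v[i-1]` are zigzag-mapped
#' (`2|n| - (n < 0)`) and emitted as byte-aligned varints; the baseline
#' (first value) is stored in the layout, not the payload.
#'
#' @param values non-empty numeric vector of non-negative integers.
#' @param baseline must equal `values[1]`.
#' @return raw payload (empty for a single value).
#' @export
encode_numeric_series <- function(values, baseline) {
  stopifnot(length(values) >= 1, values[1] == baseline)
  if (length(values) == 1L) return(raw(0))
  rp_zigzag_encode(diff(values))
}

#' Decode a delta-encoded numeric series
#'
#' @param payload raw payload from [encode_numeric_series()].
#' @param n number of values.
#' @param baseline the stored baseline.
#' @return numeric vector of length `n`.
#' @export
decode_numeric_series <- function(payload, n, baseline) {
  if (n == 1L) return(baseline)
  baseline + c(0, cumsum(rp_zigzag_decode(payload, n - 1L)))
}

fmt_numeric_field <- function(values, width) {
  if (width > 0) sprintf(paste0("%0", width, ".0f"), values)
  else sprintf("%.0f", values)
}

# serialize a non-degraded layout plus its per-record payloads
encode_layout_section <- function(layout) {
  n <- nrow(layout$tokens)
  k <- length(layout$kind)
  parts <- list(rp_varint_encode(k))
  for (j in seq_len(k)) {
    if (layout$kind[j] == "constant") {
      parts <- c(parts, list(as.raw(0L), rp_pack_strings(layout$text[j])))
    } else if (layout$kind[j] == "numeric") {
      parts <- c(parts, list(as.raw(1L), as.raw(layout$width[j]),
                             rp_varint_encode(layout$baseline[j])))
    } else {
      parts <- c(parts, list(as.raw(2L)))
    }
  }
  for (j in seq_len(k)) {
    if (layout$kind[j] == "numeric") {
      vals <- as.numeric(layout$tokens[, j])
      parts <- c(parts, list(encode_numeric_series(vals, layout$baseline[j])))
    } else if (layout$kind[j] == "literal") {
      parts <- c(parts, list(rp_pack_strings(layout$tokens[, j])))
    }
  }
  do.call(c, parts)
}

decode_layout_section <- function(payload, n, pos) {
  vint <- function(m) {
    r <- rp_varint_decode_at(payload, m, pos)
    pos <<- r$pos
    r$values
  }
  k <- as.integer(vint(1))
  kind <- character(k); width <- integer(k); baseline <- numeric(k)
  text <- character(k)
  for (j in seq_len(k)) {
    type <- as.integer(payload[pos + 1]); pos <- pos + 1
    if (type == 0L) {
      kind[j] <- "constant"
      r <- rp_unpack_strings(payload, 1L, pos); pos <- r$pos
      text[j] <- r$strings
    } else if (type == 1L) {
      kind[j] <- "numeric"
      width[j] <- as.integer(payload[pos + 1]); pos <- pos + 1
      baseline[j] <- vint(1)
    } else if (type == 2L) {
      kind[j] <- "literal"
    } else stop("corrupt meta block: unknown token type")
  }
  cols <- vector("list", k)
  for (j in seq_len(k)) {
    if (kind[j] == "constant") {
      cols[[j]] <- rep.int(text[j], n)
    } else if (kind[j] == "numeric") {
      if (n == 1L) vals <- baseline[j]
      else {
        r <- rp_zigzag_decode_at(payload, n - 1L, pos); pos <- r$pos
        vals <- baseline[j] + c(0, cumsum(r$values))
      }
      cols[[j]] <- fmt_numeric_field(vals, width[j])
    } else {
      r <- rp_unpack_strings(payload, n, pos); pos <- r$pos
      cols[[j]] <- r$strings
    }
  }
  list(ids = do.call(paste0, cols), pos = pos)
}

#' Encode the identifier/meta block of a chunk
#'
#' Read1 identifiers are stored through the derived layout (or literally
#' when the chunk degrades). In paired mode, read2 identifiers that are
#' identical to read1's, or differ in exactly one token that is constant
#' across the chunk (typically the Casava read-number field), are derived
#' from read1 instead of being stored. Plus lines are stored literally only
#' for the rare mixed-style chunks.
#'
#' @param ids1,ids2 identifier vectors (`ids2` `NULL` for single-end).
#' @param plus1,plus2 plus-line literals to embed, or `NULL` when the
#'   chunk's plus style is bare/identifier-repeating.
#' @return raw meta block.
#' @export
encode_meta_block <- function(ids1, ids2 = NULL, plus1 = NULL, plus2 = NULL) {
  n <- length(ids1)
  lay1 <- derive_layout(ids1)
  mflags <- 0L
  if (lay1$degraded) mflags <- bitwOr(mflags, 1L)
  r2_mode <- 0L
  lay2 <- NULL
  subst <- NULL
  if (!is.null(ids2)) {
    if (identical(ids1, ids2)) {
      r2_mode <- 0L
    } else {
      tk2 <- rp_tokenize_chunk(ids2)
      shared <- FALSE
      if (!lay1$degraded && tk2$ok &&
          identical(dim(tk2$tokens), dim(lay1$tokens)) &&
          identical(tk2$digit, lay1$digit)) {
        differs <- colSums(tk2$tokens != lay1$tokens) > 0
        dc <- which(differs)
        if (length(dc) == 1L && all(tk2$tokens[, dc] == tk2$tokens[1, dc])) {
          shared <- TRUE
          r2_mode <- 1L
          subst <- list(col = dc, text = tk2$tokens[1, dc])
        }
      }
      if (!shared) {
        r2_mode <- 2L
        lay2 <- derive_layout(ids2)
        if (lay2$degraded) mflags <- bitwOr(mflags, 8L)
      }
    }
    mflags <- bitwOr(mflags, bitwShiftL(r2_mode, 1L))
  }
  if (!is.null(plus1)) mflags <- bitwOr(mflags, 16L)
  if (!is.null(plus2)) mflags <- bitwOr(mflags, 32L)
  parts <- list(as.raw(mflags))
  parts <- c(parts, list(
    if (lay1$degraded) rp_pack_strings(ids1) else encode_layout_section(lay1)))
  if (!is.null(ids2)) {
    if (r2_mode == 1L) {
      parts <- c(parts, list(rp_varint_encode(subst$col - 1L),
                             rp_pack_strings(subst$text)))
    } else if (r2_mode == 2L) {
      parts <- c(parts, list(
        if (lay2$degraded) rp_pack_strings(ids2) else encode_layout_section(lay2)))
    }
  }
  if (!is.null(plus1)) parts <- c(parts, list(rp_pack_strings(plus1)))
  if (!is.null(plus2)) parts <- c(parts, list(rp_pack_strings(plus2)))
  do.call(c, parts)
}

#' Decode a meta block
#'
#' Exact inverse of [encode_meta_block()].
#'
#' @param payload raw meta block.
#' @param n record count of the chunk.
#' @param paired whether the chunk stores read pairs.
#' @return list with `ids1`, `ids2` (`NULL` for single-end), and plus-line
#'   literals `plus1`/`plus2` (`NULL` unless stored).
#' @export
decode_meta_block <- function(payload, n, paired) {
  pos <- 0
  mflags <- as.integer(payload[1]); pos <- 1
  r1_degraded <- bitwAnd(mflags, 1L) > 0
  r2_mode <- bitwAnd(bitwShiftR(mflags, 1L), 3L)
  r2_degraded <- bitwAnd(mflags, 8L) > 0
  has_plus1 <- bitwAnd(mflags, 16L) > 0
  has_plus2 <- bitwAnd(mflags, 32L) > 0
  if (r1_degraded) {
    r <- rp_unpack_strings(payload, n, pos); pos <- r$pos
    ids1 <- r$strings
  } else {
    r <- decode_layout_section(payload, n, pos); pos <- r$pos
    ids1 <- r$ids
  }
  ids2 <- NULL
  if (paired) {
    if (r2_mode == 0L) {
      ids2 <- ids1
    } else if (r2_mode == 1L) {
      r <- rp_varint_decode_at(payload, 1L, pos); pos <- r$pos
      col <- as.integer(r$values) + 1L
      r <- rp_unpack_strings(payload, 1L, pos); pos <- r$pos
      repl <- r$strings
      ids2 <- substitute_token(ids1, col, repl)
    } else {
      if (r2_degraded) {
        r <- rp_unpack_strings(payload, n, pos); pos <- r$pos
        ids2 <- r$strings
      } else {
        r <- decode_layout_section(payload, n, pos); pos <- r$pos
        ids2 <- r$ids
      }
    }
  }
  plus1 <- plus2 <- NULL
  if (has_plus1) {
    r <- rp_unpack_strings(payload, n, pos); pos <- r$pos
    plus1 <- r$strings
  }
  if (has_plus2) {
    r <- rp_unpack_strings(payload, n, pos); pos <- r$pos
    plus2 <- r$strings
  }
  if (pos != length(payload)) stop("corrupt meta block: trailing bytes")
  list(ids1 = ids1, ids2 = ids2, plus1 = plus1, plus2 = plus2)
}

# rebuild read2 ids by replacing token column `col` of read1's tokenization
substitute_token <- function(ids1, col, replacement) {
  tk <- rp_tokenize_chunk(ids1)
  if (!isTRUE(tk$ok)) stop("corrupt meta block: read1 identifiers not tokenizable")
  toks <- tk$tokens
  if (col > ncol(toks)) stop("corrupt meta block: substitution column out of range")
  toks[, col] <- replacement
  do.call(paste0, lapply(seq_len(ncol(toks)), function(j) toks[, j]))
}
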