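#' Open a streaming FASTQ reader
#'
#' Reads one or two FASTQ files (plain or gzip; gzip is detected
#' transparently) record by record and yields chunks cut at the first record
#' boundary where the accumulated base count (both mates) reaches
#' `chunk_kb * 1000`. Records are never split across chunks; only one
#' chunk's worth of records is held in memory at a time.
#'
#' Only Unix `'\n'` line endings are supported; CRLF input is rejected.
#' Whether each file ends with a trailing newline is tracked so that
#' decompression can reproduce it; query it with `$trailing_newline()` after
#' the reader returns `NULL`.
#'
#' @param path1 path to the (first) FASTQ file.
#' @param path2 optional path to the mate file for paired-end data.
#' @param chunk_kb chunk size in kilobases (default 1000, i.e. 1 Mb).
#' @return an environment with `$read_chunk()` (returns a chunk list or
#'   `NULL` at end of input), `$trailing_newline()`, `$close()`.
#'   A chunk is a list with elements `ids1`, `seqs1`, `plus1`, `quals1`
#'   (and the `*2` counterparts in paired mode) plus `paired` and `bases`.
#' @export
fastq_reader <- function(path1, path2 = NULL, chunk_kb = 1000) {
  stopifnot(chunk_kb >= 1)
  paired <- !is.null(path2)
  budget <- chunk_kb * 1000

  new_file_state <- function(path) {
    con <- gzfile(path, "rb")
    env <- new.env(parent = emptyenv())
    env$con <- con
    env$leftover <- raw(0)
    env$lines <- character(0)
    env$eof <- FALSE
    env$trailing_nl <- TRUE
    env$consumed <- 0L         # records handed out so far
    env$pushback <- NULL       # record columns returned by a previous pull
    env$path <- path
    env
  }

  pull_more_lines <- function(fs) {
    if (fs$eof) return(invisible(FALSE))
    buf <- readBin(fs$con, "raw", n = 4L * 1024L * 1024L)
    if (length(buf) == 0) {
      fs$eof <- TRUE
      if (length(fs$leftover) > 0) {
        # final line without a trailing newline
        if (any(fs$leftover == as.raw(13L)))
          stop("CRLF line endings are not supported; expected Unix '\\n' endings")
        fs$lines <- c(fs$lines, rawToChar(fs$leftover))
        fs$leftover <- raw(0)
        fs$trailing_nl <- FALSE
      }
      return(invisible(FALSE))
    }
    sp <- rp_split_lines(c(fs$leftover, buf))
    fs$leftover <- sp$leftover
    fs$lines <- c(fs$lines, sp$lines)
    invisible(TRUE)
  }

  # pull up to `max_records` parsed records; fewer only at end of file
  pull_records <- function(fs, max_records) {
    if (!is.null(fs$pushback)) {
      rec <- fs$pushback
      n <- length(rec$id)
      if (n > max_records) {
        keep <- seq_len(max_records)
        out <- lapply(rec, function(x) x[keep])
        fs$pushback <- lapply(rec, function(x) x[-keep])
        return(out)
      }
      fs$pushback <- NULL
      return(rec)
    }
    while (length(fs$lines) < 4L * max_records && !fs$eof) pull_more_lines(fs)
    n_lines <- length(fs$lines)
    n_rec <- min(n_lines %/% 4L, max_records)
    if (n_rec == 0 && fs$eof && n_lines > 0)
      stop(sprintf("truncated FASTQ record at end of '%s' (record %d)",
                   fs$path, fs$consumed + 1L))
    if (n_rec == 0) return(NULL)
    idx <- seq_len(4L * n_rec)
    lns <- fs$lines[idx]
    fs$lines <- fs$lines[-idx]
    id <- lns[seq(1L, by = 4L, length.out = n_rec)]
    sq <- lns[seq(2L, by = 4L, length.out = n_rec)]
    pl <- lns[seq(3L, by = 4L, length.out = n_rec)]
    ql <- lns[seq(4L, by = 4L, length.out = n_rec)]
    bad <- which(!startsWith(id, "@"))
    if (length(bad))
      stop(sprintf("malformed FASTQ record %d in '%s': identifier line does not start with '@'",
                   fs$consumed + bad[1], fs$path))
    bad <- which(!startsWith(pl, "+"))
    if (length(bad))
      stop(sprintf("malformed FASTQ record %d in '%s': third line does not start with '+'",
                   fs$consumed + bad[1], fs$path))
    bad <- which(nchar(sq, type = "bytes") != nchar(ql, type = "bytes"))
    if (length(bad))
      stop(sprintf("malformed FASTQ record %d in '%s': sequence and quality lengths differ",
                   fs$consumed + bad[1], fs$path))
    fs$consumed <- fs$consumed + n_rec
    list(id = substring(id, 2L), seq = sq, plus = substring(pl, 2L), qual = ql)
  }

  fs1 <- new_file_state(path1)
  fs2 <- if (paired) new_file_state(path2) else NULL

  read_chunk <- function() {
    batches <- list()
    total_bases <- 0
    repeat {
      b1 <- pull_records(fs1, 2048L)
      if (paired) {
        b2 <- pull_records(fs2, if (is.null(b1)) 2048L else length(b1$id))
        n1 <- if (is.null(b1)) 0L else length(b1$id)
        n2 <- if (is.null(b2)) 0L else length(b2$id)
        if (n1 != n2) {
          # one file ended early; report which
          short <- if (n1 < n2) path1 else path2
          stop(sprintf("R1/R2 record counts differ: '%s' ended early", short))
        }
        if (n1 == 0L) break
        bases <- nchar(b1$seq, type = "bytes") + nchar(b2$seq, type = "bytes")
        batches[[length(batches) + 1L]] <- list(b1 = b1, b2 = b2, bases = bases)
      } else {
        if (is.null(b1)) break
        bases <- nchar(b1$seq, type = "bytes")
        batches[[length(batches) + 1L]] <- list(b1 = b1, b2 = NULL, bases = bases)
      }
      total_bases <- total_bases + sum(bases)
      if (total_bases >= budget) break
    }
    if (length(batches) == 0) return(NULL)
    bases <- unlist(lapply(batches, `[[`, "bases"), use.names = FALSE)
    col <- function(which, field) {
      unlist(lapply(batches, function(b) b[[which]][[field]]), use.names = FALSE)
    }
    cum <- cumsum(bases)
    cut <- if (cum[length(cum)] >= budget) which(cum >= budget)[1] else length(bases)
    if (cut < length(bases)) {
      keep <- seq_len(cut)
      push <- function(fs, which) {
        rec <- list(id = col(which, "id")[-keep], seq = col(which, "seq")[-keep],
                    plus = col(which, "plus")[-keep], qual = col(which, "qual")[-keep])
        fs$pushback <- rec
      }
      chunk <- list(
        ids1 = col("b1", "id")[keep], seqs1 = col("b1", "seq")[keep],
        plus1 = col("b1", "plus")[keep], quals1 = col("b1", "qual")[keep])
      if (paired) {
        chunk$ids2 <- col("b2", "id")[keep]; chunk$seqs2 <- col("b2", "seq")[keep]
        chunk$plus2 <- col("b2", "plus")[keep]; chunk$quals2 <- col("b2", "qual")[keep]
      }
      push(fs1, "b1")
      if (paired) push(fs2, "b2")
      chunk$bases <- sum(bases[keep])
    } else {
      chunk <- list(
        ids1 = col("b1", "id"), seqs1 = col("b1", "seq"),
        plus1 = col("b1", "plus"), quals1 = col("b1", "qual"))
      if (paired) {
        chunk$ids2 <- col("b2", "id"); chunk$seqs2 <- col("b2", "seq")
        chunk$plus2 <- col("b2", "plus"); chunk$quals2 <- col("b2", "qual")
      }
      chunk$bases <- sum(bases)
    }
    chunk$paired <- paired
    chunk
  }

  env <- new.env(parent = emptyenv())
  env$read_chunk <- read_chunk
  env$trailing_newline <- function() {
    c(file1 = fs1$trailing_nl, file2 = if (paired) fs2$trailing_nl else NA)
  }
  env$close <- function() {
    close(fs1$con)
    if (paired) close(fs2$con)
  }
  env$paired <- paired
  env
}

#' Write FASTQ records to a file
#'
#' @param path output path; written as gzip when `gzip = TRUE`.
#' @param ids identifier lines without the leading `@`.
#' @param seqs,quals base and quality strings.
#' @param plus content of the `+` lines after the `+` (recycled).
#' @param gzip write gzip-compressed output.
#' @param trailing_newline whether the file ends with a final newline.
#' @return the path, invisibly.
#' @export
write_fastq <- function(path, ids, seqs, quals, plus = "",
                        gzip = FALSE, trailing_newline = TRUE) {
  con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  n <- length(ids)
  if (n > 0) {
    plus <- rep_len(plus, n)
    txt <- paste(paste0("@", ids), seqs, paste0("+", plus), quals, sep = "\n")
    writeBin(charToRaw(paste(txt, collapse = "\n")), con)
    if (trailing_newline) writeBin(charToRaw("\n"), con)
  }
  invisible(path)
}
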