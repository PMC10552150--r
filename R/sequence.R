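#' Pack A/C/G/T bases into a 2-bit stream
#'
#' Mapping A=00, C=01, G=10, T=11 with the first base in the
#' least-significant two bits of each byte; the final partial byte is
#' zero-padded. `"ACGT"` packs to `0xE4`. N bases and other characters must
#' be substituted by the caller beforehand (the chunk encoder stores them in
#' the N-position/exception side channels).
#'
#' @param bases a base string, or a character vector whose elements are
#'   packed as one concatenated stream.
#' @return raw vector of `ceiling(n/4)` bytes.
#' @export
pack_bases <- function(bases) rp_pack_bases(bases)

#' Unpack a 2-bit base stream
#'
#' @param packed raw vector from [pack_bases()].
#' @param n_bases number of bases to restore.
#' @return a single base string.
#' @export
unpack_bases <- function(packed, n_bases) rp_unpack_bases(packed, n_bases)

#' Reverse complement
#'
#' A/T and C/G swap; N maps to N. Errors on other characters.
#'
#' @param bases base string.
#' @return reverse-complemented string.
#' @export
reverse_complement <- function(bases) rp_revcomp(bases)

#' Detect the overlap between a read pair
#'
#' Searches for the placement of read2's reverse complement against read1
#' that corresponds to both reads being sequenced from one fragment.
#' Candidate offsets are scanned from the smallest merged length (largest
#' overlap) upward, seeded by exact occurrences of read1's last 16 bases in
#' the reverse complement of read2, with a full Hamming scan as fallback;
#' the first offset whose overlap is at least `min_overlap` bases with at
#' most `max_mismatch` mismatching positions is accepted. N-versus-base
#' comparisons count as mismatches; pairs containing non-ACGTN characters
#' are never merged. Because every disagreeing read2 base is recorded in
#' the descriptor, a merge is lossless whether or not the detected overlap
#' is real.
#'
#' @param read1,read2 base strings.
#' @param min_overlap minimum acceptable overlap length (default 30).
#' @param max_mismatch maximum mismatching positions in the overlap
#'   (default 4).
#' @return `NULL` if no acceptable overlap, otherwise a list with `offset`
#'   (0-based start of read2's reverse complement in the merged fragment),
#'   `merged_length` (`offset + nchar(read2)`), `mismatch_pos` (0-based
#'   positions within the overlap) and `mismatch_base` (read2's original
#'   bases at those positions, one string).
#' @export
find_overlap <- function(read1, read2, min_overlap = 30L, max_mismatch = 4L) {
  rp_find_overlap(read1, read2, as.integer(min_overlap), as.integer(max_mismatch))
}

#' Merge an overlapping read pair
#'
#' Produces read1 followed by the tail of read2's reverse complement beyond
#' the overlap; within the overlap read1's base is kept (read2's differing
#' bases live in the descriptor's mismatch list).
#'
#' @param read1,read2 base strings.
#' @param descriptor result of [find_overlap()] for this pair.
#' @return the merged base string of length `descriptor$merged_length`.
#' @export
merge_pair <- function(read1, read2, descriptor) {
  rp_merge_pair(read1, read2, descriptor$offset)
}

#' Split a merged fragment back into its read pair
#'
#' Exact inverse of [merge_pair()]: re-extracts read1 as the prefix,
#' reverse-complements the read2 window, and restores the recorded
#' mismatching bases into read2.
#'
#' @param merged merged base string.
#' @param descriptor overlap descriptor used for the merge.
#' @param len1,len2 original read lengths.
#' @return list with `read1` and `read2`.
#' @export
split_pair <- function(merged, descriptor, len1, len2) {
  rp_split_pair(merged, descriptor$offset, len1, len2,
                as.integer(descriptor$mismatch_pos), descriptor$mismatch_base)
}

#' Encode per-record lengths
#'
#' Fixed-width little-endian integers; the width is the number of bytes
#' needed for the maximum length and is stored as a leading byte.
#'
#' @param lengths non-negative integer vector.
#' @return raw payload.
#' @export
encode_lengths <- function(lengths) rp_encode_lengths(as.integer(lengths))

#' Decode per-record lengths
#'
#' @param payload raw payload from [encode_lengths()].
#' @param n number of lengths.
#' @return integer vector.
#' @export
decode_lengths <- function(payload, n) rp_decode_lengths(payload, n)
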