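#' Compress bytes into a standard xz/LZMA2 stream
#'
#' With `threads = 1` the output is a single block using the configured
#' dictionary, which gives the best ratio; with more threads the stream is
#' split into independently compressed blocks (faster, slightly larger).
#' The output is a standard xz container decodable by any conformant tool.
#'
#' @param data raw vector.
#' @param preset LZMA preset level 0-9 (default 6).
#' @param dict_mib dictionary size in MiB (default 64); larger dictionaries
#'   let the encoder find repeats across more of the stream.
#' @param threads worker threads (default 1).
#' @param block_mib block size in MiB for the multi-threaded encoder; 0
#'   uses liblzma's default (three times the dictionary).
#' @return raw vector with the xz stream.
#' @export
xz_compress <- function(data, preset = 6L, dict_mib = 64, threads = 1L,
                        block_mib = 0) {
  rp_xz_compress(data, as.integer(preset), dict_mib * 1024^2,
                 as.integer(threads), block_mib * 1024^2)
}

#' Decompress an xz stream
#'
#' @param data raw vector holding a standard xz stream.
#' @return the decompressed bytes.
#' @export
xz_decompress <- function(data) rp_xz_decompress(data)
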