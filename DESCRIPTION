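Package: rfqpack
Title: Two-Stage Lossless FASTQ Compression by Record Repacking and LZMA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Lossless compressor for single-end and paired-end FASTQ files
    built on a two-step design: records are first repacked chunk-by-chunk
    into a compact byte-aligned binary container (delta-coded identifier
    fields, 2-bit packed bases, paired-end overlap merging, run-length and
    column-based quality-score codecs), and the repacked stream is then
    compressed with LZMA into a standard xz container. Decompression
    reconstructs the original FASTQ files byte-exactly. Includes a seeded
    synthetic FASTQ generator for paired-end corpora with controllable
    insert-size distributions, quality binning schemes and error rates.
License: MIT + file LICENSE
Encoding: UTF-8
SystemRequirements: liblzma (xz-utils development headers), zlib
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
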