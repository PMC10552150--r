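---
title: "Repack-then-LZMA FASTQ compression: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repack-then-LZMA FASTQ compression: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfqpack)
```

## The model

FASTQ stores three streams per read — an identifier, a base string and a
quality string — and almost all of the file's entropy is avoidable
structure:

* identifiers within a run differ only in a few numeric coordinates, and
  a read pair's two identifiers typically differ in a single character;
* bases come from a 4-letter alphabet, and when the sequenced fragment
  ("insert") is shorter than twice the read length, the two mates of a
  pair overlap and record the same fragment bases twice;
* modern instruments bin qualities into a handful of values, one of
  which dominates.

`rfqpack` compresses in two stages. The first stage is a reversible
repacking that makes each kind of redundancy explicit and byte-aligned;
the second is off-the-shelf LZMA over the repacked stream. The division
of labour matters: repacking removes the structure that a generic
compressor models poorly (base alphabet, mate overlap, identifier
arithmetic), while LZMA removes what repacking cannot see (repeated
genomic substrings across reads at depth). Keeping the repacked stream
free of any entropy coding is deliberate — sub-byte bit packing in the
style of Huffman coding destroys the byte-level repeats that LZMA's
dictionary search needs, which is why a gzip stream of the same FASTQ
barely responds to LZMA at all (the acceptance script measures both
fractions).

Records are processed in chunks: a chunk closes at the first record
boundary where the accumulated base count (both mates) reaches
`chunk_kb * 1000`, default 1000 kb. Chunks bound memory, let the
encoder re-derive per-chunk state (quality tables, identifier layout,
N-score validity) so that losslessness never depends on the first chunk
being representative, and allow streaming: each chunk frame is emitted
as soon as it is encoded.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `chunk_kb` | 1000 | chunk size in kilobases; larger chunks amortize per-chunk headers, smaller ones localize corruption and reduce memory |
| `min_overlap` | 30 | minimum mate-overlap length (bases) accepted for merging |
| `max_mismatch` | 4 | cap on mismatching positions tolerated inside an accepted overlap |
| `preset` | 6 | LZMA preset; speed/ratio trade-off of the second stage |
| `dict_mib` | 64 | LZMA dictionary (MiB); must span the repacked stream for cross-chunk matches |
| `threads` | 1 | LZMA worker threads; more than one splits the stream into blocks and costs some ratio |

Overlap parameters tune the compression ratio only, never correctness:
every accepted merge stores the read2 bases that disagree with read1 in
a mismatch list, so a spurious merge still decodes byte-exactly.

## Numerical and representational choices

**Overlap acceptance.** Candidate offsets are scanned from the largest
overlap downward, seeded by exact occurrences of read1's last 16-mer in
the reverse complement of read2. A seed miss (a sequencing error inside
either copy of the 16-mer) would lose a few percent of true overlaps, so
a full Hamming scan over all valid offsets runs whenever no seeded
candidate is accepted; both phases accept the first offset whose
mismatch count is within budget. The budget scales with the overlap —
`min(max_mismatch, overlap/8)` — because a flat cap would let a
near-random 5-base overlap outcompete the true alignment. Merges are
only accepted when read2's reverse complement reaches read1's end
(offset + len2 ≥ len1), so the merged length is always offset + len2;
read-through-adapter geometries fall back to separate storage. Pairs
containing bytes outside ACGTN are never merged.

**N bases.** If every N in a chunk carries the file's N-score quality
and no non-N base does, N positions are not stored at all: the decoder
restores them from the quality stream (mapping merged-tail positions
back through the reverse complement). Otherwise explicit per-record
positions are stored. The consistency check runs per chunk on the
original reads, which makes the quality-based restoration provably
equivalent to the explicit list.

**Identifier fields.** Digit runs with leading zeros are delta-coded
only when all records share one width (decode re-pads); runs longer than
15 digits stay literal so that all arithmetic is exact in doubles.
Chunks whose identifiers change token shape degrade to literal storage
— correctness first, compactness second.

**Quality combos.** The column codec's `<OFFSET, LEN>` combo stores the
gap from the previous segment's *end* rather than start-to-start
distances: continuation combos for runs longer than a combo's capacity
then carry offset 0 naturally, and gaps beyond the 15-bit size-4
capacity are expressed with zero-length "skip" combos. LEN is stored
verbatim with 0 reserved for skips. The run-length codec gives the two
most frequent scores 6 length bits, ranks 3–10 get 3 bits, further
ranks encode single positions, and scores beyond the 63 representable
ranks use a two-byte escape — the one-byte combo cannot address more
than 64 ranks, so the escape is what keeps arbitrary inputs lossless.

**Degenerate inputs.** Empty files produce a header plus end marker and
decode to empty files. Zero-length reads, mixed plus-line styles
(stored literally per record), missing trailing newlines (a flag in the
end marker, recorded there because the encoder streams and cannot know
the answer before reading the whole input), and arbitrary non-ACGTN
bytes (a global exception list of position/byte pairs) all round-trip.
CRLF input is rejected outright rather than silently normalized.

## The synthetic generator

`simulate_pe_corpus()` draws fragments from a finite random genome
(default 2 Mb) rather than generating independent uniform reads: at
realistic depth, reads revisit the same genomic positions, and that
cross-read redundancy is precisely what the LZMA stage exploits in real
data. Read1 is the fragment prefix; read2 is the reverse complement of
the fragment suffix; the insert is normal (default mean 300, sd 50)
truncated below at the read length, so mates overlap exactly when the
insert is under twice the read length and the true merge offset
(insert − read length) is recorded as ground truth. Substitution errors
(default 1e-3) and N bases (default 2e-3, carrying the `#` quality) are
injected per base. Qualities follow the documented NovaSeq-like 4-bin
scheme {F: 0.85, ",": 0.08, ":": 0.05, "#": 0.02}, drawn as runs of
geometric mean length 8 so that the marginals match the scheme while the
stream has the run structure real binned qualities show.

What the generator does not emulate: position-dependent error and
quality profiles, adapter read-through, optical duplicates, platform
repeat structure, and GC bias. Passing the losslessness and recovery
tests on synthetic corpora therefore demonstrates correctness of the
transforms on realistic *structure*, but the measured compression
ratios are conservative for real deep data (real genomes are more
repetitive than a uniform random genome) and should not be read as
benchmark claims.

## Evaluation sizes

The test suite checks losslessness over 100 seeded corpora (20–150
pairs each, read lengths 36–150, varied insert, error, N and run
parameters) plus all edge cases in both containers and both endedness
modes; codec-versus-oracle agreement on 10,000 fuzzed base strings and
10,000 quality streams (1–70 bins, lengths to 5,000); offset recovery
on 10,000 simulated pairs (150 bp reads, insert N(250, 30), error
1e-3), requiring ≥ 99% exact recovery among pairs with true overlap
≥ 30; and ratio orderings on a 200,000-pair corpus (repacked < gzip;
LZMA shrinks the repacked stream ≥ 30% while shrinking a gzip stream
< 5%). The single-thread versus multi-thread LZMA ordering is measured
on a ≥ 50 MB repacked fixture with a fast preset and an 8 MiB block
size, which makes the block-splitting cost visible at any preset.

## Known limitations

* The container is this package's own format; it is not bit-compatible
  with any other tool's `.rfq` files.
* Only 4-line FASTQ with Unix line endings is supported (no wrapped
  sequences, no color space).
* The LZMA stage holds the repacked stream in memory; repacking itself
  is chunk-streamed. For multi-gigabyte inputs a streaming hand-off to
  the encoder would be the next step.
* Long-read data (much longer, noisier reads; no mate structure) gets
  no benefit from overlap merging and only modest benefit from 2-bit
  packing relative to its error structure.
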