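# The .rfq container, format version 1

All multi-byte integers are little-endian. "varint" is an LEB128-style
variable integer: 7 data bits per byte, high bit set on continuation
bytes. "zigzag" maps a signed integer n to the unsigned `2|n| - (n < 0)`
before varint coding. Every element is byte-aligned — no value crosses a
byte boundary except inside its own multi-byte field — so the repacked
stream remains compressible by LZMA's byte-oriented dictionary search.

A `.rfq.xz` file is a standard xz/LZMA2 stream whose decompressed content
is a `.rfq` stream.

## File layout

```
"RFQ2"            4 magic bytes
u8                format version (1)
header frame
chunk frame *     zero or more
end frame
```

### Frames

```
u8   type         2 = header, 1 = chunk, 0 = end marker
u32  length       payload byte count
     payload
u32  crc32        CRC32 of the payload (zlib polynomial)
```

### Header payload (type 2)

Built from the first chunk; the quality table and N-score are hints — each
chunk re-derives its own quality codec state.

```
u8      flags       bit0 paired-end, bit1 constant read length,
                    bit2 N-score present
u8      dialect     0 generic, 1 Illumina Casava 1.8
u8      major quality character
u8      N-score character          (iff flags bit2)
varint  read length                (iff flags bit1)
varint  quality table entry count
u8 *    quality characters, ascending
varint* their occurrence counts
```

### Chunk payload (type 1)

```
varint  record count n             (record = read pair in paired mode)
varint  base count                 (original bases, both mates)
u8      chunk flags                bit0 N-elision active
                                   bit1 constant read length
                                   bit2 meta degraded (informational)
                                   bit3 quality strategy (0 column, 1 rle)
                                   bits4-5 plus-line style file1
                                   bits6-7 plus-line style file2
u32     meta block length, meta block
u32     sequence block length, sequence block
        quality block              (to end of payload)
```

Plus-line style: 0 = bare `+`, 1 = `+` repeats the identifier,
2 = stored literally per record in the meta block.

#### Meta block

```
u8   mflags      bit0 read1 layout degraded
                 bits1-2 read2 mode: 0 identical to read1,
                         1 single-token substitution, 2 independent
                 bit3 read2 layout degraded
                 bit4 plus-line literals for file1 present
                 bit5 plus-line literals for file2 present
read1 section:
  degraded:      n x (varint length + bytes)      raw identifiers
  otherwise:     layout section (below)
read2 section (paired only):
  mode 0:        nothing
  mode 1:        varint token index + (varint length + bytes) replacement
  mode 2:        layout section, or raw identifiers if degraded
plus-line literal sections (if flagged): n x (varint length + bytes)
```

Layout section — identifiers are tokenized into maximal digit / non-digit
runs; all identifiers of the chunk share one token shape:

```
varint  token count k
k x:    u8 kind: 0 CONSTANT  + (varint length + bytes)
                 1 NUMERIC   + u8 zero-pad width (0 = none) + varint baseline
                 2 LITERAL
payloads, in token order:
        NUMERIC: (n-1) zigzag varints of successive differences
        LITERAL: n x (varint length + bytes)
```

#### Sequence block

One stored sequence unit per merged pair (read1 followed by the tail of
read2's reverse complement), two units for separate pairs, one for
single-end. N bases and non-ACGTN bytes are packed as `A` placeholders
and restored from the side channels below.

```
varint  total stored bases
paired only:
  pair-mode bitfield, ceil(n/8) bytes, LSB-first; bit set = merged
  per merged pair, in record order:
    varint offset                  start of reverse-complemented read2
    varint mismatch count m        within the overlap
    m x (varint position delta, u8 read2 original base)
                                   positions 0-based in the overlap,
                                   first absolute then differences
unless constant-length flag:
  u8 width (bytes needed for the maximum length)
  per record: read1 length [, read2 length], width-byte integers
unless N-elision flag:
  per record: varint count, count varints of N positions
              (pair-local stored-base coordinates; first absolute,
              then differences)
varint  exception count
per exception: varint global stored-position delta, u8 literal byte
packed 2-bit bases, ceil(total/4) bytes
        A=00 C=01 G=10 T=11, first base in the least-significant
        two bits of each byte, final byte zero-padded
```

With N-elision active, the decoder restores an N wherever the quality
character at the corresponding original-read position equals the N-score
(for a merged unit, tail positions map back through the reverse
complement).

#### Quality block

```
varint  stream length              concatenated qualities, read1 then
                                   read2 per record
column strategy (chunk flag bit3 = 0; < 64 distinct scores):
  u8 major quality character
  varint score count (major excluded)
  per score, ascending: u8 score, varint combo count, combos
rle strategy (bit3 = 1):
  varint table size, table bytes in descending-frequency order
  combos to end of block
```

Column `<OFFSET, LEN>` combo, 1-4 bytes, big-endian within the combo:

```
bits 7-6 of first byte: size tag 00/01/10/11 = 1/2/3/4 bytes
remaining bits split evenly: offset, then length
  size 1: 3+3 bits, size 2: 7+7, size 3: 11+11, size 4: 15+15
```

OFFSET is the gap from the previous segment's end (0 before the first
segment). LEN is stored verbatim; LEN = 0 is a skip combo that advances
the position without emitting a run (used for gaps beyond 15 bits). Runs
longer than a combo's capacity continue with offset-0 combos. Positions
not covered by any stored segment decode as the major score.

RLE `<SCORE, LEN>` combo, one byte, scores ranked by descending chunk
frequency (rank 1 = most frequent):

```
0 r LLLLLL    ranks 1-2, run of LLLLLL+1 (1..64)
1 0 SSS LLL   ranks 3-10, run of LLL+1 (1..8)
1 1 SSSSSS    ranks 11-73, run of exactly 1 (0xFF excluded)
0xFF + u8     escape: literal score byte, run of exactly 1
```

### End frame payload (type 0)

```
u8      flags     bit0 file1 ends with a newline, bit1 file2 does
varint  total record count
u32     running CRC32 over all chunk payloads, in order
```
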