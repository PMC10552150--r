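// Quality-score codecs over a chunk's concatenated quality stream.
//
// COLUMN codec (used when the chunk has < 64 distinct quality characters):
// per non-major score, maximal runs are stored as <OFFSET, LEN> combos of
// 1..4 whole bytes. The top two bits of the first byte are a size tag
// (00/01/10/11 = 1/2/3/4 bytes); the remaining bits split evenly into an
// offset field and a length field (3+3, 7+7, 11+11, 15+15 bits). OFFSET is
// the gap from the previous segment's end (0 for the first segment); LEN is
// stored verbatim, with LEN == 0 reserved as a "skip" combo that advances
// the position without emitting a run (the escape for gaps beyond the
// 15-bit capacity). Long runs split into continuation combos with offset 0.
// The major score is never stored: the decoder fills gaps with it.
//
// RLE codec (>= 64 distinct characters): runs of all scores interleaved,
// one byte per combo. Scores ranked by descending frequency get shorter
// codes and therefore more length bits:
//   ranks 1-2 : 0b0r LLLLLL  run of 1..64
//   ranks 3-10: 0b10 SSS LLL run of 1..8
//   ranks 11-73: 0b11 SSSSSS run of exactly 1 (0xFF excluded)
//   beyond    : 0xFF escape + literal score byte, run of exactly 1
#include "bytestream.h"

using namespace Rcpp;

static const int OFF_BITS[4] = {3, 7, 11, 15};
static const int LEN_BITS[4] = {3, 7, 11, 15};

static void emit_combo(ByteWriter& w, int size, long off, long len) {
  // size in 1..4; big-endian within the combo so the tag leads
  uint32_t v = ((uint32_t)(size - 1) << (OFF_BITS[size - 1] + LEN_BITS[size - 1])) |
               ((uint32_t)off << LEN_BITS[size - 1]) | (uint32_t)len;
  for (int b = size - 1; b >= 0; b--) w.u8((uint8_t)((v >> (8 * b)) & 0xff));
}

static void emit_segment(ByteWriter& w, long gap, long len, int& count) {
  const long offcap[4] = {7, 127, 2047, 32767};
  const long lencap[4] = {7, 127, 2047, 32767};
  while (gap > offcap[3]) {
    emit_combo(w, 4, offcap[3], 0);  // skip combo
    gap -= offcap[3];
    count++;
  }
  while (len > 0) {
    int s = 0;
    while (gap > offcap[s]) s++;
    while (s < 3 && len > lencap[s]) s++;
    long l = len > lencap[s] ? lencap[s] : len;
    emit_combo(w, s + 1, gap, l);
    count++;
    len -= l;
    gap = 0;
  }
}

// Maximal runs of the stream, in stream order.
// [[Rcpp::export(rng = false)]]
List rp_segment_stream(std::string q) {
  std::vector<double> pos, len;
  std::string score;
  size_t n = q.size(), i = 0;
  while (i < n) {
    size_t j = i;
    while (j < n && q[j] == q[i]) j++;
    pos.push_back((double)i);
    len.push_back((double)(j - i));
    score.push_back(q[i]);
    i = j;
  }
  CharacterVector sc(score.size());
  for (size_t k = 0; k < score.size(); k++) sc[k] = std::string(1, score[k]);
  return List::create(_["score"] = sc,
                      _["pos"] = NumericVector(pos.begin(), pos.end()),
                      _["len"] = NumericVector(len.begin(), len.end()));
}

// [[Rcpp::export(rng = false)]]
RawVector rp_encode_column(std::string q, int major) {
  // per-score segment lists (positions ascending by construction)
  std::vector<std::vector<std::pair<double, double>>> segs(256);
  size_t n = q.size(), i = 0;
  while (i < n) {
    size_t j = i;
    while (j < n && q[j] == q[i]) j++;
    if ((uint8_t)q[i] != (uint8_t)major)
      segs[(uint8_t)q[i]].push_back(std::make_pair((double)i, (double)(j - i)));
    i = j;
  }
  int nscores = 0;
  for (int c = 0; c < 256; c++)
    if (!segs[c].empty()) nscores++;
  ByteWriter w;
  w.varint((uint64_t)nscores);
  for (int c = 0; c < 256; c++) {
    if (segs[c].empty()) continue;
    ByteWriter combos;
    int count = 0;
    double prev_end = 0;
    for (auto& s : segs[c]) {
      emit_segment(combos, (long)(s.first - prev_end), (long)s.second, count);
      prev_end = s.first + s.second;
    }
    w.u8((uint8_t)c);
    w.varint((uint64_t)count);
    w.bytes(combos.buf.data(), combos.buf.size());
  }
  return w.raw();
}

// [[Rcpp::export(rng = false)]]
String rp_decode_column(RawVector payload, double stream_length, int major) {
  size_t n = (size_t)stream_length;
  std::string out(n, (char)major);
  ByteReader r(payload);
  int nscores = (int)r.varint();
  for (int s = 0; s < nscores; s++) {
    uint8_t score = r.u8();
    uint64_t count = r.varint();
    size_t pos = 0;
    for (uint64_t k = 0; k < count; k++) {
      uint8_t b0 = r.u8();
      int size = (b0 >> 6) + 1;
      uint32_t v = b0 & 0x3f;
      for (int b = 1; b < size; b++) v = (v << 8) | r.u8();
      uint32_t off = v >> LEN_BITS[size - 1];
      uint32_t len = v & ((1u << LEN_BITS[size - 1]) - 1);
      pos += off;
      if (len > 0) {
        if (pos + len > n) stop("corrupt quality block: segment beyond stream end");
        for (uint32_t t = 0; t < len; t++) {
          if (out[pos + t] != (char)major)
            stop("corrupt quality block: overlapping segments");
          out[pos + t] = (char)score;
        }
        pos += len;
      }
    }
  }
  if (!r.done()) stop("corrupt quality block: trailing bytes");
  return String(out);
}

// [[Rcpp::export(rng = false)]]
RawVector rp_encode_rle(std::string q, std::string score_table) {
  int rank[256];
  for (int i = 0; i < 256; i++) rank[i] = -1;
  for (size_t i = 0; i < score_table.size(); i++) rank[(uint8_t)score_table[i]] = (int)i;
  ByteWriter w;
  size_t n = q.size(), i = 0;
  while (i < n) {
    size_t j = i;
    while (j < n && q[j] == q[i]) j++;
    long len = (long)(j - i);
    uint8_t c = (uint8_t)q[i];
    int rk = rank[c];
    if (rk < 0) stop("encode_rle: score not in table");
    if (rk < 2) {
      while (len > 0) {
        long l = len > 64 ? 64 : len;
        w.u8((uint8_t)((rk << 6) | (l - 1)));
        len -= l;
      }
    } else if (rk < 10) {
      while (len > 0) {
        long l = len > 8 ? 8 : len;
        w.u8((uint8_t)(0x80 | ((rk - 2) << 3) | (l - 1)));
        len -= l;
      }
    } else if (rk < 73) {
      for (long t = 0; t < len; t++) w.u8((uint8_t)(0xc0 | (rk - 10)));
    } else {
      for (long t = 0; t < len; t++) {
        w.u8(0xff);
        w.u8(c);
      }
    }
    i = j;
  }
  return w.raw();
}

// [[Rcpp::export(rng = false)]]
String rp_decode_rle(RawVector payload, double stream_length,
                     std::string score_table) {
  size_t n = (size_t)stream_length;
  std::string out;
  out.reserve(n);
  ByteReader r(payload);
  while (out.size() < n) {
    uint8_t b = r.u8();
    uint8_t score;
    long len;
    if (b < 0x80) {
      int rk = b >> 6;
      if ((size_t)rk >= score_table.size()) stop("corrupt quality block: rank out of table");
      score = (uint8_t)score_table[rk];
      len = (b & 0x3f) + 1;
    } else if (b < 0xc0) {
      int rk = ((b >> 3) & 7) + 2;
      if ((size_t)rk >= score_table.size()) stop("corrupt quality block: rank out of table");
      score = (uint8_t)score_table[rk];
      len = (b & 7) + 1;
    } else if (b == 0xff) {
      score = r.u8();
      len = 1;
    } else {
      int rk = (b & 0x3f) + 10;
      if ((size_t)rk >= score_table.size()) stop("corrupt quality block: rank out of table");
      score = (uint8_t)score_table[rk];
      len = 1;
    }
    if (out.size() + len > n) stop("corrupt quality block: run beyond stream end");
    out.append((size_t)len, (char)score);
  }
  if (!r.done()) stop("corrupt quality block: trailing bytes");
  return String(out);
}

// Distinct quality characters and their counts for one stream.
// [[Rcpp::export(rng = false)]]
List rp_qual_table(std::string q) {
  std::vector<double> tab(256, 0.0);
  for (size_t i = 0; i < q.size(); i++) tab[(uint8_t)q[i]] += 1;
  std::string chars;
  std::vector<double> counts;
  for (int c = 0; c < 256; c++)
    if (tab[c] > 0) {
      chars.push_back((char)c);
      counts.push_back(tab[c]);
    }
  CharacterVector ch(chars.size());
  for (size_t i = 0; i < chars.size(); i++) ch[i] = std::string(1, chars[i]);
  return List::create(_["score"] = ch,
                      _["count"] = NumericVector(counts.begin(), counts.end()));
}
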