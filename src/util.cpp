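// Low-level helpers: varint/zigzag series, length-prefixed string packing,
// CRC32 (zlib), newline splitting for the streaming FASTQ reader, and
// per-chunk base/quality tallies.
#include "bytestream.h"
#include <zlib.h>

using namespace Rcpp;

// [[Rcpp::export(rng = false)]]
RawVector rp_varint_encode(NumericVector values) {
  ByteWriter w;
  for (double v : values) {
    if (v < 0 || v != v) stop("varint values must be non-negative");
    w.varint((uint64_t)v);
  }
  return w.raw();
}

// [[Rcpp::export(rng = false)]]
NumericVector rp_varint_decode(RawVector payload, int n) {
  ByteReader r(payload);
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = (double)r.varint();
  return out;
}

// [[Rcpp::export(rng = false)]]
List rp_varint_decode_at(RawVector payload, int n, double at) {
  ByteReader r(payload);
  r.pos = (size_t)at;
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = (double)r.varint();
  return List::create(_["values"] = out, _["pos"] = (double)r.pos);
}

// [[Rcpp::export(rng = false)]]
RawVector rp_zigzag_encode(NumericVector values) {
  ByteWriter w;
  for (double v : values) w.zigzag((int64_t)v);
  return w.raw();
}

// [[Rcpp::export(rng = false)]]
NumericVector rp_zigzag_decode(RawVector payload, int n) {
  ByteReader r(payload);
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = (double)r.zigzag();
  return out;
}

// [[Rcpp::export(rng = false)]]
List rp_zigzag_decode_at(RawVector payload, int n, double at) {
  ByteReader r(payload);
  r.pos = (size_t)at;
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = (double)r.zigzag();
  return List::create(_["values"] = out, _["pos"] = (double)r.pos);
}

// [[Rcpp::export(rng = false)]]
RawVector rp_pack_strings(CharacterVector x) {
  ByteWriter w;
  for (int i = 0; i < x.size(); i++) {
    const char* s = CHAR(STRING_ELT(x, i));
    w.str(s, strlen(s));
  }
  return w.raw();
}

// [[Rcpp::export(rng = false)]]
List rp_unpack_strings(RawVector payload, int n, double at) {
  ByteReader r(payload);
  r.pos = (size_t)at;
  CharacterVector out(n);
  for (int i = 0; i < n; i++) {
    std::string s = r.str();
    out[i] = s;
  }
  return List::create(_["strings"] = out, _["pos"] = (double)r.pos);
}

// [[Rcpp::export(rng = false)]]
double rp_crc32(RawVector data, double init) {
  uLong crc = (uLong)init;
  if (data.size() > 0) crc = crc32(crc, (const Bytef*)RAW(data), (uInt)data.size());
  return (double)crc;
}

// [[Rcpp::export(rng = false)]]
RawVector rp_u32_raw(double v) {
  ByteWriter w;
  w.u32((uint32_t)v);
  return w.raw();
}

// [[Rcpp::export(rng = false)]]
double rp_raw_u32(RawVector r, double at) {
  ByteReader rd(r);
  rd.pos = (size_t)at;
  return (double)rd.u32();
}

// Split a raw buffer into '\n'-terminated lines. Bytes after the final
// newline are returned as leftover for the caller to prepend to the next
// read. '\r' immediately before '\n' is rejected (CRLF input unsupported).
// [[Rcpp::export(rng = false)]]
List rp_split_lines(RawVector buf) {
  const uint8_t* p = buf.size() ? (const uint8_t*)RAW(buf) : nullptr;
  size_t n = buf.size();
  std::vector<std::pair<size_t, size_t>> spans;
  size_t start = 0;
  for (size_t i = 0; i < n; i++) {
    if (p[i] == '\n') {
      if (i > start && p[i - 1] == '\r')
        stop("CRLF line endings are not supported; expected Unix '\\n' endings");
      spans.push_back(std::make_pair(start, i - start));
      start = i + 1;
    }
  }
  CharacterVector lines(spans.size());
  for (size_t i = 0; i < spans.size(); i++) {
    lines[i] = std::string((const char*)p + spans[i].first, spans[i].second);
  }
  RawVector leftover(n - start);
  for (size_t i = start; i < n; i++) leftover[i - start] = p[i];
  return List::create(_["lines"] = lines, _["leftover"] = leftover);
}

// Concatenate read1[/read2] qualities record by record into one stream.
// [[Rcpp::export(rng = false)]]
String rp_concat_interleave(CharacterVector a, Nullable<CharacterVector> b) {
  size_t total = 0;
  int n = a.size();
  CharacterVector bb;
  bool paired = b.isNotNull();
  if (paired) {
    bb = b.get();
    if (bb.size() != n) stop("length mismatch");
  }
  for (int i = 0; i < n; i++) {
    total += strlen(CHAR(STRING_ELT(a, i)));
    if (paired) total += strlen(CHAR(STRING_ELT(bb, i)));
  }
  std::string out;
  out.reserve(total);
  for (int i = 0; i < n; i++) {
    out.append(CHAR(STRING_ELT(a, i)));
    if (paired) out.append(CHAR(STRING_ELT(bb, i)));
  }
  return String(out);
}

// Tally quality characters overall and over N bases, in one pass over the
// chunk. Used for header generation and the per-chunk N-score consistency
// check: N elision is valid iff all N bases share one quality character and
// no non-N base carries it.
// [[Rcpp::export(rng = false)]]
List rp_base_qual_stats(CharacterVector seqs, CharacterVector quals) {
  if (seqs.size() != quals.size()) stop("length mismatch");
  std::vector<double> qtab(256, 0.0), ntab(256, 0.0);
  double n_bases = 0;
  for (int i = 0; i < seqs.size(); i++) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    const char* q = CHAR(STRING_ELT(quals, i));
    size_t ls = strlen(s), lq = strlen(q);
    if (ls != lq) stop("record %d: sequence and quality lengths differ", i + 1);
    for (size_t j = 0; j < ls; j++) {
      qtab[(uint8_t)q[j]] += 1;
      if (s[j] == 'N') {
        ntab[(uint8_t)q[j]] += 1;
        n_bases += 1;
      }
    }
  }
  return List::create(_["qtable"] = NumericVector(qtab.begin(), qtab.end()),
                      _["ntable"] = NumericVector(ntab.begin(), ntab.end()),
                      _["n_bases"] = n_bases);
}

static void tokenize_one(const char* s, size_t len,
                         std::vector<std::pair<size_t, size_t>>& spans,
                         std::vector<int>& digit) {
  spans.clear();
  digit.clear();
  size_t i = 0;
  while (i < len) {
    bool d = s[i] >= '0' && s[i] <= '9';
    size_t j = i;
    while (j < len && ((s[j] >= '0' && s[j] <= '9') == d)) j++;
    spans.push_back(std::make_pair(i, j - i));
    digit.push_back(d ? 1 : 0);
    i = j;
  }
}

// Tokenize one identifier into maximal digit / non-digit runs.
// [[Rcpp::export(rng = false)]]
List rp_tokenize_id(std::string id) {
  std::vector<std::pair<size_t, size_t>> spans;
  std::vector<int> digit;
  tokenize_one(id.c_str(), id.size(), spans, digit);
  CharacterVector toks(spans.size());
  LogicalVector dig(spans.size());
  for (size_t i = 0; i < spans.size(); i++) {
    toks[i] = id.substr(spans[i].first, spans[i].second);
    dig[i] = digit[i] == 1;
  }
  return List::create(_["tokens"] = toks, _["digit"] = dig);
}

// Tokenize all identifiers of a chunk against the shape of the first one.
// Returns ok = FALSE if any identifier has a different token count or
// digit/text pattern (the caller then degrades to literal storage).
// [[Rcpp::export(rng = false)]]
List rp_tokenize_chunk(CharacterVector ids) {
  int n = ids.size();
  if (n == 0) stop("empty identifier set");
  std::vector<std::pair<size_t, size_t>> spans;
  std::vector<int> digit, digit0;
  const char* s0 = CHAR(STRING_ELT(ids, 0));
  tokenize_one(s0, strlen(s0), spans, digit0);
  int k = (int)spans.size();
  CharacterMatrix toks(n, k);
  for (int i = 0; i < n; i++) {
    const char* s = CHAR(STRING_ELT(ids, i));
    tokenize_one(s, strlen(s), spans, digit);
    if ((int)spans.size() != k || digit != digit0)
      return List::create(_["ok"] = false);
    for (int j = 0; j < k; j++)
      toks(i, j) = std::string(s + spans[j].first, spans[j].second);
  }
  LogicalVector dig(k);
  for (int j = 0; j < k; j++) dig[j] = digit0[j] == 1;
  return List::create(_["ok"] = true, _["tokens"] = toks, _["digit"] = dig);
}
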