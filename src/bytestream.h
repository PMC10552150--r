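// Byte-aligned little-endian primitives shared by the block codecs.
// Varints are LEB128-style: 7 data bits per byte, high bit = continuation.
// Zigzag maps signed n to 2|n| - (n<0) so small magnitudes stay small.
#ifndef RFQPACK_BYTESTREAM_H
#define RFQPACK_BYTESTREAM_H

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

struct ByteWriter {
  std::vector<uint8_t> buf;

  void u8(uint8_t v) { buf.push_back(v); }
  void u32(uint32_t v) {
    for (int i = 0; i < 4; i++) buf.push_back((uint8_t)((v >> (8 * i)) & 0xff));
  }
  void fixed(uint64_t v, int width) {
    for (int i = 0; i < width; i++) buf.push_back((uint8_t)((v >> (8 * i)) & 0xff));
  }
  void varint(uint64_t v) {
    while (v >= 0x80) {
      buf.push_back((uint8_t)(v | 0x80));
      v >>= 7;
    }
    buf.push_back((uint8_t)v);
  }
  void zigzag(int64_t v) {
    varint(((uint64_t)v << 1) ^ (uint64_t)(v >> 63));
  }
  void bytes(const uint8_t* p, size_t n) { buf.insert(buf.end(), p, p + n); }
  void str(const char* s, size_t n) {
    varint(n);
    bytes((const uint8_t*)s, n);
  }
  Rcpp::RawVector raw() const {
    Rcpp::RawVector r(buf.size());
    if (!buf.empty()) std::copy(buf.begin(), buf.end(), r.begin());
    return r;
  }
};

struct ByteReader {
  const uint8_t* p;
  size_t n;
  size_t pos;

  ByteReader(const uint8_t* p_, size_t n_) : p(p_), n(n_), pos(0) {}
  explicit ByteReader(const Rcpp::RawVector& r)
      : p(r.size() ? (const uint8_t*)RAW(r) : nullptr), n(r.size()), pos(0) {}

  void need(size_t k) {
    if (pos + k > n) Rcpp::stop("corrupt block: payload exhausted");
  }
  uint8_t u8() { need(1); return p[pos++]; }
  uint32_t u32() {
    need(4);
    uint32_t v = 0;
    for (int i = 0; i < 4; i++) v |= ((uint32_t)p[pos++]) << (8 * i);
    return v;
  }
  uint64_t fixed(int width) {
    need(width);
    uint64_t v = 0;
    for (int i = 0; i < width; i++) v |= ((uint64_t)p[pos++]) << (8 * i);
    return v;
  }
  uint64_t varint() {
    uint64_t v = 0;
    int shift = 0;
    for (;;) {
      uint8_t b = u8();
      v |= ((uint64_t)(b & 0x7f)) << shift;
      if (!(b & 0x80)) break;
      shift += 7;
      if (shift > 63) Rcpp::stop("corrupt block: varint overflow");
    }
    return v;
  }
  int64_t zigzag() {
    uint64_t u = varint();
    return (int64_t)(u >> 1) ^ -(int64_t)(u & 1);
  }
  std::string str() {
    uint64_t l = varint();
    need(l);
    std::string s((const char*)p + pos, (size_t)l);
    pos += (size_t)l;
    return s;
  }
  bool done() const { return pos == n; }
};

#endif
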