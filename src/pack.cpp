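// 2-bit base packing. Mapping A=00, C=01, G=10, T=11; the first base of
// each group of four sits in the least-significant two bits of the byte,
// so "ACGT" packs to 0b11100100 = 0xE4. The final partial byte is
// zero-padded.
#include "bytestream.h"

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static const char CODE_BASE[4] = {'A', 'C', 'G', 'T'};

// [[Rcpp::export(rng = false)]]
RawVector rp_pack_bases(CharacterVector seqs) {
  size_t total = 0;
  for (int i = 0; i < seqs.size(); i++) total += strlen(CHAR(STRING_ELT(seqs, i)));
  RawVector out((total + 3) / 4);
  uint8_t* o = out.size() ? (uint8_t*)RAW(out) : nullptr;
  if (o) memset(o, 0, out.size());
  size_t pos = 0;
  for (int i = 0; i < seqs.size(); i++) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    for (; *s; s++, pos++) {
      int c = base_code(*s);
      if (c < 0)
        stop("pack_bases: non-ACGT character '%c' (caller must substitute N/exceptions first)", *s);
      o[pos >> 2] |= (uint8_t)(c << ((pos & 3) * 2));
    }
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
String rp_unpack_bases(RawVector packed, double n_bases) {
  size_t n = (size_t)n_bases;
  if ((size_t)packed.size() < (n + 3) / 4) stop("packed stream too short for %.0f bases", n_bases);
  const uint8_t* p = packed.size() ? (const uint8_t*)RAW(packed) : nullptr;
  std::string out(n, 'A');
  for (size_t i = 0; i < n; i++)
    out[i] = CODE_BASE[(p[i >> 2] >> ((i & 3) * 2)) & 3];
  return String(out);
}
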