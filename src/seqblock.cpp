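// Chunk sequence block.
//
// Layout (see FORMAT.md):
//   varint  total stored bases
//   [PE]    pair-mode bitfield, ceil(n/8) bytes, LSB-first; bit set = merged
//   [PE]    per merged pair: varint offset, varint n_mm,
//           n_mm x (varint position delta, u8 read2 original base)
//   [!const] u8 width, then per record len1 [+ len2] as width-byte LE ints
//   [!Nelide] per pair: varint count, positions (first absolute, then deltas)
//             in pair-local stored-base coordinates
//   varint exception count; per exception: varint global-position delta,
//           u8 literal byte (non-ACGTN characters)
//   packed 2-bit base stream, ceil(total/4) bytes
//
// Stored sequences: one unit per merged pair (read1 + tail of revcomp
// read2), two units for separate pairs, one for single-end. N bases and
// exception bytes are packed as 'A' placeholders and restored on decode --
// N either from explicit positions or, when the chunk's N-elision flag is
// active, from quality characters equal to the N-score.
#include "bytestream.h"

using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

static inline int base_code_or(char c, int fallback) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return fallback;
  }
}

// [[Rcpp::export(rng = false)]]
RawVector rp_encode_lengths(IntegerVector lengths) {
  int64_t mx = 0;
  for (int v : lengths) {
    if (v < 0) stop("negative length");
    if (v > mx) mx = v;
  }
  int width = 1;
  while (mx >= ((int64_t)1 << (8 * width))) width++;
  ByteWriter w;
  w.u8((uint8_t)width);
  for (int v : lengths) w.fixed((uint64_t)v, width);
  return w.raw();
}

// [[Rcpp::export(rng = false)]]
IntegerVector rp_decode_lengths(RawVector payload, int n) {
  ByteReader r(payload);
  int width = r.u8();
  if (width < 1 || width > 4) stop("corrupt length payload: bad width");
  IntegerVector out(n);
  for (int i = 0; i < n; i++) out[i] = (int)r.fixed(width);
  return out;
}

struct StoredScan {
  std::string stored;              // concatenated stored units, placeholders applied
  std::vector<std::vector<int>> npos;   // per pair, pair-local N positions
  std::vector<double> xpos;        // global exception positions
  std::string xbyte;               // exception bytes
};

static void scan_unit(const char* s, StoredScan& sc, int pair_local_base) {
  // append s to stored, recording N positions and exceptions
  for (int j = 0; s[j]; j++) {
    char c = s[j];
    if (c == 'A' || c == 'C' || c == 'G' || c == 'T') {
      sc.stored.push_back(c);
    } else if (c == 'N') {
      sc.npos.back().push_back(pair_local_base + j);
      sc.stored.push_back('A');
    } else {
      sc.xpos.push_back((double)sc.stored.size());
      sc.xbyte.push_back(c);
      sc.stored.push_back('A');
    }
  }
}

// [[Rcpp::export(rng = false)]]
List rp_encode_sequence_block(CharacterVector seqs1,
                              Nullable<CharacterVector> seqs2_,
                              Nullable<IntegerVector> offsets_, List mm_pos,
                              CharacterVector mm_base, bool n_elision,
                              bool const_len, int read_len) {
  int n = seqs1.size();
  bool paired = seqs2_.isNotNull();
  CharacterVector seqs2;
  IntegerVector offsets;
  if (paired) {
    seqs2 = seqs2_.get();
    offsets = offsets_.get();
    if (seqs2.size() != n || offsets.size() != n) stop("length mismatch");
  }

  StoredScan sc;
  std::vector<int> len1(n), len2(n, 0);
  size_t total_guess = 0;
  for (int i = 0; i < n; i++) {
    total_guess += strlen(CHAR(STRING_ELT(seqs1, i)));
    if (paired) total_guess += strlen(CHAR(STRING_ELT(seqs2, i)));
  }
  sc.stored.reserve(total_guess);

  for (int i = 0; i < n; i++) {
    const char* s1 = CHAR(STRING_ELT(seqs1, i));
    len1[i] = (int)strlen(s1);
    sc.npos.push_back(std::vector<int>());
    if (paired) {
      const char* s2 = CHAR(STRING_ELT(seqs2, i));
      len2[i] = (int)strlen(s2);
      if (offsets[i] >= 0) {
        // merged: read1 + tail of revcomp(read2); reads are pure ACGTN here
        int off = offsets[i];
        if (off + len2[i] < len1[i]) stop("encode: bad overlap offset");
        std::string unit(s1);
        for (int j = len1[i]; j < off + len2[i]; j++)
          unit.push_back(comp(s2[len2[i] - 1 - (j - off)]));
        scan_unit(unit.c_str(), sc, 0);
      } else {
        scan_unit(s1, sc, 0);
        scan_unit(s2, sc, len1[i]);
      }
    } else {
      scan_unit(s1, sc, 0);
    }
  }

  ByteWriter w;
  size_t total = sc.stored.size();
  w.varint(total);
  if (paired) {
    int nb = (n + 7) / 8;
    std::vector<uint8_t> bits(nb, 0);
    for (int i = 0; i < n; i++)
      if (offsets[i] >= 0) bits[i >> 3] |= (uint8_t)(1 << (i & 7));
    w.bytes(bits.data(), nb);
    for (int i = 0; i < n; i++) {
      if (offsets[i] < 0) continue;
      w.varint((uint64_t)offsets[i]);
      IntegerVector mp = mm_pos[i];
      const char* mb = CHAR(STRING_ELT(mm_base, i));
      if ((int)strlen(mb) != mp.size()) stop("encode: mismatch list lengths differ");
      w.varint((uint64_t)mp.size());
      int prev = 0;
      for (int j = 0; j < mp.size(); j++) {
        int d = j == 0 ? mp[j] : mp[j] - prev;
        if (d < 0 || (j > 0 && d == 0)) stop("encode: mismatch positions not increasing");
        w.varint((uint64_t)d);
        w.u8((uint8_t)mb[j]);
        prev = mp[j];
      }
    }
  }
  if (!const_len) {
    int64_t mx = 0;
    for (int i = 0; i < n; i++) {
      if (len1[i] > mx) mx = len1[i];
      if (len2[i] > mx) mx = len2[i];
    }
    int width = 1;
    while (mx >= ((int64_t)1 << (8 * width))) width++;
    w.u8((uint8_t)width);
    for (int i = 0; i < n; i++) {
      w.fixed((uint64_t)len1[i], width);
      if (paired) w.fixed((uint64_t)len2[i], width);
    }
  }
  if (!n_elision) {
    for (int i = 0; i < n; i++) {
      const std::vector<int>& np = sc.npos[i];
      w.varint((uint64_t)np.size());
      int prev = 0;
      for (size_t j = 0; j < np.size(); j++) {
        w.varint((uint64_t)(j == 0 ? np[j] : np[j] - prev));
        prev = np[j];
      }
    }
  }
  w.varint((uint64_t)sc.xpos.size());
  double xprev = 0;
  for (size_t j = 0; j < sc.xpos.size(); j++) {
    w.varint((uint64_t)(j == 0 ? sc.xpos[j] : sc.xpos[j] - xprev));
    w.u8((uint8_t)sc.xbyte[j]);
    xprev = sc.xpos[j];
  }
  // 2-bit pack (placeholders already substituted)
  std::vector<uint8_t> packed((total + 3) / 4, 0);
  for (size_t i = 0; i < total; i++)
    packed[i >> 2] |= (uint8_t)(base_code_or(sc.stored[i], 0) << ((i & 3) * 2));
  w.bytes(packed.data(), packed.size());

  return List::create(_["block"] = w.raw(), _["stored_bases"] = (double)total);
}

// [[Rcpp::export(rng = false)]]
List rp_decode_sequence_block(RawVector block, int n, bool paired,
                              bool n_elision, bool const_len, int read_len,
                              std::string qual_stream, int n_score) {
  static const char CODE_BASE[4] = {'A', 'C', 'G', 'T'};
  ByteReader r(block);
  size_t total = (size_t)r.varint();

  std::vector<uint8_t> merged_flag(n, 0);
  std::vector<int> offs(n, -1);
  std::vector<std::vector<int>> mmpos(n);
  std::vector<std::string> mmbase(n);
  if (paired) {
    int nb = (n + 7) / 8;
    r.need(nb);
    for (int i = 0; i < n; i++)
      merged_flag[i] = (r.p[r.pos + (i >> 3)] >> (i & 7)) & 1;
    r.pos += nb;
    for (int i = 0; i < n; i++) {
      if (!merged_flag[i]) continue;
      offs[i] = (int)r.varint();
      int nm = (int)r.varint();
      int prev = 0;
      for (int j = 0; j < nm; j++) {
        int d = (int)r.varint();
        int p = j == 0 ? d : prev + d;
        mmpos[i].push_back(p);
        mmbase[i].push_back((char)r.u8());
        prev = p;
      }
    }
  }
  std::vector<int> len1(n), len2(n, 0);
  if (const_len) {
    for (int i = 0; i < n; i++) {
      len1[i] = read_len;
      if (paired) len2[i] = read_len;
    }
  } else {
    int width = r.u8();
    if (width < 1 || width > 4) stop("corrupt sequence block: bad length width");
    for (int i = 0; i < n; i++) {
      len1[i] = (int)r.fixed(width);
      if (paired) len2[i] = (int)r.fixed(width);
    }
  }
  std::vector<std::vector<int>> npos(n);
  if (!n_elision) {
    for (int i = 0; i < n; i++) {
      int c = (int)r.varint();
      int prev = 0;
      for (int j = 0; j < c; j++) {
        int d = (int)r.varint();
        int p = j == 0 ? d : prev + d;
        npos[i].push_back(p);
        prev = p;
      }
    }
  }
  int nx = (int)r.varint();
  std::vector<double> xpos(nx);
  std::string xbyte(nx, 'A');
  double xprev = 0;
  for (int j = 0; j < nx; j++) {
    double d = (double)r.varint();
    xpos[j] = j == 0 ? d : xprev + d;
    xbyte[j] = (char)r.u8();
    xprev = xpos[j];
  }
  size_t pbytes = (total + 3) / 4;
  r.need(pbytes);
  std::string stored(total, 'A');
  for (size_t i = 0; i < total; i++)
    stored[i] = CODE_BASE[(r.p[r.pos + (i >> 2)] >> ((i & 3) * 2)) & 3];
  r.pos += pbytes;

  // span bookkeeping: stored-base start and quality start per pair
  std::vector<size_t> sstart(n + 1, 0), qstart(n + 1, 0);
  for (int i = 0; i < n; i++) {
    size_t slen = merged_flag[i] ? (size_t)(offs[i] + len2[i])
                                 : (size_t)(len1[i] + len2[i]);
    sstart[i + 1] = sstart[i] + slen;
    qstart[i + 1] = qstart[i] + (size_t)(len1[i] + len2[i]);
  }
  if (sstart[n] != total) stop("corrupt sequence block: stored base count mismatch");

  // restore N bases
  if (n_elision) {
    if (qstart[n] > qual_stream.size())
      stop("corrupt chunk: quality stream shorter than sequence data");
    const char* q = qual_stream.data();
    char ns = (char)n_score;
    for (int i = 0; i < n; i++) {
      const char* q1 = q + qstart[i];
      const char* q2 = q1 + len1[i];
      size_t s0 = sstart[i];
      if (merged_flag[i]) {
        int m = offs[i] + len2[i];
        for (int j = 0; j < len1[i]; j++)
          if (q1[j] == ns) stored[s0 + j] = 'N';
        for (int j = len1[i]; j < m; j++)
          if (q2[len2[i] - 1 - (j - offs[i])] == ns) stored[s0 + j] = 'N';
      } else {
        for (int j = 0; j < len1[i]; j++)
          if (q1[j] == ns) stored[s0 + j] = 'N';
        for (int j = 0; j < len2[i]; j++)
          if (q2[j] == ns) stored[s0 + len1[i] + j] = 'N';
      }
    }
  } else {
    for (int i = 0; i < n; i++)
      for (int p : npos[i]) {
        if ((size_t)p >= sstart[i + 1] - sstart[i])
          stop("corrupt sequence block: N position out of range");
        stored[sstart[i] + p] = 'N';
      }
  }
  // exceptions override
  for (int j = 0; j < nx; j++) {
    if (xpos[j] >= (double)total) stop("corrupt sequence block: exception position out of range");
    stored[(size_t)xpos[j]] = xbyte[j];
  }

  CharacterVector out1(n), out2(paired ? n : 0);
  for (int i = 0; i < n; i++) {
    size_t s0 = sstart[i];
    if (merged_flag[i]) {
      out1[i] = stored.substr(s0, len1[i]);
      std::string rc2 = stored.substr(s0 + offs[i], len2[i]);
      std::string r2(len2[i], 'N');
      for (int j = 0; j < len2[i]; j++) r2[j] = comp(rc2[len2[i] - 1 - j]);
      for (size_t j = 0; j < mmpos[i].size(); j++) {
        int p = mmpos[i][j];
        if (p < 0 || p >= len2[i]) stop("corrupt sequence block: mismatch position out of range");
        r2[len2[i] - 1 - p] = mmbase[i][j];
      }
      out2[i] = r2;
    } else {
      out1[i] = stored.substr(s0, len1[i]);
      if (paired) out2[i] = stored.substr(s0 + len1[i], len2[i]);
    }
  }
  List res = List::create(
      _["seqs1"] = out1, _["seqs2"] = paired ? (SEXP)out2 : R_NilValue,
      _["len1"] = IntegerVector(len1.begin(), len1.end()),
      _["len2"] = IntegerVector(len2.begin(), len2.end()));
  return res;
}
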