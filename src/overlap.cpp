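// Paired-end overlap detection and merging.
//
// Geometry: let rc2 = reverse complement of read2 and "offset" the start of
// rc2 within the merged fragment (read1 starts at 0). The overlap region is
// [offset, len1); a merge is accepted only when offset >= 0 and
// offset + len2 >= len1, so merged_length == offset + len2 and the merged
// sequence is read1 followed by the tail of rc2 past read1's end. Inside
// the overlap read1's base is the one stored; read2 bases that disagree
// (including N-vs-base) are kept as (position-in-overlap, original read2
// byte) mismatch records, which makes the merge lossless regardless of
// whether the detected overlap is biologically real.
//
// Search: candidate offsets are seeded by exact occurrences of read1's last
// 16-mer inside rc2 and scanned in ascending offset order (largest overlap
// first); if no seeded candidate is accepted, a full scan over all valid
// offsets runs in the same order. First offset with overlap >= min_overlap
// and at most max_mismatch mismatches wins.
#include "bytestream.h"

using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
    default: return 0;  // non-ACGTN: pair is not mergeable
  }
}

static bool revcomp(const char* s, size_t n, std::string& out) {
  out.resize(n);
  for (size_t i = 0; i < n; i++) {
    char c = comp(s[n - 1 - i]);
    if (!c) return false;
    out[i] = c;
  }
  return true;
}

static bool pure_acgtn(const char* s) {
  for (; *s; s++)
    if (*s != 'A' && *s != 'C' && *s != 'G' && *s != 'T' && *s != 'N') return false;
  return true;
}

struct OvResult {
  int offset;  // -1 = none
  std::vector<int> mm_pos;
  std::string mm_base;  // read2's original base per mismatch
};

static bool verify_offset(const char* r1, int len1, const std::string& rc2,
                          int len2, const char* r2, int off, int max_mismatch,
                          OvResult& res) {
  int ov = len1 - off;  // overlap length (rc2 covers read1's tail entirely)
  // mismatch budget scales with the overlap so short overlaps must be
  // near-exact: min(max_mismatch, overlap / 8)
  int allowed = ov / 8;
  if (allowed > max_mismatch) allowed = max_mismatch;
  std::vector<int> pos;
  for (int p = 0; p < ov; p++) {
    if (r1[off + p] != rc2[p]) {
      pos.push_back(p);
      if ((int)pos.size() > allowed) return false;
    }
  }
  res.offset = off;
  res.mm_pos = pos;
  res.mm_base.clear();
  for (int p : pos) res.mm_base.push_back(r2[len2 - 1 - p]);
  return true;
}

static OvResult find_overlap_one(const char* r1, const char* r2,
                                 int min_overlap, int max_mismatch) {
  OvResult none;
  none.offset = -1;
  int len1 = (int)strlen(r1), len2 = (int)strlen(r2);
  if (len1 < min_overlap || len2 < min_overlap) return none;
  if (!pure_acgtn(r1) || !pure_acgtn(r2)) return none;
  std::string rc2;
  if (!revcomp(r2, len2, rc2)) return none;

  // valid offsets: off >= max(0, len1 - len2), off <= len1 - min_overlap
  int lo = len1 > len2 ? len1 - len2 : 0;
  int hi = len1 - min_overlap;
  if (hi < lo) return none;

  OvResult res;
  std::vector<char> tried(hi - lo + 1, 0);
  const int K = 16;
  if (len1 >= K) {
    const char* tail = r1 + (len1 - K);
    // seed: exact occurrences of read1's last 16-mer in rc2, ascending offset
    // offset = (len1 - K) - j for a match at rc2 position j, so scan j descending
    for (int j = (int)rc2.size() - K; j >= 0; j--) {
      int off = (len1 - K) - j;
      if (off < lo || off > hi) continue;
      if (memcmp(tail, rc2.data() + j, K) != 0) continue;
      tried[off - lo] = 1;
      if (verify_offset(r1, len1, rc2, len2, r2, off, max_mismatch, res)) return res;
    }
  }
  // fallback: full scan (tolerates errors inside the seed k-mer)
  for (int off = lo; off <= hi; off++) {
    if (tried[off - lo]) continue;
    if (verify_offset(r1, len1, rc2, len2, r2, off, max_mismatch, res)) return res;
  }
  return none;
}

// [[Rcpp::export(rng = false)]]
SEXP rp_find_overlap(std::string read1, std::string read2, int min_overlap,
                     int max_mismatch) {
  OvResult r = find_overlap_one(read1.c_str(), read2.c_str(), min_overlap, max_mismatch);
  if (r.offset < 0) return R_NilValue;
  return List::create(
      _["offset"] = r.offset,
      _["merged_length"] = r.offset + (int)read2.size(),
      _["mismatch_pos"] = IntegerVector(r.mm_pos.begin(), r.mm_pos.end()),
      _["mismatch_base"] = r.mm_base);
}

// Vectorized over a chunk: offsets[i] == -1 means store the pair separately.
// [[Rcpp::export(rng = false)]]
List rp_find_overlaps(CharacterVector s1, CharacterVector s2, int min_overlap,
                      int max_mismatch) {
  int n = s1.size();
  if (s2.size() != n) stop("length mismatch");
  IntegerVector offsets(n);
  List mm_pos(n);
  CharacterVector mm_base(n);
  for (int i = 0; i < n; i++) {
    OvResult r = find_overlap_one(CHAR(STRING_ELT(s1, i)), CHAR(STRING_ELT(s2, i)),
                                  min_overlap, max_mismatch);
    offsets[i] = r.offset;
    if (r.offset >= 0) {
      mm_pos[i] = IntegerVector(r.mm_pos.begin(), r.mm_pos.end());
      mm_base[i] = r.mm_base;
    } else {
      mm_pos[i] = IntegerVector(0);
      mm_base[i] = "";
    }
  }
  return List::create(_["offset"] = offsets, _["mismatch_pos"] = mm_pos,
                      _["mismatch_base"] = mm_base);
}

// [[Rcpp::export(rng = false)]]
String rp_merge_pair(std::string read1, std::string read2, int offset) {
  int len1 = (int)read1.size(), len2 = (int)read2.size();
  if (offset < 0 || offset + len2 < len1)
    stop("merge_pair: descriptor inconsistent with read lengths");
  std::string rc2;
  if (!revcomp(read2.c_str(), len2, rc2)) stop("merge_pair: non-ACGTN base in read2");
  std::string merged = read1 + rc2.substr(len1 - offset);
  return String(merged);
}

// [[Rcpp::export(rng = false)]]
List rp_split_pair(std::string merged, int offset, int len1, int len2,
                   IntegerVector mismatch_pos, std::string mismatch_base) {
  if (offset < 0 || offset + len2 != (int)merged.size() || len1 > (int)merged.size())
    stop("split_pair: corrupt overlap descriptor");
  std::string r1 = merged.substr(0, len1);
  std::string rc2 = merged.substr(offset, len2);
  std::string r2;
  if (!revcomp(rc2.c_str(), len2, r2)) stop("split_pair: non-ACGTN base in merged sequence");
  if ((int)mismatch_base.size() != mismatch_pos.size())
    stop("split_pair: corrupt mismatch list");
  for (int i = 0; i < mismatch_pos.size(); i++) {
    int p = mismatch_pos[i];
    if (p < 0 || p >= len2 || len2 - 1 - p < 0)
      stop("split_pair: mismatch position out of range");
    r2[len2 - 1 - p] = mismatch_base[i];
  }
  return List::create(_["read1"] = r1, _["read2"] = r2);
}

// [[Rcpp::export(rng = false)]]
String rp_revcomp(std::string s) {
  std::string out;
  if (!revcomp(s.c_str(), s.size(), out)) stop("reverse complement: non-ACGTN base");
  return String(out);
}
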