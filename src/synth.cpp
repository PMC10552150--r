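// Synthetic read simulation core. All randomness comes from R's RNG so
// corpora are reproducible from set.seed().
#include <Rcpp.h>

using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

// [[Rcpp::export]]
String rp_random_bases(double n) {
  size_t len = (size_t)n;
  std::string s(len, 'A');
  for (size_t i = 0; i < len; i++) s[i] = BASES[(int)(unif_rand() * 4) & 3];
  return String(s);
}

static void fill_quality(std::string& q, double run_mean, const std::string& bins,
                         const std::vector<double>& cum) {
  size_t pos = 0, L = q.size();
  double p = 1.0 / run_mean;
  while (pos < L) {
    // geometric run length with mean run_mean
    int run = 1 + (int)(std::log(unif_rand()) / std::log(1.0 - p));
    if (run < 1) run = 1;
    double u = unif_rand();
    size_t b = 0;
    while (b + 1 < cum.size() && u > cum[b]) b++;
    char sc = bins[b];
    for (int t = 0; t < run && pos < L; t++, pos++) q[pos] = sc;
  }
}

// Simulate paired reads from fragments of a genome string. read1 is the
// fragment prefix, read2 the reverse complement of the fragment suffix.
// Substitution errors at rate err, then N injection at rate n_rate (N bases
// get quality n_score). Qualities are runs of geometric length run_mean
// with run scores drawn from the bin distribution.
// [[Rcpp::export]]
List rp_simulate_reads(std::string genome, IntegerVector starts,
                       IntegerVector fraglens, int read_len, double err,
                       double n_rate, std::string bins, NumericVector binprobs,
                       double run_mean, std::string n_score) {
  int n = starts.size();
  if (fraglens.size() != n) stop("length mismatch");
  if ((int)bins.size() != binprobs.size() || bins.empty()) stop("bad bin scheme");
  std::vector<double> cum(binprobs.size());
  double tot = 0;
  for (int i = 0; i < binprobs.size(); i++) tot += binprobs[i];
  double acc = 0;
  for (int i = 0; i < binprobs.size(); i++) {
    acc += binprobs[i] / tot;
    cum[i] = acc;
  }
  char nsc = n_score.empty() ? '#' : n_score[0];

  CharacterVector s1(n), s2(n), q1(n), q2(n);
  std::string r1, r2, qa, qb;
  for (int i = 0; i < n; i++) {
    int start = starts[i] - 1;  // 1-based from R
    int flen = fraglens[i];
    if (start < 0 || start + flen > (int)genome.size())
      stop("fragment %d outside genome", i + 1);
    r1.assign(genome, start, read_len);
    r2.resize(read_len);
    for (int j = 0; j < read_len; j++)
      r2[j] = comp(genome[start + flen - 1 - j]);
    for (int k = 0; k < 2; k++) {
      std::string& r = k == 0 ? r1 : r2;
      if (err > 0) {
        for (int j = 0; j < read_len; j++) {
          if (unif_rand() < err) {
            char nb = BASES[(int)(unif_rand() * 4) & 3];
            while (nb == r[j]) nb = BASES[(int)(unif_rand() * 4) & 3];
            r[j] = nb;
          }
        }
      }
    }
    qa.assign(read_len, '!');
    qb.assign(read_len, '!');
    fill_quality(qa, run_mean, bins, cum);
    fill_quality(qb, run_mean, bins, cum);
    if (n_rate > 0) {
      for (int j = 0; j < read_len; j++) {
        if (unif_rand() < n_rate) { r1[j] = 'N'; qa[j] = nsc; }
        if (unif_rand() < n_rate) { r2[j] = 'N'; qb[j] = nsc; }
      }
    }
    s1[i] = r1; s2[i] = r2; q1[i] = qa; q2[i] = qb;
  }
  return List::create(_["seq1"] = s1, _["seq2"] = s2, _["qual1"] = q1,
                      _["qual2"] = q2);
}
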