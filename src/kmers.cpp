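#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; -1 for anything else.
static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Canonical k-mer codes for every window of `seq`; NA where the window
// contains a non-ACGT symbol. Codes fit exactly in a double for k <= 26
// (2k bits <= 52); callers enforce the cap.
// [[Rcpp::export]]
NumericVector cpp_kmer_codes(const std::string& seq, int k) {
  const R_xlen_t n = (R_xlen_t)seq.size();
  if (k < 1 || n < k) return NumericVector(0);
  NumericVector out(n - k + 1, NA_REAL);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0; // valid bases since last ambiguity
  for (R_xlen_t i = 0; i < n; ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++run >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      out[i - k + 1] = (double)canon;
    }
  }
  return out;
}

// Count canonical k-mers over a set of sequences. Returns sorted codes and
// their occurrence counts.
// [[Rcpp::export]]
List cpp_count_kmers(const CharacterVector& seqs, int k) {
  std::unordered_map<uint64_t, uint32_t> tab;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* p = CHAR(STRING_ELT(seqs, s));
    R_xlen_t n = (R_xlen_t)LENGTH(STRING_ELT(seqs, s));
    if (n < k) continue;
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      int b = base2bits(p[i]);
      if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
      if (++run >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++tab[canon];
      }
    }
  }
  std::vector<uint64_t> keys;
  keys.reserve(tab.size());
  for (auto& kv : tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  NumericVector codes((R_xlen_t)keys.size());
  IntegerVector counts((R_xlen_t)keys.size());
  for (R_xlen_t i = 0; i < (R_xlen_t)keys.size(); ++i) {
    codes[i] = (double)keys[i];
    counts[i] = (int)tab[keys[i]];
  }
  return List::create(_["codes"] = codes, _["counts"] = counts);
}

// Occurrence counts for query codes against a sorted code table (0 when
// absent, NA propagated).
// [[Rcpp::export]]
IntegerVector cpp_lookup_codes(const NumericVector& codes,
                               const IntegerVector& counts,
                               const NumericVector& queries) {
  IntegerVector out(queries.size());
  const double* beg = codes.begin();
  const double* end = codes.end();
  for (R_xlen_t i = 0; i < queries.size(); ++i) {
    double q = queries[i];
    if (NumericVector::is_na(q)) { out[i] = NA_INTEGER; continue; }
    const double* it = std::lower_bound(beg, end, q);
    out[i] = (it != end && *it == q) ? counts[(R_xlen_t)(it - beg)] : 0;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmers(const NumericVector& codes, int k) {
  CharacterVector out(codes.size());
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    if (NumericVector::is_na(codes[i])) { out[i] = NA_STRING; continue; }
    uint64_t code = (uint64_t)codes[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = bases[code & 3ULL];
      code >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// Fraction of each read's canonical k-mers found in a sorted code set.
// Reads with no valid k-mer get NA.
// [[Rcpp::export]]
NumericVector cpp_shared_kmer_fraction(const CharacterVector& reads, int k,
                                       const NumericVector& set_codes) {
  NumericVector out(reads.size());
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const double* beg = set_codes.begin();
  const double* end = set_codes.end();
  for (R_xlen_t s = 0; s < reads.size(); ++s) {
    const char* p = CHAR(STRING_ELT(reads, s));
    R_xlen_t n = (R_xlen_t)LENGTH(STRING_ELT(reads, s));
    long total = 0, hit = 0;
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      int b = base2bits(p[i]);
      if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
      if (++run >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++total;
        double q = (double)canon;
        const double* it = std::lower_bound(beg, end, q);
        if (it != end && *it == q) ++hit;
      }
    }
    out[s] = (total == 0) ? NA_REAL : (double)hit / (double)total;
  }
  return out;
}

// Order-2 Markov chain walk over a 16x4 cumulative transition matrix.
// `u` supplies the uniforms (length n); the first two states are given.
// Returns 1-based base indices.
// [[Rcpp::export]]
IntegerVector cpp_markov_walk(int n, const NumericMatrix& cum,
                              const NumericVector& u, int s1, int s2) {
  IntegerVector out(n);
  if (n >= 1) out[0] = s1;
  if (n >= 2) out[1] = s2;
  for (int i = 2; i < n; ++i) {
    int ctx = (out[i - 2] - 1) * 4 + (out[i - 1] - 1);
    double ui = u[i];
    int b = 0;
    while (b < 3 && ui > cum(ctx, b)) ++b;
    out[i] = b + 1;
  }
  return out;
}
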