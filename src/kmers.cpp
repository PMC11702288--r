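#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// DNA helpers shared across the compiled kernels.
inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string s) {
  return revcomp_str(s);
}

typedef unsigned __int128 u128;

struct u128_hash {
  size_t operator()(u128 x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    uint64_t h = lo * 0x9E3779B97F4A7C15ULL ^ (hi + 0x9E3779B97F4A7C15ULL + (lo << 6));
    h ^= h >> 31; h *= 0xBF58476D1CE4E5B9ULL; h ^= h >> 27;
    return (size_t)h;
  }
};

// Canonical kmer counting with rolling 2-bit encodings (A=0 C=1 G=2 T=3,
// most significant first, so numeric order equals lexicographic order).
// Every ACGT-only window contributes one occurrence to min(kmer, revcomp).
// k up to 64 fits the 128-bit code.
// [[Rcpp::export]]
IntegerVector count_kmers_cpp(CharacterVector reads, int k) {
  if (k > 64) stop("kmer size above 64 is not supported");
  std::unordered_map<u128, int, u128_hash> counts;
  const u128 mask = (k == 64) ? (u128)~(u128)0 : (((u128)1 << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* r = CHAR(STRING_ELT(reads, i));
    int n = (int)LENGTH(STRING_ELT(reads, i));
    u128 fwd = 0, rc = 0;
    int run = 0; // valid bases accumulated in the current window
    for (int j = 0; j < n; ++j) {
      int b = base_code(r[j]);
      if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (u128)b) & mask;
      rc = (rc >> 2) | ((u128)(3 - b) << shift);
      if (++run >= k) ++counts[fwd < rc ? fwd : rc];
    }
  }
  IntegerVector out(counts.size());
  R_xlen_t i = 0;
  for (auto& kv : counts) out[i++] = kv.second;
  return out;
}
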