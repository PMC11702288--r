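#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
#include <cstdint>
using namespace Rcpp;

std::string revcomp_str(const std::string& s); // kmers.cpp

inline int base_code2(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char* B = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = B[code & 3]; code >>= 2; }
  return s;
}

// Node-centric de Bruijn graph over the strand-augmented read set: every read
// and its reverse complement is inserted, so the forward strand of the target
// is a directed path. Nodes are distinct kmers (not canonicalized) with count
// >= min_count; a directed edge a->b requires suffix/prefix (k-1)-overlap AND
// a witnessed (k+1)-mer in the augmented reads. Rolling 2-bit codes cap the
// graph kmer size at 31 (so the witness (k+1)-mer fits 64 bits).
// [[Rcpp::export]]
List build_dbg_cpp(CharacterVector reads, int k, int min_count) {
  if (k > 31) stop("graph kmer size above 31 is not supported");
  std::vector<std::string> seqs;
  seqs.reserve(2 * reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string r = as<std::string>(reads[i]);
    seqs.push_back(r);
    seqs.push_back(revcomp_str(r));
  }

  const uint64_t mask = (((uint64_t)1) << (2 * k)) - 1;
  std::unordered_map<uint64_t, int> counts;
  for (const auto& r : seqs) {
    uint64_t fwd = 0;
    int run = 0;
    for (char ch : r) {
      int b = base_code2(ch);
      if (b < 0) { run = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      if (++run >= k) ++counts[fwd];
    }
  }

  // surviving kmers get dense ids
  std::unordered_map<uint64_t, int> id;
  std::vector<uint64_t> kcode;
  std::vector<int> kcount;
  for (auto& kv : counts) {
    if (kv.second >= min_count) {
      id[kv.first] = (int)kcode.size();
      kcode.push_back(kv.first);
      kcount.push_back(kv.second);
    }
  }
  counts.clear();
  if (kcode.empty()) {
    return List::create(_["kmers"] = CharacterVector(0),
                        _["counts"] = IntegerVector(0),
                        _["edges"] = IntegerMatrix(0, 2),
                        _["k"] = k);
  }

  // edges witnessed by (k+1)-mers
  const int kw = k + 1;
  const uint64_t wmask = (kw == 32) ? ~(uint64_t)0 : ((((uint64_t)1) << (2 * kw)) - 1);
  std::unordered_set<uint64_t> eset;
  std::vector<int> efrom, eto;
  for (const auto& r : seqs) {
    uint64_t w = 0;
    int run = 0;
    for (char ch : r) {
      int b = base_code2(ch);
      if (b < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)b) & wmask;
      if (++run >= kw) {
        auto ia = id.find(w >> 2);        // prefix kmer
        if (ia != id.end()) {
          auto ib = id.find(w & mask);    // suffix kmer
          if (ib != id.end()) {
            // ids are < 2^32 so the pair packs into one key
            uint64_t key = ((uint64_t)ia->second << 32) | (uint32_t)ib->second;
            if (eset.insert(key).second) {
              efrom.push_back(ia->second + 1);
              eto.push_back(ib->second + 1);
            }
          }
        }
      }
    }
  }

  CharacterVector kstr(kcode.size());
  for (size_t i = 0; i < kcode.size(); ++i) kstr[i] = decode_kmer(kcode[i], k);
  IntegerMatrix edges((int)efrom.size(), 2);
  for (int i = 0; i < (int)efrom.size(); ++i) {
    edges(i, 0) = efrom[i];
    edges(i, 1) = eto[i];
  }
  return List::create(_["kmers"] = kstr,
                      _["counts"] = wrap(kcount),
                      _["edges"] = edges,
                      _["k"] = k);
}

// Compact maximal non-branching paths of a raw kmer graph into unitigs.
// Unitig weight is the arithmetic mean of member kmer counts. Isolated simple
// cycles are broken at their smallest member id and kept as one unitig with a
// self-edge.
// [[Rcpp::export]]
List compact_cpp(CharacterVector kmers, IntegerVector counts, IntegerMatrix edges, int k) {
  int n = (int)kmers.size();
  int m = edges.nrow();
  std::vector<std::vector<int>> out(n), in(n);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    out[a].push_back(b);
    in[b].push_back(a);
  }

  // v extends its unique predecessor u iff u->v is the only way in and out
  auto pred_unique = [&](int v) {
    if (in[v].size() != 1) return false;
    int u = in[v][0];
    return out[u].size() == 1 && u != v;
  };

  std::vector<int> unit_of(n, -1), pos_in_unit(n, -1);
  std::vector<std::vector<int>> members;

  auto walk = [&](int start) {
    std::vector<int> path;
    path.push_back(start);
    unit_of[start] = (int)members.size();
    pos_in_unit[start] = 0;
    int cur = start;
    while (out[cur].size() == 1) {
      int nxt = out[cur][0];
      if (in[nxt].size() != 1) break;
      if (nxt == cur || nxt == start) break;        // self-loop / cycle closure
      if (unit_of[nxt] != -1) break;                // safety
      unit_of[nxt] = (int)members.size();
      pos_in_unit[nxt] = (int)path.size();
      path.push_back(nxt);
      cur = nxt;
    }
    members.push_back(path);
  };

  for (int v = 0; v < n; ++v)
    if (unit_of[v] == -1 && !pred_unique(v)) walk(v);
  // leftovers are perfect cycles; break each at its smallest unassigned id
  for (int v = 0; v < n; ++v)
    if (unit_of[v] == -1) walk(v);

  int nu = (int)members.size();
  CharacterVector useq(nu);
  NumericVector uweight(nu);
  IntegerVector ulen(nu);
  for (int u = 0; u < nu; ++u) {
    const std::vector<int>& path = members[u];
    std::string s = as<std::string>(kmers[path[0]]);
    double wsum = counts[path[0]];
    s.reserve(k + path.size() - 1);
    for (size_t i = 1; i < path.size(); ++i) {
      const char* km = CHAR(STRING_ELT(kmers, path[i]));
      s.push_back(km[k - 1]);
      wsum += counts[path[i]];
    }
    useq[u] = s;
    uweight[u] = wsum / path.size();
    ulen[u] = (int)s.size();
  }

  // lift non-internal kmer edges to unitig edges
  std::unordered_set<uint64_t> ueset;
  std::vector<int> uefrom, ueto;
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    if (unit_of[a] == unit_of[b] && pos_in_unit[b] == pos_in_unit[a] + 1)
      continue; // internal to a unitig
    uint64_t key = ((uint64_t)unit_of[a] << 32) | (uint32_t)unit_of[b];
    if (ueset.insert(key).second) {
      uefrom.push_back(unit_of[a] + 1);
      ueto.push_back(unit_of[b] + 1);
    }
  }
  IntegerMatrix uedges((int)uefrom.size(), 2);
  for (int i = 0; i < (int)uefrom.size(); ++i) {
    uedges(i, 0) = uefrom[i];
    uedges(i, 1) = ueto[i];
  }

  return List::create(_["seq"] = useq,
                      _["weight"] = uweight,
                      _["length"] = ulen,
                      _["edges"] = uedges,
                      _["n_kmers"] = n,
                      _["k"] = k);
}
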