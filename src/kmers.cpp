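#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 2-bit base codes follow lexicographic order (A<C<G<T), so numeric order
// on encoded k-mers equals lexicographic order on the strings.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Emit the canonical (min of forward and reverse complement) code of every
// valid k-mer of seq; windows containing non-ACGT bases are skipped.
template <typename F>
static void for_each_canonical_kmer(const char* s, int n, int k, F f) {
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int shift = 2 * (k - 1);
  int valid = 0;  // length of current run of ACGT bases
  for (int i = 0; i < n; i++) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++valid >= k) f(std::min(fwd, rev));
  }
}

// [[Rcpp::export(name = ".kmer_db_build_cpp")]]
List kmer_db_build_cpp(CharacterVector seqs, IntegerVector taxon,
                       IntegerMatrix lca, int k) {
  std::vector<std::pair<uint64_t, int>> all;
  for (int g = 0; g < seqs.size(); g++) {
    const char* s = CHAR(STRING_ELT(seqs, g));
    int n = LENGTH(STRING_ELT(seqs, g));
    int tx = taxon[g];
    for_each_canonical_kmer(s, n, k, [&](uint64_t km) {
      all.emplace_back(km, tx);
    });
  }
  std::sort(all.begin(), all.end());
  std::vector<uint64_t> keys;
  std::vector<int> vals;
  keys.reserve(all.size());
  vals.reserve(all.size());
  for (size_t i = 0; i < all.size(); i++) {
    if (!keys.empty() && keys.back() == all[i].first) {
      int a = vals.back(), b = all[i].second;
      if (a != b) vals.back() = lca(a - 1, b - 1);
    } else {
      keys.push_back(all[i].first);
      vals.push_back(all[i].second);
    }
  }
  int m = (int)keys.size();
  IntegerVector hi(m), lo(m), tx(m);
  for (int i = 0; i < m; i++) {
    hi[i] = (int)(keys[i] >> 31);
    lo[i] = (int)(keys[i] & 0x7FFFFFFFULL);
    tx[i] = vals[i];
  }
  return List::create(_["hi"] = hi, _["lo"] = lo, _["taxon"] = tx);
}

// [[Rcpp::export(name = ".kmer_classify_cpp")]]
List kmer_classify_cpp(IntegerVector hi, IntegerVector lo, IntegerVector taxon,
                       CharacterVector reads, int k,
                       IntegerMatrix anc, IntegerVector leaves,
                       IntegerMatrix lca, bool return_hits) {
  int m = hi.size();
  std::vector<uint64_t> keys(m);
  for (int i = 0; i < m; i++)
    keys[i] = ((uint64_t)(unsigned int)hi[i] << 31) | (uint64_t)(unsigned int)lo[i];
  int n_taxa = anc.nrow();
  int nr = reads.size();
  IntegerVector assigned(nr);
  IntegerMatrix hitmat = return_hits ? IntegerMatrix(nr, n_taxa) : IntegerMatrix(0, 0);
  std::vector<int> hits(n_taxa);
  for (int r = 0; r < nr; r++) {
    std::fill(hits.begin(), hits.end(), 0);
    const char* s = CHAR(STRING_ELT(reads, r));
    int n = LENGTH(STRING_ELT(reads, r));
    int total = 0;
    for_each_canonical_kmer(s, n, k, [&](uint64_t km) {
      auto it = std::lower_bound(keys.begin(), keys.end(), km);
      if (it != keys.end() && *it == km) {
        hits[taxon[it - keys.begin()] - 1]++;
        total++;
      }
    });
    if (return_hits)
      for (int t = 0; t < n_taxa; t++) hitmat(r, t) = hits[t];
    if (total == 0) { assigned[r] = 0; continue; }
    // score each root-to-leaf path by the summed hits on its nodes
    int best = -1;
    std::vector<int> tied;
    for (int li = 0; li < leaves.size(); li++) {
      int leaf = leaves[li];  // 1-based
      int score = 0;
      for (int a = 0; a < n_taxa; a++)
        if (anc(leaf - 1, a)) score += hits[a];
      if (score > best) { best = score; tied.clear(); tied.push_back(leaf); }
      else if (score == best) tied.push_back(leaf);
    }
    int asg = tied[0];
    for (size_t i = 1; i < tied.size(); i++) asg = lca(asg - 1, tied[i] - 1);
    assigned[r] = asg;
  }
  if (return_hits)
    return List::create(_["assigned"] = assigned, _["hits"] = hitmat);
  return List::create(_["assigned"] = assigned);
}

// [[Rcpp::export(name = ".kmer_decode_cpp")]]
CharacterVector kmer_decode_cpp(IntegerVector hi, IntegerVector lo, int k) {
  static const char* bases = "ACGT";
  int m = hi.size();
  CharacterVector out(m);
  std::string buf(k, 'A');
  for (int i = 0; i < m; i++) {
    uint64_t km = ((uint64_t)(unsigned int)hi[i] << 31) | (uint64_t)(unsigned int)lo[i];
    for (int j = k - 1; j >= 0; j--) {
      buf[j] = bases[km & 3ULL];
      km >>= 2;
    }
    out[i] = buf;
  }
  return out;
}
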