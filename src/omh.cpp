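#include "core.h"

#include <algorithm>
#include <queue>
#include <unordered_map>

static inline uint32_t fold32(uint64_t x) { return (uint32_t)(x ^ (x >> 32)); }

// Per-repetition hash seed, derived reproducibly from the sketch seed:
// seed_i = seed XOR fold32(wang_mix64(i)), i = 0..m-1.
// [[Rcpp::export]]
double cpp_omh_row_seed(double seed, int i) {
  return (double)((uint32_t)seed ^ fold32(wang_mix64((uint64_t)i)));
}

struct OmhCand {
  uint64_t hash;
  int win;  // index into the valid-window arrays
};

// Candidate ordering for the size-l max-heap: worst = largest hash,
// ties broken by larger position (so ties keep the earlier occurrence).
struct WorseCand {
  bool operator()(const OmhCand &a, const OmhCand &b) const {
    if (a.hash != b.hash) return a.hash < b.hash;
    return a.win < b.win;
  }
};

// OrderMinHash sketch: m repetitions; per repetition, hash every (k-mer,
// occurrence-index) pair and keep the l smallest, then re-sort those by
// sequence position. `block` = number of repetitions whose priority queues
// are maintained simultaneously while scanning positions (1 = row-wise;
// values > 1 exercise the cache-blocked traversal); the traversal order must
// never change the result.
// [[Rcpp::export]]
Rcpp::List cpp_omh_sketch(std::string seq, int k, int m, int l, double seed,
                          int block) {
  if (m < 1 || l < 1) Rcpp::stop("m and l must be >= 1");
  if (block < 1) Rcpp::stop("block must be >= 1");
  if ((int64_t)seq.size() < k)
    Rcpp::stop("sequence length (%d) is shorter than k (%d); OrderMinHash is undefined",
               (int)seq.size(), k);

  // valid windows with positions, k-mer strings and occurrence indices
  std::vector<int> pos;
  std::vector<uint64_t> codes;
  for_each_kmer(seq, k, [&](size_t p, uint64_t fwd, uint64_t) {
    pos.push_back((int)p);
    codes.push_back(fwd);
  });
  const int nw = (int)pos.size();
  if (nw == 0)
    Rcpp::stop("no valid k-mer window (all windows contain non-ACGT characters)");

  std::vector<std::string> kmers(nw);
  std::vector<int> occ(nw);
  std::unordered_map<uint64_t, int> counts;
  std::vector<char> buf(k, 0);
  for (int i = 0; i < nw; ++i) {
    decode_kmer(codes[i], k, buf.data());
    kmers[i].assign(buf.data(), k);
    occ[i] = counts[codes[i]]++;
  }

  // hashed bytes: k-mer ASCII, ':', then the decimal occurrence index --
  // weights repeated k-mers apart while staying reproducible from plain
  // strings in any implementation
  std::vector<std::string> hkey(nw);
  for (int i = 0; i < nw; ++i)
    hkey[i] = kmers[i] + ":" + std::to_string(occ[i]);
  auto occ_hash = [&](int w, uint32_t sd) {
    return murmur3_lo64(hkey[w].data(), hkey[w].size(), sd);
  };

  std::vector<uint32_t> row_seed(m);
  for (int r = 0; r < m; ++r)
    row_seed[r] = (uint32_t)seed ^ fold32(wang_mix64((uint64_t)r));

  Rcpp::List rows(m);
  std::vector<std::priority_queue<OmhCand, std::vector<OmhCand>, WorseCand>> pq(block);
  for (int r0 = 0; r0 < m; r0 += block) {
    const int nb = std::min(block, m - r0);
    for (int j = 0; j < nb; ++j) pq[j] = {};
    for (int w = 0; w < nw; ++w) {       // positions outer: one k-mer load ...
      for (int j = 0; j < nb; ++j) {     // ... feeds every queue in the block
        OmhCand c{occ_hash(w, row_seed[r0 + j]), w};
        if ((int)pq[j].size() < l) {
          pq[j].push(c);
        } else if (WorseCand()(c, pq[j].top())) {
          pq[j].pop();
          pq[j].push(c);
        }
      }
    }
    for (int j = 0; j < nb; ++j) {
      std::vector<OmhCand> sel;
      while (!pq[j].empty()) { sel.push_back(pq[j].top()); pq[j].pop(); }
      std::sort(sel.begin(), sel.end(),
                [](const OmhCand &a, const OmhCand &b) { return a.win < b.win; });
      const int ns = (int)sel.size();
      std::vector<uint64_t> h(ns);
      Rcpp::CharacterVector km(ns);
      Rcpp::IntegerVector oc(ns), ps(ns);
      for (int t = 0; t < ns; ++t) {
        h[t] = sel[t].hash;
        km[t] = kmers[sel[t].win];
        oc[t] = occ[sel[t].win];
        ps[t] = pos[sel[t].win];
      }
      rows[r0 + j] = Rcpp::List::create(
          Rcpp::Named("hash") = u642chr(h), Rcpp::Named("kmer") = km,
          Rcpp::Named("occ") = oc, Rcpp::Named("pos") = ps);
    }
  }
  return rows;
}
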