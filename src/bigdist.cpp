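#include "core.h"

#include <algorithm>

// Flatten all sketch hash lists into one ascending stream of
// (hash, sketch id) pairs -- the inverted index in streaming form.
static void gather(const Rcpp::List &hash_lists,
                   std::vector<std::pair<uint64_t, int>> &ev, int &n) {
  n = hash_lists.size();
  for (int i = 0; i < n; ++i) {
    Rcpp::CharacterVector h = hash_lists[i];
    for (R_xlen_t j = 0; j < h.size(); ++j)
      ev.emplace_back(str2u64(CHAR(STRING_ELT(h, j))), i);
  }
  std::sort(ev.begin(), ev.end());
}

// Shared-hash counts for every sketch pair via the inverted index, with the
// per-pair union rank tracked so the bottom-s' (Mash) estimator is exact:
// a shared hash is credited only while the pair's union count is below s.
// With s = 0 the cap is disabled (full-set semantics, e.g. Kssd).
// [[Rcpp::export]]
Rcpp::List cpp_index_allvsall(Rcpp::List hash_lists, int s) {
  std::vector<std::pair<uint64_t, int>> ev;
  int n = 0;
  gather(hash_lists, ev, n);
  const size_t cap = s > 0 ? (size_t)s : (size_t)-1;

  std::vector<size_t> uni((size_t)n * n, 0), shared((size_t)n * n, 0);
  std::vector<char> member(n, 0);
  std::vector<int> ids;
  size_t t = 0;
  while (t < ev.size()) {
    size_t t2 = t;
    ids.clear();
    while (t2 < ev.size() && ev[t2].first == ev[t].first) {
      member[ev[t2].second] = 1;
      ids.push_back(ev[t2].second);
      ++t2;
    }
    // every pair with at least one member gains a union element; pairs with
    // both members may also gain a shared element (subject to the rank cap)
    for (int id : ids) {
      for (int j = 0; j < n; ++j) {
        if (j == id) continue;
        int i = id < j ? id : j, jj = id < j ? j : id;
        if (member[j] && id > j) continue;  // count both-member pairs once
        size_t idx = (size_t)i * n + jj;
        if (member[i] && member[jj] && uni[idx] < cap) ++shared[idx];
        ++uni[idx];
      }
    }
    for (int id : ids) member[id] = 0;
    t = t2;
  }

  Rcpp::NumericMatrix sh(n, n), un(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      size_t idx = (size_t)i * n + j;
      sh(i, j) = sh(j, i) = (double)shared[idx];
      un(i, j) = un(j, i) = (double)uni[idx];
    }
  return Rcpp::List::create(Rcpp::Named("shared") = sh,
                            Rcpp::Named("union_size") = un);
}
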