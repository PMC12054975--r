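#include "core.h"

#include <algorithm>

static void check_sorted(const std::vector<uint64_t> &v, const char *which) {
  for (size_t i = 1; i < v.size(); ++i)
    if (v[i] <= v[i - 1])
      Rcpp::stop("input '%s' is not strictly increasing at element %d", which,
                 (int)(i + 1));
}

static size_t merge_count(const std::vector<uint64_t> &a,
                          const std::vector<uint64_t> &b,
                          size_t ia, size_t ib) {
  size_t n = 0;
  while (ia < a.size() && ib < b.size()) {
    if (a[ia] == b[ib]) { ++n; ++ia; ++ib; }
    else if (a[ia] < b[ib]) ++ia;
    else ++ib;
  }
  return n;
}

// Block intersection: compare fixed-width blocks and advance the list whose
// block maximum is smaller (both on ties); remainders finish via the merge.
// Exactly equivalent to the two-pointer merge on strictly-increasing inputs.
static size_t block_count(const std::vector<uint64_t> &a,
                          const std::vector<uint64_t> &b, size_t w) {
  size_t ia = 0, ib = 0, n = 0;
  while (ia + w <= a.size() && ib + w <= b.size()) {
    const uint64_t amax = a[ia + w - 1], bmax = b[ib + w - 1];
    size_t x = ia, y = ib;
    while (x < ia + w && y < ib + w) {
      if (a[x] == b[y]) { ++n; ++x; ++y; }
      else if (a[x] < b[y]) ++x;
      else ++y;
    }
    if (amax < bmax) ia += w;
    else if (bmax < amax) ib += w;
    else { ia += w; ib += w; }
  }
  return n + merge_count(a, b, ia, ib);
}

// [[Rcpp::export]]
double cpp_intersect_count(Rcpp::CharacterVector a, Rcpp::CharacterVector b,
                           std::string method, int block_width, bool check) {
  std::vector<uint64_t> va = chr2u64(a), vb = chr2u64(b);
  if (check) { check_sorted(va, "a"); check_sorted(vb, "b"); }
  if (method == "merge") return (double)merge_count(va, vb, 0, 0);
  if (method == "block") {
    if (block_width < 1) Rcpp::stop("block width must be >= 1");
    return (double)block_count(va, vb, (size_t)block_width);
  }
  Rcpp::stop("unknown intersection method '%s'", method.c_str());
}
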