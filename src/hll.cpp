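#include "core.h"

static inline int hll_rank(uint64_t hash, int p) {
  // rank = leading zeros of the (64-p)-bit suffix + 1, in [1, 64-p+1]
  uint64_t w = hash << p;
  if (w == 0) return 64 - p + 1;
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_clzll(w) + 1;
#else
  int n = 0;
  while (!(w & 0x8000000000000000ULL)) { w <<= 1; ++n; }
  return n + 1;
#endif
}

static void check_p(int p) {
  if (p < 4 || p > 18) Rcpp::stop("HLL precision p must be in [4, 18]");
}

static void hll_insert(int *regs, int p, uint64_t h) {
  uint64_t bucket = h >> (64 - p);  // top p bits select the register
  int r = hll_rank(h, p);
  if (r > regs[bucket]) regs[bucket] = r;
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_hll_add_hashes(Rcpp::IntegerVector regs,
                                       Rcpp::CharacterVector hashes, int p) {
  check_p(p);
  if (regs.size() != (R_xlen_t)1 << p) Rcpp::stop("register array length must be 2^p");
  Rcpp::IntegerVector out = Rcpp::clone(regs);
  for (R_xlen_t i = 0; i < hashes.size(); ++i)
    hll_insert(INTEGER(out), p, str2u64(CHAR(STRING_ELT(hashes, i))));
  return out;
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_hll_update_seq(Rcpp::IntegerVector regs, std::string seq,
                                       int k, int p, double seed, bool canonical) {
  check_p(p);
  if (regs.size() != (R_xlen_t)1 << p) Rcpp::stop("register array length must be 2^p");
  Rcpp::IntegerVector out = Rcpp::clone(regs);
  uint32_t sd = (uint32_t)seed;
  std::vector<char> buf(k, 0);
  int *r = INTEGER(out);
  for_each_kmer(seq, k, [&](size_t, uint64_t fwd, uint64_t canon) {
    uint64_t code = canonical ? canon : fwd;
    decode_kmer(code, k, buf.data());
    hll_insert(r, p, murmur3_lo64(buf.data(), (size_t)k, sd));
  });
  return out;
}

// Register-wise max. branchfree = arithmetic max (the branch-misprediction
// avoidance contract); otherwise a plain conditional. Both must agree exactly.
// [[Rcpp::export]]
Rcpp::IntegerVector cpp_hll_merge(Rcpp::IntegerVector a, Rcpp::IntegerVector b,
                                  bool branchfree) {
  if (a.size() != b.size()) Rcpp::stop("register arrays differ in length");
  Rcpp::IntegerVector out(a.size());
  const int *pa = INTEGER(a), *pb = INTEGER(b);
  int *po = INTEGER(out);
  if (branchfree) {
    for (R_xlen_t i = 0; i < a.size(); ++i) {
      int x = pa[i], y = pb[i];
      int lt = -(int)(x < y);          // all-ones mask when x < y
      po[i] = x ^ ((x ^ y) & lt);      // branch-free max
    }
  } else {
    for (R_xlen_t i = 0; i < a.size(); ++i)
      po[i] = pa[i] > pb[i] ? pa[i] : pb[i];
  }
  return out;
}
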