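#include "core.h"

static int8_t make_base_code_entry(int c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case 'N': case 'n': return -2;
    default: return -1;
  }
}

static char make_comp_entry(int c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    case 'N': case 'n': return 'N';
    default: return 0;
  }
}

static struct Tables {
  int8_t base[256];
  char comp[256];
  Tables() {
    for (int c = 0; c < 256; ++c) {
      base[c] = make_base_code_entry(c);
      comp[c] = make_comp_entry(c);
    }
  }
} TAB;

const int8_t *const BASE_CODE = TAB.base;
const char *const COMP_CHAR = TAB.comp;
const char CODE_BASE[4] = {'A', 'C', 'G', 'T'};

// [[Rcpp::export]]
std::string cpp_revcomp(std::string seq) {
  // table-lookup complement, branchless per base; a zero entry marks an
  // invalid character and is reported with its 1-based position
  const size_t n = seq.size();
  std::string out(n, 0);
  for (size_t i = 0; i < n; ++i) {
    char c = TAB.comp[(uint8_t)seq[i]];
    out[n - 1 - i] = c;
  }
  for (size_t i = 0; i < n; ++i)
    if (out[i] == 0)
      Rcpp::stop("invalid nucleotide '%c' at position %d (expected A/C/G/T/N)",
                 seq[n - 1 - i], (int)(n - i));
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_extract_kmers(std::string seq, int k, bool canonical) {
  std::vector<int> pos;
  std::vector<uint64_t> code;
  for_each_kmer(seq, k, [&](size_t p, uint64_t fwd, uint64_t canon) {
    pos.push_back((int)p);
    code.push_back(canonical ? canon : fwd);
  });
  return Rcpp::List::create(Rcpp::Named("pos") = Rcpp::IntegerVector(pos.begin(), pos.end()),
                            Rcpp::Named("code") = u642chr(code));
}

// [[Rcpp::export]]
Rcpp::CharacterVector cpp_decode_kmer(Rcpp::CharacterVector codes, int k) {
  if (k < 1 || k > 32) Rcpp::stop("k must be in [1, 32]");
  Rcpp::CharacterVector out(codes.size());
  std::vector<char> buf(k + 1, 0);
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t c = str2u64(CHAR(STRING_ELT(codes, i)));
    if (k < 32 && c >= (1ULL << (2 * k)))
      Rcpp::stop("code %s does not fit a %d-mer", CHAR(STRING_ELT(codes, i)), k);
    decode_kmer(c, k, buf.data());
    out[i] = std::string(buf.data(), k);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::CharacterVector cpp_encode_kmer(Rcpp::CharacterVector kmers) {
  std::vector<uint64_t> out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    size_t len = std::strlen(s);
    if (len < 1 || len > 32) Rcpp::stop("k-mer length must be in [1, 32]");
    uint64_t c = 0;
    for (size_t j = 0; j < len; ++j) {
      int8_t b = TAB.base[(uint8_t)s[j]];
      if (b < 0) Rcpp::stop("invalid base '%c' in k-mer '%s'", s[j], s);
      c = (c << 2) | (uint64_t)b;
    }
    out[i] = c;
  }
  return u642chr(out);
}
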