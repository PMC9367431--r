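// Canonical k-mer counting over {A,C,G,T}; windows containing any other
// character are skipped. Canonical form = lexicographic min of the k-mer
// and its reverse complement under the 2-bit encoding A<C<G<T, which
// coincides with string order. k must be odd (no self-palindromes) and
// k <= 31 so a k-mer packs into 62 bits.
#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;
typedef std::unordered_map<uint64_t, uint32_t> KmerMap;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static void count_sequence(const char* s, R_xlen_t n, int k, KmerMap& map) {
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0; // length of current run of valid bases
  for (R_xlen_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      ++map[canon];
    }
  }
}

// [[Rcpp::export(name = ".cpp_kmer_index")]]
SEXP cpp_kmer_index(CharacterVector seqs, int k) {
  if (k < 1 || k > 31 || k % 2 == 0)
    stop("k must be odd and between 1 and 31");
  KmerMap* map = new KmerMap();
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    count_sequence(s, LENGTH(STRING_ELT(seqs, i)), k, *map);
  }
  XPtr<KmerMap> ptr(map, true);
  ptr.attr("k") = k;
  return ptr;
}

// Histogram of multiplicities: depths above `cap` accumulate in the cap bin.
// [[Rcpp::export(name = ".cpp_kmer_histogram")]]
List cpp_kmer_histogram(SEXP index, int cap) {
  XPtr<KmerMap> ptr(index);
  std::unordered_map<uint32_t, double> h;
  for (KmerMap::const_iterator it = ptr->begin(); it != ptr->end(); ++it) {
    uint32_t d = it->second;
    if (cap > 0 && d > (uint32_t)cap) d = (uint32_t)cap;
    h[d] += 1.0;
  }
  std::vector<uint32_t> depths;
  depths.reserve(h.size());
  for (std::unordered_map<uint32_t, double>::const_iterator it = h.begin();
       it != h.end(); ++it)
    depths.push_back(it->first);
  std::sort(depths.begin(), depths.end());
  IntegerVector depth(depths.size());
  NumericVector species(depths.size());
  for (size_t i = 0; i < depths.size(); ++i) {
    depth[i] = (int)depths[i];
    species[i] = h[depths[i]];
  }
  return List::create(_["depth"] = depth, _["species"] = species);
}

// Per-position multiplicity of the canonical k-mer starting at each position
// of each query sequence; -1 where the window contains a non-ACGT base.
// [[Rcpp::export(name = ".cpp_kmer_lookup")]]
List cpp_kmer_lookup(SEXP index, CharacterVector seqs) {
  XPtr<KmerMap> ptr(index);
  int k = as<int>(ptr.attr("k"));
  const uint64_t mask = ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  List out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, i));
    R_xlen_t m = n >= k ? n - k + 1 : 0;
    IntegerVector mult(m, -1);
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (R_xlen_t j = 0; j < n; ++j) {
      int c = base_code(s[j]);
      if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++run >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        KmerMap::const_iterator it = ptr->find(canon);
        mult[j - k + 1] = it == ptr->end() ? 0 : (int)it->second;
      }
    }
    out[i] = mult;
  }
  return out;
}

// Total number of distinct canonical k-mers held by an index.
// [[Rcpp::export(name = ".cpp_kmer_index_size")]]
double cpp_kmer_index_size(SEXP index) {
  XPtr<KmerMap> ptr(index);
  return (double)ptr->size();
}
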