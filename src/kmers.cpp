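#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <cstring>

using namespace Rcpp;

// 2-bit k-mer machinery shared by the census, the long-read evidence
// accumulator, the exact-occurrence index and the off-target scan.
// k is limited to 31 so a k-mer fits one 64-bit word (default k = 25).

namespace {

inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char bits2base(int b) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  return bases[b & 3];
}

std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bits2base((int)(code & 3ULL));
    code >>= 2;
  }
  return s;
}

// Encode an ACGT string of length k; returns false on any other character.
bool encode_kmer(const char* s, int k, uint64_t& fwd, uint64_t& rc) {
  fwd = 0;
  rc = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    fwd = (fwd << 2) | (uint64_t)b;
    rc |= (uint64_t)(3 - b) << (2 * i);
  }
  return true;
}

// Call f(fwd, rc) for every k-window of s made of ACGT only.
// Windows touching any other character (e.g. N) are skipped.
template <typename F>
void for_each_window(const char* s, int n, int k, F f) {
  uint64_t fwd = 0, rc = 0;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) {
      run = 0;
      fwd = 0;
      rc = 0;
      continue;
    }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++run >= k) f(fwd, rc);
  }
}

void check_k(int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
}

// Map canonical k-mer code -> 0-based index into `kmers`.
std::unordered_map<uint64_t, int> build_query_map(const CharacterVector& kmers,
                                                  int k, bool canonical) {
  std::unordered_map<uint64_t, int> map;
  map.reserve(kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int)std::strlen(s) != k) stop("query k-mer %d does not have length k", (int)(i + 1));
    uint64_t fwd, rc;
    if (!encode_kmer(s, k, fwd, rc)) stop("query k-mer %d contains a non-ACGT character", (int)(i + 1));
    uint64_t key = canonical ? std::min(fwd, rc) : fwd;
    map.emplace(key, (int)i);
  }
  return map;
}

}  // namespace

// Count every k-window of every sequence exactly once. In canonical mode a
// k-mer and its reverse complement share one record keyed by the
// lexicographically smaller of the two.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k, bool canonical) {
  check_k(k);
  std::unordered_map<uint64_t, double> tab;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    SEXP el = STRING_ELT(seqs, r);
    if (el == NA_STRING) stop("NA sequence at position %d", (int)(r + 1));
    const char* s = CHAR(el);
    int n = (int)std::strlen(s);
    for_each_window(s, n, k, [&](uint64_t fwd, uint64_t rc) {
      uint64_t key = canonical ? std::min(fwd, rc) : fwd;
      tab[key] += 1.0;
    });
  }
  R_xlen_t m = (R_xlen_t)tab.size();
  CharacterVector kmer(m);
  NumericVector count(m);
  R_xlen_t i = 0;
  for (const auto& kv : tab) {
    kmer[i] = decode_kmer(kv.first, k);
    count[i] = kv.second;
    ++i;
  }
  return List::create(_["kmer"] = kmer, _["count"] = count);
}

// Per-sequence sums of the female/male weights of its constituent k-mers
// (looked up in the census), plus window bookkeeping. Used for long-read
// chromosome-quotient computation.
// [[Rcpp::export]]
DataFrame cpp_read_evidence(CharacterVector seqs, CharacterVector kmers,
                            NumericVector female, NumericVector male,
                            int k, bool canonical) {
  check_k(k);
  if (kmers.size() != female.size() || kmers.size() != male.size())
    stop("kmers, female and male must have equal length");
  std::unordered_map<uint64_t, int> map = build_query_map(kmers, k, canonical);
  R_xlen_t nseq = seqs.size();
  NumericVector fsum(nseq), msum(nseq);
  IntegerVector nhit(nseq), nwin(nseq);
  for (R_xlen_t r = 0; r < nseq; ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    int n = (int)std::strlen(s);
    double f = 0.0, m = 0.0;
    int hits = 0, wins = 0;
    for_each_window(s, n, k, [&](uint64_t fwd, uint64_t rc) {
      ++wins;
      uint64_t key = canonical ? std::min(fwd, rc) : fwd;
      auto it = map.find(key);
      if (it != map.end()) {
        f += female[it->second];
        m += male[it->second];
        ++hits;
      }
    });
    fsum[r] = f;
    msum[r] = m;
    nhit[r] = hits;
    nwin[r] = wins;
  }
  return DataFrame::create(_["female_evidence"] = fsum, _["male_evidence"] = msum,
                           _["n_kmers_hit"] = nhit, _["n_windows"] = nwin,
                           _["stringsAsFactors"] = false);
}

// Exact-occurrence index: for each query k-mer, the sequences containing it
// and the per-sequence occurrence count. Occurrences are counted on both
// strands (a window matches if it equals the query or its reverse
// complement), which is the canonical-key comparison.
// [[Rcpp::export]]
DataFrame cpp_kmer_read_hits(CharacterVector seqs, CharacterVector kmers, int k) {
  check_k(k);
  std::unordered_map<uint64_t, int> map = build_query_map(kmers, k, true);
  std::vector<int> out_kmer, out_seq, out_count;
  std::unordered_map<int, int> local;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    int n = (int)std::strlen(s);
    local.clear();
    for_each_window(s, n, k, [&](uint64_t fwd, uint64_t rc) {
      uint64_t key = std::min(fwd, rc);
      auto it = map.find(key);
      if (it != map.end()) local[it->second] += 1;
    });
    for (const auto& kv : local) {
      out_kmer.push_back(kv.first + 1);
      out_seq.push_back((int)r + 1);
      out_count.push_back(kv.second);
    }
  }
  return DataFrame::create(_["kmer"] = out_kmer, _["seq"] = out_seq,
                           _["count"] = out_count, _["stringsAsFactors"] = false);
}

// Fraction of a sequence's k-windows present in a reference k-mer set
// (canonical comparison). Used for mitochondrial matching of reads.
// [[Rcpp::export]]
NumericVector cpp_kmerset_fraction(CharacterVector seqs, CharacterVector kmers, int k) {
  check_k(k);
  std::unordered_map<uint64_t, int> map = build_query_map(kmers, k, true);
  R_xlen_t nseq = seqs.size();
  NumericVector frac(nseq);
  for (R_xlen_t r = 0; r < nseq; ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    int n = (int)std::strlen(s);
    int wins = 0, hits = 0;
    for_each_window(s, n, k, [&](uint64_t fwd, uint64_t rc) {
      ++wins;
      if (map.count(std::min(fwd, rc))) ++hits;
    });
    frac[r] = wins > 0 ? (double)hits / (double)wins : NA_REAL;
  }
  return frac;
}

// Off-target scan: occurrences of [spacer][NGG] on either strand of each
// reference sequence with at most max_mm mismatches in the spacer. The PAM
// must remain NGG (it carries no mismatch budget).
// [[Rcpp::export]]
IntegerVector cpp_offtarget_hits(CharacterVector refs, std::string spacer, int max_mm) {
  int sl = (int)spacer.size();
  if (sl < 1) stop("empty spacer");
  for (auto& c : spacer) c = (char)toupper(c);
  std::string rc_spacer(sl, 'A');
  for (int i = 0; i < sl; ++i) {
    int b = base2bits(spacer[i]);
    if (b < 0) stop("spacer contains a non-ACGT character");
    rc_spacer[sl - 1 - i] = bits2base(3 - b);
  }
  int w = sl + 3;  // spacer + NGG
  R_xlen_t nref = refs.size();
  IntegerVector hits(nref);
  for (R_xlen_t r = 0; r < nref; ++r) {
    const char* s = CHAR(STRING_ELT(refs, r));
    int n = (int)std::strlen(s);
    int count = 0;
    for (int i = 0; i + w <= n; ++i) {
      // forward placement: spacer at i..i+sl-1, PAM at i+sl..i+sl+2 (NGG)
      if (toupper(s[i + sl + 1]) == 'G' && toupper(s[i + sl + 2]) == 'G') {
        int mm = 0;
        for (int j = 0; j < sl && mm <= max_mm; ++j)
          if (toupper(s[i + j]) != spacer[j]) ++mm;
        if (mm <= max_mm) ++count;
      }
      // reverse placement: CCN at i..i+2, revcomp(spacer) at i+3..i+w-1
      if (toupper(s[i]) == 'C' && toupper(s[i + 1]) == 'C') {
        int mm = 0;
        for (int j = 0; j < sl && mm <= max_mm; ++j)
          if (toupper(s[i + 3 + j]) != rc_spacer[j]) ++mm;
        if (mm <= max_mm) ++count;
      }
    }
    hits[r] = count;
  }
  return hits;
}
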