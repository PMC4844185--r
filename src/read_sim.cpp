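#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <random>
#include <cmath>
#include <cstring>
#include <vector>
#include <string>
#include <unordered_set>

using namespace Rcpp;

// Self-contained 64-bit Mersenne Twister draws so that identical seeds give
// identical libraries on any platform (std::*_distribution is not portable).
namespace {

struct SimRng {
  std::mt19937_64 eng;
  explicit SimRng(uint64_t seed) : eng(seed) {}
  double unif() { // in [0, 1)
    return (eng() >> 11) * (1.0 / 9007199254740992.0);
  }
  // uniform integer in [0, n); modulo bias is negligible for n << 2^64
  uint64_t below(uint64_t n) { return eng() % n; }
  double norm(double mean, double sd) {
    double u1 = 0.0;
    while (u1 <= 0.0) u1 = unif();
    double u2 = unif();
    return mean + sd * std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  // index of next error position >= 0 under per-base rate p (geometric skip)
  long next_gap(double log1mp) {
    double u = 0.0;
    while (u <= 0.0) u = unif();
    return (long)std::floor(std::log(u) / log1mp);
  }
};

const char BASES[4] = {'A', 'C', 'G', 'T'};

inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

inline int base_index(char c) {
  switch (c) {
    case 'A': case 'a': return 0; case 'C': case 'c': return 1;
    case 'G': case 'g': return 2; case 'T': case 't': return 3;
    default: return -1;
  }
}

inline void add_errors(char* s, int len, double rate, double log1mp, SimRng& rng) {
  if (rate <= 0) return;
  long b = rng.next_gap(log1mp);
  while (b < len) {
    int bi = base_index(s[b]);
    if (bi >= 0) s[b] = BASES[(bi + 1 + (int)rng.below(3)) % 4];
    b += 1 + rng.next_gap(log1mp);
  }
}

} // namespace

// Draw paired-end fragments from a set of scaffolds.
//
// weights: per-scaffold sampling weight per bp (already includes the
// enrichment fold for planted scaffolds in a treatment library and zeroes
// for excluded scaffolds); the effective scaffold weight is weight * length.
// Duplicates are exact re-emissions (sequence and origin) of earlier pairs,
// appended after the originals; dup_of records the 1-based source index.
// Mate sequences are returned as two concatenated blobs of n * read_len
// characters (one string per mate file), which keeps allocation linear
// instead of creating millions of short R strings.
// [[Rcpp::export]]
List cpp_simulate_fragments(CharacterVector seqs, CharacterVector scaf_names,
                            NumericVector weights, int n_fragments,
                            int read_len, double frag_mean, double frag_sd,
                            double error_rate, double dup_rate, double seed,
                            bool make_ids) {
  const int ns = seqs.size();
  if (ns != weights.size() || ns != scaf_names.size())
    stop("scaffold vectors of unequal length");
  std::vector<const char*> sp(ns);
  std::vector<long> slen(ns);
  std::vector<double> cumw(ns);
  double tot = 0.0;
  for (int i = 0; i < ns; ++i) {
    sp[i] = CHAR(STRING_ELT(seqs, i));
    slen[i] = LENGTH(STRING_ELT(seqs, i));
    double w = weights[i] * (double)slen[i];
    tot += (w > 0 ? w : 0);
    cumw[i] = tot;
  }
  if (tot <= 0) stop("no scaffold has positive sampling weight");

  SimRng rng((uint64_t)seed);
  const double log1mp = (error_rate > 0) ? std::log(1.0 - error_rate) : 0.0;
  int n_dup = (int)std::floor(dup_rate * n_fragments + 0.5);
  int n_orig = n_fragments - n_dup;
  if (n_orig < 1) stop("duplicate_rate leaves no original fragments");

  SEXP b1 = PROTECT(Rf_allocVector(RAWSXP, (R_xlen_t)n_fragments * read_len));
  SEXP b2 = PROTECT(Rf_allocVector(RAWSXP, (R_xlen_t)n_fragments * read_len));
  char* blob1 = (char*)RAW(b1);
  char* blob2 = (char*)RAW(b2);
  SEXP id = PROTECT(make_ids ? Rf_allocVector(STRSXP, n_fragments) : R_NilValue);
  IntegerVector o_scaf(n_fragments), o_start(n_fragments), o_end(n_fragments),
      o_dup(n_fragments);
  CharacterVector o_strand(n_fragments);
  SEXP plus_chr = PROTECT(Rf_mkChar("+"));
  SEXP minus_chr = PROTECT(Rf_mkChar("-"));
  std::unordered_set<uint64_t> spans;
  std::vector<int> per_scaf_pairs(ns, 0);
  std::vector<int> per_scaf_distinct(ns, 0);
  char namebuf[256];

  for (int i = 0; i < n_orig; ++i) {
    double u = rng.unif() * tot;
    int lo = 0, hi = ns - 1;
    while (lo < hi) { int mid = (lo + hi) / 2; if (cumw[mid] <= u) lo = mid + 1; else hi = mid; }
    int s = lo;
    long L = slen[s];
    // truncated normal fragment length on [2*read_len, L]
    double flo = 2.0 * read_len, fhi = (double)L;
    long flen = -1;
    for (int t = 0; t < 200; ++t) {
      double f = rng.norm(frag_mean, frag_sd);
      if (f >= flo && f <= fhi) { flen = (long)std::floor(f + 0.5); break; }
    }
    if (flen < 0) flen = (long)std::min(fhi, std::max(flo, frag_mean));
    if (flen > L) flen = L;
    long start = (L - flen > 0) ? (long)rng.below((uint64_t)(L - flen + 1)) : 0;
    long end = start + flen;
    bool plus = rng.below(2) == 0;

    // mate 1 reads from the fragment's 5' end on its strand
    const char* sq = sp[s];
    char* m1 = &blob1[(size_t)i * read_len];
    char* m2 = &blob2[(size_t)i * read_len];
    if (plus) {
      for (int b = 0; b < read_len; ++b) m1[b] = sq[start + b];
      for (int b = 0; b < read_len; ++b) m2[b] = comp(sq[end - 1 - b]);
    } else {
      for (int b = 0; b < read_len; ++b) m1[b] = comp(sq[end - 1 - b]);
      for (int b = 0; b < read_len; ++b) m2[b] = sq[start + b];
    }
    add_errors(m1, read_len, error_rate, log1mp, rng);
    add_errors(m2, read_len, error_rate, log1mp, rng);
    if (make_ids) {
      int nl = std::snprintf(namebuf, sizeof(namebuf), "frag%07d|%s|%ld|%ld|%c|0",
                             i + 1, CHAR(STRING_ELT(scaf_names, s)), start, end,
                             plus ? '+' : '-');
      SET_STRING_ELT(id, i, Rf_mkCharLen(namebuf, nl));
    }
    o_scaf[i] = s + 1; o_start[i] = (int)start; o_end[i] = (int)end;
    SET_STRING_ELT(o_strand, i, plus ? plus_chr : minus_chr);
    o_dup[i] = 0;
    per_scaf_pairs[s]++;
    uint64_t key = ((uint64_t)s << 34) | ((uint64_t)start << 17) |
                   ((uint64_t)flen << 1) | (plus ? 1u : 0u);
    if (spans.insert(key).second) per_scaf_distinct[s]++;
  }

  for (int j = 0; j < n_dup; ++j) {
    int i = n_orig + j;
    int src = (int)rng.below((uint64_t)n_orig); // 0-based source
    std::memcpy(&blob1[(size_t)i * read_len], &blob1[(size_t)src * read_len], read_len);
    std::memcpy(&blob2[(size_t)i * read_len], &blob2[(size_t)src * read_len], read_len);
    if (make_ids) {
      int nl = std::snprintf(namebuf, sizeof(namebuf), "frag%07d|%s|%d|%d|%c|%d",
                             i + 1, CHAR(STRING_ELT(scaf_names, o_scaf[src] - 1)),
                             o_start[src], o_end[src],
                             CHAR(STRING_ELT(o_strand, src))[0], src + 1);
      SET_STRING_ELT(id, i, Rf_mkCharLen(namebuf, nl));
    }
    o_scaf[i] = o_scaf[src]; o_start[i] = o_start[src]; o_end[i] = o_end[src];
    SET_STRING_ELT(o_strand, i, STRING_ELT(o_strand, src));
    o_dup[i] = src + 1;
    per_scaf_pairs[o_scaf[src] - 1]++;
  }

  List out = List::create(
      _["id"] = id,
      _["blob1"] = b1, _["blob2"] = b2,
      _["origin_scaffold"] = o_scaf, _["origin_start"] = o_start,
      _["origin_end"] = o_end, _["origin_strand"] = o_strand,
      _["dup_of"] = o_dup,
      _["n_pairs"] = n_fragments, _["n_original"] = n_orig,
      _["n_duplicates"] = n_dup,
      _["n_distinct_spans"] = (int)spans.size(),
      _["per_scaffold_pairs"] = IntegerVector(per_scaf_pairs.begin(), per_scaf_pairs.end()),
      _["per_scaffold_distinct"] = IntegerVector(per_scaf_distinct.begin(), per_scaf_distinct.end()));
  UNPROTECT(5);
  return out;
}
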