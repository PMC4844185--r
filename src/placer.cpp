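#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Exact k-mer seeded paired-end placer.
//
// Seeds: (max_mismatches + 1) disjoint k-mers per mate (pigeonhole: at least
// one seed is error-free whenever the mate matches a locus with no more than
// max_mismatches substitutions), each looked up in a sorted (kmer, position)
// index of the concatenated genome. Every seed hit proposes a mate start,
// verified by 2-bit-packed XOR/popcount comparison (a byte-wise fallback
// handles ambiguity codes).

namespace {

inline int base2(char c) {
  switch (c) {
    case 'A': case 'a': return 0; case 'C': case 'c': return 1;
    case 'G': case 'g': return 2; case 'T': case 't': return 3;
    default: return -1;
  }
}

const uint64_t ODD_MASK = 0x5555555555555555ULL;

inline int mm_count(uint64_t x) {
  return __builtin_popcountll((x | (x >> 1)) & ODD_MASK);
}

struct PackedSeq {
  std::vector<uint8_t> bytes;   // 0..3, 4 = ambiguous
  std::vector<uint64_t> words;  // 2 bits per base, base j at bits 2*(j%32)
  bool has_amb = false;
  void load(const char* s, long n) {
    bytes.resize(n);
    words.assign((n + 31) / 32 + 1, 0ULL);
    has_amb = false;
    for (long j = 0; j < n; ++j) {
      int b = base2(s[j]);
      if (b < 0) { bytes[j] = 4; has_amb = true; b = 0; }
      else bytes[j] = (uint8_t)b;
      words[j >> 5] |= ((uint64_t)b) << (2 * (j & 31));
    }
  }
  void load_revcomp(const PackedSeq& o) {
    long n = (long)o.bytes.size();
    bytes.resize(n);
    words.assign((n + 31) / 32 + 1, 0ULL);
    has_amb = o.has_amb;
    for (long j = 0; j < n; ++j) {
      uint8_t b = o.bytes[n - 1 - j];
      b = (b > 3) ? 4 : (uint8_t)(3 - b);
      bytes[j] = b;
      words[j >> 5] |= ((uint64_t)(b > 3 ? 0 : b)) << (2 * (j & 31));
    }
  }
};

struct KmerIndex {
  PackedSeq g;
  std::vector<long> offset;      // scaffold start in the concatenation
  // open-addressing hash table over distinct k-mers; each 16-byte entry
  // (key + run bounds) fits one cache line and points at a run in the
  // position-sorted array `pos`
  struct Entry { uint64_t key; uint32_t start; uint32_t end; };
  std::vector<Entry> htab;       // key == EMPTY marks a free slot
  std::vector<uint32_t> pos;
  uint64_t hmask = 0;
  int k;
  static const uint64_t EMPTY = ~0ULL;

  static uint64_t mix(uint64_t x) { // splitmix64 finalizer
    x += 0x9e3779b97f4a7c15ULL;
    x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
    x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
    return x ^ (x >> 31);
  }

  // positions run for a k-mer key, or (0,0)
  inline std::pair<uint32_t, uint32_t> lookup(uint64_t key) const {
    uint64_t h = mix(key) & hmask;
    while (true) {
      const Entry& e = htab[h];
      if (e.key == key) return {e.start, e.end};
      if (e.key == EMPTY) return {0u, 0u};
      h = (h + 1) & hmask;
    }
  }

  int scaffold_of(long p) const {
    int lo = 0, hi = (int)offset.size() - 2;
    while (lo < hi) { int mid = (lo + hi + 1) / 2; if (offset[mid] <= p) lo = mid; else hi = mid - 1; }
    return lo;
  }

  // extract 32 packed bases starting at global position p
  inline uint64_t window(long p) const {
    long w = p >> 5; int o = 2 * (int)(p & 31);
    uint64_t chunk = g.words[w] >> o;
    if (o) chunk |= g.words[w + 1] << (64 - o);
    return chunk;
  }
};

void build_index(const CharacterVector& seqs, int k, KmerIndex& ix) {
  ix.k = k;
  const int ns = seqs.size();
  long tot = 0;
  ix.offset.resize(ns + 1);
  for (int i = 0; i < ns; ++i) { ix.offset[i] = tot; tot += LENGTH(STRING_ELT(seqs, i)); }
  ix.offset[ns] = tot;
  ix.g.bytes.resize(tot);
  ix.g.words.assign((tot + 31) / 32 + 1, 0ULL);
  for (int i = 0; i < ns; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    long L = ix.offset[i + 1] - ix.offset[i];
    for (long j = 0; j < L; ++j) {
      long p = ix.offset[i] + j;
      int b = base2(s[j]);
      if (b < 0) { ix.g.bytes[p] = 4; ix.g.has_amb = true; b = 0; }
      else ix.g.bytes[p] = (uint8_t)b;
      ix.g.words[p >> 5] |= ((uint64_t)b) << (2 * (p & 31));
    }
  }
  std::vector<std::pair<uint64_t, uint32_t>> tab;
  tab.reserve(tot);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int i = 0; i < ns; ++i) {
    long L = ix.offset[i + 1] - ix.offset[i];
    if (L < k) continue;
    uint64_t key = 0;
    int valid = 0;
    const uint8_t* g = ix.g.bytes.data() + ix.offset[i];
    for (long j = 0; j < L; ++j) {
      uint8_t b = g[j];
      if (b > 3) { valid = 0; key = 0; continue; }
      key = ((key << 2) | b) & mask;
      if (++valid >= k)
        tab.emplace_back(key, (uint32_t)(ix.offset[i] + j - k + 1));
    }
  }
  std::sort(tab.begin(), tab.end());
  ix.pos.resize(tab.size());
  size_t n_unique = 0;
  for (size_t i = 0; i < tab.size(); ++i) {
    ix.pos[i] = tab[i].second;
    if (i == 0 || tab[i].first != tab[i - 1].first) ++n_unique;
  }
  size_t cap = 16;
  while (cap < 2 * n_unique + 1) cap <<= 1;
  ix.hmask = cap - 1;
  ix.htab.assign(cap, KmerIndex::Entry{KmerIndex::EMPTY, 0u, 0u});
  size_t i = 0;
  while (i < tab.size()) {
    size_t j = i;
    while (j < tab.size() && tab[j].first == tab[i].first) ++j;
    uint64_t h = KmerIndex::mix(tab[i].first) & ix.hmask;
    while (ix.htab[h].key != KmerIndex::EMPTY) h = (h + 1) & ix.hmask;
    ix.htab[h] = KmerIndex::Entry{tab[i].first, (uint32_t)i, (uint32_t)j};
    i = j;
  }
}

// mismatches of `read` against the genome at global position p, early exit
inline int verify(const KmerIndex& ix, const PackedSeq& read, long p, int max_mm) {
  const int len = (int)read.bytes.size();
  if (!ix.g.has_amb && !read.has_amb) {
    int mm = 0;
    int full = len >> 5, rem = len & 31;
    for (int c = 0; c < full; ++c) {
      uint64_t diff = read.words[c] ^ ix.window(p + 32L * c);
      mm += mm_count(diff);
      if (mm > max_mm) return mm;
    }
    if (rem) {
      uint64_t m = (1ULL << (2 * rem)) - 1;
      uint64_t diff = (read.words[full] ^ ix.window(p + 32L * full)) & m;
      mm += mm_count(diff);
    }
    return mm;
  }
  int mm = 0;
  const uint8_t* g = ix.g.bytes.data();
  for (int j = 0; j < len; ++j) {
    uint8_t a = read.bytes[j], b = g[p + j];
    if (a != b || a > 3) { if (++mm > max_mm) return mm; }
  }
  return mm;
}

// all genome positions where `read` matches with <= max_mm substitutions
void find_hits(const KmerIndex& ix, const PackedSeq& read, int max_mm,
               std::vector<long>& cand, std::vector<std::pair<long,int>>& out) {
  out.clear(); cand.clear();
  const int len = (int)read.bytes.size();
  const int k = ix.k;
  int nseed = max_mm + 1;
  if ((long)nseed * k > len) nseed = std::max(1, len / k);
  // per-seed runs are position-sorted; k-way merge keeps candidates sorted
  const uint32_t* rs[8]; const uint32_t* re[8]; long roff[8];
  int nr = 0;
  for (int s = 0; s < nseed && s < 8; ++s) {
    int off = s * k;
    if (off + k > len) break;
    uint64_t key = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      if (read.bytes[off + j] > 3) { ok = false; break; }
      key = (key << 2) | read.bytes[off + j];
    }
    if (!ok) continue;
    auto run = ix.lookup(key);
    if (run.second > run.first) {
      rs[nr] = ix.pos.data() + run.first;
      re[nr] = ix.pos.data() + run.second;
      roff[nr] = off;
      ++nr;
    }
  }
  if (nr == 0) return;
  long last = -2;
  while (true) {
    int best = -1; long bp = 0;
    for (int r = 0; r < nr; ++r) {
      if (rs[r] == re[r]) continue;
      long p = (long)*rs[r] - roff[r];
      if (best < 0 || p < bp) { best = r; bp = p; }
    }
    if (best < 0) break;
    ++rs[best];
    if (bp == last || bp < 0) continue;
    last = bp;
    int sc = ix.scaffold_of(bp);
    if (bp + len > ix.offset[sc + 1]) continue; // crosses scaffold boundary
    int mm = verify(ix, read, bp, max_mm);
    if (mm <= max_mm) out.emplace_back(bp, mm);
  }
}

// combine left-mate and right-mate hits (both position-sorted) with a
// two-pointer sweep over the admissible insert window
void pair_hits(const KmerIndex& ix,
               const std::vector<std::pair<long,int>>& left,
               const std::vector<std::pair<long,int>>& right,
               int right_len, int lmax, int max_insert, int read_i,
               char strand, std::vector<int>& o_read, std::vector<int>& o_scaf,
               std::vector<int>& o_start, std::vector<int>& o_end,
               std::vector<char>& o_strand, std::vector<int>& o_mm) {
  if (left.empty() || right.empty()) return;
  size_t j0 = 0;
  for (const auto& a : left) {
    int sc = ix.scaffold_of(a.first);
    long hi_pos = a.first + (long)max_insert - right_len; // last admissible right start
    while (j0 < right.size() && right[j0].first < a.first) ++j0;
    for (size_t j = j0; j < right.size() && right[j].first <= hi_pos; ++j) {
      long span = right[j].first + right_len - a.first;
      if (span < lmax) continue;
      if (right[j].first + right_len > ix.offset[sc + 1]) break; // next scaffold
      o_read.push_back(read_i + 1); o_scaf.push_back(sc + 1);
      o_start.push_back((int)(a.first - ix.offset[sc]));
      o_end.push_back((int)(a.first - ix.offset[sc] + span));
      o_strand.push_back(strand); o_mm.push_back(a.second + right[j].second);
    }
  }
}

} // namespace

// Build a reusable k-mer index over a scaffold set.
// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector scaffolds, int k) {
  if (k < 4 || k > 32) stop("seed k must be in [4, 32]");
  XPtr<KmerIndex> p(new KmerIndex(), true);
  build_index(scaffolds, k, *p);
  return p;
}

// Enumerate all candidate pair placements (proper forward/reverse
// orientation, fragment span within [max(mate lengths), max_insert]).
// Mates arrive as concatenated blobs with per-read lengths. Returns one row
// per candidate: read (1-based pair index), scaffold (1-based), fragment
// start/end (0-based half-open), strand of mate 1, total mismatches.
static const char* blob_ptr(SEXP blob, R_xlen_t* len) {
  if (TYPEOF(blob) == RAWSXP) { *len = XLENGTH(blob); return (const char*)RAW(blob); }
  if (TYPEOF(blob) == STRSXP && XLENGTH(blob) == 1) {
    SEXP c = STRING_ELT(blob, 0);
    *len = XLENGTH(c);
    return CHAR(c);
  }
  stop("mate blob must be a raw vector or a single string");
}

// [[Rcpp::export]]
List cpp_place_pairs(CharacterVector scaffolds, SEXP blob1,
                     IntegerVector lens1, SEXP blob2,
                     IntegerVector lens2, int k, int max_mm, int max_insert,
                     SEXP index) {
  if (lens1.size() != lens2.size()) stop("mate vectors of unequal length");
  if (k < 4 || k > 32) stop("seed k must be in [4, 32]");
  KmerIndex own;
  KmerIndex* ixp = &own;
  if (index != R_NilValue) {
    XPtr<KmerIndex> p(index);
    if (p->k != k) stop("prebuilt index was made with a different seed_k");
    ixp = p.get();
  } else {
    build_index(scaffolds, k, own);
  }
  KmerIndex& ix = *ixp;

  const int n = lens1.size();
  R_xlen_t bl1 = 0, bl2 = 0;
  const char* b1 = blob_ptr(blob1, &bl1);
  const char* b2 = blob_ptr(blob2, &bl2);
  {
    long long t1 = 0, t2 = 0;
    for (int i = 0; i < n; ++i) { t1 += lens1[i]; t2 += lens2[i]; }
    if (t1 != (long long)bl1 || t2 != (long long)bl2)
      stop("mate blob length does not match the sum of read lengths");
  }

  std::vector<int> o_read, o_scaf, o_start, o_end, o_mm;
  std::vector<char> o_strand;
  PackedSeq m1, m2, m1rc, m2rc;
  std::vector<long> scratch;
  std::vector<std::pair<long,int>> h1f, h2r, h2f, h1r;
  long long off1 = 0, off2 = 0;

  for (int i = 0; i < n; ++i) {
    const int l1 = lens1[i], l2 = lens2[i];
    const int lmax = std::max(l1, l2);
    m1.load(b1 + off1, l1); m2.load(b2 + off2, l2);
    off1 += l1; off2 += l2;
    m1rc.load_revcomp(m1); m2rc.load_revcomp(m2);

    // strand '+': mate1 forward (left), mate2 reverse-complemented (right)
    find_hits(ix, m1, max_mm, scratch, h1f);
    find_hits(ix, m2rc, max_mm, scratch, h2r);
    pair_hits(ix, h1f, h2r, l2, lmax, max_insert, i, '+', o_read, o_scaf,
              o_start, o_end, o_strand, o_mm);
    // strand '-': mate2 forward (left), mate1 reverse-complemented (right)
    find_hits(ix, m2, max_mm, scratch, h2f);
    find_hits(ix, m1rc, max_mm, scratch, h1r);
    pair_hits(ix, h2f, h1r, l1, lmax, max_insert, i, '-', o_read, o_scaf,
              o_start, o_end, o_strand, o_mm);
  }

  SEXP strand = PROTECT(Rf_allocVector(STRSXP, o_strand.size()));
  {
    SEXP pc = PROTECT(Rf_mkChar("+")), mc = PROTECT(Rf_mkChar("-"));
    for (size_t i = 0; i < o_strand.size(); ++i)
      SET_STRING_ELT(strand, i, o_strand[i] == '+' ? pc : mc);
    UNPROTECT(2);
  }
  List out = List::create(
      _["read"] = IntegerVector(o_read.begin(), o_read.end()),
      _["scaffold"] = IntegerVector(o_scaf.begin(), o_scaf.end()),
      _["start"] = IntegerVector(o_start.begin(), o_start.end()),
      _["end"] = IntegerVector(o_end.begin(), o_end.end()),
      _["strand"] = strand,
      _["mismatches"] = IntegerVector(o_mm.begin(), o_mm.end()));
  UNPROTECT(1);
  return out;
}
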