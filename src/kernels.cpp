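#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; anything else is invalid and resets the k-mer window
static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Canonical k-mer enumeration over a sequence; calls f(canonical_code) per
// valid window. k <= 31 so 2k bits fit a uint64.
template <typename F>
static void for_each_canonical(const char* s, size_t n, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int filled = 0;
  const int rshift = 2 * (k - 1);
  for (size_t i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { filled = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << rshift);
    if (++filled >= k) f(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export]]
List cpp_kmer_histogram(CharacterVector seqs, int k, int cap) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_map<uint64_t, uint32_t> counts;
  counts.reserve(1 << 24);
  double total = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t n = LENGTH(STRING_ELT(seqs, i));
    for_each_canonical(s, n, k, [&](uint64_t code) {
      ++counts[code];
      total += 1;
    });
  }
  // dense histogram over multiplicities 1..cap (cap bin pools the tail)
  std::vector<double> hist((size_t)cap, 0.0);
  for (auto& kv : counts) {
    uint32_t m = kv.second;
    if ((int)m > cap) m = cap;
    hist[m - 1] += 1;
  }
  int maxm = cap;
  while (maxm > 1 && hist[maxm - 1] == 0) --maxm;
  NumericVector out(maxm);
  for (int i = 0; i < maxm; ++i) out[i] = hist[i];
  return List::create(_["counts"] = out, _["total_kmers"] = total,
                      _["distinct"] = (double)counts.size());
}

// Fraction of the reference's distinct canonical k-mers present in each query
// [[Rcpp::export]]
NumericVector cpp_kmer_containment(std::string ref, CharacterVector queries, int k) {
  std::unordered_set<uint64_t> refset;
  for_each_canonical(ref.c_str(), ref.size(), k, [&](uint64_t code) {
    refset.insert(code);
  });
  NumericVector out(queries.size());
  if (refset.empty()) { out.fill(NA_REAL); return out; }
  for (R_xlen_t i = 0; i < queries.size(); ++i) {
    std::unordered_set<uint64_t> seen;
    const char* s = CHAR(STRING_ELT(queries, i));
    size_t n = LENGTH(STRING_ELT(queries, i));
    for_each_canonical(s, n, k, [&](uint64_t code) {
      if (refset.count(code)) seen.insert(code);
    });
    out[i] = (double)seen.size() / (double)refset.size();
  }
  return out;
}

// Per-base depth from alignment records. tid is a 1-based index into the
// contig table; pos0 0-based leftmost reference position; CIGAR M/=/X add
// depth, D/N consume reference without depth, I/S/H/P consume none.
// [[Rcpp::export]]
List cpp_depth(IntegerVector tid, IntegerVector pos0, CharacterVector cigar,
               IntegerVector contig_len) {
  int nc = contig_len.size();
  std::vector<IntegerVector> depths;
  depths.reserve(nc);
  for (int i = 0; i < nc; ++i) depths.push_back(IntegerVector(contig_len[i]));
  int skipped = 0;
  for (R_xlen_t r = 0; r < tid.size(); ++r) {
    int t = tid[r] - 1;
    if (t < 0 || t >= nc) { ++skipped; continue; }
    const char* cg = CHAR(STRING_ELT(cigar, r));
    int len = contig_len[t];
    long p = pos0[r];
    IntegerVector& d = depths[t];
    long num = 0;
    bool ok = true, any = false;
    for (const char* c = cg; *c; ++c) {
      if (*c >= '0' && *c <= '9') { num = num * 10 + (*c - '0'); continue; }
      if (num == 0 && *c != '*') { ok = false; break; }
      switch (*c) {
      case 'M': case '=': case 'X': {
        long from = p < 0 ? 0 : p, to = p + num > len ? len : p + num;
        for (long q = from; q < to; ++q) d[q] += 1;
        p += num; any = true; break;
      }
      case 'D': case 'N': p += num; any = true; break;
      case 'I': case 'S': case 'H': case 'P': break;
      case '*': break;
      default: ok = false;
      }
      if (!ok) break;
      num = 0;
    }
    if (!ok || !any) {
      // roll back nothing: malformed records are rare and skipped whole
      // (re-walk to subtract what was added before the bad op)
      const char* c2 = cg; long p2 = pos0[r]; long n2 = 0;
      for (; c2 != nullptr && *c2; ++c2) {
        if (*c2 >= '0' && *c2 <= '9') { n2 = n2 * 10 + (*c2 - '0'); continue; }
        if (n2 == 0 && *c2 != '*') break;
        bool stop_here = false;
        switch (*c2) {
        case 'M': case '=': case 'X': {
          long from = p2 < 0 ? 0 : p2, to = p2 + n2 > len ? len : p2 + n2;
          for (long q = from; q < to; ++q) d[q] -= 1;
          p2 += n2; break;
        }
        case 'D': case 'N': p2 += n2; break;
        case 'I': case 'S': case 'H': case 'P': break;
        case '*': break;
        default: stop_here = true;
        }
        if (stop_here) break;
        n2 = 0;
      }
      ++skipped;
    }
  }
  List out(nc);
  for (int i = 0; i < nc; ++i) out[i] = depths[i];
  return List::create(_["depth"] = out, _["skipped"] = skipped);
}

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3 - (code & 3));
    code >>= 2;
  }
  return rc;
}

// Shared-k-mer seeding: for each fragment, vote over (reference contig,
// strand, diagonal) and return the winner. Diagonal = ref_pos - frag_pos on
// the fragment's mapping orientation. Heavily repeated reference k-mers
// (> occ_cap positions) are masked from the index.
// [[Rcpp::export]]
IntegerMatrix cpp_seed_best(CharacterVector fragments, CharacterVector refs,
                            int k, int stride, int occ_cap) {
  struct Hit { int32_t ref; int32_t pos; };
  std::unordered_map<uint64_t, std::vector<Hit>> index;
  index.reserve(1 << 20);
  for (R_xlen_t i = 0; i < refs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(refs, i));
    size_t n = LENGTH(STRING_ELT(refs, i));
    const uint64_t mask = (1ULL << (2 * k)) - 1;
    uint64_t fwd = 0; int filled = 0;
    for (size_t j = 0; j < n; ++j) {
      int b = base2bit(s[j]);
      if (b < 0) { filled = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      if (++filled >= k) {
        auto& v = index[fwd];
        if ((int)v.size() <= occ_cap)
          v.push_back({(int32_t)i, (int32_t)(j - k + 1)});
      }
    }
  }
  IntegerMatrix out(fragments.size(), 4); // ref(1-based|0), strand(+1/-1), diag, votes
  for (R_xlen_t f = 0; f < fragments.size(); ++f) {
    const char* s = CHAR(STRING_ELT(fragments, f));
    int n = LENGTH(STRING_ELT(fragments, f));
    std::unordered_map<uint64_t, int> votes; // packed key
    const uint64_t mask = (1ULL << (2 * k)) - 1;
    uint64_t fwd = 0; int filled = 0;
    int best = 0; uint64_t bestkey = 0;
    for (int j = 0; j < n; ++j) {
      int b = base2bit(s[j]);
      if (b < 0) { filled = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      ++filled;
      int qpos = j - k + 1;
      if (filled < k || (qpos % stride) != 0) continue;
      // forward-strand lookup
      auto it = index.find(fwd);
      if (it != index.end() && (int)it->second.size() <= occ_cap) {
        for (auto& h : it->second) {
          int diag = h.pos - qpos;
          uint64_t key = ((uint64_t)(h.ref + 1) << 33) | (1ULL << 32) |
                         (uint32_t)(diag + (1 << 30));
          int v = ++votes[key];
          if (v > best) { best = v; bestkey = key; }
        }
      }
      // reverse-strand lookup: fragment k-mer's reverse complement on ref
      uint64_t rc = revcomp_code(fwd, k);
      auto it2 = index.find(rc);
      if (it2 != index.end() && (int)it2->second.size() <= occ_cap) {
        for (auto& h : it2->second) {
          // anti-diagonal: ref_pos + qpos is constant for a rc match
          int diag = h.pos + qpos;
          uint64_t key = ((uint64_t)(h.ref + 1) << 33) | (0ULL << 32) |
                         (uint32_t)(diag + (1 << 30));
          int v = ++votes[key];
          if (v > best) { best = v; bestkey = key; }
        }
      }
    }
    if (best == 0) {
      out(f, 0) = 0; out(f, 1) = 0; out(f, 2) = NA_INTEGER; out(f, 3) = 0;
    } else {
      out(f, 0) = (int)(bestkey >> 33);
      out(f, 1) = ((bestkey >> 32) & 1) ? 1 : -1;
      out(f, 2) = (int)((uint32_t)(bestkey & 0xFFFFFFFFULL)) - (1 << 30);
      out(f, 3) = best;
    }
  }
  return out;
}

// I.i.d. substitution errors at `rate`, drawing from R's RNG so results
// respect set.seed(). Substituted base is always different from the original.
// [[Rcpp::export]]
CharacterVector cpp_mutate(CharacterVector seqs, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  RNGScope scope;
  CharacterVector out(seqs.size());
  std::string buf;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t n = LENGTH(STRING_ELT(seqs, i));
    buf.assign(s, n);
    if (rate > 0) {
      int nmut = (int)R::rbinom((double)n, rate);
      for (int m = 0; m < nmut; ++m) {
        size_t p = (size_t)(R::unif_rand() * n);
        if (p >= n) p = n - 1;
        int cur = base2bit(buf[p]);
        int shift = 1 + (int)(R::unif_rand() * 3);
        if (shift > 3) shift = 3;
        buf[p] = bases[cur < 0 ? shift - 1 : (cur + shift) & 3];
      }
    }
    out[i] = buf;
  }
  return out;
}
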