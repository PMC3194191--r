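// FM-index over DNA text with d-mismatch locate, plus the segment-extension
// driver that consumes it. One index class serves both the reference (read
// mapping) and the concatenated insertion-read set R' (anchored search).
//
// d-mismatch locate uses pigeonhole seeding: the pattern is split into d+1
// chunks, each chunk is searched exactly by FM backward search, and candidate
// placements are verified by direct comparison against the stored text. For
// substitution-only matching this returns exactly the set a bounded
// backtracking search would, at a fraction of the cost on high-duplication
// read sets.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <cstring>
#include <deque>
#include <algorithm>

using namespace Rcpp;

// codes: 0 = sentinel, 1..4 = ACGT, 5 = N (never matches anything, incl. N)
static const int SIGMA = 6;
static const char DECODE[7] = "$ACGTN";

static inline uint8_t base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 3;
    case 'T': case 't': return 4;
    default: return 5;
  }
}

// SA-IS suffix array construction (linear time); the text gets a unique
// smallest sentinel appended internally
static void sais_int(const int32_t* s, int32_t* SA, int n, int K) {
  if (n == 1) { SA[0] = 0; return; }
  std::vector<uint8_t> t(n);
  t[n - 1] = 1;
  for (int i = n - 2; i >= 0; i--)
    t[i] = (s[i] < s[i + 1] || (s[i] == s[i + 1] && t[i + 1])) ? 1 : 0;
  auto isLMS = [&](int i) { return i > 0 && t[i] && !t[i - 1]; };
  std::vector<int32_t> bkt(K);
  auto getBuckets = [&](bool end) {
    std::fill(bkt.begin(), bkt.end(), 0);
    for (int i = 0; i < n; i++) bkt[s[i]]++;
    int sum = 0;
    for (int i = 0; i < K; i++) {
      sum += bkt[i];
      bkt[i] = end ? sum : sum - bkt[i];
    }
  };
  auto induce = [&]() {
    getBuckets(false);
    for (int i = 0; i < n; i++) {
      int j = SA[i] - 1;
      if (SA[i] > 0 && !t[j]) SA[bkt[s[j]]++] = j;
    }
    getBuckets(true);
    for (int i = n - 1; i >= 0; i--) {
      int j = SA[i] - 1;
      if (SA[i] > 0 && t[j]) SA[--bkt[s[j]]] = j;
    }
  };
  getBuckets(true);
  std::fill(SA, SA + n, -1);
  for (int i = 1; i < n; i++)
    if (isLMS(i)) SA[--bkt[s[i]]] = i;
  induce();
  int n1 = 0;
  for (int i = 0; i < n; i++)
    if (SA[i] > 0 && isLMS(SA[i])) SA[n1++] = SA[i];
  std::fill(SA + n1, SA + n, -1);
  int name = 0, prev = -1;
  for (int i = 0; i < n1; i++) {
    int pos = SA[i];
    bool diff = false;
    for (int d = 0; d < n; d++) {
      if (prev == -1 || s[pos + d] != s[prev + d] || t[pos + d] != t[prev + d]) {
        diff = true;
        break;
      } else if (d > 0 && (isLMS(pos + d) || isLMS(prev + d))) {
        break;
      }
    }
    if (diff) {
      name++;
      prev = pos;
    }
    SA[n1 + pos / 2] = name - 1;
  }
  for (int i = n - 1, j = n - 1; i >= n1; i--)
    if (SA[i] >= 0) SA[j--] = SA[i];
  int32_t* SA1 = SA;
  int32_t* s1 = SA + n - n1;
  if (name < n1)
    sais_int(s1, SA1, n1, name);
  else
    for (int i = 0; i < n1; i++) SA1[s1[i]] = i;
  for (int i = 1, j = 0; i < n; i++)
    if (isLMS(i)) s1[j++] = i;
  for (int i = 0; i < n1; i++) SA1[i] = s1[SA1[i]];
  getBuckets(true);
  std::fill(SA + n1, SA + n, -1);
  for (int i = n1 - 1; i >= 0; i--) {
    int j = SA[i];
    SA[i] = -1;
    SA[--bkt[s[j]]] = j;
  }
  induce();
}

struct FMIndex {
  std::vector<uint8_t> txt;    // coded text (no sentinel)
  std::vector<char> chars;     // decoded text, for overlap scoring
  std::vector<int32_t> sa;     // suffix array over txt + sentinel
  std::vector<int64_t> Carr;   // Carr[c] = # symbols < c in txt + sentinel
  // 2-bit-packed BWT with popcount rank: per 64-symbol block, low/high code
  // bits and an ACGT-validity mask, plus per-symbol count checkpoints
  std::vector<uint64_t> blo, bhi, bvalid;
  std::vector<int32_t> cp;     // 4 checkpoints per block (codes 1..4)
  int64_t nx;                  // extended length = |txt| + 1

  void build(const std::string& text) {
    txt.resize(text.size());
    for (size_t i = 0; i < text.size(); i++) txt[i] = base_code(text[i]);
    chars.resize(text.size());
    for (size_t i = 0; i < text.size(); i++) chars[i] = DECODE[txt[i]];
    nx = (int64_t)txt.size() + 1;
    std::vector<int32_t> s32(nx);
    for (int64_t i = 0; i < nx - 1; i++) s32[i] = txt[i];
    s32[nx - 1] = 0;
    sa.resize(nx);
    sais_int(s32.data(), sa.data(), (int)nx, SIGMA);
    std::vector<int64_t> cnt(SIGMA, 0);
    for (int64_t i = 0; i < nx - 1; i++) cnt[txt[i]]++;
    cnt[0]++;  // sentinel
    Carr.assign(SIGMA + 1, 0);
    for (int c = 0; c < SIGMA; c++) Carr[c + 1] = Carr[c] + cnt[c];
    const int64_t nblk = (nx + 63) / 64;
    blo.assign(nblk, 0);
    bhi.assign(nblk, 0);
    bvalid.assign(nblk, 0);
    cp.assign((nblk + 1) * 4, 0);
    int32_t run[4] = {0, 0, 0, 0};
    for (int64_t i = 0; i < nx; i++) {
      if (i % 64 == 0)
        for (int c = 0; c < 4; c++) cp[(i / 64) * 4 + c] = run[c];
      int64_t j = sa[i] == 0 ? nx - 1 : sa[i] - 1;
      uint8_t b = (j == nx - 1) ? 0 : txt[j];  // BWT symbol
      if (b >= 1 && b <= 4) {
        uint8_t q = b - 1;
        blo[i / 64] |= (uint64_t)(q & 1) << (i % 64);
        bhi[i / 64] |= (uint64_t)(q >> 1) << (i % 64);
        bvalid[i / 64] |= (uint64_t)1 << (i % 64);
        run[q]++;
      }
    }
    for (int c = 0; c < 4; c++) cp[nblk * 4 + c] = run[c];
  }

  // occurrences of code c (1..4) in bwt[0..i)
  inline int64_t rank(int c, int64_t i) const {
    const int64_t blk = i >> 6;
    const int off = (int)(i & 63);
    int64_t r = cp[blk * 4 + (c - 1)];
    if (off) {
      const uint8_t q = c - 1;
      uint64_t m = bvalid[blk];
      m &= (q & 1) ? blo[blk] : ~blo[blk];
      m &= (q >> 1) ? bhi[blk] : ~bhi[blk];
      m &= (off == 64) ? ~0ULL : ((1ULL << off) - 1);
      r += __builtin_popcountll(m);
    }
    return r;
  }

  // exact backward search over coded pattern; empty interval if any code > 4
  bool search_exact(const uint8_t* pat, int m, int64_t& lo, int64_t& hi) const {
    lo = 0;
    hi = nx;
    for (int j = m - 1; j >= 0; j--) {
      int c = pat[j];
      if (c < 1 || c > 4) return false;
      lo = Carr[c] + rank(c, lo);
      hi = Carr[c] + rank(c, hi);
      if (lo >= hi) return false;
    }
    return true;
  }

// all placements of pattern with <= d substitutions (N never matches)
  void locate_mm(const uint8_t* pat, int m, int d,
                 std::vector<int32_t>& pos_out, std::vector<int>& mm_out) const {
    const int64_t n = nx - 1;  // true text length
    if (m == 0 || m > n) return;
    std::vector<int32_t> cand;
    int nchunk = d + 1;
    int base = m / nchunk, rem = m % nchunk;
    int off = 0;
    for (int k = 0; k < nchunk; k++) {
      int len = base + (k < rem ? 1 : 0);
      if (len > 0) {
        int64_t lo, hi;
        if (search_exact(pat + off, len, lo, hi)) {
          for (int64_t i = lo; i < hi; i++) {
            int64_t p = (int64_t)sa[i] - off;
            if (p >= 0 && p + m <= n) cand.push_back((int32_t)p);
          }
        }
      }
      off += len;
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    for (int32_t p : cand) {
      int mm = 0;
      for (int j = 0; j < m; j++) {
        uint8_t a = pat[j], b = txt[p + j];
        if (a != b || a == 5 || b == 5) {
          if (++mm > d) break;
        }
      }
      if (mm <= d) {
        pos_out.push_back(p);
        mm_out.push_back(mm);
      }
    }
  }
};

static std::vector<uint8_t> encode(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); i++) v[i] = base_code(s[i]);
  return v;
}

// ---------------------------------------------------------------- R bindings

// [[Rcpp::export(name = ".fm_build_cpp")]]
SEXP fm_build_cpp(std::string text) {
  if (text.empty()) stop("cannot index an empty sequence");
  FMIndex* fm = new FMIndex();
  fm->build(text);
  XPtr<FMIndex> xp(fm, true);
  return xp;
}

// [[Rcpp::export(name = ".fm_length_cpp")]]
double fm_length_cpp(SEXP xp_) {
  XPtr<FMIndex> xp(xp_);
  return (double)(xp->nx - 1);
}

// [[Rcpp::export(name = ".fm_locate_cpp")]]
List fm_locate_cpp(SEXP xp_, std::string pattern, int d) {
  XPtr<FMIndex> xp(xp_);
  if (d < 0 || d > 3) stop("mismatch budget d must be between 0 and 3");
  std::vector<uint8_t> pat = encode(pattern);
  std::vector<int32_t> pos;
  std::vector<int> mm;
  xp->locate_mm(pat.data(), (int)pat.size(), d, pos, mm);
  return List::create(_["pos"] = IntegerVector(pos.begin(), pos.end()),
                      _["mm"] = IntegerVector(mm.begin(), mm.end()));
}

// batch-map mates against a reference index, both strands (the reverse
// complement is formed internally)
// [[Rcpp::export(name = ".fm_map_batch_cpp")]]
List fm_map_batch_cpp(SEXP xp_, CharacterVector fwd, int d) {
  XPtr<FMIndex> xp(xp_);
  if (d < 0 || d > 3) stop("mismatch budget d must be between 0 and 3");
  std::vector<int32_t> idx, pos;
  std::vector<int> strand, mm;
  std::vector<int32_t> p1;
  std::vector<int> m1;
  std::vector<uint8_t> pat, patrc;
  for (int i = 0; i < fwd.size(); i++) {
    const char* sq = CHAR(STRING_ELT(fwd, i));
    int m = (int)std::strlen(sq);
    pat.resize(m);
    patrc.resize(m);
    for (int j = 0; j < m; j++) pat[j] = base_code(sq[j]);
    for (int j = 0; j < m; j++) {
      uint8_t c = pat[m - 1 - j];
      patrc[j] = (c >= 1 && c <= 4) ? (uint8_t)(5 - c) : c;  // A<->T, C<->G
    }
    for (int s = 0; s < 2; s++) {
      p1.clear();
      m1.clear();
      xp->locate_mm(s == 0 ? pat.data() : patrc.data(), m, d, p1, m1);
      for (size_t k = 0; k < p1.size(); k++) {
        idx.push_back(i + 1);
        pos.push_back(p1[k]);
        strand.push_back(s);
        mm.push_back(m1[k]);
      }
    }
  }
  return List::create(_["idx"] = IntegerVector(idx.begin(), idx.end()),
                      _["pos"] = IntegerVector(pos.begin(), pos.end()),
                      _["strand"] = IntegerVector(strand.begin(), strand.end()),
                      _["mm"] = IntegerVector(mm.begin(), mm.end()));
}

// search within concatenated fixed-length reads; drops boundary-crossers
// [[Rcpp::export(name = ".ri_search_cpp")]]
List ri_search_cpp(SEXP xp_, int l, std::string pattern, int d) {
  XPtr<FMIndex> xp(xp_);
  if (d < 0 || d > 3) stop("mismatch budget d must be between 0 and 3");
  int m = (int)pattern.size();
  std::vector<uint8_t> pat = encode(pattern);
  std::vector<int32_t> pos;
  std::vector<int> mm;
  xp->locate_mm(pat.data(), m, d, pos, mm);
  std::vector<int32_t> sid, off;
  std::vector<int> mm2;
  for (size_t k = 0; k < pos.size(); k++) {
    int32_t o = pos[k] % l;
    if (o + m <= l) {  // fully inside one read
      sid.push_back(pos[k] / l);
      off.push_back(o);
      mm2.push_back(mm[k]);
    }
  }
  return List::create(_["sid"] = IntegerVector(sid.begin(), sid.end()),
                      _["off"] = IntegerVector(off.begin(), off.end()),
                      _["mm"] = IntegerVector(mm2.begin(), mm2.end()));
}

static void anchored_sids(const FMIndex* fm, int l, const char* win, int d,
                          std::vector<int32_t>& out, std::vector<int>* mm_out) {
  std::vector<uint8_t> pat(l);
  for (int j = 0; j < l; j++) pat[j] = base_code(win[j]);
  std::vector<int32_t> pos;
  std::vector<int> mm;
  fm->locate_mm(pat.data(), l, d, pos, mm);
  for (size_t k = 0; k < pos.size(); k++) {
    if (pos[k] % l == 0) {  // whole-mate match anchored at a read start
      out.push_back(pos[k] / l);
      if (mm_out) mm_out->push_back(mm[k]);
    }
  }
}

// anchored search over every length-l substring of the window;
// n_calls reports the number of bwt_search invocations issued
// [[Rcpp::export(name = ".ri_find_anchored_cpp")]]
List ri_find_anchored_cpp(SEXP xp_, int l, std::string window, int d) {
  XPtr<FMIndex> xp(xp_);
  if (d < 0 || d > 3) stop("mismatch budget d must be between 0 and 3");
  int W = (int)window.size();
  std::vector<int32_t> wpos, sid;
  std::vector<int> mm;
  int ncalls = 0;
  for (int s = 0; s + l <= W; s++) {
    ncalls++;
    std::vector<int32_t> hits;
    std::vector<int> hmm;
    anchored_sids(xp.get(), l, window.c_str() + s, d, hits, &hmm);
    for (size_t k = 0; k < hits.size(); k++) {
      wpos.push_back(s);
      sid.push_back(hits[k]);
      mm.push_back(hmm[k]);
    }
  }
  return List::create(_["win_pos"] = IntegerVector(wpos.begin(), wpos.end()),
                      _["sid"] = IntegerVector(sid.begin(), sid.end()),
                      _["mm"] = IntegerVector(mm.begin(), mm.end()),
                      _["n_calls"] = ncalls);
}

// naive engine: Hamming-scan every indexed read against every window substring
// (the pre-index formulation; kept for the runtime-scaling comparison)
// [[Rcpp::export(name = ".ri_find_anchored_naive_cpp")]]
List ri_find_anchored_naive_cpp(SEXP xp_, int l, std::string window, int d) {
  XPtr<FMIndex> xp(xp_);
  int W = (int)window.size();
  int nread = (int)(xp->txt.size() / l);
  std::vector<uint8_t> win = encode(window);
  std::vector<int32_t> wpos, sid;
  std::vector<int> mmv;
  for (int s = 0; s + l <= W; s++) {
    for (int r = 0; r < nread; r++) {
      const uint8_t* rd = xp->txt.data() + (size_t)r * l;
      int mm = 0;
      for (int j = 0; j < l; j++) {
        uint8_t a = win[s + j], b = rd[j];
        if (a != b || a == 5 || b == 5) {
          if (++mm > d) break;
        }
      }
      if (mm <= d) {
        wpos.push_back(s);
        sid.push_back(r);
        mmv.push_back(mm);
      }
    }
  }
  return List::create(_["win_pos"] = IntegerVector(wpos.begin(), wpos.end()),
                      _["sid"] = IntegerVector(sid.begin(), sid.end()),
                      _["mm"] = IntegerVector(mmv.begin(), mmv.end()),
                      _["n_calls"] = std::max(0, W - l + 1));
}

// ----------------------------------------------------------- pair classifier

// labels: 0 orphan, 1 oea, 2 concordant, 3 discordant
// [[Rcpp::export(name = ".classify_pairs_cpp")]]
IntegerVector classify_pairs_cpp(int npairs, IntegerVector pair, IntegerVector mate,
                                 IntegerVector pos, IntegerVector strand,
                                 int l, double dmin, double dmax) {
  std::vector<std::vector<int32_t>> p1(npairs), p2(npairs);
  std::vector<std::vector<int>> s1(npairs), s2(npairs);
  int nh = pair.size();
  for (int i = 0; i < nh; i++) {
    int p = pair[i] - 1;
    if (mate[i] == 1) {
      p1[p].push_back(pos[i]);
      s1[p].push_back(strand[i]);
    } else {
      p2[p].push_back(pos[i]);
      s2[p].push_back(strand[i]);
    }
  }
  IntegerVector lab(npairs);
  for (int p = 0; p < npairs; p++) {
    bool e1 = p1[p].empty(), e2 = p2[p].empty();
    if (e1 && e2) {
      lab[p] = 0;
    } else if (e1 || e2) {
      lab[p] = 1;
    } else {
      bool conc = false;
      for (size_t i = 0; i < p1[p].size() && !conc; i++) {
        for (size_t j = 0; j < p2[p].size() && !conc; j++) {
          if (s1[p][i] == s2[p][j]) continue;
          int32_t fp = s1[p][i] == 0 ? p1[p][i] : p2[p][j];
          int32_t rp = s1[p][i] == 0 ? p2[p][j] : p1[p][i];
          if (rp < fp) continue;
          double span = (double)rp + l - fp;  // outer fragment length
          if (span >= dmin && span <= dmax) conc = true;
        }
      }
      lab[p] = conc ? 2 : 3;
    }
  }
  return lab;
}

// -------------------------------------------------------- extension machinery

// capped mismatch count over len chars, 8 bytes at a time; exact as long as
// neither string contains N (callers take the byte path when one might)
static inline int mm_capped(const char* a, const char* b, int len, int cap) {
  int mm = 0, i = 0;
  for (; i + 8 <= len; i += 8) {
    uint64_t x, y;
    std::memcpy(&x, a + i, 8);
    std::memcpy(&y, b + i, 8);
    uint64_t z = x ^ y;
    if (z) {
      uint64_t t = (z & 0x7F7F7F7F7F7F7F7FULL) + 0x7F7F7F7F7F7F7F7FULL;
      t = (t | z) & 0x8080808080808080ULL;
      mm += __builtin_popcountll(t);
      if (mm > cap) return mm;
    }
  }
  for (; i < len; i++) {
    if (a[i] != b[i] && ++mm > cap) return mm;
  }
  return mm;
}

static inline int mm_capped_n(const char* a, const char* b, int len, int cap) {
  int mm = 0;
  for (int i = 0; i < len; i++) {
    char x = a[i], y = b[i];
    if (x != y || x == 'N' || y == 'N') {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// longest ext in (kappa, l) s.t. mate prefix ~ segment suffix under the
// mismatch-fraction threshold; returns ext or 0, vote char via out param
static int best_ext(const char* mate, int l, const std::string& seq, int pos,
                    int kappa, double tau, char* vote) {
  int emax = std::min(l - 1, pos);
  bool has_n = std::memchr(seq.data() + (pos - emax), 'N', emax) != NULL ||
               std::memchr(mate, 'N', l) != NULL;
  for (int ext = emax; ext > kappa; ext--) {
    int allowed = (int)std::floor((1.0 - tau) * ext + 1e-9);
    const char* suf = seq.data() + (pos - ext);
    int mm = has_n ? mm_capped_n(mate, suf, ext, allowed)
                   : mm_capped(mate, suf, ext, allowed);
    if (mm <= allowed) {
      *vote = mate[ext];
      return ext;
    }
  }
  return 0;
}

// [[Rcpp::export(name = ".compute_ext_cpp")]]
List compute_ext_cpp(std::string mate, std::string segment, int kappa, double tau) {
  char vote = 'N';
  int l = (int)mate.size();
  int ext = best_ext(mate.c_str(), l, segment, (int)segment.size(), kappa, tau, &vote);
  return List::create(_["ext"] = ext, _["vote"] = std::string(1, ext > 0 ? vote : 'N'));
}

struct Vote {
  int32_t pair;
  int ext_mate;   // 0/1: which mate extends
  int orient;     // 0 fwd, 1 rc orientation of the extending string
  int ext;
  char vote;
};

// sliding per-substring anchored-hit cache: the anchor window advances one
// column per consensus position, so only the newest substring needs a fresh
// index search; cloned wholesale on divergence branching
struct AnchorCache {
  int32_t base = 0;  // substring start of lists.front()
  std::deque<std::vector<int32_t>> lists;
};

// strings per pair are laid out [m1+, m1-, m2+, m2-]; sid -> pair = sid/4
static void covering_votes(const FMIndex* fm, int l, const std::string& seq, int pos,
                           int dmin, int dmax, int kappa, int d, double tau,
                           AnchorCache* cache, std::vector<Vote>& votes) {
  int wlo = pos - l - dmax;
  int whi = pos - dmin;  // window [wlo, whi)
  if (wlo < 0) return;
  std::vector<int32_t> sids;
  if (cache) {
    if (cache->lists.empty()) cache->base = wlo;
    while (cache->base < wlo && !cache->lists.empty()) {
      cache->lists.pop_front();
      cache->base++;
    }
    if (cache->lists.empty()) cache->base = wlo;
    while (cache->base + (int32_t)cache->lists.size() <= whi - l) {
      std::vector<int32_t> fresh;
      anchored_sids(fm, l, seq.data() + (cache->base + cache->lists.size()), d,
                    fresh, NULL);
      cache->lists.push_back(std::move(fresh));
    }
    for (int s0 = wlo; s0 + l <= whi; s0++) {
      const std::vector<int32_t>& li = cache->lists[s0 - cache->base];
      sids.insert(sids.end(), li.begin(), li.end());
    }
  } else {
    for (int s0 = wlo; s0 + l <= whi; s0++)
      anchored_sids(fm, l, seq.data() + s0, d, sids, NULL);
  }
  std::sort(sids.begin(), sids.end());
  sids.erase(std::unique(sids.begin(), sids.end()), sids.end());
  // one candidate per (pair, extending mate)
  std::vector<int64_t> keys;
  for (int32_t sid : sids) {
    int32_t pr = sid / 4;
    int anchor_mate = (sid % 4) < 2 ? 0 : 1;
    keys.push_back((int64_t)pr * 2 + (1 - anchor_mate));
  }
  std::sort(keys.begin(), keys.end());
  keys.erase(std::unique(keys.begin(), keys.end()), keys.end());
  size_t nstr = fm->txt.size() / l;
  for (int64_t key : keys) {
    int32_t pr = (int32_t)(key / 2);
    int em = (int)(key % 2);
    int best = 0, bor = 0;
    char bvote = 'N';
    for (int orient = 0; orient < 2; orient++) {
      size_t sid = (size_t)pr * 4 + em * 2 + orient;
      if (sid >= nstr) continue;
      const char* pstr = fm->chars.data() + sid * l;
      char vote = 'N';
      int ext = best_ext(pstr, l, seq, pos, kappa, tau, &vote);
      if (ext > best) {
        best = ext;
        bvote = vote;
        bor = orient;
      }
    }
    if (best > 0 && bvote != 'N') {
      Vote v;
      v.pair = pr;
      v.ext_mate = em;
      v.orient = bor;
      v.ext = best;
      v.vote = bvote;
      votes.push_back(v);
    }
  }
}

// direct (uncached) covering set for one position; used by the R-level op
// [[Rcpp::export(name = ".covering_set_cpp")]]
List covering_set_cpp(SEXP xp_, int l, std::string segment, int dmin, int dmax,
                      int kappa, int d, double tau) {
  XPtr<FMIndex> xp(xp_);
  int pos = (int)segment.size();
  std::vector<Vote> votes;
  covering_votes(xp.get(), l, segment, pos, dmin, dmax, kappa, d, tau, NULL, votes);
  int n = (int)votes.size();
  IntegerVector pr(n), em(n), orient(n), ext(n);
  CharacterVector vt(n);
  for (int i = 0; i < n; i++) {
    pr[i] = votes[i].pair + 1;
    em[i] = votes[i].ext_mate + 1;
    orient[i] = votes[i].orient;
    ext[i] = votes[i].ext;
    vt[i] = std::string(1, votes[i].vote);
  }
  return List::create(_["pair"] = pr, _["ext_mate"] = em, _["orient"] = orient,
                      _["ext"] = ext, _["vote"] = vt);
}

struct Branch {
  std::string seq;
  AnchorCache cache;
  std::vector<int32_t> consumed;
  std::vector<int> support;
  std::string path;
};

struct Hyp {
  std::string appended;
  std::string reason;
  std::vector<int32_t> consumed;
  std::vector<int> support;
  std::string path;
};

// [[Rcpp::export(name = ".extend_segment_cpp")]]
List extend_segment_cpp(SEXP xp_, int l, std::string base, std::string opposite_head,
                        int dmin, int dmax, int kappa, int d, double tau,
                        double eps, double eps_branch, int branch_min_reads,
                        int max_branches, int max_extension, double node_budget) {
  XPtr<FMIndex> xp(xp_);
  const FMIndex* fm = xp.get();
  const int base_len = (int)base.size();
  if (base_len < l + dmax)
    stop("known flank (%d bp) shorter than l + delta_max (%d bp); cannot extend here",
         base_len, l + dmax);
  const int flank_allow = (int)std::floor((1.0 - tau) * l + 1e-9);
  const bool has_opp = (int)opposite_head.size() >= l;
  std::vector<Hyp> out;
  std::vector<Branch> stack;
  Branch b0;
  b0.seq = base;
  stack.push_back(b0);
  int spawned = 1;
  double nodes = 0;
  int flank_app = -1;  // appended length of the first flank-overlap success
  // every consensus column is a deterministic function of the trailing
  // l + dmax bases; once a sibling branch agrees with the first finished
  // hypothesis over that span (same coordinates), its continuation is
  // identical and can be spliced in rather than re-derived
  const int span = l + dmax;
  std::string ref_full;
  std::string ref_reason;
  while (!stack.empty()) {
    Branch br = std::move(stack.back());
    stack.pop_back();
    std::string reason;
    while (true) {
      int pos = (int)br.seq.size();
      int appended = pos - base_len;
      if (!ref_full.empty() && (int)ref_full.size() > pos && appended > 0 &&
          ref_full.compare(pos - span, span, br.seq, pos - span, span) == 0) {
        int ref_app = pos - base_len;
        br.seq.append(ref_full, pos, std::string::npos);
        const Hyp& h0 = out[0];
        for (size_t k = ref_app; k < h0.support.size(); k++)
          br.support.push_back(h0.support[k]);
        br.path += "~conv;";
        reason = ref_reason;
        break;
      }
      // once one branch has reached the opposite flank, competitors that
      // overshoot it cannot represent the same insertion: prune them
      int eff_max = (flank_app >= 0 && flank_app + 2 * l < max_extension)
                        ? flank_app + 2 * l
                        : max_extension;
      if (appended >= eff_max) {
        reason = appended >= max_extension ? "max_extension" : "pruned";
        break;
      }
      if (nodes >= node_budget) {
        reason = "budget";
        break;
      }
      nodes += 1;
      if (has_opp && appended >= l) {
        int mm = 0;
        bool hit = true;
        for (int i = 0; i < l; i++) {
          char a = br.seq[pos - l + i], b = opposite_head[i];
          if (a != b || a == 'N' || b == 'N') {
            if (++mm > flank_allow) {
              hit = false;
              break;
            }
          }
        }
        if (hit) {
          reason = "flank_overlap";
          if (flank_app < 0 || appended < flank_app) flank_app = appended;
          break;
        }
      }
      std::vector<Vote> votes;
      covering_votes(fm, l, br.seq, pos, dmin, dmax, kappa, d, tau, &br.cache, votes);
      int ncov = (int)votes.size();
      if (ncov == 0) {
        reason = "no_consensus";
        break;
      }
      int cnt[4] = {0, 0, 0, 0};
      for (const Vote& v : votes) {
        switch (v.vote) {
          case 'A': cnt[0]++; break;
          case 'C': cnt[1]++; break;
          case 'G': cnt[2]++; break;
          case 'T': cnt[3]++; break;
        }
      }
      int ord[4] = {0, 1, 2, 3};
      std::sort(ord, ord + 4, [&](int a, int b) {
        return cnt[a] != cnt[b] ? cnt[a] > cnt[b] : a < b;
      });
      int nb = 0, ne = 0;
      for (int c = 0; c < 4; c++) {
        if ((double)cnt[c] >= eps_branch * ncov - 1e-9 && cnt[c] > 0) nb++;
        if ((double)cnt[c] >= eps * ncov - 1e-9 && cnt[c] > 0) ne++;
      }
      static const char BASES[5] = "ACGT";
      int chosen = -1;
      // a real divergence needs reads behind its minority base; one or two
      // dissenting votes are read-error noise, not a second haplotype
      bool branchable = nb >= 2 && cnt[ord[1]] >= branch_min_reads;
      if (branchable) {
        // divergence: continue with the best-supported base, clone the rest
        for (int k = 1; k < 4; k++) {
          int c = ord[k];
          if ((double)cnt[c] >= eps_branch * ncov - 1e-9 && cnt[c] > 0 &&
              spawned < max_branches) {
            Branch child;
            child.seq = br.seq + BASES[c];
            child.cache = br.cache;
            child.consumed = br.consumed;
            child.support = br.support;
            child.support.push_back(ncov);
            char lab[64];
            snprintf(lab, sizeof(lab), "%s%c@%d;", br.path.c_str(), BASES[c], appended);
            child.path = lab;
            for (const Vote& v : votes)
              if (v.vote == BASES[c]) child.consumed.push_back(v.pair);
            stack.push_back(std::move(child));
            spawned++;
          }
        }
        chosen = ord[0];
      } else if (ne == 1 || ncov - cnt[ord[0]] <= 1) {
        // consensus, or at most one dissenting vote on a thin column
        chosen = ord[0];
      } else {
        reason = "no_consensus";
        break;
      }
      br.seq.push_back(BASES[chosen]);
      br.support.push_back(ncov);
      for (const Vote& v : votes)
        if (v.vote == BASES[chosen]) br.consumed.push_back(v.pair);
    }
    Hyp h;
    h.appended = br.seq.substr(base_len);
    h.reason = reason;
    if (ref_full.empty()) {
      ref_full = br.seq;
      ref_reason = reason;
    }
    std::sort(br.consumed.begin(), br.consumed.end());
    br.consumed.erase(std::unique(br.consumed.begin(), br.consumed.end()),
                      br.consumed.end());
    h.consumed = br.consumed;
    h.support = br.support;
    h.path = br.path;
    out.push_back(std::move(h));
  }
  List res(out.size());
  for (size_t i = 0; i < out.size(); i++) {
    res[i] = List::create(
        _["sequence"] = out[i].appended, _["reason"] = out[i].reason,
        _["consumed"] = IntegerVector(out[i].consumed.begin(), out[i].consumed.end()),
        _["support"] = IntegerVector(out[i].support.begin(), out[i].support.end()),
        _["path"] = out[i].path);
  }
  return res;
}

// ------------------------------------------------------------- evaluation ops

// semi-global (infix) edit distance: best placement of `query` inside `text`,
// substitutions and indels at unit cost, free leading/trailing text
// [[Rcpp::export(name = ".semiglobal_edit_cpp")]]
int semiglobal_edit_cpp(std::string query, std::string text) {
  const int m = (int)query.size(), n = (int)text.size();
  if (m == 0) return 0;
  if (n == 0) return m;
  std::vector<int32_t> dp(n + 1), ndp(n + 1);
  for (int j = 0; j <= n; j++) dp[j] = 0;
  const char* tc = text.data();
  for (int i = 1; i <= m; i++) {
    const char qc = query[i - 1];
    const int qn = (qc == 'N');
    int prev_diag = dp[0];
    int left = i;
    ndp[0] = i;
    for (int j = 1; j <= n; j++) {
      const int up = dp[j];
      int cur = prev_diag + ((qc != tc[j - 1]) | qn);
      const int alt = (up < left ? up : left) + 1;
      if (alt < cur) cur = alt;
      ndp[j] = cur;
      prev_diag = up;
      left = cur;
    }
    dp.swap(ndp);
  }
  int best = dp[0];
  for (int j = 0; j <= n; j++) best = std::min(best, dp[j]);
  return best;
}

// best ungapped suffix(left)/prefix(right) overlap of length >= l passing the
// mismatch-fraction threshold; returns overlap length 0 if none qualifies
// [[Rcpp::export(name = ".overlap_merge_cpp")]]
List overlap_merge_cpp(std::string left, std::string right, int l, double tau) {
  int maxo = std::min((int)left.size(), (int)right.size());
  int besto = 0, bestmm = 0, bestscore = -1;
  std::vector<int> bmm;
  for (int o = l; o <= maxo; o++) {
    int allowed = (int)std::floor((1.0 - tau) * o + 1e-9);
    const char* a = left.data() + left.size() - o;
    int mm = 0;
    bool ok = true;
    for (int i = 0; i < o; i++) {
      if (a[i] != right[i] || a[i] == 'N' || right[i] == 'N') {
        if (++mm > allowed) {
          ok = false;
          break;
        }
      }
    }
    if (ok) {
      int score = o - 2 * mm;
      if (score > bestscore || (score == bestscore && o > besto)) {
        bestscore = score;
        besto = o;
        bestmm = mm;
      }
    }
  }
  return List::create(_["overlap"] = besto, _["mismatches"] = bestmm);
}

// [[Rcpp::export(name = ".hamming_cpp")]]
int hamming_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("hamming distance requires equal lengths");
  int mm = 0;
  for (size_t i = 0; i < a.size(); i++)
    if (a[i] != b[i] || a[i] == 'N' || b[i] == 'N') mm++;
  return mm;
}
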