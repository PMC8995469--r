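#include <Rcpp.h>
#include <climits>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

// Scoring is integer, scaled by 10 so gap open (-0.5) and extension (-0.1)
// stay exact: match +10, mismatch 0, first gap position -5, each further
// contiguous gap position -1. Terminal (end) gaps in either sequence are
// free and classed as overhang, never counted in the nucleotide distance.
static const int SC_MATCH = 10;
static const int SC_MISMATCH = 0;
static const int SC_OPEN = 5;   // cost of the first position of a gap
static const int SC_EXT = 1;    // cost of each additional position
// sentinel low enough that a few subtractions can never wrap or compete
static const int NEG = INT_MIN / 4;

static inline int sub_score(char x, char y) {
  return (x == y) ? SC_MATCH : SC_MISMATCH;
}

// ---------------------------------------------------------------------------
// diagonal selection: either exact k-mer seeding (fast, needs a shared
// k-mer) or an exhaustive gap-free diagonal scan (O(mn) byte compares,
// vectorizable), so every pair gets a well-supported diagonal to band on.
// Diagonal convention: column j of b pairs with row i = j + c of a.
// ---------------------------------------------------------------------------

static bool encode_kmer(const std::string& s, size_t pos, int k, uint64_t& code) {
  uint64_t c = 0;
  for (int t = 0; t < k; ++t) {
    char ch = s[pos + t];
    uint64_t v;
    switch (ch) {
      case 'A': v = 0; break;
      case 'C': v = 1; break;
      case 'G': v = 2; break;
      case 'T': v = 3; break;
      default: return false; // ambiguous base: skip this k-mer
    }
    c = (c << 2) | v;
  }
  code = c;
  return true;
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static KmerIndex build_kmer_index(const std::string& s, int k) {
  KmerIndex idx;
  if ((int)s.size() >= k) {
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t code;
      if (encode_kmer(s, p, k, code)) idx[code].push_back((int)p);
    }
  }
  return idx;
}

static bool seeded_diagonal(const std::string& a, int n_target,
                            const KmerIndex& bidx, int k, int& diag_out) {
  const int m = (int)a.size(), n = n_target;
  if (m < k) return false;
  // diagonals c = p - pos range over [-(n-k), m-k]; flat vote counts
  std::vector<int> votes((size_t)(m + n + 1), 0);
  const int off = n;
  bool any = false;
  uint64_t code = 0;
  const uint64_t mask = (k < 32) ? ((uint64_t)1 << (2 * k)) - 1 : ~(uint64_t)0;
  int run = 0; // valid consecutive encoded bases (rolling k-mer)
  for (int p = 0; p < m; ++p) {
    uint64_t v;
    switch (a[p]) {
      case 'A': v = 0; break;
      case 'C': v = 1; break;
      case 'G': v = 2; break;
      case 'T': v = 3; break;
      default: run = 0; continue;
    }
    code = ((code << 2) | v) & mask;
    if (++run < k) continue;
    KmerIndex::const_iterator it = bidx.find(code);
    if (it == bidx.end()) continue;
    any = true;
    const std::vector<int>& ps = it->second;
    const int qpos = p - k + 1;
    for (size_t q = 0; q < ps.size(); ++q) votes[qpos - ps[q] + off]++;
  }
  if (!any) return false;
  int best_i = 0, best_n = -1;
  for (size_t t = 0; t < votes.size(); ++t)
    if (votes[t] > best_n) { best_n = votes[t]; best_i = (int)t; }
  diag_out = best_i - off;
  return true;
}

static int gapfree_best_diagonal(const std::string& a, const std::string& b) {
  const int m = (int)a.size(), n = (int)b.size();
  int best_c = 0, best_n = -1;
  for (int c = -(n - 1); c <= m - 1; ++c) {
    int i0 = std::max(0, c);           // a index of first overlapping pos
    int j0 = i0 - c;                   // matching b index
    int len = std::min(m - i0, n - j0);
    const char* pa = a.data() + i0;
    const char* pb = b.data() + j0;
    int cnt = 0;
    for (int t = 0; t < len; ++t) cnt += (pa[t] == pb[t]);
    if (cnt > best_n) { best_n = cnt; best_c = c; }
  }
  return best_c;
}

static int choose_diagonal(const std::string& a, const std::string& b,
                           const KmerIndex& bidx, int k) {
  int c0;
  if (seeded_diagonal(a, (int)b.size(), bidx, k, c0)) return c0;
  return gapfree_best_diagonal(a, b);
}

// ---------------------------------------------------------------------------
// Score-only free-end-gap affine DP (Gotoh). Optionally banded around a
// diagonal c0 (band half-width w): cells with |(i - j) - c0| > w are not
// computed. band < 0 means full DP. Returns the best score over the last
// row and last column (end gaps free). The inner loop is branch-free:
// out-of-band neighbours hold the NEG sentinel and lose every max().
// ---------------------------------------------------------------------------

static int score_only(const std::string& a, const std::string& b,
                      int c0, int band) {
  const int m = (int)a.size(), n = (int)b.size();
  std::vector<int> rowA(n + 1, 0), rowB(n + 1, NEG), F(n + 1, NEG);
  int* Hprev = rowA.data(); // row 0: all zero (free leading gap in a)
  int* Hcur = rowB.data();
  int* Fp = F.data();
  int best = 0; // empty-overlap alignment is always attainable
  int jlo_m = 1, jhi_m = 0; // band of the last computed row
  for (int i = 1; i <= m; ++i) {
    int jlo = 1, jhi = n;
    if (band >= 0) {
      jlo = std::max(1, i - c0 - band);
      jhi = std::min(n, i - c0 + band);
      if (jlo > jhi) { // band off the matrix for this row
        std::fill(Hcur, Hcur + n + 1, NEG);
        Hcur[0] = 0;
        std::swap(Hprev, Hcur);
        jlo_m = jlo; jhi_m = jhi;
        continue;
      }
    }
    Hcur[0] = 0; // free leading gap in b
    if (jlo > 1) Hcur[jlo - 1] = NEG;
    int E = NEG;
    const char ai = a[i - 1];
    const char* pb = b.data();
    for (int j = jlo; j <= jhi; ++j) {
      E = std::max(Hcur[j - 1] - SC_OPEN, E - SC_EXT);
      int f = std::max(Hprev[j] - SC_OPEN, Fp[j] - SC_EXT);
      Fp[j] = f;
      int h = Hprev[j - 1] + ((ai == pb[j - 1]) ? SC_MATCH : SC_MISMATCH);
      if (E > h) h = E;
      if (f > h) h = f;
      Hcur[j] = h;
    }
    if (jhi < n) Hcur[jhi + 1] = NEG; // guard: next row may read this cell
    if (jhi == n && Hcur[n] > best) best = Hcur[n];
    std::swap(Hprev, Hcur);
    jlo_m = jlo; jhi_m = jhi;
  }
  // last-row endpoints, restricted to the band actually computed
  if (jlo_m <= jhi_m)
    for (int j = jlo_m; j <= jhi_m; ++j)
      if (Hprev[j] > best) best = Hprev[j];
  return best;
}

// ---------------------------------------------------------------------------
// Full traceback alignment (optionally banded). Produces a column transcript
// over {M,X,D,I,A,B}:
//   M match, X mismatch, D gap in b (consumes a), I gap in a (consumes b),
//   A terminal overhang consuming a, B terminal overhang consuming b.
// Deterministic traceback preference: diagonal (M/X) > D > I; gap runs are
// closed as early as possible.
// ---------------------------------------------------------------------------

static List align_core(const std::string& a, const std::string& b,
                       int c0, int band) {
  const int m = (int)a.size(), n = (int)b.size();
  const size_t W = (size_t)(n + 1);
  const int DINF = INT_MAX / 4;
  std::vector<int> H((size_t)(m + 1) * W, NEG), E(H), F(H);
  // co-optimal distance refinement: DH/DE/DF hold the minimum distance
  // (mismatch + internal gap columns) among maximum-score paths into the
  // cell, so equal-score alternatives resolve to the fewest differences
  // (score primary, distance secondary) without extra tracebacks
  std::vector<int> DH((size_t)(m + 1) * W, DINF), DE(DH), DF(DH);
  for (int j = 0; j <= n; ++j) { H[(size_t)j] = 0; DH[(size_t)j] = 0; }
  for (int i = 0; i <= m; ++i) { H[(size_t)i * W] = 0; DH[(size_t)i * W] = 0; }

  for (int i = 1; i <= m; ++i) {
    int jlo = 1, jhi = n;
    if (band >= 0) {
      jlo = std::max(1, i - c0 - band);
      jhi = std::min(n, i - c0 + band);
    }
    const char ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      size_t c = (size_t)i * W + j;
      int eo = H[c - 1] - SC_OPEN, ee = E[c - 1] - SC_EXT;
      E[c] = std::max(eo, ee);
      DE[c] = DINF;
      if (eo == E[c]) DE[c] = std::min(DE[c], DH[c - 1] + 1);
      if (ee == E[c]) DE[c] = std::min(DE[c], DE[c - 1] + 1);
      int fo = H[c - W] - SC_OPEN, fe = F[c - W] - SC_EXT;
      F[c] = std::max(fo, fe);
      DF[c] = DINF;
      if (fo == F[c]) DF[c] = std::min(DF[c], DH[c - W] + 1);
      if (fe == F[c]) DF[c] = std::min(DF[c], DF[c - W] + 1);
      bool match = (ai == b[j - 1]);
      int M = H[c - W - 1] + (match ? SC_MATCH : SC_MISMATCH);
      int h = M;
      if (E[c] > h) h = E[c];
      if (F[c] > h) h = F[c];
      H[c] = h;
      int d = DINF;
      if (M == h) d = std::min(d, DH[c - W - 1] + (match ? 0 : 1));
      if (E[c] == h) d = std::min(d, DE[c]);
      if (F[c] == h) d = std::min(d, DF[c]);
      DH[c] = d;
    }
  }

  // Endpoint: best score over the last row and last column (end gaps
  // free); equal-scoring endpoints resolve to the smallest co-optimal
  // distance (score primary, distance secondary, as in best-match
  // selection), then the longer alignment, then scan order. If no
  // positive-scoring alignment exists the corner endpoint is kept, so a
  // zero-score empty overlap never masquerades as distance 0.
  int best = H[(size_t)m * W + n];
  for (int j = n - 1; j >= 0; --j)
    best = std::max(best, H[(size_t)m * W + j]);
  for (int i = m - 1; i >= 0; --i)
    best = std::max(best, H[(size_t)i * W + n]);

  int bi = m, bj = n;
  if (best > 0) {
    bool have = false;
    int bdist = 0;
    auto consider = [&](int i, int j) {
      size_t c = (size_t)i * W + j;
      if (H[c] != best) return;
      int dist = DH[c];
      if (!have || dist < bdist ||
          (dist == bdist && i + j > bi + bj)) {
        have = true; bi = i; bj = j; bdist = dist;
      }
    };
    consider(m, n);
    for (int j = n - 1; j >= 0; --j) consider(m, j);
    for (int i = m - 1; i >= 0; --i) consider(i, n);
  }

  std::string rev; // trailing overhang, reversed below
  rev.reserve((size_t)(m + n));
  for (int i = m; i > bi; --i) rev.push_back('A');
  for (int j = n; j > bj; --j) rev.push_back('B');
  std::string tail(rev.rbegin(), rev.rend());

  // traceback along a (score, distance)-co-optimal path; among such
  // branches prefer diagonal, then gap-in-b, then gap-in-a
  std::string core;
  int i = bi, j = bj;
  char state = 'H';
  while (i > 0 && j > 0) {
    size_t c = (size_t)i * W + j;
    if (state == 'H') {
      bool match = (a[i - 1] == b[j - 1]);
      int M = H[c - W - 1] + (match ? SC_MATCH : SC_MISMATCH);
      int dM = DH[c - W - 1] + (match ? 0 : 1);
      if (M == H[c] && dM == DH[c]) {
        core.push_back(match ? 'M' : 'X');
        --i; --j;
      } else if (F[c] == H[c] && DF[c] == DH[c]) {
        state = 'F';
      } else {
        state = 'E';
      }
    } else if (state == 'F') { // gap in b, consumes a
      core.push_back('D');
      if (H[c - W] - SC_OPEN == F[c] && DH[c - W] + 1 == DF[c]) state = 'H';
      --i;
    } else { // E: gap in a, consumes b
      core.push_back('I');
      if (H[c - 1] - SC_OPEN == E[c] && DH[c - 1] + 1 == DE[c]) state = 'H';
      --j;
    }
  }
  std::string head;
  for (int t = 0; t < i; ++t) head.push_back('A');
  for (int t = 0; t < j; ++t) head.push_back('B');

  std::string transcript = head;
  transcript.append(core.rbegin(), core.rend());
  transcript.append(tail);

  // spans of the internal (non-terminal) region, 0-based half-open
  int a0 = i, b0 = j, a1 = bi, b1 = bj;
  int dist = 0, a_over = 0, b_over = 0;
  for (size_t t = 0; t < transcript.size(); ++t) {
    char ch = transcript[t];
    if (ch == 'X' || ch == 'D' || ch == 'I') ++dist;
    else if (ch == 'A') ++a_over;
    else if (ch == 'B') ++b_over;
  }

  return List::create(
      _["score"] = best / 10.0,
      _["transcript"] = transcript,
      _["distance"] = dist,
      _["a_start"] = a0, _["a_end"] = a1,
      _["b_start"] = b0, _["b_end"] = b1,
      _["a_overhang"] = a_over, _["b_overhang"] = b_over);
}

// [[Rcpp::export(name = ".cpp_align_pair")]]
List cpp_align_pair(std::string a, std::string b, int band = -1, int k = 8) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  int c0 = 0;
  if (band >= 0) {
    KmerIndex idx = build_kmer_index(b, k);
    c0 = choose_diagonal(a, b, idx, k);
  }
  return align_core(a, b, c0, band);
}

// Score every read against every target. band < 0: full DP for all pairs.
// band >= 0: banded DP around the best-supported diagonal per pair
// (k-mer-seeded, or an exhaustive gap-free diagonal scan when no k-mer is
// shared). Returns a reads x targets matrix of scores (match = +1 scale).
// [[Rcpp::export(name = ".cpp_score_scan")]]
NumericMatrix cpp_score_scan(CharacterVector reads, CharacterVector targets,
                             int band = -1, int k = 8) {
  const int nr = reads.size(), nt = targets.size();
  std::vector<std::string> tg(nt);
  std::vector<KmerIndex> idx(nt);
  for (int t = 0; t < nt; ++t) {
    tg[t] = as<std::string>(targets[t]);
    if (band >= 0) idx[t] = build_kmer_index(tg[t], k);
  }
  NumericMatrix out(nr, nt);
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    for (int t = 0; t < nt; ++t) {
      int c0 = (band >= 0) ? choose_diagonal(rd, tg[t], idx[t], k) : 0;
      out(r, t) = score_only(rd, tg[t], c0, band) / 10.0;
    }
    if ((r & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Score and distance for every read x target pair (traceback per pair).
// Used where per-pair error counts across the whole database are needed,
// e.g. database-subset comparisons.
// [[Rcpp::export(name = ".cpp_stats_scan")]]
List cpp_stats_scan(CharacterVector reads, CharacterVector targets,
                    int band = -1, int k = 8) {
  const int nr = reads.size(), nt = targets.size();
  std::vector<std::string> tg(nt);
  std::vector<KmerIndex> idx(nt);
  for (int t = 0; t < nt; ++t) {
    tg[t] = as<std::string>(targets[t]);
    if (band >= 0) idx[t] = build_kmer_index(tg[t], k);
  }
  NumericMatrix sc(nr, nt);
  IntegerMatrix di(nr, nt);
  IntegerMatrix cov(nr, nt); // target positions inside the aligned span
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    for (int t = 0; t < nt; ++t) {
      int c0 = (band >= 0) ? choose_diagonal(rd, tg[t], idx[t], k) : 0;
      List al = align_core(rd, tg[t], c0, band >= 0 ? band : -1);
      sc(r, t) = as<double>(al["score"]);
      di(r, t) = as<int>(al["distance"]);
      cov(r, t) = as<int>(al["b_end"]) - as<int>(al["b_start"]);
    }
    if ((r & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["score"] = sc, _["distance"] = di,
                      _["target_span"] = cov);
}
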