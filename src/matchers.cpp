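// Dynamic-programming matchers for descriptor elements.
//
// Text encoding: A=0 C=1 G=2 T=3 N=4.  Pattern tokens are bitmasks over
// ACGT (A=1 C=2 G=4 T=8); mask 0 is the wildcard `*`, which matches one
// arbitrary nucleotide or the empty string.  An N in the text belongs only
// to the fully degenerate class (mask 15) and never forms a valid pair.
//
// All coordinates here are 1-based inclusive; an empty match at position s
// is reported as [s, s-1].

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cstring>
using namespace Rcpp;

static inline bool in_class(int b, int mask) {
  if (mask == 0) return b < 4;        // wildcard consumes any nucleotide
  if (b == 4) return mask == 15;      // N only matches the full class
  return (mask >> b) & 1;
}

// ---------------------------------------------------------------------------
// Single-stranded element.
//
// State: (j tokens processed, a text chars consumed, mm, ins, pending)
// where `pending` is true when the last consumed char was an insertion that
// is not yet followed by a token consumption (insertions must be internal).
// Insertions may be adjacent in single strands; they may not precede the
// first consumed token or trail after the last one.

struct SingleDP {
  int K, A, M, I;
  std::vector<unsigned char> reach; // [j][a][mm][ins][pending]
  size_t idx(int j, int a, int mm, int ins, int p) const {
    return ((((size_t)j * A + a) * M + mm) * I + ins) * 2 + p;
  }
};

// Run the DP for one start position; record minimal (mm, ins) per end.
static void single_from_start(const IntegerVector &text,
                              const IntegerVector &masks,
                              int mmax, int imax, int s,
                              SingleDP &dp,
                              std::map<int, std::pair<int,int> > &best_by_end) {
  const int n = text.size(), K = masks.size();
  std::fill(dp.reach.begin(), dp.reach.end(), 0);
  dp.reach[dp.idx(0, 0, 0, 0, 0)] = 1;

  for (int j = 0; j <= K; ++j) {
    // insertion moves stay within layer j: process a ascending
    for (int a = 0; a < dp.A; ++a)
      for (int mm = 0; mm <= mmax; ++mm)
        for (int ins = 0; ins <= imax; ++ins)
          for (int p = 0; p < 2; ++p) {
            if (!dp.reach[dp.idx(j, a, mm, ins, p)]) continue;
            int tpos = s + a; // 1-based index of next text char
            // insertion: consume a text char without advancing the pattern;
            // requires at least one previously consumed char and a later
            // token consumption (enforced via pending at accept time)
            if (j > 0 && j < K && a >= 1 && ins < imax && tpos <= n)
              dp.reach[dp.idx(j, a + 1, mm, ins + 1, 1)] = 1;
            if (j == K) continue;
            int mask = masks[j];
            if (mask == 0) { // wildcard: skip or consume (free)
              dp.reach[dp.idx(j + 1, a, mm, ins, p)] = 1;
              if (tpos <= n)
                dp.reach[dp.idx(j + 1, a + 1, mm, ins, 0)] = 1;
            } else if (tpos <= n) {
              int miss = in_class(text[tpos - 1], mask) ? 0 : 1;
              if (mm + miss <= mmax)
                dp.reach[dp.idx(j + 1, a + 1, mm + miss, ins, 0)] = 1;
            }
          }
  }
  // accept: all tokens processed, no trailing insertion
  for (int mm = 0; mm <= mmax; ++mm)
    for (int ins = 0; ins <= imax; ++ins)
      for (int a = 0; a < dp.A; ++a)
        if (dp.reach[dp.idx(K, a, mm, ins, 0)]) {
          int end = s + a - 1;
          std::map<int, std::pair<int,int> >::iterator it = best_by_end.find(end);
          if (it == best_by_end.end())
            best_by_end[end] = std::make_pair(mm, ins);
          else if (std::make_pair(mm, ins) < it->second)
            it->second = std::make_pair(mm, ins);
        }
}

// [[Rcpp::export(name = ".dp_match_single")]]
IntegerMatrix dp_match_single(IntegerVector text, IntegerVector masks,
                              int mmax, int imax,
                              int s_lo, int s_hi, int e_lo, int e_hi,
                              int cov_lo, int cov_hi) {
  const int n = text.size(), K = masks.size();
  SingleDP dp;
  dp.K = K; dp.A = K + imax + 1; dp.M = mmax + 1; dp.I = imax + 1;
  dp.reach.assign((size_t)(K + 1) * dp.A * dp.M * dp.I * 2, 0);

  std::vector<int> rs, re, rm, ri;
  int lo = std::max(s_lo, 1), hi = std::min(s_hi, n + 1);
  for (int s = lo; s <= hi; ++s) {
    std::map<int, std::pair<int,int> > best;
    single_from_start(text, masks, mmax, imax, s, dp, best);
    for (std::map<int, std::pair<int,int> >::iterator it = best.begin();
         it != best.end(); ++it) {
      int end = it->first;
      if (end < e_lo || end > e_hi) continue;
      if (cov_lo >= 1 && !(s <= cov_lo && cov_hi <= end)) continue;
      rs.push_back(s); re.push_back(end);
      rm.push_back(it->second.first); ri.push_back(it->second.second);
    }
  }
  IntegerMatrix out(rs.size(), 4);
  for (size_t k = 0; k < rs.size(); ++k) {
    out(k, 0) = rs[k]; out(k, 1) = re[k]; out(k, 2) = rm[k]; out(k, 3) = ri[k];
  }
  colnames(out) = CharacterVector::create("start", "end", "mismatches",
                                          "insertions");
  return out;
}

// ---------------------------------------------------------------------------
// Helical element, matched outside-in from (s5, e3).
//
// State: (j columns processed, c columns consumed, b5/b3 bulges per strand,
// mm mismatches over both strands, mp mispairs, bf adjacent-insertion flag).
// A column where both tokens are wildcards may be skipped; otherwise both
// strands consume one base forming an aligned pair.  A bulge consumes one
// base on one strand; bulges must sit between consumed columns and no two
// may be adjacent (bf is true right after a bulge and is cleared by a
// column consumption).

struct HelixDP {
  int K, C, B, M, R;
  std::vector<int> reach; // generation stamps, [j][c][b5][b3][mm][mp][bf]
  int gen;
  size_t idx(int j, int c, int b5, int b3, int mm, int mp, int bf) const {
    return ((((((size_t)j * C + c) * B + b5) * B + b3) * M + mm) * R + mp) * 2 + bf;
  }
};

// [[Rcpp::export(name = ".dp_match_helix")]]
IntegerMatrix dp_match_helix(IntegerVector text,
                             IntegerVector masks5, IntegerVector masks3,
                             LogicalMatrix pairs,
                             int mmax, int rmax, int imax,
                             IntegerVector dom5,  // s_lo s_hi e_lo e_hi cov_lo cov_hi
                             IntegerVector dom3,
                             int g_lo, int g_hi) {
  const int n = text.size(), K = masks5.size();
  std::vector<bool> mandatory(K);
  int cmin = 0;
  for (int j = 0; j < K; ++j) {
    mandatory[j] = !(masks5[j] == 0 && masks3[j] == 0);
    if (mandatory[j]) cmin++;
  }
  if (cmin == 0) cmin = 1; // a helix must pair at least one column

  HelixDP dp;
  dp.K = K; dp.C = K + 1; dp.B = imax + 1; dp.M = mmax + 1; dp.R = rmax + 1;
  dp.reach.assign((size_t)(K + 1) * dp.C * dp.B * dp.B * dp.M * dp.R * 2, 0);
  dp.gen = 0;

  // The first consumed column always pairs text[s5] with text[e3] (bulges
  // require a preceding consumed column, and only both-wildcard columns may
  // be skipped before it).  Precompute which base pairs can open a match.
  bool feas_first[5][5];
  {
    std::vector<int> openers;
    for (int j = 0; j < K; ++j) { openers.push_back(j); if (mandatory[j]) break; }
    for (int x = 0; x < 5; ++x)
      for (int y = 0; y < 5; ++y) {
        bool ok = false;
        for (size_t q = 0; q < openers.size() && !ok; ++q) {
          int j = openers[q];
          int madd = (masks5[j] != 0 && !in_class(x, masks5[j])) +
                     (masks3[j] != 0 && !in_class(y, masks3[j]));
          int padd = (x < 4 && y < 4 && pairs(x, y)) ? 0 : 1;
          ok = madd <= mmax && padd <= rmax;
        }
        feas_first[x][y] = ok;
      }
  }

  const int s5_lo = std::max(dom5[0], 1), s5_hi = std::min(dom5[1], n);
  const int e3_lo = std::max(dom3[2], 1), e3_hi = std::min(dom3[3], n);
  const int glo = g_lo < 0 ? 0 : g_lo;
  const int ghi = g_hi < 0 ? n : g_hi;

  std::vector<int> r5s, r5e, r3s, r3e, rm, rr, ri;

  for (int s5 = s5_lo; s5 <= s5_hi; ++s5) {
    int lo = std::max(e3_lo, s5 + 2 * cmin - 1 + glo);
    int hi = std::min(e3_hi, s5 + 2 * (K + imax) - 1 + ghi);
    for (int e3 = lo; e3 <= hi; ++e3) {
      if (!feas_first[text[s5 - 1]][text[e3 - 1]]) continue;
      ++dp.gen;
      dp.reach[dp.idx(0, 0, 0, 0, 0, 0, 0)] = dp.gen;
      for (int j = 0; j <= K; ++j)
        for (int t = 0; t <= imax; ++t)         // bulge total ascending within layer
          for (int b5 = 0; b5 <= t; ++b5) {
            int b3 = t - b5;
            if (b3 > imax) continue;
            for (int c = 0; c <= K; ++c)
              for (int mm = 0; mm <= mmax; ++mm)
                for (int mp = 0; mp <= rmax; ++mp)
                  for (int bf = 0; bf < 2; ++bf) {
                    if (dp.reach[dp.idx(j, c, b5, b3, mm, mp, bf)] != dp.gen)
                      continue;
                    int pos5 = s5 + c + b5;        // next char on 5' strand
                    int pos3 = e3 - (c + b3);      // next char on 3' strand
                    // bulges (stay in layer j)
                    if (j < K && c >= 1 && !bf && b5 + b3 < imax) {
                      if (pos5 < pos3 && pos5 <= n)
                        dp.reach[dp.idx(j, c, b5 + 1, b3, mm, mp, 1)] = dp.gen;
                      if (pos5 < pos3 && pos3 >= 1)
                        dp.reach[dp.idx(j, c, b5, b3 + 1, mm, mp, 1)] = dp.gen;
                    }
                    if (j == K) continue;
                    if (!mandatory[j]) // both wildcards: may skip the column
                      dp.reach[dp.idx(j + 1, c, b5, b3, mm, mp, bf)] = dp.gen;
                    // consume the column as an aligned pair
                    if (pos5 < pos3 && pos5 >= 1 && pos5 <= n &&
                        pos3 >= 1 && pos3 <= n) {
                      int x = text[pos5 - 1], y = text[pos3 - 1];
                      int madd = (masks5[j] != 0 && !in_class(x, masks5[j])) +
                                 (masks3[j] != 0 && !in_class(y, masks3[j]));
                      int padd = (x < 4 && y < 4 && pairs(x, y)) ? 0 : 1;
                      if (mm + madd <= mmax && mp + padd <= rmax)
                        dp.reach[dp.idx(j + 1, c + 1, b5, b3, mm + madd,
                                        mp + padd, 0)] = dp.gen;
                    }
                  }
          }
      // accept in lexicographic (mm, mp, ins) order, dedup per (e5, s3)
      std::map<std::pair<int,int>, bool> seen;
      for (int mm = 0; mm <= mmax; ++mm)
        for (int mp = 0; mp <= rmax; ++mp)
          for (int t = 0; t <= imax; ++t)
            for (int b5 = 0; b5 <= t; ++b5) {
              int b3 = t - b5;
              if (b3 > imax) continue;
              for (int c = cmin; c <= K; ++c) {
                if (dp.reach[dp.idx(K, c, b5, b3, mm, mp, 0)] != dp.gen) continue;
                int e5 = s5 + c + b5 - 1;
                int s3 = e3 - (c + b3) + 1;
                if (e5 < dom5[2] || e5 > dom5[3]) continue;
                if (s3 < dom3[0] || s3 > dom3[1]) continue;
                if (e5 >= s3) continue;
                if (dom5[4] >= 1 && !(s5 <= dom5[4] && dom5[5] <= e5)) continue;
                if (dom3[4] >= 1 && !(s3 <= dom3[4] && dom3[5] <= e3)) continue;
                int gap = s3 - e5 - 1;
                if (g_lo >= 0 && gap < g_lo) continue;
                if (g_hi >= 0 && gap > g_hi) continue;
                std::pair<int,int> key(e5, s3);
                if (seen.count(key)) continue;
                seen[key] = true;
                r5s.push_back(s5); r5e.push_back(e5);
                r3s.push_back(s3); r3e.push_back(e3);
                rm.push_back(mm); rr.push_back(mp); ri.push_back(t);
              }
            }
    }
  }
  IntegerMatrix out(r5s.size(), 7);
  for (size_t k = 0; k < r5s.size(); ++k) {
    out(k, 0) = r5s[k]; out(k, 1) = r5e[k]; out(k, 2) = r3s[k];
    out(k, 3) = r3e[k]; out(k, 4) = rm[k]; out(k, 5) = rr[k]; out(k, 6) = ri[k];
  }
  colnames(out) = CharacterVector::create("start5", "end5", "start3", "end3",
                                          "mismatches", "mispairs",
                                          "insertions");
  return out;
}

// ---------------------------------------------------------------------------
// Exhaustive counters used to validate the information-content upper bound
// X_U against the exact number X of matching sequences.

static bool single_prefix_feasible(const IntegerVector &text,
                                   const IntegerVector &masks,
                                   int mmax, int imax, SingleDP &dp) {
  std::map<int, std::pair<int,int> > best;
  single_from_start(text, masks, mmax, imax, 1, dp, best);
  return !best.empty();
}

// Count sequences of length N over ACGT with an element occurrence starting
// at position 1 (any end), allowing the element's full budgets.
// [[Rcpp::export(name = ".count_prefix_single")]]
double count_prefix_single(IntegerVector masks, int mmax, int imax, int N) {
  if (N > 13) stop("enumeration limited to N <= 13");
  const int K = masks.size();
  SingleDP dp;
  dp.K = K; dp.A = K + imax + 1; dp.M = mmax + 1; dp.I = imax + 1;
  dp.reach.assign((size_t)(K + 1) * dp.A * dp.M * dp.I * 2, 0);
  IntegerVector text(N);
  double count = 0;
  long total = 1; for (int i = 0; i < N; ++i) total *= 4;
  for (long code = 0; code < total; ++code) {
    long c = code;
    for (int i = 0; i < N; ++i) { text[i] = c & 3; c >>= 2; }
    if (single_prefix_feasible(text, masks, mmax, imax, dp)) count += 1;
  }
  return count;
}

// Count pairs (u, v) of sequences of length N such that the 5' strand
// matches a prefix of u anchored at position 1 and the 3' strand matches a
// suffix of v anchored at its last position, with pairing constraints.
// Enumerates 4^(2N) pairs: feasible for N <= 5.
// [[Rcpp::export(name = ".count_anchored_helix")]]
double count_anchored_helix(IntegerVector masks5, IntegerVector masks3,
                            LogicalMatrix pairs,
                            int mmax, int rmax, int imax, int N) {
  if (N > 6) stop("enumeration limited to N <= 6");
  IntegerVector text(2 * N);
  IntegerVector dom5 = IntegerVector::create(1, 1, 1, N, -1, -1);
  IntegerVector dom3 = IntegerVector::create(N + 1, 2 * N, 2 * N, 2 * N, -1, -1);
  double count = 0;
  long total = 1; for (int i = 0; i < 2 * N; ++i) total *= 4;
  for (long code = 0; code < total; ++code) {
    long c = code;
    for (int i = 0; i < 2 * N; ++i) { text[i] = c & 3; c >>= 2; }
    IntegerMatrix res = dp_match_helix(text, masks5, masks3, pairs,
                                       mmax, rmax, imax, dom5, dom3, -1, -1);
    if (res.nrow() > 0) count += 1;
  }
  return count;
}
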