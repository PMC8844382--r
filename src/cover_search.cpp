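// Branch-and-bound engines for the exhaustive cocktail search.
//
// Host sets are packed into 64-bit words so that union and coverage-count
// operations are a handful of popcount instructions. Two searches share the
// same admissible bound (current coverage plus the sum of the largest
// remaining per-phage gains, which can only overestimate what a completion
// can add):
//   * cover_value_cpp establishes the best attainable coverage with at most
//     k phages, branching in decreasing-gain order for maximal pruning;
//   * lex_first_cover_cpp then recovers the first size-k subset in
//     lexicographic column order attaining that (known optimal) value.
// Both are exact; the R test suite validates them against a plain
// enumeration with no reductions.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<uint64_t> BitVec;

static inline int gain_count(const BitVec &col, const BitVec &covered) {
  int c = 0;
  for (size_t w = 0; w < col.size(); ++w)
    c += __builtin_popcountll(col[w] & ~covered[w]);
  return c;
}

struct CoverProblem {
  int p, words;
  std::vector<BitVec> cols;
  explicit CoverProblem(const LogicalMatrix &hosts) {
    const int B = hosts.nrow();
    p = hosts.ncol();
    words = (B + 63) / 64;
    cols.assign(p, BitVec(words, 0));
    for (int j = 0; j < p; ++j)
      for (int i = 0; i < B; ++i)
        if (hosts(i, j))
          cols[j][i >> 6] |= (uint64_t(1) << (i & 63));
  }
};

namespace {

struct ValueSearch {
  const CoverProblem &P;
  int k, n_target, best_val;
  bool done;
  unsigned long nodes;
  ValueSearch(const CoverProblem &P_, int k_, int n_target_, int lower)
      : P(P_), k(k_), n_target(n_target_), best_val(lower), done(false),
        nodes(0) {}

  void recurse(const std::vector<int> &cand, const BitVec &covered, int covn,
               int m) {
    if (done) return;
    if ((++nodes & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    std::vector<std::pair<int, int>> g;  // (gain, column)
    g.reserve(cand.size());
    for (int j : cand) {
      const int gn = gain_count(P.cols[j], covered);
      if (gn > 0) g.emplace_back(gn, j);
    }
    if (g.empty()) return;
    std::sort(g.begin(), g.end(),
              [](const std::pair<int, int> &a, const std::pair<int, int> &b) {
                return a.first > b.first;
              });
    long top = 0;
    const int lim = std::min<int>(m, (int)g.size());
    for (int i = 0; i < lim; ++i) top += g[i].first;
    if (covn + top <= best_val) return;
    long t_rest = 0;
    const int lim2 = std::min<int>(m - 1, (int)g.size());
    for (int i = 0; i < lim2; ++i) t_rest += g[i].first;

    for (size_t i = 0; i < g.size(); ++i) {
      if (done) return;
      // gains are sorted: once the optimistic child bound fails beyond the
      // top-(m-1) block it fails for every later child
      if ((int)i >= m - 1 && covn + t_rest + g[i].first <= best_val) break;
      BitVec newcov(covered);
      const BitVec &cj = P.cols[g[i].second];
      int newn = 0;
      for (int w = 0; w < P.words; ++w) {
        newcov[w] |= cj[w];
        newn += __builtin_popcountll(newcov[w]);
      }
      if (newn > best_val) {
        best_val = newn;
        if (best_val >= n_target) {
          done = true;
          return;
        }
      }
      if (m > 1 && i + 1 < g.size()) {
        std::vector<int> rest;
        rest.reserve(g.size() - i - 1);
        for (size_t t = i + 1; t < g.size(); ++t) rest.push_back(g[t].second);
        recurse(rest, newcov, newn, m - 1);
      }
    }
  }
};

struct LexSearch {
  const CoverProblem &P;
  int k, value;
  unsigned long nodes;
  std::vector<int> sel, found;
  LexSearch(const CoverProblem &P_, int k_, int value_)
      : P(P_), k(k_), value(value_), nodes(0), sel(k_, 0) {}

  void recurse(int start, const BitVec &covered, int covn, int depth) {
    if (!found.empty()) return;
    if ((++nodes & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    const int m = k - depth;
    const int nc = P.p - start;
    std::vector<int> gains(nc);
    for (int t = 0; t < nc; ++t)
      gains[t] = gain_count(P.cols[start + t], covered);
    std::vector<int> gs(gains);
    std::sort(gs.begin(), gs.end(), std::greater<int>());
    long top = 0;
    for (int i = 0; i < std::min<int>(m, (int)gs.size()); ++i) top += gs[i];
    if (covn + top < value) return;
    long t_all = 0;
    for (int i = 0; i < std::min<int>(m - 1, (int)gs.size()); ++i)
      t_all += gs[i];

    for (int t = 0; t <= nc - m; ++t) {
      if (!found.empty()) return;
      if (covn + gains[t] + t_all < value) continue;
      const int j = start + t;
      BitVec newcov(covered);
      const BitVec &cj = P.cols[j];
      int newn = 0;
      for (int w = 0; w < P.words; ++w) {
        newcov[w] |= cj[w];
        newn += __builtin_popcountll(newcov[w]);
      }
      sel[depth] = j;
      if (m == 1) {
        if (newn >= value) {
          found = sel;
          return;
        }
      } else {
        recurse(j + 1, newcov, newn, depth + 1);
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
int cover_value_cpp(LogicalMatrix hosts, int k, int n_target, int lower) {
  CoverProblem P(hosts);
  // greedy incumbent
  BitVec covered(P.words, 0);
  for (int pick = 0; pick < k; ++pick) {
    int best_g = 0, best_j = -1;
    for (int j = 0; j < P.p; ++j) {
      const int gn = gain_count(P.cols[j], covered);
      if (gn > best_g) {
        best_g = gn;
        best_j = j;
      }
    }
    if (best_j < 0) break;
    for (int w = 0; w < P.words; ++w) covered[w] |= P.cols[best_j][w];
  }
  int greedy_cov = 0;
  for (int w = 0; w < P.words; ++w)
    greedy_cov += __builtin_popcountll(covered[w]);
  int seed = std::max(greedy_cov, lower);
  if (seed >= n_target) return seed;

  ValueSearch S(P, k, n_target, seed);
  std::vector<int> cand(P.p);
  for (int j = 0; j < P.p; ++j) cand[j] = j;
  S.recurse(cand, BitVec(P.words, 0), 0, k);
  return S.best_val;
}

// [[Rcpp::export]]
IntegerVector lex_first_cover_cpp(LogicalMatrix hosts, int k, int value) {
  CoverProblem P(hosts);
  LexSearch S(P, k, value);
  S.recurse(0, BitVec(P.words, 0), 0, 0);
  if (S.found.empty()) return IntegerVector(0);
  IntegerVector out(k);
  for (int i = 0; i < k; ++i) out[i] = S.found[i] + 1;  // 1-based
  return out;
}
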