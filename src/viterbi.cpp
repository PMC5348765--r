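#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <string>
#include <vector>
using namespace Rcpp;

// Local (Smith-Waterman-style entry/exit) Viterbi decoding of a profile with
// match/insert/delete states against a residue-encoded target.
//
// Model:
//   * entry into any match state and exit from any match state at zero cost;
//   * match state k emits residue a with log-odds E(k, a) (bits);
//   * insert states emit at background (log-odds 0) and cost `co` to open
//     from a match, `ce` to extend;
//   * delete states cost `co` to open, `ce` to extend, and consume no
//     residue;
//   * I<->D transitions are disallowed (standard profile grammar).
//
// Hits are extracted greedily best-first: the best local path is recovered
// by a full-traceback pass restricted to a window ending at the best cell
// (widened until the windowed optimum matches the global one), its residues
// are masked, and the scan repeats until the best score drops below the
// threshold.  Because no path may cross a masked residue, scores at
// positions before a new mask are unchanged; after masking only the suffix
// starting at the mask is recomputed (per-position best-score cache).
// Residue codes are 1..ncol(E); the caller maps neutral symbols (X, *) to
// a column of zeros.

static const double NEG = -1e30;

// Rolling DP from `from` (fresh start) to end; records the best score over
// match cells at every position in colmax/colarg.
static void fill_colmax(const NumericMatrix& E, const IntegerVector& x,
                        const std::vector<char>& masked,
                        double co, double ce, int from,
                        std::vector<double>& colmax,
                        std::vector<int>& colarg) {
  const int K = E.nrow(), L = x.size();
  // flat copy, state-contiguous per residue column, for cache locality
  const int A = E.ncol();
  std::vector<double> Ef((size_t)K * A);
  for (int a = 0; a < A; ++a)
    for (int k = 0; k < K; ++k) Ef[(size_t)a * K + k] = E(k, a);
  std::vector<double> Mp(K, NEG), Ip(K, NEG), Dp(K, NEG);
  std::vector<double> Mc(K, NEG), Ic(K, NEG), Dc(K, NEG);
  for (int i = from; i < L; ++i) {
    if (masked[i] != 0) {
      std::fill(Mc.begin(), Mc.end(), NEG);
      std::fill(Ic.begin(), Ic.end(), NEG);
      std::fill(Dc.begin(), Dc.end(), NEG);
      colmax[i] = NEG;
      colarg[i] = -1;
      std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
      continue;
    }
    const double* e = &Ef[(size_t)(x[i] - 1) * K];
    double cb = NEG;
    int ck = -1;
    {  // k = 0
      Mc[0] = e[0];
      const double i1 = Mp[0] + co, i2 = Ip[0] + ce;
      Ic[0] = i1 > i2 ? i1 : i2;
      Dc[0] = NEG;
      if (Mc[0] > cb) { cb = Mc[0]; ck = 0; }
    }
    for (int k = 1; k < K; ++k) {
      double pm = 0.0;  // fresh local entry
      if (Mp[k - 1] > pm) pm = Mp[k - 1];
      if (Ip[k - 1] > pm) pm = Ip[k - 1];
      if (Dp[k - 1] > pm) pm = Dp[k - 1];
      const double m = e[k] + pm;
      Mc[k] = m;
      const double i1 = Mp[k] + co, i2 = Ip[k] + ce;
      Ic[k] = i1 > i2 ? i1 : i2;
      const double d1 = Mc[k - 1] + co, d2 = Dc[k - 1] + ce;
      Dc[k] = d1 > d2 ? d1 : d2;
      if (m > cb) { cb = m; ck = k; }
    }
    colmax[i] = cb;
    colarg[i] = ck;
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
  }
}

// Full-traceback fill over target window [w0, bi]; returns false when the
// optimal path escapes the window (caller widens and retries).
static bool window_pass(const NumericMatrix& E, const IntegerVector& x,
                        const std::vector<char>& masked, double co, double ce,
                        int w0, int bi, int bk, double target,
                        int& start, int& kstart, std::string& path) {
  const int K = E.nrow();
  const int W = bi - w0 + 1;
  std::vector<double> M((size_t)W * K, NEG), I((size_t)W * K, NEG),
      D((size_t)W * K, NEG);
  // pointer codes: M: 0 entry, 1 from M, 2 from I, 3 from D;
  //                I: 1 from M, 2 from I;  D: 1 from M, 3 from D.
  std::vector<signed char> pM((size_t)W * K, 0), pI((size_t)W * K, 1),
      pD((size_t)W * K, 1);
  for (int w = 0; w < W; ++w) {
    const int i = w0 + w;
    const int a = x[i] - 1;
    const bool msk = masked[i] != 0;
    for (int k = 0; k < K; ++k) {
      const size_t c = (size_t)w * K + k;
      if (!msk) {
        double pm = 0.0;
        signed char pt = 0;
        if (w > 0 && k > 0) {
          const size_t p = (size_t)(w - 1) * K + (k - 1);
          if (M[p] > pm) { pm = M[p]; pt = 1; }
          if (I[p] > pm) { pm = I[p]; pt = 2; }
          if (D[p] > pm) { pm = D[p]; pt = 3; }
        }
        M[c] = E(k, a) + pm;
        pM[c] = pt;
        if (w > 0) {
          const size_t p = (size_t)(w - 1) * K + k;
          const double i1 = M[p] + co, i2 = I[p] + ce;
          if (i1 >= i2) { I[c] = i1; pI[c] = 1; }
          else          { I[c] = i2; pI[c] = 2; }
        }
      }
      if (k > 0) {
        const double d1 = M[c - 1] + co, d2 = D[c - 1] + ce;
        if (d1 >= d2) { D[c] = d1; pD[c] = 1; }
        else          { D[c] = d2; pD[c] = 3; }
      }
    }
  }
  const size_t bc = (size_t)(bi - w0) * K + bk;
  if (std::fabs(M[bc] - target) > 1e-6) return false;
  // traceback
  std::string rev;
  int w = bi - w0, k = bk;
  char st = 'M';
  for (;;) {
    const size_t c = (size_t)w * K + k;
    if (st == 'M') {
      rev.push_back('M');
      const signed char pt = pM[c];
      if (pt == 0) { start = w0 + w; kstart = k; break; }
      st = (pt == 1) ? 'M' : (pt == 2 ? 'I' : 'D');
      --w; --k;  // all M predecessors sit at (w-1, k-1)
    } else if (st == 'I') {
      rev.push_back('I');
      st = (pI[c] == 1) ? 'M' : 'I';
      --w;
    } else {  // D
      rev.push_back('D');
      st = (pD[c] == 1) ? 'M' : 'D';
      --k;
    }
  }
  path.assign(rev.rbegin(), rev.rend());
  return true;
}

// [[Rcpp::export]]
List viterbi_hits_cpp(NumericMatrix E, IntegerVector x, double co, double ce,
                      double threshold, int max_hits) {
  const int L = x.size();
  const int K = E.nrow();
  std::vector<char> masked(L, 0);
  std::vector<double> colmax(L, NEG);
  std::vector<int> colarg(L, -1);
  std::vector<int> starts, ends, kstarts, kends;
  std::vector<double> scores;
  std::vector<std::string> paths;
  const int base_w = 4 * K + 200;
  fill_colmax(E, x, masked, co, ce, 0, colmax, colarg);
  while ((int)scores.size() < max_hits) {
    int bi = -1;
    double best = NEG;
    for (int i = 0; i < L; ++i)
      if (colmax[i] > best) { best = colmax[i]; bi = i; }
    if (bi < 0 || best < threshold) break;
    const int bk = colarg[bi];
    int W = base_w;
    int start = bi, kstart = bk;
    std::string path;
    for (;;) {
      const int w0 = bi - W + 1 < 0 ? 0 : bi - W + 1;
      if (window_pass(E, x, masked, co, ce, w0, bi, bk, best,
                      start, kstart, path)) break;
      if (w0 == 0) stop("internal error: traceback failed");
      W *= 2;
    }
    starts.push_back(start);
    ends.push_back(bi + 1);
    kstarts.push_back(kstart + 1);  // 1-based match-state index
    kends.push_back(bk + 1);
    scores.push_back(best);
    paths.push_back(path);
    for (int i = start; i <= bi; ++i) masked[i] = 1;
    // recompute only the suffix: no path may cross the new mask, so all
    // positions before `start` keep their scores.
    fill_colmax(E, x, masked, co, ce, start, colmax, colarg);
  }
  return List::create(_["protein_start"] = starts, _["protein_end"] = ends,
                      _["kstart"] = kstarts, _["kend"] = kends,
                      _["score"] = scores, _["path"] = paths);
}
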