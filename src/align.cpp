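#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Alphabet encoding shared with R/msa-engine.R:
//   0=A, 1=C, 2=G, 3=T, 4=N, 5=gap.
// Profiles are 6 x W integer count matrices over that alphabet.

static const double NEG = -1e18;

static inline double subScore(int c, int b, double match, double mismatch) {
  if (c == 4 || b == 4) return 0.0;            // N is scored neutrally
  return (c == b) ? match : mismatch;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_profile_align")]]
IntegerVector cpp_profile_align(IntegerMatrix prof, IntegerVector seq,
                                double match, double mismatch,
                                double gapOpen, double gapExtend,
                                int band) {
  const int W = prof.ncol();
  const int n = seq.size();

  // degenerate shapes: pure gap runs
  if (W == 0) return IntegerVector(n, 2);
  if (n == 0) return IntegerVector(W, 1);

  if (band < 2) band = 2;
  long width = 2L * band + 1;

  // per-column cached quantities
  std::vector<double> colTot(W), colNonGapFrac(W);
  for (int j = 0; j < W; ++j) {
    double tot = 0.0;
    for (int r = 0; r < 6; ++r) tot += prof(r, j);
    colTot[j] = tot > 0 ? tot : 1.0;
    colNonGapFrac[j] = (tot - prof(5, j)) / colTot[j];
  }
  // score of aligning residue c against column j
  auto colScore = [&](int c, int j) -> double {
    double s = 0.0;
    for (int b = 0; b < 5; ++b) {
      int cnt = prof(b, j);
      if (cnt) s += cnt * subScore(c, b, match, mismatch);
    }
    s += prof(5, j) * gapExtend;               // residue against column gaps
    return s / colTot[j];
  };

  auto center = [&](int i) -> int {
    return (int) std::llround((double) i * W / n);
  };
  auto lo = [&](int i) { int l = center(i) - band; return l < 0 ? 0 : l; };
  auto hi = [&](int i) { int h = center(i) + band; return h > W ? W : h; };

  std::vector<double> prevM(width), prevX(width), prevY(width);
  std::vector<double> curM(width), curX(width), curY(width);
  // traceback: tbM 0=M,1=X,2=Y (diag predecessor); tbX 0=M,1=X (left); tbY 0=M,1=Y (up)
  std::vector<int8_t> tbM((size_t)(n + 1) * width, 0);
  std::vector<int8_t> tbX((size_t)(n + 1) * width, 0);
  std::vector<int8_t> tbY((size_t)(n + 1) * width, 0);

  // row 0
  {
    int l = lo(0), h = hi(0);
    std::fill(curM.begin(), curM.end(), NEG);
    std::fill(curX.begin(), curX.end(), NEG);
    std::fill(curY.begin(), curY.end(), NEG);
    for (int j = l; j <= h; ++j) {
      long k = j - (center(0) - band);
      if (j == 0) { curM[k] = 0.0; continue; }
      double w = colNonGapFrac[j - 1];
      double fromM = (j - 1 >= l) ? curM[k - 1] + (gapOpen + gapExtend) * w : NEG;
      double fromX = (j - 1 >= l) ? curX[k - 1] + gapExtend * w : NEG;
      if (fromM >= fromX) { curX[k] = fromM; tbX[k] = 0; }
      else                { curX[k] = fromX; tbX[k] = 1; }
    }
    prevM.swap(curM); prevX.swap(curX); prevY.swap(curY);
  }

  for (int i = 1; i <= n; ++i) {
    int l = lo(i), h = hi(i), base_i = center(i) - band;
    int pl = lo(i - 1), ph = hi(i - 1), base_p = center(i - 1) - band;
    std::fill(curM.begin(), curM.end(), NEG);
    std::fill(curX.begin(), curX.end(), NEG);
    std::fill(curY.begin(), curY.end(), NEG);
    int c = seq[i - 1];
    for (int j = l; j <= h; ++j) {
      long k = j - base_i;
      size_t off = (size_t) i * width + k;
      // diag (i-1, j-1)
      double dM = NEG, dX = NEG, dY = NEG;
      if (j >= 1 && j - 1 >= pl && j - 1 <= ph) {
        long kp = j - 1 - base_p;
        dM = prevM[kp]; dX = prevX[kp]; dY = prevY[kp];
      }
      // up (i-1, j)
      double uM = NEG, uY = NEG;
      if (j >= pl && j <= ph) {
        long ku = j - base_p;
        uM = prevM[ku]; uY = prevY[ku];
      }
      // left (i, j-1)
      double lM = NEG, lX = NEG;
      if (j - 1 >= l) { lM = curM[k - 1]; lX = curX[k - 1]; }

      if (j >= 1) {
        double best = dM; int8_t tb = 0;
        if (dX > best) { best = dX; tb = 1; }
        if (dY > best) { best = dY; tb = 2; }
        if (best > NEG / 2) { curM[k] = best + colScore(c, j - 1); tbM[off] = tb; }
        double w = colNonGapFrac[j - 1];
        double xm = lM + (gapOpen + gapExtend) * w, xx = lX + gapExtend * w;
        if (xm >= xx) { curX[k] = xm; tbX[off] = 0; }
        else          { curX[k] = xx; tbX[off] = 1; }
      }
      double ym = uM + gapOpen + gapExtend, yy = uY + gapExtend;
      if (ym >= yy) { curY[k] = ym; tbY[off] = 0; }
      else          { curY[k] = yy; tbY[off] = 1; }
    }
    prevM.swap(curM); prevX.swap(curX); prevY.swap(curY);
  }

  // end state at (n, W)
  long kend = W - (center(n) - band);
  if (kend < 0 || kend >= width) stop("alignment band does not reach the terminal cell");
  int state = 0;
  double best = prevM[kend];
  if (prevX[kend] > best) { best = prevX[kend]; state = 1; }
  if (prevY[kend] > best) { best = prevY[kend]; state = 2; }
  if (best <= NEG / 2) stop("alignment band too narrow for these lengths");

  // traceback
  std::vector<int> ops;
  ops.reserve(n + W);
  int i = n, j = W;
  while (i > 0 || j > 0) {
    long k = j - (center(i) - band);
    size_t off = (size_t) i * width + k;
    if (state == 0) {
      ops.push_back(0);
      state = tbM[off]; --i; --j;
    } else if (state == 1) {
      ops.push_back(1);
      state = (tbX[off] == 0) ? 0 : 1; --j;
    } else {
      ops.push_back(2);
      state = (tbY[off] == 0) ? 0 : 2; --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return wrap(ops);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_edit_arrays")]]
List cpp_edit_arrays(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  IntegerVector prefMin(n + 1);
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  prefMin[0] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    int rowMin = i;
    int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int d = prev[j - 1] + ((ai == b[j - 1]) ? 0 : 1);
      int up = prev[j] + 1, left = cur[j - 1] + 1;
      if (up < d) d = up;
      if (left < d) d = left;
      cur[j] = d;
      if (d < rowMin) rowMin = d;
    }
    prefMin[i] = rowMin;
    prev.swap(cur);
  }
  return List::create(_["prefix_min"] = prefMin, _["full"] = prev[m]);
}
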