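#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Global (end-to-end) pairwise alignment with affine gaps, Gotoh three-state
// DP. A gap of length L scores gap_open + L * gap_extend (both <= 0).
// Sequences arrive integer-encoded: A=0, C=1, G=2, T=3, N=4; N is
// scoring-neutral (0 against anything). Traceback is deterministic with
// fixed state precedence M > Ix (gap in y) > Iy (gap in x).
// Score matrices are kept as rolling rows; only the byte traceback
// matrices are stored in full.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".affine_align_cpp")]]
List affine_align_cpp(IntegerVector x, IntegerVector y,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = x.size(), m = y.size();
  const double go = gap_open, ge = gap_extend;

  auto sub = [&](int a, int b) -> double {
    if (a == 4 || b == 4) return 0.0;
    return a == b ? match : mismatch;
  };

  const size_t W = static_cast<size_t>(m) + 1;
  std::vector<unsigned char> tbM(((size_t)n + 1) * W, 0);
  std::vector<unsigned char> tbX(((size_t)n + 1) * W, 0);
  std::vector<unsigned char> tbY(((size_t)n + 1) * W, 0);
  auto at = [&](size_t i, size_t j) { return i * W + j; };

  std::vector<double> Mp(W), Xp(W), Yp(W), Mc(W), Xc(W), Yc(W);
  // row 0
  Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF; Xp[j] = NEG_INF;
    Yp[j] = go + ge * j;
    tbY[at(0, j)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG_INF;
    Xc[0] = go + ge * i;
    Yc[0] = NEG_INF;
    tbX[at(i, 0)] = 1;
    for (int j = 1; j <= m; ++j) {
      const size_t c = at(i, j);
      // M: diagonal from best of the three states at (i-1, j-1)
      {
        double best = Mp[j - 1]; unsigned char from = 0;
        if (Xp[j - 1] > best) { best = Xp[j - 1]; from = 1; }
        if (Yp[j - 1] > best) { best = Yp[j - 1]; from = 2; }
        Mc[j] = best + sub(x[i - 1], y[j - 1]);
        tbM[c] = from;
      }
      // Ix: consume x[i-1] (gap in y), from (i-1, j)
      {
        double best = Mp[j] + go + ge; unsigned char from = 0;
        if (Xp[j] + ge > best) { best = Xp[j] + ge; from = 1; }
        if (Yp[j] + go + ge > best) { best = Yp[j] + go + ge; from = 2; }
        Xc[j] = best; tbX[c] = from;
      }
      // Iy: consume y[j-1] (gap in x), from (i, j-1)
      {
        double best = Mc[j - 1] + go + ge; unsigned char from = 0;
        if (Xc[j - 1] + go + ge > best) { best = Xc[j - 1] + go + ge; from = 1; }
        if (Yc[j - 1] + ge > best) { best = Yc[j - 1] + ge; from = 2; }
        Yc[j] = best; tbY[c] = from;
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  double score = Mp[m]; int state = 0;
  if (Xp[m] > score) { score = Xp[m]; state = 1; }
  if (Yp[m] > score) { score = Yp[m]; state = 2; }

  std::string ax, ay;
  ax.reserve(n + m); ay.reserve(n + m);
  static const char LET[] = "ACGTN";
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t c = at(i, j);
    if (state == 0) {
      ax.push_back(LET[x[i - 1]]);
      ay.push_back(LET[y[j - 1]]);
      state = tbM[c]; --i; --j;
    } else if (state == 1) {
      ax.push_back(LET[x[i - 1]]);
      ay.push_back('-');
      state = tbX[c]; --i;
    } else {
      ax.push_back('-');
      ay.push_back(LET[y[j - 1]]);
      state = tbY[c]; --j;
    }
  }
  std::reverse(ax.begin(), ax.end());
  std::reverse(ay.begin(), ay.end());

  return List::create(_["left"] = ax, _["right"] = ay, _["score"] = score);
}
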