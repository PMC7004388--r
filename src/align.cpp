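#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Chunk-chain dynamic programming over two ordered label vectors.
//
// A chunk pairs query label i with target label j given the previous
// matched pair (i', j'); its score is
//   reward - (dq - dr)^2 / (2 * (cv^2 * dr^2 + 2 * jit^2))
//          - nq_skip * fp_pen - nr_skip * fn_pen
// where dq = q[i] - q[i'], dr = t[j] - t[j'].  Unmatched query labels
// look like false-positive labels, unmatched target labels like missed
// ones, hence the asymmetric penalties.  mode 0 = "fit" (every query
// label outside the chunk chain is penalised, target ends are free);
// mode 1 = "overlap" (both maps' ends are free).
//
// Scores are rounded to 1e-9 before comparisons so tie-breaking is
// reproducible across platforms; among equal scores the first cell in
// (i, j) scan order wins.

static inline double round9(double x) {
  return std::round(x * 1e9) / 1e9;
}

// [[Rcpp::export(name = ".dp_align_cpp")]]
List dp_align_cpp(NumericVector q, NumericVector t,
                  double reward, double fp_pen, double fn_pen,
                  double cv, double jit, int max_skip, int mode) {
  const int m = q.size(), n = t.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = R_NegInf,
                        _["qi"] = IntegerVector(0),
                        _["ti"] = IntegerVector(0));

  NumericMatrix S(m, n);
  IntegerMatrix Pi(m, n), Pj(m, n);

  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      // start a chain at (i, j)
      double best = (mode == 0) ? reward - i * fp_pen : reward;
      int bi = -1, bj = -1;
      const int i0 = std::max(0, i - 1 - max_skip);
      const int j0 = std::max(0, j - 1 - max_skip);
      for (int ip = i0; ip < i; ++ip) {
        for (int jp = j0; jp < j; ++jp) {
          const double dq = q[i] - q[ip];
          const double dr = t[j] - t[jp];
          const double var = cv * cv * dr * dr + 2.0 * jit * jit;
          double chunk = reward - fp_pen * (i - ip - 1) - fn_pen * (j - jp - 1);
          if (var > 0.0) chunk -= (dq - dr) * (dq - dr) / (2.0 * var);
          else if (dq != dr) chunk = -std::numeric_limits<double>::infinity();
          const double cand = round9(S(ip, jp) + chunk);
          if (cand > round9(best)) { best = cand; bi = ip; bj = jp; }
        }
      }
      S(i, j) = best;
      Pi(i, j) = bi;
      Pj(i, j) = bj;
    }
  }

  double best = -std::numeric_limits<double>::infinity();
  int ei = -1, ej = -1;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      double fin = S(i, j);
      if (mode == 0) fin -= (m - 1 - i) * fp_pen;
      fin = round9(fin);
      if (fin > best) { best = fin; ei = i; ej = j; }
    }
  }

  std::vector<int> qi, ti;
  int i = ei, j = ej;
  while (i >= 0 && j >= 0) {
    qi.push_back(i + 1);  // 1-based for R
    ti.push_back(j + 1);
    const int ni = Pi(i, j), nj = Pj(i, j);
    i = ni; j = nj;
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(ti.begin(), ti.end());

  return List::create(_["score"] = best,
                      _["qi"] = IntegerVector(qi.begin(), qi.end()),
                      _["ti"] = IntegerVector(ti.begin(), ti.end()));
}
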