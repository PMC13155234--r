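#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Copy an M x d row-per-state matrix into a contiguous d x M buffer so each
// state occupies d consecutive doubles (cache-friendly inner loops).
static std::vector<double> to_state_major(const NumericMatrix &x) {
  const int m = x.nrow(), d = x.ncol();
  std::vector<double> buf((size_t)m * d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < m; ++i) buf[(size_t)i * d + j] = x(i, j);
  return buf;
}

// Nearest Euclidean neighbour of every state, excluding a temporal (Theiler)
// window around each index. Ties broken by the smallest index (strict <).
// Returns 1-based indices; NA where no admissible neighbour exists.
// [[Rcpp::export(name = ".nn_theiler_cpp")]]
IntegerVector nn_theiler_cpp(NumericMatrix x, int theiler) {
  const int m = x.nrow(), d = x.ncol();
  const std::vector<double> buf = to_state_major(x);
  IntegerVector nn(m);
  for (int i = 0; i < m; ++i) {
    const double *xi = &buf[(size_t)i * d];
    double best = R_PosInf;
    int bj = -1;
    const int lo = i - theiler, hi = i + theiler;
    for (int j = 0; j < m; ++j) {
      if (j >= lo && j <= hi) continue;
      const double *xj = &buf[(size_t)j * d];
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = xi[k] - xj[k];
        s += diff * diff;
      }
      if (s < best) {
        best = s;
        bj = j;
      }
    }
    nn[i] = (bj < 0) ? NA_INTEGER : bj + 1;
  }
  return nn;
}

// Mean log Euclidean divergence between each state and its nearest neighbour,
// followed forward k = 0..horizon steps; pairs with either index out of range
// are dropped from the average at that k. Distances are floored at floor_dist
// before the log.
// [[Rcpp::export(name = ".mean_log_div_cpp")]]
NumericVector mean_log_div_cpp(NumericMatrix x, IntegerVector nn, int horizon,
                               double floor_dist) {
  const int m = x.nrow(), d = x.ncol();
  const std::vector<double> buf = to_state_major(x);
  NumericVector out(horizon + 1);
  for (int k = 0; k <= horizon; ++k) {
    double acc = 0.0;
    int cnt = 0;
    for (int i = 0; i < m; ++i) {
      if (nn[i] == NA_INTEGER) continue;
      const int j = nn[i] - 1;
      if (i + k >= m || j + k >= m) continue;
      const double *xi = &buf[(size_t)(i + k) * d];
      const double *xj = &buf[(size_t)(j + k) * d];
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = xi[c] - xj[c];
        s += diff * diff;
      }
      double dist = std::sqrt(s);
      if (dist < floor_dist) dist = floor_dist;
      acc += std::log(dist);
      ++cnt;
    }
    out[k] = (cnt > 0) ? acc / cnt : NA_REAL;
  }
  return out;
}
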