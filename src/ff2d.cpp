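#include <Rcpp.h>
using namespace Rcpp;

// Fasano-Franceschini 2-D two-sample statistic.
// For each origin point, compare the two samples' empirical fractions in the
// four open quadrants around the origin (points on the dividing lines are
// excluded) and track the maximal absolute difference. D_A uses origins from
// sample A, D_B origins from sample B; D = (D_A + D_B) / 2.
static double ff2d_max_diff(const double* x, const double* y,
                            const int* grp, int n, int na, int nb,
                            int origin_grp) {
  double dmax = 0.0;
  for (int i = 0; i < n; ++i) {
    if (grp[i] != origin_grp) continue;
    const double x0 = x[i], y0 = y[i];
    int ca1 = 0, ca2 = 0, ca3 = 0, ca4 = 0;
    int cb1 = 0, cb2 = 0, cb3 = 0, cb4 = 0;
    for (int j = 0; j < n; ++j) {
      const double dx = x[j] - x0, dy = y[j] - y0;
      if (dx == 0.0 || dy == 0.0) continue;
      if (grp[j] == 0) {
        if (dx > 0) { if (dy > 0) ++ca1; else ++ca4; }
        else        { if (dy > 0) ++ca2; else ++ca3; }
      } else {
        if (dx > 0) { if (dy > 0) ++cb1; else ++cb4; }
        else        { if (dy > 0) ++cb2; else ++cb3; }
      }
    }
    const double ia = 1.0 / na, ib = 1.0 / nb;
    double d;
    d = std::fabs(ca1 * ia - cb1 * ib); if (d > dmax) dmax = d;
    d = std::fabs(ca2 * ia - cb2 * ib); if (d > dmax) dmax = d;
    d = std::fabs(ca3 * ia - cb3 * ib); if (d > dmax) dmax = d;
    d = std::fabs(ca4 * ia - cb4 * ib); if (d > dmax) dmax = d;
  }
  return dmax;
}

static double ff2d_stat_impl(const double* x, const double* y,
                             const int* grp, int n) {
  int na = 0;
  for (int i = 0; i < n; ++i) if (grp[i] == 0) ++na;
  int nb = n - na;
  const double da = ff2d_max_diff(x, y, grp, n, na, nb, 0);
  const double db = ff2d_max_diff(x, y, grp, n, na, nb, 1);
  return 0.5 * (da + db);
}

// [[Rcpp::export]]
double ff2d_stat_cpp(NumericVector x, NumericVector y, IntegerVector grp) {
  return ff2d_stat_impl(x.begin(), y.begin(), grp.begin(), x.size());
}

// Permutation null distribution of the statistic; labels are shuffled with
// R's RNG (Fisher-Yates), so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector ff2d_perm_cpp(NumericVector x, NumericVector y,
                            IntegerVector grp, int n_perm) {
  const int n = x.size();
  std::vector<int> lab(grp.begin(), grp.end());
  NumericVector out(n_perm);
  RNGScope scope;
  for (int p = 0; p < n_perm; ++p) {
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(lab[i], lab[j]);
    }
    out[p] = ff2d_stat_impl(x.begin(), y.begin(), lab.data(), n);
  }
  return out;
}
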