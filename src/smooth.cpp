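// Local-regression smoothing of per-sample methylation profiles along
// one cluster of loci: for each locus, a coverage- and tricube-weighted
// quadratic fit of raw fraction on position over the smallest symmetric
// locus window holding >= min_loci loci and spanning >= min_width bp
// (truncated at cluster boundaries). Loci with no coverage (NA raw
// fraction) get the fitted value: imputation from neighbours.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double tricube(double u) {
  if (u >= 1.0) return 0.0;
  double w = 1.0 - u * u * u;
  return w * w * w;
}

// [[Rcpp::export(name = ".smooth_cluster_cpp")]]
NumericMatrix smooth_cluster_cpp(NumericVector pos, NumericMatrix frac,
                                 NumericMatrix cov, int min_loci,
                                 double min_width,
                                 bool coverage_weighting) {
  const int n = pos.size(), S = frac.ncol();
  NumericMatrix out(n, S);
  std::fill(out.begin(), out.end(), NA_REAL);

  for (int j = 0; j < n; ++j) {
    // symmetric expansion in locus index, truncated at cluster ends
    int lo = j, hi = j, h = 0;
    while ((hi - lo + 1 < min_loci || pos[hi] - pos[lo] < min_width) &&
           (lo > 0 || hi < n - 1)) {
      ++h;
      lo = std::max(0, j - h);
      hi = std::min(n - 1, j + h);
    }
    double hw = std::max(pos[hi] - pos[j], pos[j] - pos[lo]) + 1.0;

    for (int s = 0; s < S; ++s) {
      // gather observed points with positive weight
      int m = 0;
      arma::mat X(hi - lo + 1, 3);
      arma::vec y(hi - lo + 1), w(hi - lo + 1);
      double wsum = 0.0, wy = 0.0;
      for (int i = lo; i <= hi; ++i) {
        double f = frac(i, s);
        if (ISNAN(f)) continue;
        double x = (pos[i] - pos[j]) / hw;  // in (-1, 1)
        double wi = tricube(std::fabs(x));
        if (coverage_weighting) wi *= cov(i, s);
        if (wi <= 0.0) continue;
        X(m, 0) = 1.0; X(m, 1) = x; X(m, 2) = x * x;
        y(m) = f; w(m) = wi;
        wsum += wi; wy += wi * f;
        ++m;
      }
      if (m == 0) continue;                 // nothing observed nearby
      if (m < 3) { out(j, s) = wy / wsum; continue; }
      X.resize(m, 3); y.resize(m); w.resize(m);
      arma::vec sw = arma::sqrt(w);
      arma::mat Xw = X.each_col() % sw;
      arma::vec yw = y % sw;
      arma::vec beta;
      bool ok = arma::solve(beta, Xw.t() * Xw, Xw.t() * yw,
                            arma::solve_opts::no_approx);
      if (!ok || !beta.is_finite())
        beta = arma::pinv(Xw.t() * Xw) * (Xw.t() * yw);
      out(j, s) = beta(0);                  // fit evaluated at x = 0
    }
  }
  return out;
}
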