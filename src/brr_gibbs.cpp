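#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for Bayesian ridge regression
//   y = X beta + e,  beta_j ~ N(0, s2b) for penalized columns,
//   s2b ~ Scale-inv-chi2(nub, taub), s2e ~ Scale-inv-chi2(nue, taue),
// with the scale parameterized as a prior sum of squares: the full
// conditional draw is s2 = (SS + tau) / chisq(nu + df).
// Unpenalized columns (the intercept) get a flat prior.
// fix_s2b / fix_s2e <= 0 mean "sample"; positive values freeze the variance.
// Uses R's RNG (set.seed-reproducible).
// [[Rcpp::export]]
List brr_gibbs_cpp(const NumericVector& y, const NumericMatrix& X,
                   const LogicalVector& penalized,
                   const double nub, const double taub,
                   const double nue, const double taue,
                   const int n_iter, const int burn_in, const int thin,
                   const double fix_s2b, const double fix_s2e) {
  const int n = y.size(), p = X.ncol();
  if (X.nrow() != n) stop("rows of X must match length of y");
  const int S = (n_iter - burn_in) / thin;
  int n_pen = 0;
  for (int j = 0; j < p; ++j) if (penalized[j]) ++n_pen;

  std::vector<double> xx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xx[j] = s;
  }

  std::vector<double> beta(p, 0.0), e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];
  double s2b = fix_s2b > 0 ? fix_s2b : taub / (nub + 2.0);
  double s2e = fix_s2e > 0 ? fix_s2e : taue / (nue + 2.0);

  NumericMatrix samples(S, p);
  NumericVector s2b_draws(S), s2e_draws(S);
  int stored = 0;

  for (int it = 1; it <= n_iter; ++it) {
    for (int j = 0; j < p; ++j) {
      const double old = beta[j];
      double rhs = 0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * (e[i] + X(i, j) * old);
      const double lambda = penalized[j] ? s2e / s2b : 0.0;
      const double C = xx[j] + lambda;
      if (C <= 0) { beta[j] = 0.0; continue; }
      const double bnew = rhs / C + norm_rand() * std::sqrt(s2e / C);
      const double d = bnew - old;
      for (int i = 0; i < n; ++i) e[i] -= X(i, j) * d;
      beta[j] = bnew;
    }
    if (fix_s2b <= 0) {
      double ssb = 0;
      for (int j = 0; j < p; ++j) if (penalized[j]) ssb += beta[j] * beta[j];
      s2b = (ssb + taub) / R::rchisq(nub + n_pen);
    }
    if (fix_s2e <= 0) {
      double sse = 0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      s2e = (sse + taue) / R::rchisq(nue + n);
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && stored < S) {
      for (int j = 0; j < p; ++j) samples(stored, j) = beta[j];
      s2b_draws[stored] = s2b;
      s2e_draws[stored] = s2e;
      ++stored;
    }
  }
  return List::create(_["samples"] = samples,
                      _["sigma2_beta"] = s2b_draws,
                      _["sigma2_e"] = s2e_draws);
}
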