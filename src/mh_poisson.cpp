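#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Unnormalized log posterior of a Poisson log-linear model with
// independent Normal(0, prior_sd_j) priors; log(y!) terms dropped.
static double log_post(const NumericMatrix &X, const NumericVector &y,
                       const NumericVector &off,
                       const std::vector<double> &th,
                       const NumericVector &prior_sd) {
  const int n = X.nrow(), p = X.ncol();
  double lp = 0.0;
  for (int j = 0; j < p; ++j)
    lp += -0.5 * th[j] * th[j] / (prior_sd[j] * prior_sd[j]);
  for (int i = 0; i < n; ++i) {
    double eta = off[i];
    for (int j = 0; j < p; ++j) eta += X(i, j) * th[j];
    if (eta > 50.0) return R_NegInf;  // rate overflow guard
    lp += y[i] * eta - std::exp(eta);
  }
  return lp;
}

// Lower Cholesky of a small covariance matrix (with jitter); row-major
// p x p in `a`, result in `l`.
static bool chol_lower(const std::vector<double> &a, std::vector<double> &l,
                       int p) {
  l.assign(p * p, 0.0);
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = a[i * p + j];
      for (int k = 0; k < j; ++k) s -= l[i * p + k] * l[j * p + k];
      if (i == j) {
        if (s <= 0.0) return false;
        l[i * p + i] = std::sqrt(s);
      } else {
        l[i * p + j] = s / l[j * p + j];
      }
    }
  }
  return true;
}

// One adaptive random-walk Metropolis chain.  During warmup the global
// proposal scale follows a Robbins-Monro recursion targeting 30%
// acceptance and the proposal covariance is refreshed periodically from
// the accumulated warmup history; both are frozen afterwards.  Uses R's
// RNG, so seeding via set.seed() in R gives bit-reproducible chains.
// [[Rcpp::export(name = ".mhPoissonChain")]]
List mh_poisson_chain(NumericMatrix X, NumericVector y, NumericVector off,
                      NumericVector init, NumericVector prior_sd,
                      int n_iter, int n_warmup) {
  const int p = X.ncol();
  if (n_warmup >= n_iter) stop("warmup must be smaller than iterations");
  std::vector<double> th(init.begin(), init.end());
  double lp = log_post(X, y, off, th, prior_sd);
  if (!R_finite(lp)) stop("initial values have zero posterior density");

  // proposal: th' = th + exp(ls) * L z
  std::vector<double> L(p * p, 0.0), cov(p * p, 0.0);
  for (int j = 0; j < p; ++j) L[j * p + j] = 0.1;
  double ls = 0.0;
  const double target = (p > 2) ? 0.234 : 0.35;

  std::vector<double> hist;  // warmup history, row-major
  hist.reserve((size_t)n_warmup * p);
  std::vector<double> mean(p, 0.0), prop(p), z(p);

  const int n_keep = n_iter - n_warmup;
  NumericMatrix draws(n_keep, p);
  double acc_post = 0.0;

  for (int t = 0; t < n_iter; ++t) {
    for (int j = 0; j < p; ++j) z[j] = norm_rand();
    const double s = std::exp(ls);
    for (int i = 0; i < p; ++i) {
      double d = 0.0;
      for (int j = 0; j <= i; ++j) d += L[i * p + j] * z[j];
      prop[i] = th[i] + s * d;
    }
    const double lp_new = log_post(X, y, off, prop, prior_sd);
    double a = std::exp(std::min(0.0, lp_new - lp));
    if (!R_finite(lp_new)) a = 0.0;
    if (unif_rand() < a) {
      th = prop;
      lp = lp_new;
    }
    if (t < n_warmup) {
      ls += (a - target) / std::sqrt((double)t + 1.0);
      for (int j = 0; j < p; ++j) hist.push_back(th[j]);
      const int m = t + 1;
      if (m >= 100 && m % 50 == 0) {
        // estimate the proposal covariance from the second half of the
        // warmup history, discarding the early transient
        const int lo = m / 2, cnt = m - lo;
        for (int j = 0; j < p; ++j) {
          double mu = 0.0;
          for (int r = lo; r < m; ++r) mu += hist[(size_t)r * p + j];
          mean[j] = mu / cnt;
        }
        for (int i = 0; i < p; ++i)
          for (int j = 0; j <= i; ++j) {
            double c = 0.0;
            for (int r = lo; r < m; ++r)
              c += (hist[(size_t)r * p + i] - mean[i]) *
                   (hist[(size_t)r * p + j] - mean[j]);
            c /= (cnt > 1 ? cnt - 1 : 1);
            if (i == j) c += 1e-8;
            cov[i * p + j] = cov[j * p + i] = c;
          }
        std::vector<double> Lnew;
        if (chol_lower(cov, Lnew, p)) L = Lnew;
      }
    } else {
      acc_post += a;
      for (int j = 0; j < p; ++j) draws(t - n_warmup, j) = th[j];
    }
  }
  return List::create(_["draws"] = draws,
                      _["accept_rate"] = acc_post / n_keep,
                      _["log_scale"] = ls);
}
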