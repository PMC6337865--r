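#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// BayesR single-site Gibbs sampler.
//
// y = mu + X beta + e, with beta_j drawn from a four-component normal
// mixture whose variances are fixed fractions (fracs) of the genetic
// variance sg2; the first fraction is 0 (point mass at zero). Mixing
// proportions get a Dirichlet prior; sg2 and se2 get scaled inverse
// chi-square priors (df0, scale S0g / S0e). All randomness flows through
// R's RNG so set.seed() controls the chain.
//
// fix_pi / fix_sg2 / fix_se2 (NULL or values) pin the corresponding
// parameter, which turns the sampler into its conjugate-Gaussian limit for
// the ridge-regression cross-check.
// [[Rcpp::export]]
List bayesr_gibbs_cpp(const NumericMatrix& X, const NumericVector& y,
                      const NumericVector& fracs, int n_iter, int n_burnin,
                      const NumericVector& dir_prior, double df0,
                      double S0g, double S0e,
                      Nullable<NumericVector> fix_pi,
                      Nullable<double> fix_sg2, Nullable<double> fix_se2) {
  const int n = X.nrow(), m = X.ncol(), K = fracs.size();
  if (y.size() != n) stop("length(y) must match nrow(X)");
  if (n_burnin >= n_iter) stop("n_burnin must be smaller than n_iter");

  RNGScope scope;

  std::vector<double> xtx(m);
  for (int j = 0; j < m; ++j) {
    const double* xj = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
  }

  double ybar = 0.0, vy = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  for (int i = 0; i < n; ++i) vy += (y[i] - ybar) * (y[i] - ybar);
  vy /= (n - 1);

  bool pi_fixed = fix_pi.isNotNull();
  bool sg_fixed = fix_sg2.isNotNull();
  bool se_fixed = fix_se2.isNotNull();
  NumericVector pi(K, 1.0 / K);
  if (pi_fixed) pi = NumericVector(fix_pi);
  // the residual starts as all of y (beta = 0), so se2 starts at vy;
  // sg2 starts at half of vy, a generic data-scaled prior guess
  double sg2 = sg_fixed ? as<double>(fix_sg2) : 0.5 * vy;
  double se2 = se_fixed ? as<double>(fix_se2) : vy;

  double mu = ybar;
  std::vector<double> beta(m, 0.0), resid(n);
  std::vector<int> cls(m, 0);
  for (int i = 0; i < n; ++i) resid[i] = y[i] - mu;

  const int n_keep = n_iter - n_burnin;
  NumericVector beta_mean(m);
  NumericMatrix comp_prob(m, K);
  NumericVector h2_samples(n_keep), sg2_samples(n_keep), se2_samples(n_keep);
  NumericMatrix pi_samples(n_keep, K);
  std::vector<double> logl(K), v(K);

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double rbar = 0.0;
    for (int i = 0; i < n; ++i) rbar += resid[i];
    rbar = rbar / n;
    double mu_new = mu + rbar + R::norm_rand() * std::sqrt(se2 / n);
    double shift = mu_new - mu;
    for (int i = 0; i < n; ++i) resid[i] -= shift;
    mu = mu_new;

    for (int k = 0; k < K; ++k) v[k] = fracs[k] * sg2;

    std::vector<int> nk(K, 0);
    double ssg = 0.0;
    int m_nz = 0;

    for (int j = 0; j < m; ++j) {
      const double* xj = &X(0, j);
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * resid[i];
      rhs += xtx[j] * beta[j];

      double lmax = -INFINITY;
      for (int k = 0; k < K; ++k) {
        double l;
        if (v[k] <= 0.0) {
          l = std::log(pi[k] + 1e-300);
        } else {
          double lam = v[k] * xtx[j] / se2;
          l = std::log(pi[k] + 1e-300) - 0.5 * std::log1p(lam) +
              0.5 * rhs * rhs * v[k] / (se2 * (se2 + xtx[j] * v[k]));
        }
        logl[k] = l;
        if (l > lmax) lmax = l;
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        logl[k] = std::exp(logl[k] - lmax);
        tot += logl[k];
      }
      double u = R::unif_rand() * tot, cum = 0.0;
      int pick = K - 1;
      for (int k = 0; k < K; ++k) {
        cum += logl[k];
        if (u <= cum) { pick = k; break; }
      }

      double beta_new = 0.0;
      if (v[pick] > 0.0) {
        double C = xtx[j] + se2 / v[pick];
        beta_new = rhs / C + R::norm_rand() * std::sqrt(se2 / C);
      }
      double d = beta_new - beta[j];
      if (d != 0.0) for (int i = 0; i < n; ++i) resid[i] -= xj[i] * d;
      beta[j] = beta_new;
      cls[j] = pick;
      nk[pick]++;
      if (v[pick] > 0.0) { ssg += beta_new * beta_new / fracs[pick]; m_nz++; }
    }

    if (!pi_fixed) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        pi[k] = R::rgamma(dir_prior[k] + nk[k], 1.0);
        tot += pi[k];
      }
      for (int k = 0; k < K; ++k) pi[k] /= tot;
    }
    if (!sg_fixed) sg2 = (ssg + df0 * S0g) / R::rchisq(df0 + m_nz);
    if (!se_fixed) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += resid[i] * resid[i];
      se2 = (sse + df0 * S0e) / R::rchisq(n + df0);
    }

    if (it >= n_burnin) {
      int kp = it - n_burnin;
      // genetic values g = y - mu - resid
      double gbar = 0.0;
      for (int i = 0; i < n; ++i) gbar += y[i] - mu - resid[i];
      gbar /= n;
      double vg = 0.0;
      for (int i = 0; i < n; ++i) {
        double g = y[i] - mu - resid[i] - gbar;
        vg += g * g;
      }
      vg /= (n - 1);
      double h2 = vg / vy;
      if (h2 > 1.0) h2 = 1.0;
      h2_samples[kp] = h2;
      sg2_samples[kp] = sg2;
      se2_samples[kp] = se2;
      for (int k = 0; k < K; ++k) pi_samples(kp, k) = pi[k];
      for (int j = 0; j < m; ++j) {
        beta_mean[j] += beta[j];
        comp_prob(j, cls[j]) += 1.0;
      }
    }
  }

  for (int j = 0; j < m; ++j) {
    beta_mean[j] /= n_keep;
    for (int k = 0; k < K; ++k) comp_prob(j, k) /= n_keep;
  }

  return List::create(
      _["effect_means"] = beta_mean, _["component_probs"] = comp_prob,
      _["h2_samples"] = h2_samples, _["pi_samples"] = pi_samples,
      _["sigma_g_samples"] = sg2_samples, _["sigma_e_samples"] = se2_samples,
      _["mu"] = mu);
}
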