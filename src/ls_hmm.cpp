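#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Li-Stephens haplotype-copying forward-backward pass for one target
// haplotype against a reference panel.
//
// ref : H x M matrix of reference alleles (0/1)
// obs : length-M vector of observed target alleles; -1 at untyped sites
// rho : length-(M-1) per-step switch probabilities, rho_j = 1 - exp(-theta_j)
// eps : allele mismatch (genotyping/mutation) probability at typed sites
//
// Transition between adjacent sites: stay on the same reference haplotype
// with probability (1 - rho) + rho / H, move to any specific other haplotype
// with probability rho / H. Emissions are 1-eps / eps at typed sites and
// uninformative (1) at untyped sites. Scaled arithmetic (per-site
// normalisation) keeps the pass stable for long chromosomes.
//
// Returns posterior allele dosages per site and, optionally, the full M x H
// posterior matrix (only sensible for small instances).
// [[Rcpp::export]]
List ls_forward_backward_cpp(const IntegerMatrix& ref, const IntegerVector& obs,
                             const NumericVector& rho, double eps,
                             bool keep_posteriors) {
  const int H = ref.nrow();
  const int M = ref.ncol();
  if (M == 0) stop("reference panel has no variants");
  if (H < 2) stop("reference panel must hold at least 2 haplotypes");
  if (rho.size() != M - 1 && M > 1) stop("rho must have length M-1");

  std::vector<double> alpha((size_t)M * H);
  std::vector<double> emis(H);
  double loglik = 0.0;

  auto emission = [&](int j, int h) -> double {
    int o = obs[j];
    if (o < 0) return 1.0;
    return (ref(h, j) == o) ? (1.0 - eps) : eps;
  };

  // forward, scaled so each site's alpha sums to 1
  {
    double s = 0.0;
    for (int h = 0; h < H; ++h) {
      double a = emission(0, h) / H;
      alpha[h] = a;
      s += a;
    }
    if (s <= 0) stop("forward pass underflow at first site");
    for (int h = 0; h < H; ++h) alpha[h] /= s;
    loglik += std::log(s);
  }
  for (int j = 1; j < M; ++j) {
    const double r = rho[j - 1];
    const double stay = 1.0 - r;
    const double sw = r / H;  // previous alpha sums to 1
    double s = 0.0;
    size_t off = (size_t)j * H, prev = (size_t)(j - 1) * H;
    for (int h = 0; h < H; ++h) {
      double a = emission(j, h) * (stay * alpha[prev + h] + sw);
      alpha[off + h] = a;
      s += a;
    }
    if (s <= 0) stop("forward pass underflow");
    for (int h = 0; h < H; ++h) alpha[off + h] /= s;
    loglik += std::log(s);
  }

  // backward, renormalised per site; combine into posteriors on the fly
  NumericVector dosage(M);
  NumericMatrix post;
  if (keep_posteriors) post = NumericMatrix(M, H);

  std::vector<double> beta(H, 1.0), beta_next(H);
  {
    // site M-1
    size_t off = (size_t)(M - 1) * H;
    double s = 0.0, d = 0.0;
    for (int h = 0; h < H; ++h) s += alpha[off + h] * beta[h];
    for (int h = 0; h < H; ++h) {
      double g = alpha[off + h] * beta[h] / s;
      d += g * ref(h, M - 1);
      if (keep_posteriors) post(M - 1, h) = g;
    }
    dosage[M - 1] = d;
  }
  for (int j = M - 2; j >= 0; --j) {
    const double r = rho[j];
    const double stay = 1.0 - r;
    // beta[h] at j = sum_h' P(h->h') e_{h'}(j+1) beta_{j+1}(h')
    double tot = 0.0;
    for (int h = 0; h < H; ++h) {
      double eb = emission(j + 1, h) * beta[h];
      beta_next[h] = eb;  // reuse as scratch: e*beta at j+1
      tot += eb;
    }
    double s = 0.0;
    for (int h = 0; h < H; ++h) {
      double b = stay * beta_next[h] + (r / H) * tot;
      beta[h] = b;
      s += b;
    }
    if (s <= 0) stop("backward pass underflow");
    for (int h = 0; h < H; ++h) beta[h] /= s;

    size_t off = (size_t)j * H;
    double z = 0.0, d = 0.0;
    for (int h = 0; h < H; ++h) z += alpha[off + h] * beta[h];
    for (int h = 0; h < H; ++h) {
      double g = alpha[off + h] * beta[h] / z;
      d += g * ref(h, j);
      if (keep_posteriors) post(j, h) = g;
    }
    dosage[j] = d;
  }

  List out = List::create(_["dosage"] = dosage, _["loglik"] = loglik);
  if (keep_posteriors) out["posteriors"] = post;
  return out;
}
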