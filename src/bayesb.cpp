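// BayesB marker regression sampler: y = X b + sum_j z_j alpha_j delta_j + e.
// Each locus is excluded (delta_j = 0) with probability pi; when included,
// alpha_j ~ N(0, sigma2_j) with sigma2_j ~ scaled-inv-chi2(nu, s2_alpha),
// which integrates to the t_nu(0, s2_alpha) effect prior.  delta_j is
// sampled from its marginal odds with alpha_j integrated out given
// sigma2_j; sigma2_j is redrawn from the prior while the locus is out of
// the model.  Flat priors on b and sigma2_e (drawn as SSE/chisq_n).
//
// The genotype covariates z_j are centered 0/1/2 codes, which the sampler
// exploits: with index lists of the heterozygous and alt-homozygous
// individuals per locus, z_j' r = (sum_{g=1} r + 2 sum_{g=2} r) - mean_j
// * sum(r), and the uniform -diff*mean_j part of a residual update is
// carried as a scalar shift.  This avoids streaming the full n x k
// matrix every sweep (the cost is memory bandwidth, not flops).
// All randomness goes through the R RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

// chi-squared draw with a fast path for small integer df (the per-locus
// variance df nu and nu + 1 are drawn ~10^8 times per chain):
// chisq_2k = 2 * sum of k Exp(1); an odd df adds one squared normal.
static inline double fast_rchisq(double df) {
  int k = (int)df;
  if (df == (double)k && k >= 2 && k <= 16) {
    // sum of k/2 Exp(1) = -log(product of uniforms): one log in total
    double prod = 1.0;
    for (int i = 0; i < k / 2; ++i) prod *= R::unif_rand();
    double s = -2.0 * std::log(prod);
    if (k % 2) {
      double z = R::norm_rand();
      s += z * z;
    }
    return s;
  }
  return R::rchisq(df);
}

// [[Rcpp::export(name = ".bayesb_cpp")]]
List bayesb_cpp(const arma::vec& y, const arma::mat& X, const arma::mat& G,
                double pi_prior, double nu, double s2_alpha,
                int niter, int burnin, int thin) {
  const uword n = y.n_elem, pf = X.n_cols, k = G.n_cols;
  const int n_ret = (niter - burnin) / thin;

  // per-locus structure of the 0/1/2 codes
  std::vector<std::vector<int> > idx1(k), idx2(k);
  vec mj(k), cz(k);
  for (uword j = 0; j < k; ++j) {
    const double* gj = G.colptr(j);
    double sum = 0.0, sumsq = 0.0;
    for (uword i = 0; i < n; ++i) {
      const double g = gj[i];
      if (g == 1.0) idx1[j].push_back((int)i);
      else if (g == 2.0) idx2[j].push_back((int)i);
      else if (g != 0.0) stop("genotype codes must be 0/1/2");
      sum += g;
      sumsq += g * g;
    }
    mj(j) = sum / n;
    cz(j) = sumsq - n * mj(j) * mj(j); // sum of squared centered codes
  }

  vec b(pf, arma::fill::zeros);
  vec alpha(k, arma::fill::zeros);
  std::vector<int> delta(k, 0);
  vec sigma2(k);
  for (uword j = 0; j < k; ++j)
    sigma2(j) = nu * s2_alpha / fast_rchisq(nu);

  vec cx(pf);
  for (uword l = 0; l < pf; ++l) cx(l) = arma::dot(X.col(l), X.col(l));

  double s2e = arma::var(y);
  if (s2e <= 0) s2e = 1e-8;
  vec r = y; // residual with all effects at 0

  const double log_prior_odds = std::log1p(-pi_prior) - std::log(pi_prior);

  vec pip(k, arma::fill::zeros), alpha_mean(k, arma::fill::zeros);
  mat b_ret(std::max(n_ret, 0), pf);
  vec s2e_ret(std::max(n_ret, 0));
  std::vector<int> tri_j, tri_s;
  std::vector<double> tri_x;
  int ret = 0;

  double* __restrict rp = r.memptr();

  for (int iter = 1; iter <= niter; ++iter) {
    // fixed effects (first column is expected to be the intercept)
    for (uword l = 0; l < pf; ++l) {
      if (cx(l) <= 0) continue;
      double u = arma::dot(X.col(l), r) + cx(l) * b(l);
      double bn = u / cx(l) + R::norm_rand() * std::sqrt(s2e / cx(l));
      r += X.col(l) * (b(l) - bn);
      b(l) = bn;
    }

    // loci: maintain Srb = sum(r) and a scalar shift so that the true
    // residual is r + shift (the centered covariates never see shift)
    double Srb = 0.0;
    for (uword i = 0; i < n; ++i) Srb += rp[i];
    double shift = 0.0;
    for (uword j = 0; j < k; ++j) {
      const double c = cz(j);
      if (c <= 0) {
        // constant covariate: data carry no information, delta from prior
        delta[j] = R::unif_rand() < (1.0 - pi_prior) ? 1 : 0;
        alpha(j) = 0.0;
        sigma2(j) = nu * s2_alpha / fast_rchisq(nu);
        continue;
      }
      double s12 = 0.0;
      const std::vector<int>& i1 = idx1[j];
      const std::vector<int>& i2 = idx2[j];
      for (size_t a = 0; a < i1.size(); ++a) s12 += rp[i1[a]];
      double s2sum = 0.0;
      for (size_t a = 0; a < i2.size(); ++a) s2sum += rp[i2[a]];
      double u = s12 + 2.0 * s2sum - mj(j) * Srb;
      if (delta[j]) u += c * alpha(j);
      const double s2j = sigma2(j);
      const double denom = s2e + c * s2j;
      const double log_lr = 0.5 * std::log(s2e / denom) +
                            0.5 * u * u * s2j / (s2e * denom);
      const double p1 = 1.0 / (1.0 + std::exp(-(log_lr + log_prior_odds)));
      const int d_new = R::unif_rand() < p1 ? 1 : 0;
      double a_new = 0.0;
      if (d_new) {
        const double post_var = s2j * s2e / denom;
        const double post_mean = u * s2j / denom;
        a_new = post_mean + R::norm_rand() * std::sqrt(post_var);
      }
      const double diff = (delta[j] ? alpha(j) : 0.0) - (d_new ? a_new : 0.0);
      if (diff != 0.0) {
        // true update is r += z_j * diff = g_j * diff - mean_j * diff
        for (size_t a = 0; a < i1.size(); ++a) rp[i1[a]] += diff;
        const double d2 = 2.0 * diff;
        for (size_t a = 0; a < i2.size(); ++a) rp[i2[a]] += d2;
        Srb += diff * (double)(i1.size() + 2 * i2.size());
        shift -= diff * mj(j);
      }
      delta[j] = d_new;
      alpha(j) = a_new;
      // per-locus variance
      if (d_new)
        sigma2(j) = (nu * s2_alpha + a_new * a_new) / fast_rchisq(nu + 1.0);
      else
        sigma2(j) = nu * s2_alpha / fast_rchisq(nu);
    }
    // fold the scalar shift back into the stored residual
    if (shift != 0.0) {
      for (uword i = 0; i < n; ++i) rp[i] += shift;
    }

    // residual variance (flat prior)
    s2e = arma::dot(r, r) / R::rchisq((double)n);
    if (s2e < 1e-300) s2e = 1e-300;

    if (iter > burnin && (iter - burnin) % thin == 0) {
      for (uword j = 0; j < k; ++j) {
        if (delta[j]) {
          pip(j) += 1.0;
          alpha_mean(j) += alpha(j);
          tri_j.push_back((int)j);
          tri_s.push_back(ret);
          tri_x.push_back(alpha(j));
        }
      }
      for (uword l = 0; l < pf; ++l) b_ret(ret, l) = b(l);
      s2e_ret(ret) = s2e;
      ++ret;
    }
  }
  if (ret > 0) {
    alpha_mean /= ret; // posterior mean of alpha * delta
    pip /= ret;
  }

  return List::create(
      _["pip"] = pip, _["alpha_mean"] = alpha_mean,
      _["b"] = b_ret, _["sigma2_e"] = s2e_ret,
      _["inc_locus"] = tri_j, _["inc_sample"] = tri_s, _["inc_alpha"] = tri_x,
      _["n_retained"] = ret);
}

// Per-window shares of genomic variance for each retained sample.
// Z: n x k centered covariates; inclusion triplets (locus, sample, alpha);
// win: 1-based window id per locus.  share(w, s) =
// Var_i(window genomic value) / Var_i(total genomic value), 0 if the
// total genomic variance of the sample is 0.
// [[Rcpp::export(name = ".window_shares_cpp")]]
arma::mat window_shares_cpp(const arma::mat& Z,
                            const IntegerVector& inc_locus,
                            const IntegerVector& inc_sample,
                            const NumericVector& inc_alpha,
                            const IntegerVector& win, int n_windows,
                            int n_samples) {
  const uword n = Z.n_rows;
  mat shares(n_windows, n_samples, arma::fill::zeros);
  mat buf(n, n_windows); // lazily used; reset per-sample via touched list
  vec g(n);
  std::vector<int> touched;
  const int m = inc_locus.size();
  int pos = 0;
  for (int s = 0; s < n_samples; ++s) {
    g.zeros();
    touched.clear();
    while (pos < m && inc_sample[pos] == s) {
      const int j = inc_locus[pos];
      const double a = inc_alpha[pos];
      const int w = win[j] - 1;
      if (w >= 0) {
        if (std::find(touched.begin(), touched.end(), w) == touched.end()) {
          buf.col(w).zeros();
          touched.push_back(w);
        }
        buf.col(w) += Z.col(j) * a;
        g += Z.col(j) * a;
      }
      ++pos;
    }
    const double vg = arma::var(g);
    if (vg > 0) {
      for (int w : touched) shares(w, s) = arma::var(buf.col(w)) / vg;
    }
  }
  return shares;
}
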