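// Gibbs sampler for (bi)variate animal models with direct genetic,
// maternal genetic and one iid random term (common litter or maternal
// environment), flat priors on fixed effects and covariance matrices.
//
// Mixed-model layout: per trait, the location vector shares one design
// W = [X | Zd | Zm | Wiid] (n x p); theta is p x t.  Location parameters
// are updated Gauss-Seidel style against the running residual matrix
// e = Y - W theta: for column j the data part of the full conditional is
//   rhs_s = sum_t' R0inv(s,t') (w_j' e_t' + c_j theta(j,t')),
//   precision = R0inv * c_j + prior,
// with c_j = w_j'w_j, so each update costs one pass over the column's
// incidences.  Blocks: all traits of one fixed/iid column (t x t), and
// all genetic effects of one animal (2t x 2t; the direct and maternal
// incidence columns of one animal never hit the same record, so the
// within-block data cross terms vanish).  Genetic prior coupling uses
// G0inv (x) Ainv with G0 ordered (d1..dt, m1..mt); iid prior is
// Cinv (x) I.
//
// Covariance full conditionals under flat (constant-density) priors:
// p(G0 | u) ~ |G0|^{-q/2} exp(-tr(G0^-1 S)/2) = IW(q - m - 1, S) with
// S = U' Ainv U, and analogously for Cc, Cme (df = levels - t - 1) and
// R0 (df = n - t - 1).  The IW(df, S) parameterization has
// E[draw] = S / (df - dim - 1); draws use the Bartlett decomposition of
// Wishart(df, S^-1).  (A df of `level count` instead would correspond to
// a Jeffreys-type |G0|^{-(m+1)/2} prior whose singular-boundary spike can
// trap the chain at degenerate G0.)  All randomness uses the R RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::sp_mat;
using arma::vec;
using arma::uword;

static mat rwish_bartlett(double df, const mat& Sinv) {
  const uword m = Sinv.n_rows;
  mat L = arma::chol(Sinv, "lower");
  mat A(m, m, arma::fill::zeros);
  for (uword i = 0; i < m; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (uword j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  mat LA = L * A;
  return LA * LA.t();
}

// inverse-Wishart draw, IW(df, S); a tiny ridge keeps degenerate scales
// (zero-variance data) sampleable, in which case draws collapse to ~0
static mat riwish(double df, mat S) {
  const uword m = S.n_rows;
  double eps = 1e-12 * (1.0 + arma::trace(S) / m);
  S.diag() += eps;
  mat Sinv = arma::inv_sympd(S);
  mat W = rwish_bartlett(df, Sinv);
  return arma::inv_sympd(W);
}

// Stack-based Cholesky machinery for the small (<= 4 x 4) full-conditional
// blocks; avoids per-block heap allocations in the sweep hot path.
// Returns false if the block precision is not positive definite.
static bool chol_small(const double* B, int m, double* L) {
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = B[i * m + j];
      for (int k = 0; k < j; ++k) s -= L[i * m + k] * L[j * m + k];
      if (i == j) {
        if (s <= 0.0 || !std::isfinite(s)) return false;
        L[i * m + i] = std::sqrt(s);
      } else {
        L[i * m + j] = s / L[j * m + j];
      }
    }
    for (int j = i + 1; j < m; ++j) L[i * m + j] = 0.0;
  }
  return true;
}

// draw ~ N(B^-1 rhs, B^-1) given lower Cholesky L of B (row-major, m <= 4)
static void mvn_from_prec(const double* L, const double* rhs, int m,
                          double* out) {
  double v[4], w[4];
  for (int i = 0; i < m; ++i) { // forward solve L v = rhs
    double s = rhs[i];
    for (int k = 0; k < i; ++k) s -= L[i * m + k] * v[k];
    v[i] = s / L[i * m + i];
  }
  for (int i = m - 1; i >= 0; --i) { // back solve L' w = v -> mean
    double s = v[i];
    for (int k = i + 1; k < m; ++k) s -= L[k * m + i] * w[k];
    w[i] = s / L[i * m + i];
  }
  double z[4];
  for (int i = 0; i < m; ++i) z[i] = R::norm_rand();
  for (int i = m - 1; i >= 0; --i) { // L' u = z gives N(0, B^-1)
    double s = z[i];
    for (int k = i + 1; k < m; ++k) s -= L[k * m + i] * out[k];
    out[i] = s / L[i * m + i];
  }
  for (int i = 0; i < m; ++i) out[i] += w[i];
}

// raw CSC view of a dgCMatrix-backed arma::sp_mat
struct Csc {
  const uword* p;
  const uword* ri;
  const double* x;
  explicit Csc(const sp_mat& M)
      : p(M.col_ptrs), ri(M.row_indices), x(M.values) {}
};

// [[Rcpp::export(name = ".gibbs_animal_cpp")]]
List gibbs_animal_cpp(const arma::mat& Y,
                      const arma::sp_mat& W,
                      int p_fixed, int q, bool has_maternal,
                      int n_iid,
                      const arma::sp_mat& Ainv,
                      int niter, int burnin, int thin,
                      arma::mat G0, arma::mat C, arma::mat R0,
                      const CharacterVector& col_names) {
  const uword n = Y.n_rows, t = Y.n_cols, p = W.n_cols;
  const int m_types = q > 0 ? (has_maternal ? 2 : 1) : 0;
  const uword mt = (uword)(m_types)*t;
  const bool has_iid = n_iid > 0;

  mat theta(p, t, arma::fill::zeros);
  mat E = Y; // running residual (theta = 0)
  mat R0inv = arma::inv_sympd(R0);
  mat G0inv = mt > 0 ? mat(arma::inv_sympd(G0)) : mat();
  mat Cinv = has_iid ? mat(arma::inv_sympd(C)) : mat();

  Csc Wc(W), Ac(Ainv);
  vec wtw_diag(p);
  for (uword j = 0; j < p; ++j) {
    double s = 0.0;
    for (uword k = Wc.p[j]; k < Wc.p[j + 1]; ++k) s += Wc.x[k] * Wc.x[k];
    wtw_diag(j) = s;
  }
  vec ainv_diag(std::max(q, 1), arma::fill::zeros);
  for (int a = 0; a < q; ++a) {
    for (uword k = Ac.p[a]; k < Ac.p[a + 1]; ++k)
      if ((int)Ac.ri[k] == a) ainv_diag(a) = Ac.x[k];
  }

  const int n_ret = (niter - burnin) / thin;
  const uword nc_ret = mt * mt + (has_iid ? t * t : 0) + t * t;
  mat samples(std::max(n_ret, 0), nc_ret);
  mat theta_sum(p, t, arma::fill::zeros);
  int ret = 0;

  const uword jd0 = (uword)p_fixed, jm0 = (uword)p_fixed + q;

  // data-part rhs for one column: u_s = sum_t' R0inv(s,t') (w_j'e_t' + c_j th)
  auto col_data_rhs = [&](uword j, double* u) {
    double we[2] = {0.0, 0.0};
    for (uword k = Wc.p[j]; k < Wc.p[j + 1]; ++k) {
      const uword r = Wc.ri[k];
      const double v = Wc.x[k];
      for (uword s = 0; s < t; ++s) we[s] += v * E(r, s);
    }
    const double cj = wtw_diag(j);
    for (uword s = 0; s < t; ++s) {
      double acc = 0.0;
      for (uword s2 = 0; s2 < t; ++s2)
        acc += R0inv(s, s2) * (we[s2] + cj * theta(j, s2));
      u[s] = acc;
    }
  };

  auto apply_col_delta = [&](uword j, const double* delta) {
    for (uword k = Wc.p[j]; k < Wc.p[j + 1]; ++k) {
      const uword r = Wc.ri[k];
      const double v = Wc.x[k];
      for (uword s = 0; s < t; ++s) E(r, s) -= v * delta[s];
    }
  };

  auto sample_small_block = [&](uword j, const mat& prior_prec) {
    const double cj = wtw_diag(j);
    if (cj <= 0 && prior_prec.n_elem == 0) return;
    double B[4], L[4], rhs[2], draw[2], delta[2];
    col_data_rhs(j, rhs);
    for (uword s = 0; s < t; ++s)
      for (uword s2 = 0; s2 < t; ++s2)
        B[s * t + s2] = R0inv(s, s2) * cj +
            (prior_prec.n_elem > 0 ? prior_prec(s, s2) : 0.0);
    if (!chol_small(B, (int)t, L))
      stop("singular conditional precision for effect '%s'",
           std::string(col_names[j]));
    mvn_from_prec(L, rhs, (int)t, draw);
    for (uword s = 0; s < t; ++s) {
      delta[s] = draw[s] - theta(j, s);
      theta(j, s) = draw[s];
    }
    apply_col_delta(j, delta);
  };

  for (int iter = 1; iter <= niter; ++iter) {
    // ---- fixed effects
    for (uword j = 0; j < (uword)p_fixed; ++j) sample_small_block(j, mat());

    // ---- genetic effects, one animal block at a time
    if (m_types > 0) {
      double gdot[4], Bloc[16], Lloc[16], rhs[4], draw[4], delta[4];
      double urow[4];
      for (int a = 0; a < q; ++a) {
        const uword jcols[2] = {jd0 + (uword)a, jm0 + (uword)a};
        // prior cross-sums over related animals:
        // gdot[(v,s')] = sum_{a'} Ainv(a,a') theta(col(v,a'), s')
        for (uword i = 0; i < mt; ++i) gdot[i] = 0.0;
        for (uword k = Ac.p[a]; k < Ac.p[a + 1]; ++k) {
          const uword ar = Ac.ri[k];
          const double av = Ac.x[k];
          for (int v = 0; v < m_types; ++v) {
            const uword cj = (v == 0 ? jd0 : jm0) + ar;
            for (uword s = 0; s < t; ++s)
              gdot[(uword)v * t + s] += av * theta(cj, s);
          }
        }
        const double aii = ainv_diag(a);
        for (int u = 0; u < m_types; ++u) {
          col_data_rhs(jcols[u], urow);
          const double cu = wtw_diag(jcols[u]);
          for (uword s = 0; s < t; ++s) {
            const uword bi = (uword)u * t + s;
            double r = urow[s];
            for (int v = 0; v < m_types; ++v)
              for (uword s2 = 0; s2 < t; ++s2) {
                const uword bj = (uword)v * t + s2;
                Bloc[bi * mt + bj] =
                    (u == v ? R0inv(s, s2) * cu : 0.0) + G0inv(bi, bj) * aii;
                r -= G0inv(bi, bj) * (gdot[bj] - aii * theta(jcols[v], s2));
              }
            rhs[bi] = r;
          }
        }
        if (!chol_small(Bloc, (int)mt, Lloc))
          stop("singular conditional precision for effect '%s'",
               std::string(col_names[jcols[0]]));
        mvn_from_prec(Lloc, rhs, (int)mt, draw);
        for (int u = 0; u < m_types; ++u) {
          for (uword s = 0; s < t; ++s) {
            const uword bi = (uword)u * t + s;
            delta[s] = draw[bi] - theta(jcols[u], s);
            theta(jcols[u], s) = draw[bi];
          }
          apply_col_delta(jcols[u], delta);
        }
      }
    }

    // ---- iid term
    if (has_iid) {
      const uword ji0 = jd0 + (uword)m_types * q;
      for (uword l = 0; l < (uword)n_iid; ++l) sample_small_block(ji0 + l, Cinv);
    }

    // ---- covariance components
    R0 = riwish((double)n - t - 1.0, E.t() * E);
    R0inv = arma::inv_sympd(R0);

    if (m_types > 0) {
      mat U(q, mt);
      for (int v = 0; v < m_types; ++v)
        for (uword s = 0; s < t; ++s)
          U.col((uword)v * t + s) =
              theta.rows((v == 0 ? jd0 : jm0), (v == 0 ? jd0 : jm0) + q - 1)
                  .col(s);
      mat S = U.t() * (Ainv * U);
      G0 = riwish((double)q - mt - 1.0, S);
      G0inv = arma::inv_sympd(G0);
    }
    if (has_iid) {
      const uword ji0 = jd0 + (uword)m_types * q;
      mat Lm = theta.rows(ji0, ji0 + n_iid - 1);
      C = riwish((double)n_iid - t - 1.0, Lm.t() * Lm);
      Cinv = arma::inv_sympd(C);
    }

    // ---- retain
    if (iter > burnin && (iter - burnin) % thin == 0) {
      uword k = 0;
      for (uword j = 0; j < mt; ++j)
        for (uword i = 0; i < mt; ++i) samples(ret, k++) = G0(i, j);
      if (has_iid)
        for (uword j = 0; j < t; ++j)
          for (uword i = 0; i < t; ++i) samples(ret, k++) = C(i, j);
      for (uword j = 0; j < t; ++j)
        for (uword i = 0; i < t; ++i) samples(ret, k++) = R0(i, j);
      theta_sum += theta;
      ++ret;
    }
  }

  return List::create(
      _["samples"] = samples,
      _["theta_mean"] = ret > 0 ? mat(theta_sum / ret) : theta_sum,
      _["n_retained"] = ret);
}

// [[Rcpp::export(name = ".riwish_cpp")]]
arma::mat riwish_cpp(double df, const arma::mat& S) {
  return riwish(df, mat(S));
}
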