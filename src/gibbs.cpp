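// Single-site Gibbs sampler for the pedigree-based animal model
//   y = X b + Z g + e,  g ~ N(0, A sigma_a^2),  e ~ N(0, R sigma_e^2)
// with a sparse A-inverse (Henderson's rules) and either an identity or a
// dense general residual correlation R. Scalar updates over g keep the
// per-iteration cost at O(nnz(Ainv) + n) for R = I, which is what makes
// chains over pedigrees with thousands of individuals feasible.
//
// Draws use R's RNG so results are reproducible via set.seed() in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".gibbs_animal")]]
List gibbs_animal(const arma::vec& y,
                  const arma::mat& X,
                  const arma::ivec& zid,        // 1-based individual per plot
                  const arma::sp_mat& Ainv,
                  const arma::mat& Rinv,        // ignored if !use_rinv
                  bool use_rinv,
                  int niter, int burnin, int thin,
                  double nu_a, double S_a, double nu_e, double S_e,
                  bool fix_var, double sa2_fix, double se2_fix) {
  RNGScope scope;
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int q = Ainv.n_rows;

  // plots per individual
  std::vector<std::vector<int>> plots(q);
  for (int i = 0; i < n; ++i) plots[zid[i] - 1].push_back(i);

  arma::vec b(p, arma::fill::zeros);
  arma::vec g(q, arma::fill::zeros);
  double sa2 = fix_var ? sa2_fix : arma::var(y);
  double se2 = fix_var ? se2_fix : arma::var(y);
  if (sa2 <= 0) sa2 = 1e-8;
  if (se2 <= 0) se2 = 1e-8;

  // fixed-effect precision pieces
  arma::mat RiX = use_rinv ? arma::mat(Rinv * X) : X;
  arma::mat XtRiX = X.t() * RiX;
  arma::mat XtRiX_chol_inv;
  {
    arma::mat L = arma::chol(XtRiX, "lower");
    XtRiX_chol_inv = arma::inv(arma::trimatl(L));
  }
  // Z' Rinv Z diagonal blocks (scalar per individual)
  arma::vec zRz(q, arma::fill::zeros);
  for (int i = 0; i < q; ++i) {
    const std::vector<int>& pl = plots[i];
    if (pl.empty()) continue;
    if (!use_rinv) {
      zRz[i] = (double)pl.size();
    } else {
      double s = 0.0;
      for (size_t a = 0; a < pl.size(); ++a)
        for (size_t c = 0; c < pl.size(); ++c) s += Rinv(pl[a], pl[c]);
      zRz[i] = s;
    }
  }

  arma::vec r = y;                       // y - X b - Z g (b = g = 0)
  arma::vec u = use_rinv ? arma::vec(Rinv * r) : r;

  // Covariate-genetic sweep moves. A line-level covariate is confounded
  // with the genetic effects (one plot per line), which makes single-site
  // Gibbs mix arbitrarily slowly along the direction (beta_j, -a). For
  // each non-intercept column we add an exact Gibbs update along that
  // direction: propose b_j += delta, g_i -= delta * a_i with a_i the
  // line-mean covariate; the conditional of delta is Gaussian with
  // precision  w'R^-1 w / se2 + a'Ainv a / sa2  and linear term
  // w'R^-1 r / se2 + a'Ainv g / sa2, where w = x_j - Z a is the
  // within-line covariate deviation.
  std::vector<arma::vec> sw_a, sw_w, sw_Riw, sw_Aa;
  std::vector<double> sw_wRw, sw_aAa;
  std::vector<int> sw_col;
  for (int j = 0; j < p; ++j) {
    bool is_intercept = true;
    for (int i = 0; i < n; ++i) {
      if (X(i, j) != X(0, j)) { is_intercept = false; break; }
    }
    if (is_intercept) continue;
    arma::vec a(q, arma::fill::zeros);
    for (int i = 0; i < q; ++i) {
      const std::vector<int>& pl = plots[i];
      if (pl.empty()) continue;
      double s = 0.0;
      for (size_t k2 = 0; k2 < pl.size(); ++k2) s += X(pl[k2], j);
      a[i] = s / pl.size();
    }
    arma::vec w = X.col(j);
    for (int i = 0; i < n; ++i) w[i] -= a[zid[i] - 1];
    arma::vec Riw = use_rinv ? arma::vec(Rinv * w) : w;
    arma::vec Aa = Ainv * a;
    sw_col.push_back(j);
    sw_a.push_back(a);
    sw_w.push_back(w);
    sw_Riw.push_back(Riw);
    sw_Aa.push_back(Aa);
    sw_wRw.push_back(arma::dot(w, Riw));
    sw_aAa.push_back(arma::dot(a, Aa));
  }

  const int n_keep = (niter - burnin + thin - 1) / thin;
  arma::vec keep_sa2(n_keep), keep_se2(n_keep);
  arma::mat keep_b(n_keep, p);
  arma::vec g_sum(q, arma::fill::zeros), g_sumsq(q, arma::fill::zeros);
  int kept = 0, n_accum = 0;

  for (int it = 0; it < niter; ++it) {
    // --- fixed effects: b ~ N((X'RiX)^-1 X'Ri (y - Zg), se2 (X'RiX)^-1)
    arma::vec yzg = r + X * b;           // y - Z g
    arma::vec rhs = RiX.t() * yzg;
    arma::vec bmean = arma::solve(XtRiX, rhs, arma::solve_opts::likely_sympd);
    arma::vec z(p);
    for (int j = 0; j < p; ++j) z[j] = R::rnorm(0.0, 1.0);
    arma::vec bnew = bmean + std::sqrt(se2) * (XtRiX_chol_inv.t() * z);
    arma::vec db = bnew - b;
    b = bnew;
    arma::vec xdb = X * db;
    r -= xdb;
    if (use_rinv) u -= RiX * db; else u = r;

    // --- genetic effects, scalar updates
    for (int i = 0; i < q; ++i) {
      double aii = 0.0, cross = 0.0;
      for (arma::sp_mat::const_col_iterator it2 = Ainv.begin_col(i);
           it2 != Ainv.end_col(i); ++it2) {
        if ((int)it2.row() == i) aii = *it2;
        else cross += (*it2) * g[it2.row()];
      }
      double prec = zRz[i] / se2 + aii / sa2;
      double num = -cross / sa2;
      const std::vector<int>& pl = plots[i];
      if (!pl.empty()) {
        double s = 0.0;
        for (size_t a = 0; a < pl.size(); ++a) s += u[pl[a]];
        num += (s + zRz[i] * g[i]) / se2;
      }
      double gnew = num / prec + R::rnorm(0.0, 1.0) / std::sqrt(prec);
      double d = gnew - g[i];
      g[i] = gnew;
      if (!pl.empty() && d != 0.0) {
        for (size_t a = 0; a < pl.size(); ++a) r[pl[a]] -= d;
        if (use_rinv) {
          for (size_t a = 0; a < pl.size(); ++a) u -= d * Rinv.col(pl[a]);
        } else {
          for (size_t a = 0; a < pl.size(); ++a) u[pl[a]] -= d;
        }
      }
    }
    if (use_rinv) u = Rinv * r;          // refresh against drift

    // --- sweep moves along covariate-genetic confounded directions
    for (size_t s = 0; s < sw_col.size(); ++s) {
      double prec = sw_wRw[s] / se2 + sw_aAa[s] / sa2;
      if (prec <= 0) continue;
      double lin = arma::dot(sw_w[s], u) / se2 +
        arma::dot(sw_Aa[s], g) / sa2;
      double delta = lin / prec + R::rnorm(0.0, 1.0) / std::sqrt(prec);
      b[sw_col[s]] += delta;
      g -= delta * sw_a[s];
      r -= delta * sw_w[s];
      u -= delta * sw_Riw[s];
    }

    // --- variance components
    if (!fix_var) {
      double ss_a = arma::dot(g, Ainv * g);
      sa2 = (ss_a + nu_a * S_a) / R::rchisq((double)q + nu_a);
      double ss_e = arma::dot(r, u);
      se2 = (ss_e + nu_e * S_e) / R::rchisq((double)n + nu_e);
    }

    if (it >= burnin) {
      g_sum += g;
      g_sumsq += arma::square(g);
      ++n_accum;
      if ((it - burnin) % thin == 0) {
        keep_sa2[kept] = sa2;
        keep_se2[kept] = se2;
        keep_b.row(kept) = b.t();
        ++kept;
      }
    }
  }

  arma::vec g_mean = g_sum / n_accum;
  arma::vec g_var = g_sumsq / n_accum - arma::square(g_mean);

  return List::create(
    _["sigma_a2"] = keep_sa2.head(kept),
    _["sigma_e2"] = keep_se2.head(kept),
    _["b"] = keep_b.rows(0, kept - 1),
    _["g_mean"] = g_mean,
    _["g_var"] = g_var,
    _["n_accum"] = n_accum);
}
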