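// ADMM cores for the sparse network lasso on the locally symmetric
// log-contrast model, and for the (constrained) Weber problem used to
// assign coefficient vectors to unseen samples.
//
// Conventions: n samples, p features. Edges are the undirected pairs
// (m, l), m > l, with positive relation weight; each edge carries two
// directed auxiliary copies a_{m,l}, a_{l,m} and scaled duals s_{m,l},
// s_{l,m}. The s-dual is kept in scaled form (update s += w - a), which
// matches the augmented Lagrangian; at rho = 1 this is identical to the
// unscaled update. All state is stored transposed (p x n, p x E) so that
// per-sample / per-edge vectors are contiguous columns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve (2 z z' + c I + psi 1 1') x = rhs by two Sherman-Morrison
// downdates of the scaled identity. psi = 0 gives the unconstrained
// variant. c > 0 required.
static vec solve_rank_structured(const vec& z, double c, double psi,
                                 const vec& rhs) {
  const double p = static_cast<double>(rhs.n_elem);
  auto A1inv = [&](const vec& x) -> vec {
    vec r = x / c;
    if (psi != 0.0) r -= (psi * accu(x) / (c * (c + psi * p))) * ones<vec>(x.n_elem);
    return r;
  };
  vec A1rhs = A1inv(rhs);
  if (!any(z != 0.0)) return A1rhs;
  vec A1z = A1inv(z);
  double denom = 1.0 + 2.0 * dot(z, A1z);
  return A1rhs - A1z * (2.0 * dot(z, A1rhs) / denom);
}

// [[Rcpp::export(name = ".solveRankSystem")]]
arma::vec solve_rank_system(const arma::vec& z, double c, double psi,
                            const arma::vec& rhs) {
  return solve_rank_structured(z, c, psi, rhs);
}

// [[Rcpp::export(name = ".admmSNL")]]
Rcpp::List admm_snl(const arma::mat& Z, const arma::vec& y,
                    const arma::imat& edges, const arma::vec& rw,
                    double lambda1, double lambda2,
                    double rho, double phi, double psi,
                    bool constrained, double tol, int max_iter,
                    bool exact_solve,
                    Rcpp::Nullable<Rcpp::List> init = R_NilValue) {
  const uword n = Z.n_rows, p = Z.n_cols;
  const uword E = edges.n_rows;
  const mat Zt = Z.t();                       // p x n, columns contiguous

  mat W(p, n, fill::zeros), B(p, n, fill::zeros), T(p, n, fill::zeros);
  vec u(n, fill::zeros);
  mat Aml(p, E, fill::zeros), Alm(p, E, fill::zeros);
  mat Sml(p, E, fill::zeros), Slm(p, E, fill::zeros);

  if (init.isNotNull()) {
    Rcpp::List st(init);
    W = Rcpp::as<mat>(st["W"]);   B = Rcpp::as<mat>(st["B"]);
    T = Rcpp::as<mat>(st["T"]);   u = Rcpp::as<vec>(st["u"]);
    Aml = Rcpp::as<mat>(st["Aml"]); Alm = Rcpp::as<mat>(st["Alm"]);
    Sml = Rcpp::as<mat>(st["Sml"]); Slm = Rcpp::as<mat>(st["Slm"]);
    if (W.n_rows != p || W.n_cols != n || Aml.n_cols != E)
      Rcpp::stop("warm-start state does not match the problem dimensions");
  }

  uvec em(E), el(E);
  vec deg(n, fill::zeros);
  for (uword e = 0; e < E; ++e) {
    em(e) = edges(e, 0) - 1;
    el(e) = edges(e, 1) - 1;
    deg(em(e)) += 1.0;
    deg(el(e)) += 1.0;
  }

  const double psi_eff = constrained ? psi : 0.0;
  const double kappa = lambda2 / phi;
  double r_edge = datum::inf, r_b = datum::inf, r_sum = 0.0;
  int it = 0;
  bool converged = false;
  mat M(p, n);
  vec rhs(p), uu(p), vv(p), dvec(p);

  for (it = 1; it <= max_iter; ++it) {
    // accumulate sum over incident edges of (a - s), oriented
    M.zeros();
    for (uword e = 0; e < E; ++e) {
      M.col(em(e)) += Aml.col(e) - Sml.col(e);
      M.col(el(e)) += Alm.col(e) - Slm.col(e);
    }

    // w-update, one structured solve per sample
    for (uword i = 0; i < n; ++i) {
      rhs = 2.0 * y(i) * Zt.col(i) + rho * M.col(i) - T.col(i) +
            phi * B.col(i);
      if (constrained) rhs -= u(i);
      double c = rho * deg(i) + phi;
      if (exact_solve) {
        mat Amat = 2.0 * (Zt.col(i) * Zt.col(i).t()) + c * eye<mat>(p, p);
        if (psi_eff != 0.0) Amat += psi_eff * ones<mat>(p, p);
        W.col(i) = solve(Amat, rhs, solve_opts::likely_sympd);
      } else {
        W.col(i) = solve_rank_structured(Zt.col(i), c, psi_eff, rhs);
      }
    }

    // fusion (a) update: prox of lambda1 r ||a_ml - a_lm||_2
    for (uword e = 0; e < E; ++e) {
      uu = W.col(em(e)) + Sml.col(e);
      vv = W.col(el(e)) + Slm.col(e);
      double nrm = norm(uu - vv, 2);
      double theta = 0.5;
      if (nrm > 0.0)
        theta = std::max(1.0 - lambda1 * rw(e) / (rho * nrm), 0.5);
      Aml.col(e) = theta * uu + (1.0 - theta) * vv;
      Alm.col(e) = (1.0 - theta) * uu + theta * vv;
    }

    // b-update: elementwise soft threshold of w + t/phi
    {
      const double* wp = W.memptr();
      const double* tp = T.memptr();
      double* bp = B.memptr();
      const uword N = n * p;
      for (uword k = 0; k < N; ++k) {
        double x = wp[k] + tp[k] / phi;
        bp[k] = (x > kappa) ? x - kappa : ((x < -kappa) ? x + kappa : 0.0);
      }
    }

    // dual updates (s scaled; t, u unscaled as printed)
    r_edge = 0.0;
    for (uword e = 0; e < E; ++e) {
      dvec = W.col(em(e)) - Aml.col(e);
      Sml.col(e) += dvec;
      double rm = abs(dvec).max();
      if (rm > r_edge) r_edge = rm;
      dvec = W.col(el(e)) - Alm.col(e);
      Slm.col(e) += dvec;
      double rl = abs(dvec).max();
      if (rl > r_edge) r_edge = rl;
    }
    T += phi * (W - B);
    r_sum = 0.0;
    if (constrained) {
      for (uword i = 0; i < n; ++i) {
        double sw = accu(W.col(i));
        u(i) += psi * sw;
        double ri = std::max(std::abs(sw), std::abs(accu(B.col(i))));
        if (ri > r_sum) r_sum = ri;
      }
    }
    r_b = abs(W - B).max();

    if (!W.is_finite() || !B.is_finite())
      Rcpp::stop("ADMM diverged (non-finite iterates); check tuning parameters rho/phi/psi");

    if (std::max(r_edge, std::max(r_b, r_sum)) < tol) {
      converged = true;
      break;
    }
  }
  if (it > max_iter) it = max_iter;

  return Rcpp::List::create(
      Rcpp::Named("W") = W.t(), Rcpp::Named("B") = B.t(),
      Rcpp::Named("iterations") = it,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("residuals") = Rcpp::NumericVector::create(
          Rcpp::Named("fusion") = r_edge, Rcpp::Named("sparsity") = r_b,
          Rcpp::Named("zerosum") = r_sum),
      Rcpp::Named("state") = Rcpp::List::create(
          Rcpp::Named("W") = W, Rcpp::Named("B") = B, Rcpp::Named("T") = T,
          Rcpp::Named("u") = u, Rcpp::Named("Aml") = Aml,
          Rcpp::Named("Alm") = Alm, Rcpp::Named("Sml") = Sml,
          Rcpp::Named("Slm") = Slm));
}

// Constrained / unconstrained Weber problem:
//   min_w sum_i r_i || w - anchor_i ||_2   (s.t. 1'w = 0 if constrained)
// ADMM on the splitting e_i = w - anchor_i.
// [[Rcpp::export(name = ".admmWeber")]]
Rcpp::List admm_weber(const arma::mat& anchors, const arma::vec& wts,
                      bool constrained, double mu, double eta,
                      double tol, int max_iter) {
  const uword n = anchors.n_rows, p = anchors.n_cols;
  const mat At = anchors.t();               // p x n
  vec w = At * (wts / accu(wts));           // weighted-mean start
  if (constrained) w -= accu(w) / p;
  mat Emat(p, n, fill::zeros), U(p, n, fill::zeros);
  double v = 0.0;
  int it = 0;
  bool converged = false;
  double resid = datum::inf;
  vec g(p), rhs(p), d(p);

  for (it = 1; it <= max_iter; ++it) {
    // e-update: group soft threshold toward zero with radius r_i / mu
    for (uword i = 0; i < n; ++i) {
      g = w - At.col(i) - U.col(i) / mu;
      double nrm = norm(g, 2);
      double scale = 0.0;
      if (nrm > 0.0) scale = std::max(1.0 - (wts(i) / mu) / nrm, 0.0);
      Emat.col(i) = scale * g;
    }
    // w-update: (mu n I + eta 1 1')^{-1} [ mu sum_i (e_i + anchor_i + u_i/mu) - v 1 ]
    rhs = mu * (sum(Emat, 1) + sum(At, 1) + sum(U, 1) / mu);
    if (constrained) rhs -= v;
    const double c = mu * static_cast<double>(n);
    w = rhs / c;
    if (constrained)
      w -= (eta * accu(rhs) / (c * (c + eta * p)));

    // duals + residuals
    resid = 0.0;
    for (uword i = 0; i < n; ++i) {
      d = Emat.col(i) - (w - At.col(i));
      U.col(i) += mu * d;
      double ri = abs(d).max();
      if (ri > resid) resid = ri;
    }
    if (constrained) {
      double sw = accu(w);
      v += eta * sw;
      if (std::abs(sw) > resid) resid = std::abs(sw);
    }
    if (!w.is_finite())
      Rcpp::stop("Weber ADMM diverged (non-finite iterates)");
    if (resid < tol) { converged = true; break; }
  }
  if (it > max_iter) it = max_iter;

  return Rcpp::List::create(Rcpp::Named("w") = w,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("residual") = resid);
}
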