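// Consensus ADMM core for the tree-aggregated graphical lasso.
//
// The optimization splits the penalized log-likelihood over copies:
//   Omega(1): log-det + trace term (SPD by construction),
//   Omega(3): off-diagonal l1 (or a fixed edge mask when refitting),
//   Gamma(1): row-wise group penalty on non-root rows, root row held
//             constant across its entries (or a fixed row mask),
//   (Omega(2), Gamma(2), D): exact projection onto the structural set
//             {Omega = A Gamma + diag(D), D >= 0}.
// The consensus variables average the copies; the penalty parameter is
// adapted by residual balancing within a doubling stage schedule.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// prox of -logdet(X) + tr(SX) at V with weight rho/2 * ||X - V||_F^2
static mat logdet_prox_impl(const mat& S, const mat& V, double rho) {
  mat Vs = symmatu((V + V.t()) / 2.0);
  vec lam;
  mat Q;
  eig_sym(lam, Q, symmatu(rho * Vs - S));
  vec xi = (lam + sqrt(square(lam) + 4.0 * rho)) / (2.0 * rho);
  mat X = Q * diagmat(xi) * Q.t();
  return symmatu((X + X.t()) / 2.0);
}

// [[Rcpp::export(name = ".logdet_prox_c")]]
arma::mat logdet_prox_c(const arma::mat& S, const arma::mat& V, double rho) {
  return logdet_prox_impl(S, V, rho);
}

// row-wise group soft-threshold; the root row is projected onto the
// constant-vector set (replaced by its mean)
static mat group_row_prox_impl(const mat& W, double thr, unsigned int root) {
  mat out = W;
  for (unsigned int u = 0; u < W.n_rows; ++u) {
    if (u == root) {
      out.row(u).fill(mean(W.row(u)));
    } else {
      double nrm = norm(W.row(u), 2);
      double scale = (nrm > thr) ? (1.0 - thr / nrm) : 0.0;
      out.row(u) = scale * W.row(u);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".group_row_prox_c")]]
arma::mat group_row_prox_c(const arma::mat& W, double thr, int root1) {
  return group_row_prox_impl(W, thr, (unsigned int)(root1 - 1));
}

static mat offdiag_soft_impl(const mat& U, double thr) {
  mat out = sign(U) % max(abs(U) - thr, zeros<mat>(U.n_rows, U.n_cols));
  out.diag() = U.diag();
  return out;
}

// [[Rcpp::export(name = ".offdiag_soft_c")]]
arma::mat offdiag_soft_c(const arma::mat& U, double thr) {
  return offdiag_soft_impl(U, thr);
}

struct StructProj {
  mat A;
  mat Mchol;    // upper Cholesky factor of I + A'A
  mat Y;        // (I + A'A)^{-1} A'
  vec diagAY;   // diag(A Y)
};

static StructProj make_proj(const mat& A) {
  StructProj pr;
  pr.A = A;
  mat M = eye(A.n_cols, A.n_cols) + A.t() * A;
  pr.Mchol = chol(M);
  pr.Y = solve(trimatu(pr.Mchol), solve(trimatl(pr.Mchol.t()), A.t()));
  pr.diagAY = diagvec(A * pr.Y);
  return pr;
}

// exact projection of (B, G) onto {(Omega, Gamma, D): Omega = A Gamma +
// diag(D), D >= 0}; separable over columns, solved through the normal
// equations of (I + A'A) with a rank-one correction per column, then a
// KKT re-solve for columns whose unconstrained D would be negative
static void struct_proj_impl(const StructProj& pr, const mat& B, const mat& G,
                             mat& Omega2, mat& Gamma2, vec& D) {
  const mat& A = pr.A;
  vec bdiag = B.diag();
  // r_j = A' b_j + G_j - b_jj a_j  => R = A'(B - diag(bdiag)) + G
  mat R = A.t() * (B - diagmat(bdiag)) + G;
  mat X = solve(trimatu(pr.Mchol), solve(trimatl(pr.Mchol.t()), R));
  vec alpha = diagvec(A * X);
  vec coef = alpha / (1.0 - pr.diagAY);
  Gamma2 = X + pr.Y * diagmat(coef);
  D = bdiag - diagvec(A * Gamma2);
  uvec neg = find(D < 0);
  if (neg.n_elem > 0) {
    for (unsigned int k = 0; k < neg.n_elem; ++k) {
      unsigned int j = neg(k);
      Gamma2.col(j) = X.col(j) + bdiag(j) * pr.Y.col(j);
      D(j) = 0.0;
    }
  }
  Omega2 = A * Gamma2;
  Omega2.diag() += D;
}

// [[Rcpp::export(name = ".structural_projection_c")]]
Rcpp::List structural_projection_c(const arma::mat& Omega_target,
                                   const arma::mat& Gamma_target,
                                   const arma::mat& A) {
  StructProj pr = make_proj(A);
  mat Omega2, Gamma2;
  vec D;
  struct_proj_impl(pr, Omega_target, Gamma_target, Omega2, Gamma2, D);
  return Rcpp::List::create(Rcpp::Named("Omega") = Omega2,
                            Rcpp::Named("Gamma") = Gamma2,
                            Rcpp::Named("D") = D);
}

// [[Rcpp::export(name = ".admm_core")]]
Rcpp::List admm_core(const arma::mat& S, const arma::mat& A,
                     double lambda1, double lambda2, int root1,
                     bool constrained,
                     const arma::uvec& Vmask,   // length |T|, used if constrained
                     const arma::mat& Emask,    // p x p 0/1, used if constrained
                     Rcpp::List opts, Rcpp::Nullable<Rcpp::List> init) {
  const unsigned int p = S.n_rows;
  const unsigned int nt = A.n_cols;
  const unsigned int root = (unsigned int)(root1 - 1);

  const double rho0     = Rcpp::as<double>(opts["rho_init"]);
  const double abs_tol  = Rcpp::as<double>(opts["abs_tol"]);
  const double rel_tol  = Rcpp::as<double>(opts["rel_tol"]);
  const int max_iter    = Rcpp::as<int>(opts["max_iter"]);
  const double tau      = Rcpp::as<double>(opts["adapt_factor"]);
  const double mu       = Rcpp::as<double>(opts["adapt_ratio"]);
  const int stage0      = Rcpp::as<int>(opts["stage_init"]);
  const bool adapt      = Rcpp::as<bool>(opts["adapt"]);

  StructProj pr = make_proj(A);

  mat Omega, Gamma, U1, U2, U3, W1, W2;
  double rho = rho0;
  if (init.isNotNull()) {
    Rcpp::List in(init);
    Omega = Rcpp::as<mat>(in["Omega_cons"]);
    Gamma = Rcpp::as<mat>(in["Gamma_cons"]);
    U1 = Rcpp::as<mat>(in["U1"]); U2 = Rcpp::as<mat>(in["U2"]);
    U3 = Rcpp::as<mat>(in["U3"]);
    W1 = Rcpp::as<mat>(in["W1"]); W2 = Rcpp::as<mat>(in["W2"]);
    rho = Rcpp::as<double>(in["rho"]);
  } else {
    vec d0 = 1.0 / clamp(S.diag(), 1e-8, datum::inf);
    Omega = diagmat(d0);
    Gamma = zeros(nt, p);
    U1 = zeros(p, p); U2 = zeros(p, p); U3 = zeros(p, p);
    W1 = zeros(nt, p); W2 = zeros(nt, p);
  }

  mat Omega1 = Omega, Omega2 = Omega, Omega3 = Omega;
  mat Gamma1 = Gamma, Gamma2 = Gamma;
  vec D = Omega.diag();

  const double npar = std::sqrt(3.0 * p * p + 2.0 * nt * p);
  std::vector<double> feas_hist;
  feas_hist.reserve(64);
  bool converged = false;
  int iter = 0;
  int stage_len = stage0, stage_end = stage0;
  double r_norm = datum::inf, s_norm = datum::inf;

  for (iter = 1; iter <= max_iter; ++iter) {
    // block updates
    Omega1 = logdet_prox_impl(S, Omega - U1, rho);
    if (constrained) {
      mat O3 = (Omega - U3 + (Omega - U3).t()) / 2.0;
      Omega3 = O3 % Emask;
      mat G1 = Gamma - W1;
      for (unsigned int u = 0; u < nt; ++u) {
        if (u == root) G1.row(u).fill(mean(G1.row(u)));
        else if (Vmask(u) == 0) G1.row(u).zeros();
      }
      Gamma1 = G1;
    } else {
      Omega3 = offdiag_soft_impl((Omega - U3 + (Omega - U3).t()) / 2.0,
                                 lambda2 / (2.0 * rho));
      Gamma1 = group_row_prox_impl(Gamma - W1, lambda1 / rho, root);
    }
    struct_proj_impl(pr, Omega - U2, Gamma - W2, Omega2, Gamma2, D);

    // consensus (symmetrized) and duals
    mat Omega_prev = Omega, Gamma_prev = Gamma;
    Omega = (Omega1 + U1 + Omega2 + U2 + Omega3 + U3) / 3.0;
    Omega = (Omega + Omega.t()) / 2.0;
    Gamma = (Gamma1 + W1 + Gamma2 + W2) / 2.0;

    U1 += Omega1 - Omega;
    U2 += Omega2 - Omega;
    U3 += Omega3 - Omega;
    W1 += Gamma1 - Gamma;
    W2 += Gamma2 - Gamma;

    feas_hist.push_back(norm(Omega1 - Omega2, "fro"));

    // Boyd-style stopping
    double r2 = std::pow(norm(Omega1 - Omega, "fro"), 2) +
                std::pow(norm(Omega2 - Omega, "fro"), 2) +
                std::pow(norm(Omega3 - Omega, "fro"), 2) +
                std::pow(norm(Gamma1 - Gamma, "fro"), 2) +
                std::pow(norm(Gamma2 - Gamma, "fro"), 2);
    r_norm = std::sqrt(r2);
    s_norm = rho * std::sqrt(3.0 * std::pow(norm(Omega - Omega_prev, "fro"), 2) +
                             2.0 * std::pow(norm(Gamma - Gamma_prev, "fro"), 2));
    double copy_norm = std::sqrt(
        std::pow(norm(Omega1, "fro"), 2) + std::pow(norm(Omega2, "fro"), 2) +
        std::pow(norm(Omega3, "fro"), 2) + std::pow(norm(Gamma1, "fro"), 2) +
        std::pow(norm(Gamma2, "fro"), 2));
    double cons_norm = std::sqrt(3.0 * std::pow(norm(Omega, "fro"), 2) +
                                 2.0 * std::pow(norm(Gamma, "fro"), 2));
    double dual_norm = rho * std::sqrt(
        std::pow(norm(U1, "fro"), 2) + std::pow(norm(U2, "fro"), 2) +
        std::pow(norm(U3, "fro"), 2) + std::pow(norm(W1, "fro"), 2) +
        std::pow(norm(W2, "fro"), 2));
    double eps_pri = npar * abs_tol + rel_tol * std::max(copy_norm, cons_norm);
    double eps_dual = npar * abs_tol + rel_tol * dual_norm;
    if (r_norm < eps_pri && s_norm < eps_dual) {
      converged = true;
      break;
    }

    // locally adaptive penalty: residual balancing every 10 iterations
    // within doubling stages, scaled duals rescaled with rho
    if (adapt && iter < max_iter / 2 && iter % 10 == 0) {
      double fac = 1.0;
      if (r_norm > mu * s_norm) fac = tau;
      else if (s_norm > mu * r_norm) fac = 1.0 / tau;
      if (fac != 1.0) {
        rho *= fac;
        U1 /= fac; U2 /= fac; U3 /= fac;
        W1 /= fac; W2 /= fac;
      }
    }
    if (iter == stage_end) {
      stage_len *= 2;
      stage_end += stage_len;
    }
  }
  if (iter > max_iter) iter = max_iter;

  return Rcpp::List::create(
      Rcpp::Named("Omega") = Omega1,
      Rcpp::Named("Omega_sparse") = Omega3,
      Rcpp::Named("Gamma") = Gamma1,
      Rcpp::Named("Gamma_proj") = Gamma2,
      Rcpp::Named("D") = D,
      Rcpp::Named("Omega_cons") = Omega,
      Rcpp::Named("Gamma_cons") = Gamma,
      Rcpp::Named("U1") = U1, Rcpp::Named("U2") = U2, Rcpp::Named("U3") = U3,
      Rcpp::Named("W1") = W1, Rcpp::Named("W2") = W2,
      Rcpp::Named("rho") = rho,
      Rcpp::Named("iterations") = iter,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("primal_residual") = r_norm,
      Rcpp::Named("dual_residual") = s_norm,
      Rcpp::Named("feasibility_gap") = feas_hist);
}
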