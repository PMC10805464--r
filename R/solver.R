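#' Solver configuration for the LA-ADMM algorithm
#'
#' @param rho_init initial augmented-Lagrangian penalty parameter.
#' @param abs_tol,rel_tol absolute and relative tolerances of the combined
#'   (Boyd-style) primal/dual stopping criterion.
#' @param max_iter total iteration budget.
#' @param adapt_factor factor by which the penalty parameter is multiplied
#'   (or divided) when the residuals are unbalanced.
#' @param adapt_ratio imbalance ratio that triggers an adaptation step.
#' @param stage_init length of the first stage of the doubling stage
#'   schedule (50, 100, 200, ...).
#' @param adapt logical; disable to run plain fixed-penalty ADMM.
#' @param warn logical; warn when the iteration budget is exhausted before
#'   the tolerances are met.
#' @return A list of class `taglasso_config`.
#' @export
solver_config <- function(rho_init = 1, abs_tol = 1e-5, rel_tol = 1e-5,
                          max_iter = 2000L, adapt_factor = 2, adapt_ratio = 10,
                          stage_init = 50L, adapt = TRUE, warn = TRUE) {
  stopifnot(rho_init > 0, abs_tol > 0, rel_tol > 0, max_iter >= 1,
            adapt_factor > 1, adapt_ratio > 1, stage_init >= 1)
  structure(list(rho_init = rho_init, abs_tol = abs_tol, rel_tol = rel_tol,
                 max_iter = as.integer(max_iter), adapt_factor = adapt_factor,
                 adapt_ratio = adapt_ratio, stage_init = as.integer(stage_init),
                 adapt = adapt, warn = warn),
            class = "taglasso_config")
}

#' Proximal operator of the Gaussian log-likelihood term
#'
#' Returns the minimizer over symmetric positive-definite `X` of
#' `-logdet(X) + tr(S X) + (rho/2) ||X - V||_F^2`, computed in closed form
#' through the eigendecomposition of `rho V - S` with eigenvalue map
#' `x_i = (l_i + sqrt(l_i^2 + 4 rho)) / (2 rho)`.  All output eigenvalues
#' are strictly positive, so the iterate stays SPD at every ADMM step.
#'
#' @param S p x p covariance matrix.
#' @param V p x p symmetric proximal target.
#' @param rho positive weight.
#' @return The SPD minimizer.
#' @export
logdet_prox <- function(S, V, rho) {
  stopifnot(rho > 0)
  if (max(abs(V - t(V))) > 1e-8 * (1 + max(abs(V)))) {
    stop("`V` must be symmetric")
  }
  .logdet_prox_c(S, V, rho)
}

#' Row-wise group soft-thresholding with a protected root row
#'
#' Applies the group-lasso proximal map to every non-root row, scaling row
#' `u` by `max(0, 1 - threshold / ||w_u||_2)` (an exact zero at or below
#' the threshold), and projects the root row onto the constant-vector set
#' by replacing it with its mean.  The root is never thresholded: a large
#' aggregation penalty yields complete aggregation, not a zero matrix.
#'
#' @param W |T| x p matrix (rows indexed by tree nodes).
#' @param threshold nonnegative group threshold.
#' @param root_row row index of the root node.
#' @return The thresholded matrix.
#' @export
group_row_prox <- function(W, threshold, root_row) {
  stopifnot(threshold >= 0, root_row >= 1, root_row <= nrow(W))
  out <- .group_row_prox_c(W, threshold, as.integer(root_row))
  dimnames(out) <- dimnames(W)
  out
}

#' Soft-threshold the off-diagonal entries of a symmetric matrix
#'
#' @param U p x p symmetric matrix.
#' @param threshold nonnegative threshold; entries with absolute value at or
#'   below it become exact zeros, larger entries shrink toward zero.
#' @return Matrix with unchanged diagonal and thresholded off-diagonal.
#' @export
offdiag_soft_threshold <- function(U, threshold) {
  stopifnot(threshold >= 0)
  out <- .offdiag_soft_c(U, threshold)
  dimnames(out) <- dimnames(U)
  out
}

#' Exact projection onto the structural constraint set
#'
#' Minimizes `||Omega - Omega_target||_F^2 + ||Gamma - Gamma_target||_F^2`
#' subject to `Omega = A Gamma + diag(D)` with `D >= 0`.  The problem
#' separates over columns; each column solves the normal equations of
#' `I + A'A` with a rank-one correction, and columns whose unconstrained
#' diagonal residual would be negative are re-solved with that entry
#' clamped at zero (the KKT active set has at most one scalar constraint
#' per column, so the two-step solve is exact).
#'
#' @param Omega_target p x p target for the structural precision copy.
#' @param Gamma_target |T| x p target for the structural parameter copy.
#' @param A ancestor matrix from [build_ancestor_matrix()].
#' @return List with `Omega`, `Gamma`, `D` satisfying the constraints
#'   exactly.
#' @export
structural_projection <- function(Omega_target, Gamma_target, A) {
  out <- .structural_projection_c(Omega_target, Gamma_target, A)
  out$D <- as.numeric(out$D)
  rownames(out$Gamma) <- colnames(A)
  dimnames(out$Omega) <- dimnames(Omega_target)
  out
}

#' Fit the tag-lasso by locally adaptive ADMM
#'
#' Solves the tree-aggregated graphical lasso: the Gaussian negative
#' log-likelihood `-logdet(Omega) + tr(S Omega)` plus `lambda1` times the
#' group norm of the non-root rows of `Gamma` (node aggregation along the
#' tree) and `lambda2` times the l1 norm of the unique off-diagonal entries
#' of `Omega` (edge sparsity), subject to `Omega = A Gamma + diag(D)`,
#' `D >= 0`, a constant root row, and symmetric positive-definite `Omega`.
#' With `lambda1 = 0` the problem reduces to the graphical lasso.
#'
#' @param S p x p sample covariance matrix (maximum-likelihood scaling; see
#'   [cov_mle()]).
#' @param A ancestor matrix of the similarity tree.
#' @param lambda1 nonnegative aggregation penalty.
#' @param lambda2 nonnegative edge-sparsity penalty.
#' @param config a [solver_config()].
#' @param init optional warm-start state from a previous fit (its `state`
#'   component).
#' @return A `taglasso_estimate`: `Omega` (the SPD log-likelihood copy),
#'   `Gamma` (the exactly row-sparse aggregation copy), `D`, `support`
#'   (active node ids), `edges` (logical p x p adjacency read from the
#'   exactly sparse copy), `partition`, `K`, solver diagnostics, and a
#'   `state` component usable to warm-start neighboring penalty values.
#' @export
taglasso_fit <- function(S, A, lambda1, lambda2, config = solver_config(),
                         init = NULL) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  check_covariance(S, nrow(A))
  root <- attr(A, "root_column")
  nt <- ncol(A)
  fit <- .admm_core(S, A, lambda1, lambda2, root, FALSE,
                    integer(nt), matrix(1, 1, 1), unclass(config), init)
  finish_estimate(fit, S, A, lambda1 = lambda1, lambda2 = lambda2,
                  config = config)
}

#' Constrained maximum-likelihood refit on fixed supports
#'
#' Re-estimates the precision matrix by maximizing the Gaussian likelihood
#' subject to hard aggregation and sparsity constraints: `Gamma` rows
#' outside the active node set `V` are fixed at zero and off-diagonal
#' precision entries outside the edge set are fixed at zero.  Used both for
#' cross-validation scoring and for the oracle benchmark (refit at the true
#' supports).
#'
#' @param S p x p sample covariance matrix.
#' @param A ancestor matrix.
#' @param V active node ids (character, matching `colnames(A)`) or a
#'   logical/integer column selector; the root is always kept active.
#' @param edges logical p x p matrix, `TRUE` where an off-diagonal entry may
#'   be nonzero (symmetrized internally; the diagonal is always free), or
#'   `NULL` for no sparsity constraint.
#' @param config a [solver_config()].
#' @param init optional warm-start state.
#' @return A `taglasso_estimate` (with `lambda1 = lambda2 = NA`).
#' @export
taglasso_refit <- function(S, A, V, edges = NULL, config = solver_config(),
                           init = NULL) {
  check_covariance(S, nrow(A))
  p <- nrow(A)
  root <- attr(A, "root_column")
  vmask <- integer(ncol(A))
  if (is.logical(V)) {
    stopifnot(length(V) == ncol(A))
    vmask[V] <- 1L
  } else if (is.character(V)) {
    miss <- setdiff(V, colnames(A))
    if (length(miss)) stop("unknown node id(s) in `V`: ",
                           paste(miss, collapse = ", "))
    vmask[match(V, colnames(A))] <- 1L
  } else {
    vmask[as.integer(V)] <- 1L
  }
  vmask[root] <- 1L
  if (is.null(edges)) {
    E <- matrix(1, p, p)
  } else {
    stopifnot(is.matrix(edges), all(dim(edges) == p))
    E <- (edges | t(edges)) * 1
    diag(E) <- 1
  }
  fit <- .admm_core(S, A, 0, 0, root, TRUE, vmask, E, unclass(config), init)
  finish_estimate(fit, S, A, lambda1 = NA_real_, lambda2 = NA_real_,
                  config = config)
}

#' Graphical lasso as the zero-aggregation special case
#'
#' Runs the same LA-ADMM machinery with `lambda1 = 0` on a star tree
#' (every leaf a direct child of the root), for which the structural
#' constraint is vacuous; the result is the graphical lasso estimate with
#' penalty `lambda2` on the unique off-diagonal entries.
#'
#' @param S p x p sample covariance matrix.
#' @param lambda2 nonnegative edge-sparsity penalty.
#' @param config a [solver_config()].
#' @param init optional warm-start state.
#' @return A `taglasso_estimate`.
#' @export
glasso_fit <- function(S, lambda2, config = solver_config(), init = NULL) {
  A <- star_ancestor_matrix(nrow(S), colnames(S))
  taglasso_fit(S, A, lambda1 = 0, lambda2 = lambda2, config = config,
               init = init)
}

star_ancestor_matrix <- function(p, names = NULL) {
  if (is.null(names)) names <- paste0("V", seq_len(p))
  parent <- stats::setNames(c(rep("root", p), NA_character_),
                            c(names, "root"))
  build_ancestor_matrix(similarity_tree(parent, names))
}

finish_estimate <- function(fit, S, A, lambda1, lambda2, config) {
  Omega <- fit$Omega
  dimnames(Omega) <- dimnames(S)
  Gamma <- fit$Gamma
  rownames(Gamma) <- colnames(A)
  Os <- fit$Omega_sparse
  edges <- Os != 0
  diag(edges) <- FALSE
  edges <- edges | t(edges)
  supp <- support_set(Gamma)
  # the root's parameter row is unpenalized, so the root node is always an
  # available aggregation column even when its fitted row is zero
  part <- partition_from_support(A, union(supp, colnames(A)[attr(A, "root_column")]))
  if (isTRUE(config$warn) && !isTRUE(fit$converged)) {
    warning("ADMM stopped after ", fit$iterations,
            " iterations before reaching tolerance (primal ",
            format(fit$primal_residual, digits = 3), ", dual ",
            format(fit$dual_residual, digits = 3), ")")
  }
  structure(
    list(Omega = Omega,
         Gamma = Gamma,
         D = as.numeric(fit$D),
         Omega_sparse = fit$Omega_sparse,
         edges = edges,
         support = supp,
         partition = part,
         K = part$K,
         lambda1 = lambda1, lambda2 = lambda2,
         iterations = fit$iterations,
         converged = isTRUE(fit$converged),
         primal_residual = fit$primal_residual,
         dual_residual = fit$dual_residual,
         feasibility_gap = fit$feasibility_gap,
         state = fit[c("Omega_cons", "Gamma_cons", "U1", "U2", "U3",
                       "W1", "W2", "rho")]),
    class = "taglasso_estimate")
}

#' @export
print.taglasso_estimate <- function(x, ...) {
  cat("taglasso_estimate: p =", nrow(x$Omega), ", K =", x$K,
      ", edges =", sum(x$edges) / 2, "\n")
  if (!is.na(x$lambda1)) {
    cat("penalties: lambda1 =", format(x$lambda1, digits = 4),
        ", lambda2 =", format(x$lambda2, digits = 4), "\n")
  } else {
    cat("constrained maximum-likelihood refit\n")
  }
  cat("solver:", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Tag-lasso objective value
#'
#' Evaluates `-logdet(Omega) + tr(S Omega) + lambda1 * sum_u ||gamma_u||_2 +
#' lambda2 * sum_{i<j} |Omega_ij|`, with the group sum over non-root rows.
#'
#' @param S covariance matrix.
#' @param lambda1,lambda2 penalties.
#' @param Omega precision matrix (SPD).
#' @param Gamma aggregation parameter matrix.
#' @param root_row index of the root row of `Gamma`.
#' @return The objective value.
#' @export
taglasso_objective <- function(S, lambda1, lambda2, Omega, Gamma, root_row) {
  ld <- determinant(Omega, logarithm = TRUE)
  if (ld$sign <= 0) stop("`Omega` must be positive definite")
  nll <- -as.numeric(ld$modulus) + sum(S * Omega)
  grp <- sqrt(rowSums(Gamma^2))[-root_row]
  nll + lambda1 * sum(grp) + lambda2 * sum(abs(Omega[upper.tri(Omega)]))
}

#' Maximum-likelihood sample covariance
#'
#' Column-centers the data and uses the `1/n` denominator, matching the
#' covariance that enters the Gaussian likelihood.
#'
#' @param X n x p data matrix.
#' @param center optional vector of column means to center by (defaults to
#'   the column means of `X`); pass training means when evaluating held-out
#'   folds.
#' @return p x p covariance matrix.
#' @export
cov_mle <- function(X, center = NULL) {
  X <- as.matrix(X)
  if (is.null(center)) center <- colMeans(X)
  Xc <- sweep(X, 2L, center, "-")
  crossprod(Xc) / nrow(X)
}

check_covariance <- function(S, p) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("`S` must be a square matrix")
  if (nrow(S) != p) stop("`S` and the ancestor matrix disagree on p")
  if (max(abs(S - t(S))) > 1e-8 * (1 + max(abs(S)))) {
    stop("`S` must be symmetric")
  }
  invisible(TRUE)
}
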