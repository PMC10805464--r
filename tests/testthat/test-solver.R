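tight <- solver_config(abs_tol = 1e-8, rel_tol = 1e-8, max_iter = 20000,
                       warn = FALSE)

test_that("the log-det proximal map matches its closed forms and stays SPD", {
  # S = 0, V = I, rho = 1: fixed point of -1/x + x - 1 = 0, the golden ratio
  expect_equal(logdet_prox(matrix(0, 2, 2), diag(2), 1),
               diag((1 + sqrt(5)) / 2, 2))
  # S = V = I: eigenvalues 0 map to 1
  expect_equal(logdet_prox(diag(3), diag(3), 1), diag(3))
  # scalar quadratic-formula case
  expect_equal(logdet_prox(matrix(2), matrix(0), 1)[1, 1], (-2 + sqrt(8)) / 2)
  expect_error(logdet_prox(diag(2), matrix(c(1, 2, 3, 4), 2, 2), 1),
               "symmetric")
  set.seed(2)
  for (i in 1:20) {
    p <- sample(2:8, 1)
    S <- crossprod(matrix(rnorm(p * p), p))
    V <- matrix(rnorm(p * p), p); V <- (V + t(V)) / 2
    X <- logdet_prox(S, V, runif(1, 0.1, 5))
    expect_gt(min(eigen(X, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("group row prox zeroes small rows and holds the root constant", {
  W <- rbind(c(3, 4), c(0.6, 0.8), c(1, 3))
  out <- group_row_prox(W, threshold = 1, root_row = 3)
  expect_equal(out[1, ], c(2.4, 3.2))     # norm 5 scaled by 4/5
  expect_equal(out[2, ], c(0, 0))         # norm exactly 1: annihilated
  expect_equal(out[3, ], c(2, 2))         # root projected to its mean
  # zero threshold leaves non-root rows untouched
  expect_equal(group_row_prox(W, 0, 3)[1:2, ], W[1:2, ])
})

test_that("off-diagonal soft-thresholding preserves the diagonal", {
  U <- matrix(c(1, 0.3, -0.05, 0.3, 2, 0, -0.05, 0, 3), 3, 3)
  out <- offdiag_soft_threshold(U, 0.1)
  expect_equal(diag(out), diag(U))
  expect_equal(out[1, 2], 0.2)
  expect_equal(out[1, 3], 0)
  expect_equal(out, t(out))
  expect_equal(offdiag_soft_threshold(U, 0), U)
  expect_equal(offdiag_soft_threshold(diag(3), 10), diag(3))
})

test_that("proximal operators are nonexpansive", {
  set.seed(3)
  for (i in 1:30) {
    x <- matrix(rnorm(12), 3, 4)
    y <- matrix(rnorm(12), 3, 4)
    thr <- runif(1, 0, 2)
    expect_lte(norm(group_row_prox(x, thr, 1) - group_row_prox(y, thr, 1), "F"),
               norm(x - y, "F") + 1e-12)
    u <- matrix(rnorm(9), 3); u <- u + t(u)
    v <- matrix(rnorm(9), 3); v <- v + t(v)
    expect_lte(norm(offdiag_soft_threshold(u, thr) -
                      offdiag_soft_threshold(v, thr), "F"),
               norm(u - v, "F") + 1e-12)
  }
})

test_that("the structural projection is exact", {
  tr <- read_tree("((a,b)ab,(c,d)cd)root;")
  A <- build_ancestor_matrix(tr)
  set.seed(4)
  # a feasible point projects to itself
  G0 <- matrix(rnorm(ncol(A) * 4), ncol(A), 4)
  D0 <- runif(4, 0.5, 2)
  Om0 <- A %*% G0 + diag(D0)
  pr <- structural_projection(Om0, G0, A)
  expect_equal(pr$Gamma, G0, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(pr$D, D0, tolerance = 1e-10)
  # projections satisfy the constraint exactly and D >= 0
  for (i in 1:10) {
    B <- matrix(rnorm(16), 4)
    G <- matrix(rnorm(ncol(A) * 4), ncol(A), 4)
    pr <- structural_projection(B, G, A)
    expect_equal(pr$Omega, A %*% pr$Gamma + diag(pr$D), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(all(pr$D >= 0))
    # independent oracle: smooth box-constrained quadratic program
    nt <- ncol(A)
    obj <- function(th) {
      Gm <- matrix(th[seq_len(nt * 4)], nt, 4)
      d <- th[nt * 4 + 1:4]
      sum((A %*% Gm + diag(d) - B)^2) + sum((Gm - G)^2)
    }
    o <- optim(c(as.numeric(pr$Gamma), pr$D), obj, method = "L-BFGS-B",
               lower = c(rep(-Inf, nt * 4), rep(0, 4)),
               control = list(maxit = 2000, factr = 10))
    o2 <- optim(c(numeric(nt * 4), rep(1, 4)), obj, method = "L-BFGS-B",
                lower = c(rep(-Inf, nt * 4), rep(0, 4)),
                control = list(maxit = 5000, factr = 10))
    best <- min(o$value, o2$value)
    expect_lte(obj(c(as.numeric(pr$Gamma), pr$D)), best + 1e-6)
  }
})

test_that("the single-leaf structural projection solves the scalar KKT", {
  A <- matrix(1, 1, 1, dimnames = list("a", "a"))
  attr(A, "root_column") <- 1L
  # minimize (g + d - b)^2 + (g - g0)^2, d >= 0
  pr <- structural_projection(matrix(5), matrix(1), A)
  expect_equal(unname(pr$Gamma[1, 1] + pr$D), 5)       # interior solution
  pr2 <- structural_projection(matrix(-3), matrix(1), A)
  expect_equal(pr2$D, 0)                               # clamped
  expect_equal(unname(pr2$Gamma[1, 1]), (-3 + 1) / 2)  # re-solved at d = 0
})

test_that("the ADMM attains the convex optimum on random instances", {
  set.seed(7)
  for (i in 1:6) {
    inst <- random_instance(p = sample(3:6, 1), n = 40)
    l1 <- runif(1, 0.05, 0.5)
    l2 <- runif(1, 0.02, 0.3)
    oracle <- convex_oracle(inst$S, inst$A, l1, l2, inst$root)
    fit <- taglasso_fit(inst$S, inst$A, l1, l2, config = tight)
    obj <- taglasso_objective(inst$S, l1, l2, fit$Omega, fit$Gamma,
                              inst$root)
    expect_lt(abs(obj - oracle$objective) / abs(oracle$objective), 1e-5)
  }
})

test_that("zero aggregation penalty reproduces the graphical lasso", {
  skip_if_not(python_sklearn_available(),
              "python with scikit-learn not available")
  set.seed(8)
  truth <- design_precision("chain", p = 10, K = 2, block_sizes = c(5, 5))
  X <- sample_mvn(truth$Omega, 80, seed = 3)
  S <- cov_mle(X)
  for (l2 in c(0.05, 0.2)) {
    fit <- glasso_fit(S, l2, config = tight)
    ref <- ref_glasso(S, l2)
    expect_lt(max(abs(fit$Omega - ref)), 1e-4)
  }
})

test_that("a large aggregation penalty collapses to one block", {
  set.seed(9)
  inst <- random_instance(p = 6, n = 50)
  fit <- taglasso_fit(inst$S, inst$A, lambda1 = 100, lambda2 = 0.01,
                      config = tight)
  expect_equal(fit$K, 1L)
  expect_equal(fit$support, colnames(inst$A)[inst$root])
  # all off-diagonal entries equal the root scalar
  off <- fit$Omega[upper.tri(fit$Omega)]
  expect_lt(diff(range(off)), 1e-5)
})

test_that("a large edge penalty at zero aggregation yields the diagonal MLE", {
  set.seed(10)
  inst <- random_instance(p = 5, n = 50)
  fit <- taglasso_fit(inst$S, inst$A, lambda1 = 0, lambda2 = 1e4,
                      config = tight)
  expect_equal(diag(fit$Omega), 1 / diag(inst$S), tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(sum(fit$edges), 0)
})

test_that("the feasibility gap between copies converges to zero", {
  set.seed(11)
  inst <- random_instance(p = 6, n = 60)
  fit <- taglasso_fit(inst$S, inst$A, 0.3, 0.1, config = tight)
  gap <- fit$feasibility_gap
  expect_lt(gap[length(gap)], 1e-6)
  expect_lt(gap[length(gap)], gap[1])
  # the reported precision is SPD
  expect_gt(min(eigen(fit$Omega, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("the solution is equivariant under variable permutation", {
  set.seed(12)
  truth <- design_precision("chain", p = 9, K = 3)
  X <- sample_mvn(truth$Omega, 90, seed = 4)
  tree <- ideal_tree(truth$partition)
  A <- build_ancestor_matrix(tree)
  fit <- taglasso_fit(cov_mle(X), A, 0.5, 0.1, config = tight)
  perm <- sample(9)
  Xp <- X[, perm]
  treep <- similarity_tree(tree$parent, tree$leaf_order[perm])
  Ap <- build_ancestor_matrix(treep)
  fitp <- taglasso_fit(cov_mle(Xp), Ap, 0.5, 0.1, config = tight)
  expect_equal(fitp$Omega, fit$Omega[perm, perm], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("refitting solves the constrained likelihood problem", {
  set.seed(13)
  inst <- random_instance(p = 6, n = 60)
  A <- inst$A
  # vacuous constraints: the unconstrained MLE S^{-1}
  rf <- taglasso_refit(inst$S, A, V = colnames(A), edges = NULL,
                       config = tight)
  expect_equal(rf$Omega, solve(inst$S), tolerance = 1e-5, ignore_attr = TRUE)
  # empty edge set: the diagonal MLE
  E0 <- matrix(FALSE, 6, 6)
  rf0 <- taglasso_refit(inst$S, A, V = colnames(A), edges = E0,
                        config = tight)
  expect_equal(diag(rf0$Omega), 1 / diag(inst$S), tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_lt(max(abs(rf0$Omega[upper.tri(rf0$Omega)])), 1e-6)
})

test_that("warm starts reach the same solution as cold starts", {
  set.seed(14)
  inst <- random_instance(p = 6, n = 60)
  cold <- taglasso_fit(inst$S, inst$A, 0.3, 0.1, config = tight)
  near <- taglasso_fit(inst$S, inst$A, 0.35, 0.12, config = tight)
  warm <- taglasso_fit(inst$S, inst$A, 0.3, 0.1, config = tight,
                       init = near$state)
  expect_equal(warm$Omega, cold$Omega, tolerance = 1e-5)
  expect_equal(warm$support, cold$support)
})

test_that("non-convergence is reported, never silent", {
  set.seed(15)
  inst <- random_instance(p = 6, n = 60)
  starved <- solver_config(abs_tol = 1e-12, rel_tol = 1e-12, max_iter = 5L,
                           stage_init = 5L)
  expect_warning(taglasso_fit(inst$S, inst$A, 0.3, 0.1, config = starved),
                 "iterations")
  fit <- suppressWarnings(taglasso_fit(inst$S, inst$A, 0.3, 0.1,
                                       config = starved))
  expect_false(fit$converged)
})
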