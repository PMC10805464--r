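#' Default 10 x 10 tuning grid
#'
#' The edge penalty anchor is `max |S_jk|` over off-diagonal entries (the
#' smallest penalty that removes every edge at zero aggregation is bounded
#' by it); the aggregation anchor is found by a doubling search until the
#' fit aggregates everything into a single block.  Both sequences are
#' log-spaced over `decades` orders of magnitude below their anchors,
#' sorted descending.
#'
#' @param S p x p sample covariance matrix.
#' @param A ancestor matrix of the similarity tree.
#' @param n_lambda1,n_lambda2 grid lengths (default 10 each).
#' @param decades span of each sequence in log10 units.
#' @param config solver configuration used inside the doubling search (a
#'   loosened copy of the default).
#' @return List of class `taglasso_grid` with descending `lambda1_values`
#'   and `lambda2_values`.
#' @export
default_grid <- function(S, A, n_lambda1 = 10, n_lambda2 = 10, decades = 2,
                         config = solver_config(abs_tol = 1e-4,
                                                rel_tol = 1e-4,
                                                max_iter = 500L,
                                                warn = FALSE)) {
  off <- abs(S)
  diag(off) <- 0
  # smallest edge penalty whose glasso fit (lambda1 = 0) is exactly
  # diagonal: 2 max|S_jk| under the once-per-pair penalty convention
  l2max <- 2 * max(off)
  if (l2max <= .Machine$double.eps) {
    # no off-diagonal signal: degenerate single-point edge grid
    lambda2_values <- .Machine$double.eps
    n_lambda2 <- 1L
  } else {
    lambda2_values <- l2max * 10^seq(0, -decades, length.out = n_lambda2)
  }
  l1 <- max(l2max, 0.01)
  for (i in seq_len(25L)) {
    fit <- taglasso_fit(S, A, lambda1 = l1, lambda2 = min(lambda2_values),
                        config = config)
    if (fit$K == 1L) break
    l1 <- 2 * l1
  }
  lambda1_values <- l1 * 10^seq(0, -decades, length.out = n_lambda1)
  structure(list(lambda1_values = lambda1_values,
                 lambda2_values = lambda2_values),
            class = "taglasso_grid")
}

#' Held-out likelihood score of a precision estimate
#'
#' `-logdet(Omega_hat) + tr(S_test Omega_hat)`: the Gaussian negative
#' log-likelihood of the held-out covariance under the trained precision
#' matrix, the quantity averaged over folds during cross-validation.
#'
#' @param Omega_hat SPD precision estimate (or a `taglasso_estimate`).
#' @param S_test held-out sample covariance (PSD).
#' @return Finite scalar score (smaller is better).
#' @export
cv_score <- function(Omega_hat, S_test) {
  if (inherits(Omega_hat, "taglasso_estimate")) Omega_hat <- Omega_hat$Omega
  ld <- determinant(Omega_hat, logarithm = TRUE)
  if (ld$sign <= 0) stop("`Omega_hat` must be positive definite")
  as.numeric(-ld$modulus) + sum(S_test * Omega_hat)
}

#' Deterministic fold assignment
#'
#' @param n number of samples.
#' @param folds number of folds; fold sizes differ by at most one.
#' @param seed integer seed; the assignment is a pure function of
#'   `(n, folds, seed)`.
#' @return Integer vector of fold labels in `1..folds`.
#' @export
cv_folds <- function(n, folds = 5, seed = 1) {
  stopifnot(n >= folds)
  withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
}

#' Cross-validated tag-lasso
#'
#' For every grid cell and fold, fits the tag-lasso on the training folds,
#' extracts the selected aggregation and sparsity supports, refits by
#' constrained maximum likelihood on the training covariance, and scores
#' the refit against the held-out fold's covariance (centered by the
#' training means, with the fold size as denominator).  The pair minimizing
#' the mean held-out score wins, with ties broken toward larger penalties;
#' the final model is a fit plus refit on the full data at the selected
#' pair.
#'
#' @param X n x p data matrix.
#' @param tree a [similarity_tree] over the columns of `X`.
#' @param grid a grid from [default_grid()], or `NULL` to build one from the
#'   full-data covariance.
#' @param folds number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @param refit logical; when `FALSE` the penalized estimate itself is
#'   scored and returned (used for the plain graphical lasso, which has no
#'   refitting step in its tuning).
#' @param K_max optional upper bound on the number of aggregated blocks:
#'   the selection is restricted to grid cells whose full-data fit has
#'   `K <= K_max` (constrained cross-validation).  Requires a full-data fit
#'   per cell; errors if no cell qualifies.
#' @param config a [solver_config()]; convergence warnings are silenced
#'   during the grid sweep and re-checked on the final fit.
#' @return A `taglasso_cv`: `scores` (data frame over the grid with mean
#'   held-out score and, when `K_max` is given, the full-data `K`),
#'   `best_lambda1`, `best_lambda2`, `fold_assignments`, `fit` (full-data
#'   penalized fit at the selected pair) and `estimate` (the final refit,
#'   or the fit itself when `refit = FALSE`).
#' @export
cross_validate <- function(X, tree, grid = NULL, folds = 5, seed = 1,
                           refit = TRUE, K_max = NULL,
                           config = solver_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  A <- build_ancestor_matrix(tree)
  stopifnot(ncol(X) == nrow(A))
  S_full <- cov_mle(X)
  if (is.null(grid)) grid <- default_grid(S_full, A)
  cells <- expand.grid(lambda2 = grid$lambda2_values,
                       lambda1 = grid$lambda1_values)[, c("lambda1", "lambda2")]
  # traversal: lambda1 descending (outer), lambda2 descending (inner), so
  # which.min's first-minimum rule prefers the most parsimonious tie
  fold_id <- cv_folds(n, folds, seed)
  if (min(tabulate(fold_id, folds)) < 2L) {
    stop("a fold has fewer than 2 samples; reduce `folds`")
  }
  quiet <- config
  quiet$warn <- FALSE
  S_train <- vector("list", folds)
  S_test <- vector("list", folds)
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    mu_tr <- colMeans(X[tr, , drop = FALSE])
    S_train[[k]] <- cov_mle(X[tr, , drop = FALSE])
    S_test[[k]] <- cov_mle(X[!tr, , drop = FALSE], center = mu_tr)
  }
  n_cells <- nrow(cells)
  fold_scores <- matrix(NA_real_, n_cells, folds)
  warm <- vector("list", folds)        # per-fold warm starts across cells
  warm_full <- NULL
  K_full <- rep(NA_integer_, n_cells)
  for (i in seq_len(n_cells)) {
    l1 <- cells$lambda1[i]; l2 <- cells$lambda2[i]
    for (k in seq_len(folds)) {
      fit_k <- taglasso_fit(S_train[[k]], A, l1, l2, config = quiet,
                            init = warm[[k]])
      warm[[k]] <- fit_k$state
      score_fit <- fit_k
      if (refit) {
        score_fit <- tryCatch(
          taglasso_refit(S_train[[k]], A, fit_k$support, fit_k$edges,
                         config = quiet, init = fit_k$state),
          error = function(e) NULL)
      }
      fold_scores[i, k] <- if (is.null(score_fit)) Inf else
        cv_score(score_fit, S_test[[k]])
    }
    if (!is.null(K_max)) {
      full_i <- taglasso_fit(S_full, A, l1, l2, config = quiet,
                             init = warm_full)
      warm_full <- full_i$state
      K_full[i] <- full_i$K
    }
  }
  mean_scores <- rowMeans(fold_scores)
  eligible <- if (is.null(K_max)) rep(TRUE, n_cells) else K_full <= K_max
  if (!any(eligible)) {
    stop("no grid cell satisfies K <= ", K_max)
  }
  sel <- which(eligible)[which.min(mean_scores[eligible])]
  best1 <- cells$lambda1[sel]; best2 <- cells$lambda2[sel]
  fit <- taglasso_fit(S_full, A, best1, best2, config = config)
  estimate <- fit
  if (refit) {
    estimate <- taglasso_refit(S_full, A, fit$support, fit$edges,
                               config = config, init = fit$state)
  }
  scores <- cbind(cells, score = mean_scores)
  if (!is.null(K_max)) scores$K <- K_full
  structure(list(scores = scores,
                 best_lambda1 = best1, best_lambda2 = best2,
                 fold_assignments = fold_id,
                 fit = fit, estimate = estimate,
                 K_max = K_max),
            class = "taglasso_cv")
}

#' @export
print.taglasso_cv <- function(x, ...) {
  cat("taglasso_cv: selected lambda1 =", format(x$best_lambda1, digits = 4),
      ", lambda2 =", format(x$best_lambda2, digits = 4),
      "-> K =", x$estimate$K, "\n")
  invisible(x)
}

#' Cross-validation restricted to at most `K_max` aggregated blocks
#'
#' Identical to [cross_validate()] but the selection is restricted to grid
#' cells whose full-data fit yields at most `K_max` blocks, for use when a
#' pre-determined maximum number of aggregated nodes is wanted.
#'
#' @inheritParams cross_validate
#' @param K_max maximum number of blocks (at least 1).
#' @return A `taglasso_cv`.
#' @export
constrained_cross_validate <- function(X, tree, grid = NULL, K_max,
                                       folds = 5, seed = 1,
                                       config = solver_config()) {
  stopifnot(K_max >= 1)
  cross_validate(X, tree, grid = grid, folds = folds, seed = seed,
                 refit = TRUE, K_max = K_max, config = config)
}

#' Cross-validated graphical lasso
#'
#' The zero-aggregation special case tuned over a 10-point edge-penalty
#' grid; the held-out score uses the penalized estimate itself (no
#' refitting), and the returned partition is the all-singletons partition
#' the graphical lasso corresponds to.
#'
#' @param X n x p data matrix.
#' @param n_lambda2 grid length.
#' @param folds,seed,config as in [cross_validate()].
#' @return A `taglasso_cv` whose `estimate` is the glasso fit at the
#'   selected penalty.
#' @export
cross_validate_glasso <- function(X, n_lambda2 = 10, folds = 5, seed = 1,
                                  config = solver_config()) {
  X <- as.matrix(X)
  p <- ncol(X)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))
  colnames(X) <- nm
  tree <- attr(star_ancestor_matrix(p, nm), "tree")
  S <- cov_mle(X)
  off <- abs(S); diag(off) <- 0
  l2max <- max(2 * off, .Machine$double.eps)
  grid <- structure(list(lambda1_values = 0,
                         lambda2_values = l2max * 10^seq(0, -2, length.out = n_lambda2)),
                    class = "taglasso_grid")
  out <- cross_validate(X, tree, grid = grid, folds = folds, seed = seed,
                        refit = FALSE, config = config)
  # the graphical lasso performs no aggregation: its partition is singletons
  singles <- partition(stats::setNames(seq_len(p), nm))
  out$estimate$partition <- singles
  out$estimate$K <- p
  out
}
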