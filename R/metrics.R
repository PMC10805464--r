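#' Kullback-Leibler distance between true and estimated Gaussians
#'
#' `KL = -logdet(Sigma %*% Omega_hat) + tr(Sigma %*% Omega_hat) - p`,
#' which is zero exactly when the estimated precision matrix equals the
#' inverse of the true covariance.
#'
#' @param Sigma_true true p x p covariance matrix (SPD).
#' @param Omega_hat estimated p x p precision matrix (SPD).
#' @return Nonnegative scalar.
#' @export
kl_distance <- function(Sigma_true, Omega_hat) {
  if (inherits(Omega_hat, "taglasso_estimate")) Omega_hat <- Omega_hat$Omega
  P <- Sigma_true %*% Omega_hat
  ld <- determinant(P, logarithm = TRUE)
  if (ld$sign <= 0) stop("inputs must be positive definite")
  as.numeric(-ld$modulus + sum(diag(P)) - nrow(P))
}

#' Rand and adjusted Rand indices between two partitions
#'
#' Pair-counting similarity between two partitions of the same `p`
#' variables.  The Rand index is the fraction of the `choose(p, 2)`
#' variable pairs on which the partitions agree (together in both, or apart
#' in both); it is 1 exactly for identical partitions.  The adjusted Rand
#' index rescales by the expected agreement of random partitions with the
#' same margins (hypergeometric model); it is reported as `NA` when the
#' correction's denominator is zero, which happens e.g. when both
#' partitions consist of singletons.
#'
#' @param partition_true,partition_est `taglasso_partition` objects or bare
#'   membership vectors of equal length.
#' @return Named list with `rand` and `adj_rand`.
#' @export
rand_indices <- function(partition_true, partition_est) {
  a <- as_membership(partition_true)
  b <- as_membership(partition_est)
  if (length(a) != length(b)) stop("partitions are over different p")
  p <- length(a)
  tab <- table(a, b)
  n_pairs <- choose(p, 2)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  # agreements = pairs together in both + pairs apart in both
  rand <- (n_pairs + 2 * sum_ij - sum_a - sum_b) / n_pairs
  expected <- sum_a * sum_b / n_pairs
  denom <- (sum_a + sum_b) / 2 - expected
  adj <- if (abs(denom) < .Machine$double.eps * 4) NA_real_ else
    (sum_ij - expected) / denom
  list(rand = rand, adj_rand = adj)
}

as_membership <- function(x) {
  if (inherits(x, "taglasso_partition")) x$membership else
    match(x, unique(x))
}

#' False positive and false negative rates of sparsity recovery
#'
#' Counts unordered off-diagonal pairs only (the diagonal of a precision
#' matrix is always nonzero and the sparsity penalty never touches it).
#' FPR is the fraction of truly zero pairs estimated nonzero; FNR the
#' fraction of truly nonzero pairs estimated zero.  A rate whose
#' denominator is empty (no true zeros, or no true nonzeros) is `NA`.
#'
#' @param Omega_true true p x p precision matrix.
#' @param Omega_hat estimated precision matrix, or a `taglasso_estimate`
#'   (whose exactly sparse copy then supplies the zero pattern).
#' @param tol entries of plain-matrix inputs with absolute value at or
#'   below `tol` count as zero.
#' @return Named list with `fpr` and `fnr`.
#' @export
sparsity_rates <- function(Omega_true, Omega_hat, tol = 0) {
  up <- upper.tri(Omega_true)
  truth <- abs(Omega_true[up]) > tol
  if (inherits(Omega_hat, "taglasso_estimate")) {
    est <- Omega_hat$edges[up]
  } else {
    est <- abs(Omega_hat[up]) > tol
  }
  n_zero <- sum(!truth)
  n_nonzero <- sum(truth)
  fpr <- if (n_zero == 0) NA_real_ else sum(est & !truth) / n_zero
  fnr <- if (n_nonzero == 0) NA_real_ else sum(!est & truth) / n_nonzero
  list(fpr = fpr, fnr = fnr)
}

#' Evaluate an estimate against the simulation truth
#'
#' @param estimate a `taglasso_estimate` (or list with `Omega`, `edges`,
#'   `partition`).
#' @param truth a list with `Sigma` (true covariance), `Omega` (true
#'   precision) and `partition` (true `taglasso_partition`), as produced by
#'   [design_precision()] plus [sample_mvn()].
#' @return One-row data frame with columns `kl`, `rand`, `adj_rand`, `fpr`,
#'   `fnr`, `K`.
#' @export
evaluate_estimate <- function(estimate, truth) {
  ri <- rand_indices(truth$partition, estimate$partition)
  sr <- sparsity_rates(truth$Omega, estimate)
  data.frame(kl = kl_distance(truth$Sigma, estimate$Omega),
             rand = ri$rand, adj_rand = ri$adj_rand,
             fpr = sr$fpr, fnr = sr$fnr,
             K = estimate$partition$K)
}
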