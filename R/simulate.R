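#' Benchmark precision-matrix designs
#'
#' Generates the true precision matrix, partition, and aggregated edge set
#' of the four benchmark designs.  All designs use unit diagonal,
#' within-block off-diagonal value 0.5, and cross-block value 0.25 on the
#' aggregated edges:
#' \describe{
#'   \item{chain}{`K` equal blocks; adjacent blocks (in index order) are
#'     connected.}
#'   \item{random}{`K` equal blocks; a single aggregated edge drawn
#'     uniformly at random.}
#'   \item{unbalanced}{chain connectivity with unequal block sizes
#'     (default `(8, 4, 3)` at `p = 15`).}
#'   \item{unstructured}{no aggregation (`K = p`): a sparse random support
#'     with roughly 10% off-diagonal density at value 0.25,
#'     rejection-sampled until positive definite.}
#' }
#'
#' @param name design name.
#' @param p number of variables.
#' @param K number of aggregation blocks (ignored for `unstructured`).
#' @param block_sizes optional explicit block sizes summing to `p`.
#' @param seed integer seed for the random choices of the `random` and
#'   `unstructured` designs.
#' @param within,cross,diagonal entry values of the G-block structure.
#' @return List of class `taglasso_truth` with `Omega`, `Sigma`
#'   (its inverse), `partition` (a `taglasso_partition`), `aggregated_edges`
#'   (two-column matrix of block pairs), and the design parameters.
#' @export
design_precision <- function(name = c("chain", "random", "unbalanced",
                                      "unstructured"),
                             p = 15, K = 3, block_sizes = NULL, seed = 1,
                             within = 0.5, cross = 0.25, diagonal = 1) {
  name <- match.arg(name)
  if (name == "unstructured") {
    return(unstructured_truth(p, seed, cross = cross, diagonal = diagonal))
  }
  if (is.null(block_sizes)) {
    block_sizes <- if (name == "unbalanced") {
      if (K != 3) stop("default unbalanced sizes are defined for K = 3; ",
                       "pass `block_sizes` for other K")
      sz <- round(p * c(8, 4, 3) / 15)
      sz[1] <- p - sum(sz[-1])
      sz
    } else {
      if (p %% K != 0) stop("`p` must be divisible by `K` for equal blocks")
      rep(p %/% K, K)
    }
  }
  if (sum(block_sizes) != p || any(block_sizes < 1)) {
    stop("`block_sizes` must be positive and sum to p")
  }
  K <- length(block_sizes)
  if (K < 2) stop("aggregation designs need K >= 2")
  membership <- rep(seq_len(K), block_sizes)
  names(membership) <- paste0("V", seq_len(p))
  part <- partition(membership)
  edges <- switch(name,
    chain = , unbalanced = cbind(seq_len(K - 1), 2:K),
    random = {
      pairs <- t(utils::combn(K, 2))
      pairs[withr::with_seed(seed, sample.int(nrow(pairs), 1L)), , drop = FALSE]
    })
  C <- matrix(0, K, K)
  diag(C) <- within
  C[edges] <- cross
  C <- pmax(C, t(C))
  D <- rep(diagonal - within, p)
  if (any(D < 0)) stop("`diagonal` must be at least `within`")
  Omega <- assemble_precision(gblock_model(part$M, C, D))
  dimnames(Omega) <- list(names(membership), names(membership))
  finish_truth(name, Omega, part, edges, block_sizes)
}

unstructured_truth <- function(p, seed, cross = 0.25, diagonal = 1,
                               density = 0.10, max_tries = 200) {
  pairs <- t(utils::combn(p, 2))
  vars <- paste0("V", seq_len(p))
  draws <- withr::with_seed(seed, {
    lapply(seq_len(max_tries), function(i) {
      stats::runif(nrow(pairs)) < density
    })
  })
  for (keep in draws) {
    Omega <- diag(diagonal, p)
    idx <- pairs[keep, , drop = FALSE]
    Omega[idx] <- cross
    Omega[idx[, 2:1, drop = FALSE]] <- cross
    if (min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values) > 1e-6) {
      dimnames(Omega) <- list(vars, vars)
      part <- partition(stats::setNames(seq_len(p), vars))
      return(finish_truth("unstructured", Omega, part, idx, rep(1L, p)))
    }
  }
  stop("could not draw a positive-definite unstructured support")
}

finish_truth <- function(name, Omega, part, edges, block_sizes) {
  ev <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) {
    stop("design '", name, "' produced a non-positive-definite precision ",
         "matrix (min eigenvalue ", format(ev, digits = 3), ")")
  }
  Sigma <- solve(Omega)
  Sigma <- (Sigma + t(Sigma)) / 2
  structure(list(design = name, p = nrow(Omega), K = part$K,
                 block_sizes = as.integer(block_sizes),
                 Omega = Omega, Sigma = Sigma, partition = part,
                 aggregated_edges = edges),
            class = "taglasso_truth")
}

#' The two-dependent-variables toy model
#'
#' The model `X_1 = sum_{j>=3} X_j + e_1`, `X_2 = sum_{j>=3} X_j + e_2`,
#' `X_j = e_j` with iid standard normal noise: its full p-variable precision
#' matrix is dense (order p^2 edges), while aggregating variables 3..p into
#' their sum gives a 3-node model whose precision has a single zero --
#' variables 1 and 2 are conditionally independent given the sum.
#'
#' @param p number of variables, at least 4.
#' @return List with the full `Sigma` and `Omega` and the aggregated 3 x 3
#'   `Sigma_agg` and `Omega_agg`.
#' @export
toy_example <- function(p) {
  stopifnot(p >= 4)
  q <- p - 2
  ones <- rep(1, q)
  Sigma <- rbind(
    cbind(matrix(c(p - 1, p - 2, p - 2, p - 1), 2, 2), matrix(1, 2, q)),
    cbind(matrix(1, q, 2), diag(q)))
  L <- diag(q) + 2 * tcrossprod(ones)
  Omega <- rbind(
    cbind(diag(2), matrix(-1, 2, q)),
    cbind(matrix(-1, q, 2), L))
  Sigma_agg <- matrix(p - 2, 3, 3)
  Sigma_agg[1, 1] <- Sigma_agg[2, 2] <- p - 1
  Omega_agg <- matrix(c(1, 0, -1,
                        0, 1, -1,
                        -1, -1, 2 + 1 / (p - 2)), 3, 3)
  list(Sigma = Sigma, Omega = Omega,
       Sigma_agg = Sigma_agg, Omega_agg = Omega_agg)
}

#' Ideal depth-2 tree containing a partition as its only internal level
#'
#' Builds the tree root -> one internal node per block -> leaves, so the
#' true aggregation is the sole grouping level between leaves and root.
#' Singleton blocks still get an internal node, giving `|T| = p + K + 1`.
#'
#' @param partition_true a `taglasso_partition`.
#' @return A [similarity_tree].
#' @export
ideal_tree <- function(partition_true) {
  m <- partition_true$membership
  leaves <- names(m)
  if (is.null(leaves)) leaves <- paste0("V", seq_along(m))
  block_ids <- vapply(seq_len(partition_true$K), function(k) {
    paste(sort(leaves[m == k]), collapse = "+")
  }, character(1))
  block_ids <- paste0("b_", block_ids)
  parent <- c(stats::setNames(block_ids[m], leaves),
              stats::setNames(rep("root", partition_true$K), block_ids),
              stats::setNames(NA_character_, "root"))
  similarity_tree(parent, leaves)
}

#' Realistic tree from hierarchical clustering of latent points
#'
#' Emulates trees learned from data rather than handed down as a clean
#' two-level hierarchy: each aggregation block `i` gets a latent cluster
#' mean `1/i`, one latent scalar per variable is drawn from
#' `N(1/i, (noise_factor * min_gap_i)^2)` where `min_gap_i` is the smallest
#' distance from `1/i` to another cluster mean, and the dendrogram of a
#' hierarchical clustering of the latent points becomes the similarity
#' tree.  The construction is re-drawn (with a fresh sub-seed) until every
#' true block appears as a branch of the tree, so the true aggregation is
#' recoverable but sits at varying depths below the root.
#'
#' @param partition_true a `taglasso_partition` giving the block sizes.
#' @param seed integer seed.
#' @param linkage linkage method passed to [stats::hclust()].
#' @param noise_factor noise scale relative to the smallest gap between
#'   cluster means.
#' @param max_tries number of redraws before giving up.
#' @return A [similarity_tree] whose branch set contains every true block.
#' @export
realistic_tree <- function(partition_true, seed = 1, linkage = "complete",
                           noise_factor = 0.05, max_tries = 50) {
  m <- partition_true$membership
  K <- partition_true$K
  leaves <- names(m)
  if (is.null(leaves)) leaves <- paste0("V", seq_along(m))
  mu <- 1 / seq_len(K)
  gaps <- vapply(seq_len(K), function(i) min(abs(mu[i] - mu[-i])), numeric(1))
  blocks <- split(leaves, m)
  for (try in seq_len(max_tries)) {
    pts <- withr::with_seed(seed + (try - 1L) * 7919L, {
      stats::rnorm(length(m), mean = mu[m], sd = noise_factor * gaps[m])
    })
    names(pts) <- leaves
    hc <- stats::hclust(stats::dist(pts), method = linkage)
    hc$labels <- leaves
    tree <- as_similarity_tree(hc)
    if (all(vapply(blocks, branch_in_tree, logical(1), tree = tree))) {
      return(tree)
    }
  }
  stop("no clustering of the latent points contained every true block ",
       "as a branch after ", max_tries, " draws")
}

branch_in_tree <- function(block, tree) {
  if (length(block) == 1L) return(TRUE)  # single leaves are trivially branches
  sets <- branch_leaf_sets(tree)
  any(vapply(sets, function(s) setequal(s, block), logical(1)))
}

branch_leaf_sets <- function(tree) {
  children <- split(names(tree$parent)[!is.na(tree$parent)],
                    tree$parent[!is.na(tree$parent)])
  leaves <- tree$leaf_order
  sets <- list()
  rec <- function(v) {
    kids <- children[[v]]
    if (is.null(kids)) return(v)
    s <- unlist(lapply(kids, rec))
    sets[[length(sets) + 1L]] <<- s
    s
  }
  rec(tree$root)
  sets
}

#' Draw multivariate normal samples from a precision matrix
#'
#' @param Omega_true p x p SPD precision matrix; samples have covariance
#'   `solve(Omega_true)`.
#' @param n sample size.
#' @param seed integer seed; the draw is a deterministic function of
#'   `(Omega_true, n, seed)`.
#' @return n x p data matrix (columns named after `Omega_true`'s rows).
#' @export
sample_mvn <- function(Omega_true, n, seed = 1) {
  p <- nrow(Omega_true)
  ev <- min(eigen(Omega_true, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("`Omega_true` must be positive definite")
  Sigma <- solve(Omega_true)
  R <- chol((Sigma + t(Sigma)) / 2)
  Z <- withr::with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  X <- Z %*% R
  colnames(X) <- rownames(Omega_true)
  X
}
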