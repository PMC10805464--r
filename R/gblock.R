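#' G-block precision models
#'
#' A precision matrix has G-block structure for a partition with membership
#' matrix `M` when it can be written `Omega = M C M' + diag(D)` for a
#' symmetric K x K matrix `C` and nonnegative diagonal `D`.  All
#' off-diagonal entries between (or within) a pair of blocks then share one
#' value, and `C` carries the conditional-independence structure of the
#' aggregated (block-summed) variables.
#'
#' @param M p x K binary membership matrix (one 1 per row).
#' @param C K x K symmetric matrix.
#' @param D length-p vector of nonnegative diagonal entries.
#' @return An object of class `gblock_model`.
#' @export
gblock_model <- function(M, C, D) {
  M <- as.matrix(M)
  C <- as.matrix(C)
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8))) {
    stop("`C` must be symmetric")
  }
  if (any(rowSums(M) != 1)) stop("`M` must have exactly one 1 per row")
  if (any(colSums(M) < 1)) stop("`M` must have no empty groups")
  if (length(D) != nrow(M)) stop("`D` must have length nrow(M)")
  if (any(D < 0)) stop("`D` entries must be nonnegative")
  structure(list(M = M, C = (C + t(C)) / 2, D = as.numeric(D)),
            class = "gblock_model")
}

#' Assemble the full precision matrix of a G-block model
#'
#' @param model a [gblock_model()].
#' @return The p x p matrix `M C M' + diag(D)`.
#' @export
assemble_precision <- function(model) {
  Omega <- model$M %*% model$C %*% t(model$M) + diag(model$D)
  (Omega + t(Omega)) / 2
}

#' Precision matrix of the aggregated (block-summed) variables
#'
#' For `X ~ N(0, Omega^{-1})` with `Omega = M C M' + diag(D)` and `D > 0`,
#' the block sums `M' X` have precision `C + (M' D^{-1} M)^{-1}`; the
#' second term is diagonal, so `C[k, l] = 0` is equivalent to conditional
#' independence of aggregated nodes `k` and `l`.
#'
#' Entries of `D` that are exactly zero are lifted to
#' `1e-8 * max(D)` before inverting (the aggregated-precision formula needs
#' an invertible `D`); the result then carries attribute
#' `"zero_D_adjusted" = TRUE`.
#'
#' @param model a [gblock_model()].
#' @return The K x K aggregated precision matrix.
#' @export
aggregated_precision <- function(model) {
  D <- model$D
  adjusted <- FALSE
  if (any(D == 0)) {
    eps <- 1e-8 * max(D, 1)
    D <- pmax(D, eps)
    adjusted <- TRUE
  }
  Dagg <- solve(t(model$M) %*% (model$M / D))
  out <- model$C + Dagg
  out <- (out + t(out)) / 2
  if (adjusted) attr(out, "zero_D_adjusted") <- TRUE
  out
}

#' Decompose a fitted precision matrix into G-block form
#'
#' Recovers the block matrix `C` from a precision estimate and a partition
#' by least squares through the membership matrix,
#' `C = (M'M)^{-1} M' (Omega - diag(D)) M (M'M)^{-1}`,
#' and checks that reassembly reproduces `Omega - diag(D)`.
#'
#' @param Omega p x p precision matrix (or a `taglasso_estimate`, whose
#'   `Omega` and `D` are then used).
#' @param partition a `taglasso_partition` consistent with the block
#'   structure of `Omega`.
#' @param D length-p diagonal vector; defaults to the estimate's `D`.
#' @param tol maximum allowed max-norm reassembly residual.
#' @return A [gblock_model()].
#' @export
decompose_to_gblock <- function(Omega, partition, D = NULL, tol = 1e-6) {
  if (inherits(Omega, "taglasso_estimate")) {
    if (is.null(D)) D <- Omega$D
    Omega <- Omega$Omega
  }
  if (is.null(D)) stop("`D` is required when `Omega` is a plain matrix")
  M <- partition$M
  B <- Omega - diag(D, nrow(Omega))
  MtM_inv <- solve(crossprod(M))
  C <- MtM_inv %*% t(M) %*% B %*% M %*% MtM_inv
  C <- (C + t(C)) / 2
  resid <- max(abs(M %*% C %*% t(M) - B))
  if (resid > tol) {
    stop("partition is inconsistent with the block structure of `Omega` ",
         "(reassembly residual ", format(resid, digits = 3), " > ", tol, ")")
  }
  gblock_model(M, C, pmax(D, 0))
}

#' Summarize a G-block model as aggregated-network statistics
#'
#' @param model a [gblock_model()].
#' @param tol entries of the aggregated precision with absolute value at or
#'   below `tol` count as absent edges.
#' @return List with `K`, `group_sizes`, and `aggregated_edge_count` (number
#'   of nonzero off-diagonal pairs of `C`).
#' @export
gblock_summary <- function(model, tol = 1e-8) {
  C <- model$C
  K <- ncol(model$M)
  edges <- sum(abs(C[upper.tri(C)]) > tol)
  list(K = K, group_sizes = as.integer(colSums(model$M)),
       aggregated_edge_count = edges)
}
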