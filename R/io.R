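#' Write a precision estimate to plain-text files
#'
#' Writes `Omega`, `Gamma` and `D` as dense CSV files plus a JSON metadata
#' file (penalties, iteration count, residuals, convergence flag, number of
#' blocks, group sizes, aggregated edge count).
#'
#' @param estimate a `taglasso_estimate`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return The directory, invisibly.
#' @export
write_estimate <- function(estimate, dir, prefix = "taglasso") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(estimate$Omega,
                   file.path(dir, paste0(prefix, "_omega.csv")))
  utils::write.csv(estimate$Gamma,
                   file.path(dir, paste0(prefix, "_gamma.csv")))
  utils::write.csv(data.frame(variable = rownames(estimate$Omega),
                              D = estimate$D),
                   file.path(dir, paste0(prefix, "_d.csv")),
                   row.names = FALSE)
  meta <- list(lambda1 = estimate$lambda1, lambda2 = estimate$lambda2,
               iterations = estimate$iterations,
               converged = estimate$converged,
               primal_residual = estimate$primal_residual,
               dual_residual = estimate$dual_residual,
               K = estimate$K,
               group_sizes = as.integer(table(estimate$partition$membership)),
               edge_count = sum(estimate$edges) / 2)
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, na = "null", digits = NA)
  invisible(dir)
}

#' Write a partition as CSV
#'
#' Two files: `variable,group` rows and the dense binary membership matrix.
#'
#' @param partition a `taglasso_partition`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return The directory, invisibly.
#' @export
write_partition <- function(partition, dir, prefix = "partition") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(variable = names(partition$membership),
                              group = partition$membership),
                   file.path(dir, paste0(prefix, ".csv")), row.names = FALSE)
  utils::write.csv(partition$M,
                   file.path(dir, paste0(prefix, "_membership.csv")))
  invisible(dir)
}
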