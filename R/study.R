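#' Replicate benchmark study
#'
#' Runs the full simulate / fit / evaluate loop for a set of designs and
#' estimators.  Per replicate: draw a true precision matrix and a data set,
#' build the ideal (depth-2) and realistic (clustering-derived) trees, fit
#' each requested estimator, and evaluate it against the truth.
#'
#' Estimators:
#' \describe{
#'   \item{oracle}{constrained maximum-likelihood refit at the true
#'     aggregation and sparsity supports (best-case benchmark).}
#'   \item{taglasso_ideal}{tag-lasso with the ideal tree, penalties chosen
#'     by cross-validation over an `n_lambda x n_lambda` grid.}
#'   \item{taglasso_realistic}{as above with the realistic tree.}
#'   \item{glasso}{graphical lasso (zero aggregation penalty) with its own
#'     `n_lambda`-point cross-validated edge-penalty grid.}
#' }
#'
#' @param designs character vector of design names (see
#'   [design_precision()]).
#' @param estimators subset of
#'   `c("oracle", "taglasso_ideal", "taglasso_realistic", "glasso")`.
#' @param replicates number of replicate data sets per design.
#' @param n sample size per replicate.
#' @param p,K,block_sizes design dimensions, passed to [design_precision()].
#' @param n_lambda grid length per penalty (default 10).
#' @param folds cross-validation folds.
#' @param seed master seed; all replicate-level seeds derive from it.
#' @param config a [solver_config()].
#' @param out_dir optional directory: per-replicate results are written as
#'   JSON and existing files are reused, making long studies resumable.
#' @param verbose print one line per replicate.
#' @return A `taglasso_study`: `results` (one row per design x estimator x
#'   replicate with the evaluation metrics) and `summary` (means and
#'   standard errors per design x estimator).
#' @export
run_study <- function(designs = "chain",
                      estimators = c("oracle", "taglasso_ideal",
                                     "taglasso_realistic", "glasso"),
                      replicates = 20, n = 120, p = 15, K = 3,
                      block_sizes = NULL, n_lambda = 10, folds = 5,
                      seed = 1, config = solver_config(warn = FALSE),
                      out_dir = NULL, verbose = FALSE) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  stopifnot(replicates >= 1)
  seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max %/% 2,
                      length(designs) * replicates * 3),
           ncol = 3))
  rows <- list()
  idx <- 0L
  for (d in seq_along(designs)) {
    design <- designs[d]
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      cache <- NULL
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        cache <- file.path(out_dir,
                           sprintf("%s_rep%03d.json", design, r))
        if (file.exists(cache)) {
          rows[[length(rows) + 1L]] <-
            as.data.frame(jsonlite::fromJSON(cache))
          next
        }
      }
      res <- run_replicate(design, estimators, n = n, p = p, K = K,
                           block_sizes = block_sizes, n_lambda = n_lambda,
                           folds = folds, seeds = seeds[idx, ],
                           config = config)
      res$design <- design
      res$replicate <- r
      if (!is.null(cache)) {
        jsonlite::write_json(res, cache, dataframe = "columns", na = "null",
                             digits = NA)
      }
      if (verbose) {
        message(design, " replicate ", r, "/", replicates, " done")
      }
      rows[[length(rows) + 1L]] <- res
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, summary = summarize_study(results)),
            class = "taglasso_study")
}

run_replicate <- function(design, estimators, n, p, K, block_sizes,
                          n_lambda, folds, seeds, config) {
  truth <- design_precision(design, p = p, K = K, block_sizes = block_sizes,
                            seed = seeds[1])
  X <- sample_mvn(truth$Omega, n, seed = seeds[2])
  tree_i <- ideal_tree(truth$partition)
  A_i <- build_ancestor_matrix(tree_i)
  out <- list()
  for (est in estimators) {
    fit <- switch(est,
      oracle = {
        V_true <- true_support(tree_i, truth$partition)
        E_true <- truth$Omega != 0
        diag(E_true) <- FALSE
        list(estimate = taglasso_refit(cov_mle(X), A_i, V_true, E_true,
                                       config = config),
             lambda1 = NA_real_, lambda2 = NA_real_)
      },
      taglasso_ideal = cv_wrap(X, tree_i, n_lambda, folds, seeds[3], config),
      taglasso_realistic = {
        tree_r <- realistic_tree(truth$partition, seed = seeds[3])
        cv_wrap(X, tree_r, n_lambda, folds, seeds[3], config)
      },
      glasso = {
        cv <- cross_validate_glasso(X, n_lambda2 = n_lambda, folds = folds,
                                    seed = seeds[3], config = config)
        list(estimate = cv$estimate, lambda1 = 0, lambda2 = cv$best_lambda2)
      })
    ev <- evaluate_estimate(fit$estimate, truth)
    ev$estimator <- est
    ev$lambda1 <- fit$lambda1
    ev$lambda2 <- fit$lambda2
    ev$converged <- fit$estimate$converged
    out[[est]] <- ev
  }
  do.call(rbind, out)
}

cv_wrap <- function(X, tree, n_lambda, folds, seed, config) {
  cv <- cross_validate(X, tree, folds = folds, seed = seed, config = config,
                       grid = default_grid(cov_mle(X),
                                           build_ancestor_matrix(tree),
                                           n_lambda1 = n_lambda,
                                           n_lambda2 = n_lambda))
  # metrics read the aggregation from the penalized fit's support and the
  # precision/edges from the final constrained refit
  est <- cv$estimate
  est$partition <- cv$fit$partition
  est$K <- cv$fit$K
  list(estimate = est, lambda1 = cv$best_lambda1, lambda2 = cv$best_lambda2)
}

# active tree nodes of the ideal tree that represent the true partition
true_support <- function(tree_ideal, partition_true) {
  internal <- setdiff(tree_ideal$node_ids,
                      c(tree_ideal$leaf_order, tree_ideal$root))
  c(internal, tree_ideal$root)
}

#' Mean and standard error table of a study
#'
#' @param results the `results` data frame of a `taglasso_study` (or the
#'   study itself).
#' @return Data frame with one row per design x estimator: the mean and
#'   standard error (sd / sqrt(replicates)) of each metric; `NA` metrics
#'   (e.g. the adjusted Rand index under an all-singleton truth) propagate
#'   as `NA`.
#' @export
summarize_study <- function(results) {
  if (inherits(results, "taglasso_study")) results <- results$results
  metrics <- c("kl", "rand", "adj_rand", "fpr", "fnr", "K")
  groups <- unique(results[, c("design", "estimator")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- results[results$design == groups$design[i] &
                     results$estimator == groups$estimator[i], ]
    row <- data.frame(design = groups$design[i],
                      estimator = groups$estimator[i],
                      replicates = nrow(sub))
    for (mname in metrics) {
      v <- sub[[mname]]
      row[[paste0(mname, "_mean")]] <- if (all(is.na(v))) NA_real_ else
        mean(v, na.rm = TRUE)
      row[[paste0(mname, "_se")]] <- if (all(is.na(v)) || nrow(sub) < 2)
        NA_real_ else stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
    }
    row
  })
  do.call(rbind, out)
}

#' @export
print.taglasso_study <- function(x, ...) {
  cat("taglasso_study:", nrow(x$results), "evaluations\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Estimation-accuracy ratios relative to a reference estimator
#'
#' @param study a `taglasso_study` containing the reference estimator.
#' @param reference estimator whose per-replicate KL distance is the
#'   denominator (default the oracle).
#' @return Data frame per design x estimator with the mean and median of
#'   the per-replicate KL ratios and the ratio of mean KL distances.
#' @export
summarize_kl_ratios <- function(study, reference = "oracle") {
  res <- study$results
  if (!reference %in% res$estimator) {
    stop("reference estimator '", reference, "' not in the study")
  }
  ref <- res[res$estimator == reference, c("design", "replicate", "kl")]
  names(ref)[3] <- "kl_ref"
  merged <- merge(res[res$estimator != reference, ], ref,
                  by = c("design", "replicate"))
  groups <- unique(merged[, c("design", "estimator")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- merged[merged$design == groups$design[i] &
                    merged$estimator == groups$estimator[i], ]
    data.frame(design = groups$design[i], estimator = groups$estimator[i],
               mean_ratio = mean(sub$kl / sub$kl_ref),
               median_ratio = stats::median(sub$kl / sub$kl_ref),
               ratio_of_means = mean(sub$kl) / mean(sub$kl_ref))
  })
  do.call(rbind, out)
}
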