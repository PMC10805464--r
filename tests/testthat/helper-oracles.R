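# Independent oracles used across the test suite.  None of these share code
# with the package's ADMM path.

# ---- generic convex solver for the penalized objective -----------------
#
# Minimizes
#   -logdet(A G + diag(d)) + tr(S (A G + diag(d)))
#     + lambda1 * sum_{u != root} ||g_u||_2
#     + lambda2 * sum_{i<j} |(A G)_ij|
# over (G, d >= 0) subject to A G symmetric off the diagonal and a constant
# root row, by L-BFGS-B on a null-space parameterization of the linear
# constraints with epsilon-smoothed norms and continuation.  Only intended
# for tiny instances (p <= 6); returns the solution and the unsmoothed
# objective value.
convex_oracle <- function(S, A, lambda1, lambda2, root,
                          eps_seq = c(1e-4, 1e-8, 1e-12), maxit = 3000) {
  p <- nrow(A)
  nt <- ncol(A)
  nG <- nt * p
  # constraint rows on vec(G) (column-major)
  cons <- list()
  idx <- function(u, j) (j - 1L) * nt + u
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      v <- numeric(nG)
      v[idx(seq_len(nt), j)] <- v[idx(seq_len(nt), j)] + A[i, ]
      v[idx(seq_len(nt), i)] <- v[idx(seq_len(nt), i)] - A[j, ]
      cons[[length(cons) + 1L]] <- v
    }
  }
  for (j in 2:p) {
    v <- numeric(nG)
    v[idx(root, j)] <- 1
    v[idx(root, 1L)] <- -1
    cons[[length(cons) + 1L]] <- v
  }
  Cmat <- do.call(rbind, cons)
  nsp <- svd(Cmat, nv = nG)$v[, (qr(Cmat)$rank + 1):nG, drop = FALSE]
  q <- ncol(nsp)
  obj_grad <- function(x, eps) {
    z <- x[seq_len(q)]
    d <- x[q + seq_len(p)]
    G <- matrix(nsp %*% z, nt, p)
    Omega <- A %*% G + diag(d, p)
    Omega <- (Omega + t(Omega)) / 2
    ch <- tryCatch(chol(Omega), error = function(e) NULL)
    if (is.null(ch)) {
      return(list(value = 1e10, grad = rep(0, q + p)))
    }
    Oinv <- chol2inv(ch)
    val <- -2 * sum(log(diag(ch))) + sum(S * Omega)
    Gq <- S - Oinv                     # gradient wrt Omega entries
    rn <- sqrt(rowSums(G^2) + eps)
    val <- val + lambda1 * sum(rn[-root])
    gpen <- lambda1 * G / rn
    gpen[root, ] <- 0
    off <- sqrt(Omega^2 + eps)
    diag(off) <- 0
    val <- val + lambda2 * sum(off[upper.tri(off)])
    Gl1 <- Omega / sqrt(Omega^2 + eps)
    diag(Gl1) <- 0
    Gq <- Gq + (lambda2 / 2) * Gl1
    gG <- t(A) %*% Gq + gpen
    list(value = val,
         grad = c(as.numeric(crossprod(nsp, as.numeric(gG))), diag(Gq)))
  }
  x <- c(numeric(q), 1 / pmax(diag(S), 1e-3))
  for (eps in eps_seq) {
    fit <- stats::optim(x,
                        fn = function(x) obj_grad(x, eps)$value,
                        gr = function(x) obj_grad(x, eps)$grad,
                        method = "L-BFGS-B",
                        lower = c(rep(-Inf, q), rep(0, p)),
                        control = list(maxit = maxit, factr = 10))
    x <- fit$par
  }
  z <- x[seq_len(q)]
  d <- x[q + seq_len(p)]
  G <- matrix(nsp %*% z, nt, p)
  Omega <- A %*% G + diag(d, p)
  Omega <- (Omega + t(Omega)) / 2
  obj <- taglasso_objective(S, lambda1, lambda2, Omega, G, root)
  list(Gamma = G, D = d, Omega = Omega, objective = obj)
}

# ---- reference graphical lasso through scikit-learn --------------------
#
# Our lambda2 counts each unordered pair once; sklearn counts both
# triangles, hence alpha = lambda2 / 2.
ref_glasso <- function(S, lambda2) {
  script <- paste(
    "import sys, json",
    "import numpy as np",
    "from sklearn.covariance import graphical_lasso",
    "dat = json.load(sys.stdin)",
    "S = np.array(dat['S']); alpha = dat['alpha']",
    "cov, prec = graphical_lasso(S, alpha=alpha, tol=1e-10, enet_tol=1e-10, max_iter=2000)",
    "print(json.dumps(prec.tolist()))",
    sep = "\n")
  inp <- jsonlite::toJSON(list(S = S, alpha = lambda2 / 2),
                          auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script)), input = as.character(inp),
            stdout = TRUE, stderr = FALSE))
  jsonlite::fromJSON(paste(out, collapse = ""))
}

python_sklearn_available <- function() {
  nzchar(Sys.which("python")) &&
    identical(suppressWarnings(
      system2("python", c("-c", shQuote("import sklearn.covariance")),
              stdout = FALSE, stderr = FALSE)), 0L)
}

# ---- brute-force partition indices -------------------------------------
brute_rand <- function(a, b) {
  n <- length(a)
  same_both <- 0; diff_both <- 0; n_pairs <- 0
  num <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      n_pairs <- n_pairs + 1
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) same_both <- same_both + 1
      if (!sa && !sb) diff_both <- diff_both + 1
    }
  }
  (same_both + diff_both) / n_pairs
}

# all set partitions of 1..n as membership vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxg) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (g in seq_len(maxg + 1L)) {
      rec(c(prefix, g), max(maxg, g))
    }
  }
  rec(integer(0), 0L)
  out
}

# ---- random G-block model generator ------------------------------------
random_gblock <- function(p, max_tries = 100) {
  for (i in seq_len(max_tries)) {
    K <- sample(1:min(4, p), 1)
    membership <- sample(rep_len(seq_len(K), p))
    M <- membership_matrix(match(membership, unique(membership)))
    K <- ncol(M)
    C <- matrix(rnorm(K * K, sd = 0.5), K, K)
    C <- (C + t(C)) / 2
    D <- runif(p, 0.5, 2)
    Omega <- M %*% C %*% t(M) + diag(D)
    if (min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values) > 0.05) {
      return(gblock_model(M, C, D))
    }
  }
  stop("no SPD G-block model found")
}

# small random problem instance for solver tests
random_instance <- function(p = 5, n = 40) {
  K <- sample(2:min(3, p), 1)
  sizes <- as.integer(table(sample(rep_len(seq_len(K), p))))
  membership <- rep(seq_along(sizes), sizes)
  names(membership) <- paste0("V", seq_len(p))
  part <- partition(membership)
  tree <- ideal_tree(part)
  A <- build_ancestor_matrix(tree)
  Z <- matrix(rnorm(n * p), n, p)
  B <- matrix(rnorm(p * p, sd = 0.3), p, p)
  X <- Z %*% (diag(p) + B %*% t(B) / 4)
  colnames(X) <- names(membership)
  list(S = cov_mle(X), A = A, tree = tree,
       root = attr(A, "root_column"))
}
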