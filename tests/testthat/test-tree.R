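# Five leaves, two internal branches ({1:3}, {4:5}) under the root: the
# worked two-level aggregation example used throughout.
fig_tree <- function() {
  parent <- c(L1 = "n13", L2 = "n13", L3 = "n13", L4 = "n45", L5 = "n45",
              n13 = "root", n45 = "root", root = NA)
  similarity_tree(parent, paste0("L", 1:5))
}

test_that("newick and parent-list parsing give the expected node counts", {
  tr <- read_tree("((L1,L2,L3)n13,(L4,L5)n45)root;")
  expect_s3_class(tr, "similarity_tree")
  expect_equal(n_nodes(tr), 8)
  expect_equal(tr$leaf_order, paste0("L", 1:5))
  expect_equal(tr$root, "root")

  # star tree: p leaves under the root
  star <- read_tree("(a,b,c,d);")
  expect_equal(n_nodes(star), 5)

  df <- data.frame(child = c("L1", "L2", "in", "root"),
                   parent = c("in", "in", "root", ""))
  tr2 <- read_tree(df)
  expect_equal(n_nodes(tr2), 4)
  expect_equal(sort(tr2$leaf_order), c("L1", "L2"))
})

test_that("malformed trees are rejected", {
  expect_error(read_tree(data.frame(child = "a", parent = "a")),
               "own parent")
  expect_error(similarity_tree(c(a = "b", b = "a", r = NA), "a"), "cycle|root")
  # two roots
  expect_error(similarity_tree(c(a = NA, b = NA), c("a", "b")),
               "exactly one root")
  # leaf_order mismatch
  expect_error(read_tree("((L1,L2)n,L3)r;", leaf_order = c("L1", "L2", "LX")),
               "leaf")
  # disconnected parent reference
  expect_error(similarity_tree(c(a = "ghost", r = NA), "a"), "not declared")
})

test_that("ancestor matrix marks exactly the leaf-to-root paths", {
  tr <- fig_tree()
  A <- build_ancestor_matrix(tr)
  expect_equal(dim(A), c(5L, 8L))
  expect_equal(attr(A, "root_column"), match("root", colnames(A)))
  # root column all ones; leaf block is the identity
  expect_true(all(A[, "root"] == 1))
  expect_equal(unname(A[, paste0("L", 1:5)]), diag(5))
  # leaf 1 path: {L1, n13, root}; leaf 4 path: {L4, n45, root}
  expect_equal(colnames(A)[A["L1", ] == 1], c("L1", "n13", "root"))
  expect_equal(colnames(A)[A["L4", ] == 1], c("L4", "n45", "root"))
  # row sums are 1 + depth
  expect_equal(unname(rowSums(A)), rep(3, 5))

  star <- read_tree("(a,b,c);")
  As <- build_ancestor_matrix(star)
  expect_equal(unname(As), cbind(diag(3), rep(1, 3)), ignore_attr = TRUE)
})

test_that("column sums along ancestor paths reproduce the parameterization", {
  # path-walk oracle: for random Gamma, column j of A Gamma equals the sum
  # of the gamma rows over ancestor(j) + {j}
  tr <- fig_tree()
  A <- build_ancestor_matrix(tr)
  set.seed(1)
  Gamma <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(colnames(A), NULL))
  walk <- function(leaf) {
    u <- leaf
    s <- numeric(5)
    while (!is.na(u)) {
      s <- s + Gamma[u, ]
      u <- tr$parent[[u]]
    }
    s
  }
  manual <- t(vapply(tr$leaf_order, walk, numeric(5)))
  expect_equal(unname(A %*% Gamma), unname(manual))
})

test_that("support_set applies a strict relative threshold", {
  Gamma <- matrix(0, 8, 5)
  rownames(Gamma) <- c(paste0("L", 1:5), "n13", "n45", "root")
  Gamma["root", ] <- 5
  expect_equal(support_set(Gamma), "root")
  # a row at exactly tol * max norm is excluded (strict inequality)
  Gamma["n13", 1] <- 1e-6 * sqrt(sum(Gamma["root", ]^2))
  expect_equal(support_set(Gamma, tol = 1e-6), "root")
  Gamma["n13", 1] <- Gamma["n13", 1] * 1.01
  expect_setequal(support_set(Gamma, tol = 1e-6), c("n13", "root"))
  expect_error(support_set(Gamma, tol = -1), "nonnegative")
})

test_that("partitions from active node sets follow the unique-row rule", {
  A <- build_ancestor_matrix(fig_tree())
  two <- partition_from_support(A, c("n13", "root"))
  expect_equal(two$K, 2)
  expect_equal(unname(two$membership), c(1, 1, 1, 2, 2))
  # all leaves active: singletons
  expect_equal(partition_from_support(A, paste0("L", 1:5))$K, 5)
  # root only: complete aggregation
  expect_equal(partition_from_support(A, "root")$K, 1)
  expect_error(partition_from_support(A, character(0)), "root")
  # labels are assigned by first appearance over the variable index
  rev_two <- partition_from_support(A, c("n45", "root"))
  expect_equal(unname(rev_two$membership), c(1, 1, 1, 2, 2))
})

test_that("shrinking the active set only merges groups, never splits", {
  tr <- read_tree("(((a,b)ab,(c,d)cd)abcd,(e,f)ef)root;")
  A <- build_ancestor_matrix(tr)
  nodes <- setdiff(colnames(A), "root")
  # exhaustive over subsets of the non-root nodes
  for (mask in 0:(2^length(nodes) - 1)) {
    V <- c(nodes[bitwAnd(mask, 2^(seq_along(nodes) - 1)) > 0], "root")
    big <- partition_from_support(A, V)
    for (drop in setdiff(V, "root")) {
      small <- partition_from_support(A, setdiff(V, drop))
      # every group of the smaller support is a union of groups of the
      # larger support: nesting check via contingency table
      tab <- table(big$membership, small$membership)
      expect_true(all(rowSums(tab > 0) == 1))
    }
  }
})

test_that("membership matrices are projections onto group-constant vectors", {
  part <- partition(c(1, 1, 2, 3, 3, 3))
  M <- part$M
  expect_equal(rowSums(M), rep(1, 6))
  P <- M %*% solve(crossprod(M)) %*% t(M)
  v <- c(7, 7, -2, 4, 4, 4)  # group-constant
  expect_equal(as.numeric(P %*% v), v)
})

test_that("hclust dendrograms convert to valid similarity trees", {
  set.seed(3)
  x <- c(rnorm(3, 0), rnorm(3, 10))
  names(x) <- paste0("V", 1:6)
  hc <- hclust(dist(x), method = "complete")
  hc$labels <- names(x)
  tr <- as_similarity_tree(hc)
  expect_equal(n_nodes(tr), 11)  # 6 leaves + 5 merges
  expect_setequal(tr$leaf_order, names(x))
  A <- build_ancestor_matrix(tr)
  expect_true(all(A[, tr$root] == 1))
})

test_that("newick writing round-trips, including unary block nodes", {
  tr <- fig_tree()
  txt <- write_tree_newick(tr)
  back <- read_tree(txt, leaf_order = tr$leaf_order)
  expect_equal(build_ancestor_matrix(back)[, colnames(build_ancestor_matrix(tr))],
               build_ancestor_matrix(tr), ignore_attr = TRUE)
  # ideal tree of a partition with a singleton block has a unary node
  it <- ideal_tree(partition(c(a = 1, b = 1, c = 2)))
  txt2 <- write_tree_newick(it)
  expect_match(txt2, "\\(c\\)")
})
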