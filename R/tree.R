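#' Similarity trees over the variables of a graphical model
#'
#' A similarity tree is a rooted tree whose `p` leaves are the observed
#' variables (columns of the data matrix).  Its branches are the candidate
#' aggregation groups: merging all leaves below a branch produces one
#' aggregated node.  The tree is the side information that guides the
#' aggregation penalty of the tag-lasso.
#'
#' @param parent named character vector mapping every node id to its parent
#'   node id; the single root maps to `NA`.
#' @param leaf_order character vector with the ids of the `p` leaves, in the
#'   column order of the data.
#' @param labels optional named character vector of human-readable labels per
#'   node id; defaults to the ids themselves.
#'
#' @return An object of class `similarity_tree` with components `node_ids`
#'   (leaves first, in `leaf_order`, then internal nodes, root last),
#'   `parent`, `leaf_order`, `labels`, `root`.
#' @export
similarity_tree <- function(parent, leaf_order, labels = NULL) {
  if (is.null(names(parent))) {
    stop("`parent` must be a named vector (names are the child node ids)")
  }
  nodes <- names(parent)
  if (anyDuplicated(nodes)) {
    stop("duplicated node ids in `parent`")
  }
  is_root <- is.na(parent) | parent == ""
  if (sum(is_root) != 1L) {
    stop("the tree must have exactly one root (one node with no parent), found ",
         sum(is_root))
  }
  root <- nodes[is_root]
  if (!all(parent[!is_root] %in% nodes)) {
    bad <- setdiff(parent[!is_root], nodes)
    stop("parent node(s) not declared as nodes: ", paste(bad, collapse = ", "))
  }
  # walk every node to the root; a walk longer than |T| means a cycle
  n_nodes <- length(nodes)
  depth <- stats::setNames(rep(NA_integer_, n_nodes), nodes)
  for (v in nodes) {
    u <- v
    d <- 0L
    while (!is.na(parent[[u]]) && parent[[u]] != "") {
      u <- parent[[u]]
      d <- d + 1L
      if (d > n_nodes) {
        stop("cycle detected in the parent map (starting from node '", v, "')")
      }
    }
    if (u != root) stop("node '", v, "' is not connected to the root")
    depth[[v]] <- d
  }
  leaves <- setdiff(nodes, parent[!is_root])  # nodes that are nobody's parent
  if (length(leaf_order) != length(leaves) || !setequal(leaf_order, leaves)) {
    stop("`leaf_order` must list exactly the terminal nodes of the tree; ",
         "tree leaves are {", paste(sort(leaves), collapse = ", "), "}")
  }
  if (anyDuplicated(leaf_order)) stop("duplicated names in `leaf_order`")
  internal <- setdiff(nodes, c(leaf_order, root))
  node_ids <- c(leaf_order, internal, if (root %in% leaf_order) NULL else root)
  if (root %in% leaf_order) {
    stop("the root cannot be a leaf when p > 1")
  }
  if (is.null(labels)) {
    labels <- stats::setNames(node_ids, node_ids)
  } else {
    labels <- labels[node_ids]
    labels[is.na(labels)] <- node_ids[is.na(labels)]
    names(labels) <- node_ids
  }
  structure(
    list(node_ids = node_ids,
         parent = parent[node_ids],
         leaf_order = leaf_order,
         labels = labels,
         root = root,
         depth = depth[node_ids]),
    class = "similarity_tree")
}

#' @export
print.similarity_tree <- function(x, ...) {
  cat("similarity_tree: ", length(x$leaf_order), " leaves, ",
      length(x$node_ids), " nodes, root '", x$root, "'\n", sep = "")
  invisible(x)
}

#' Number of nodes in a similarity tree
#' @param tree a `similarity_tree`.
#' @return Integer, the total node count |T| (leaves + internal + root).
#' @export
n_nodes <- function(tree) length(tree$node_ids)

#' Read a similarity tree from Newick text or a child/parent table
#'
#' Accepts either a Newick string (or path to a Newick file), parsed with
#' \pkg{ape}, or a two-column `child,parent` table (path to a CSV, or a
#' data frame) in which the root row has an empty parent field.  Internal
#' node labels are kept when present and otherwise synthesized as the sorted
#' concatenation of the descendant leaf labels.
#'
#' @param source Newick text, a file path, or a two-column data frame.
#' @param leaf_order optional character vector giving the variable order of
#'   the data columns; defaults to the leaf order found in the source.
#' @return A validated [similarity_tree].
#' @examples
#' taxonomy <- read_tree(system.file("extdata", "example_taxonomy.nwk",
#'                                   package = "taglasso"))
#' build_ancestor_matrix(taxonomy)["OTU1", ]
#' @export
read_tree <- function(source, leaf_order = NULL) {
  if (is.data.frame(source)) {
    return(tree_from_parent_list(source, leaf_order))
  }
  stopifnot(is.character(source), length(source) == 1L)
  txt <- source
  if (!grepl("[(;]", source) && file.exists(source)) {
    txt <- paste(readLines(source, warn = FALSE), collapse = "\n")
  }
  if (grepl("^\\s*\\(", txt)) {
    phy <- ape::read.tree(text = txt)
    if (is.null(phy)) stop("could not parse Newick input")
    return(as_similarity_tree(phy, leaf_order = leaf_order))
  }
  # otherwise: child,parent CSV text or path
  df <- if (file.exists(source)) {
    utils::read.csv(source, header = TRUE, colClasses = "character")
  } else {
    utils::read.csv(text = txt, header = TRUE, colClasses = "character")
  }
  tree_from_parent_list(df, leaf_order)
}

tree_from_parent_list <- function(df, leaf_order = NULL) {
  if (ncol(df) < 2L) stop("parent-list input needs two columns: child, parent")
  child <- as.character(df[[1L]])
  par <- as.character(df[[2L]])
  par[par == "" | is.na(par)] <- NA_character_
  parent <- stats::setNames(par, child)
  for (v in child) {
    if (!is.na(parent[[v]]) && parent[[v]] == v) {
      stop("node '", v, "' is listed as its own parent")
    }
  }
  if (is.null(leaf_order)) {
    leaf_order <- setdiff(child, par[!is.na(par)])
  }
  similarity_tree(parent, leaf_order)
}

#' Convert phylogeny-style objects to a similarity tree
#'
#' @param x an [ape::phylo] tree or an [stats::hclust] dendrogram.
#' @param ... passed on to methods.
#' @return A [similarity_tree].
#' @export
as_similarity_tree <- function(x, ...) UseMethod("as_similarity_tree")

#' @rdname as_similarity_tree
#' @param leaf_order optional leaf ordering (defaults to the tip order).
#' @export
as_similarity_tree.phylo <- function(x, leaf_order = NULL, ...) {
  p <- length(x$tip.label)
  n_all <- p + x$Nnode
  ids <- character(n_all)
  ids[seq_len(p)] <- x$tip.label
  internal_labels <- x$node.label
  need_synth <- is.null(internal_labels) || any(internal_labels == "" | is.na(internal_labels))
  if (is.null(internal_labels)) internal_labels <- rep("", x$Nnode)
  if (need_synth) {
    desc <- descendant_leaves_phylo(x)
    for (k in seq_len(x$Nnode)) {
      if (internal_labels[k] == "" || is.na(internal_labels[k])) {
        internal_labels[k] <- paste(sort(desc[[p + k]]), collapse = "+")
      }
    }
  }
  ids[p + seq_len(x$Nnode)] <- internal_labels
  if (anyDuplicated(ids)) stop("duplicated node labels after parsing the tree")
  parent <- stats::setNames(rep(NA_character_, n_all), ids)
  for (e in seq_len(nrow(x$edge))) {
    parent[[ids[x$edge[e, 2L]]]] <- ids[x$edge[e, 1L]]
  }
  if (is.null(leaf_order)) leaf_order <- x$tip.label
  if (!setequal(leaf_order, x$tip.label) || length(leaf_order) != p) {
    stop("`leaf_order` does not match the tree's leaf set")
  }
  similarity_tree(parent, leaf_order)
}

# list of descendant leaf label sets, indexed by phylo node number
descendant_leaves_phylo <- function(phy) {
  p <- length(phy$tip.label)
  n_all <- p + phy$Nnode
  desc <- vector("list", n_all)
  for (i in seq_len(p)) desc[[i]] <- phy$tip.label[i]
  # edges in post order: children resolved before parents
  ord <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    a <- ord$edge[e, 1L]; b <- ord$edge[e, 2L]
    desc[[a]] <- c(desc[[a]], desc[[b]])
  }
  desc
}

#' @rdname as_similarity_tree
#' @export
as_similarity_tree.hclust <- function(x, ...) {
  leaf_ids <- x$labels
  if (is.null(leaf_ids)) leaf_ids <- as.character(seq_along(x$order))
  m <- nrow(x$merge)
  desc <- vector("list", m)
  merge_ids <- character(m)
  parent <- stats::setNames(rep(NA_character_, length(leaf_ids) + m),
                            c(leaf_ids, rep("", m)))
  names_vec <- c(leaf_ids, rep(NA_character_, m))
  for (k in seq_len(m)) {
    kids <- x$merge[k, ]
    kid_leaves <- unlist(lapply(kids, function(j) {
      if (j < 0) leaf_ids[-j] else desc[[j]]
    }))
    desc[[k]] <- kid_leaves
    merge_ids[k] <- paste(sort(kid_leaves), collapse = "+")
    names_vec[length(leaf_ids) + k] <- merge_ids[k]
  }
  names(parent) <- names_vec
  for (k in seq_len(m)) {
    for (j in x$merge[k, ]) {
      child_id <- if (j < 0) leaf_ids[-j] else merge_ids[j]
      parent[[child_id]] <- merge_ids[k]
    }
  }
  similarity_tree(parent, leaf_ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a similarity tree to Newick
#'
#' Handles unary internal nodes (single-child branches), which arise in the
#' ideal depth-2 trees when an aggregation block is a singleton.
#'
#' @param tree a [similarity_tree].
#' @param file optional path; when given the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_tree_newick <- function(tree, file = NULL) {
  children <- split(names(tree$parent)[!is.na(tree$parent)],
                    tree$parent[!is.na(tree$parent)])
  rec <- function(v) {
    kids <- children[[v]]
    if (is.null(kids)) return(quote_newick(v))
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")",
           quote_newick(v))
  }
  s <- paste0(rec(tree$root), ";")
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

quote_newick <- function(x) {
  if (grepl("[ ,():;]", x)) paste0("'", x, "'") else x
}

#' Build the leaf-to-ancestor incidence matrix of a similarity tree
#'
#' Row `j` of the returned binary matrix marks every node on the path from
#' leaf `j` up to the root, including leaf `j` itself.  This matrix `A`
#' parameterizes the precision matrix as `Omega = A Gamma + diag(D)`:
#' column `j` of `Omega` (off its diagonal) is the sum of the parameter rows
#' of `Gamma` along leaf `j`'s ancestor path.
#'
#' @param tree a [similarity_tree].
#' @return A p x |T| binary matrix with `dimnames = list(leaf_order,
#'   node_ids)` and attributes `root_column` (column index of the root) and
#'   `tree`.
#' @export
build_ancestor_matrix <- function(tree) {
  p <- length(tree$leaf_order)
  nt <- length(tree$node_ids)
  A <- matrix(0L, p, nt, dimnames = list(tree$leaf_order, tree$node_ids))
  for (j in seq_len(p)) {
    u <- tree$leaf_order[j]
    repeat {
      A[j, u] <- 1L
      u <- tree$parent[[u]]
      if (is.na(u)) break
    }
  }
  attr(A, "root_column") <- match(tree$root, tree$node_ids)
  attr(A, "tree") <- tree
  A
}

#' Nonzero rows of the aggregation parameter matrix
#'
#' Declares row `u` of `Gamma` nonzero when its Euclidean norm strictly
#' exceeds `tol` times the largest row norm.  The group soft-thresholding in
#' the solver produces exact zeros, so the threshold only guards numerical
#' noise.
#'
#' @param Gamma a |T| x p matrix whose rows correspond to tree nodes
#'   (rownames are the node ids when available).
#' @param tol nonnegative relative threshold (default `1e-6`).
#' @return Character vector of node ids (or integer indices when `Gamma` has
#'   no rownames) whose rows are nonzero.
#' @export
support_set <- function(Gamma, tol = 1e-6) {
  if (tol < 0) stop("`tol` must be nonnegative")
  norms <- sqrt(rowSums(Gamma^2))
  cut <- tol * max(norms, 0)
  keep <- norms > cut
  if (!is.null(rownames(Gamma))) rownames(Gamma)[keep] else which(keep)
}

#' Partition of the variables implied by a set of active tree nodes
#'
#' Two leaves belong to the same aggregation block exactly when their rows of
#' the ancestor matrix, restricted to the active columns, coincide.  The root
#' column is always treated as active (its parameter row is unpenalized), so
#' the partition is well defined even when every other row is zero.  Group
#' labels are assigned in order of first appearance over the variable index.
#'
#' @param A ancestor matrix from [build_ancestor_matrix()].
#' @param V character vector of active node ids (or integer column indices),
#'   e.g. from [support_set()].
#' @return A `taglasso_partition`: list with `membership` (named integer
#'   vector over the leaves), `K`, and `M` (p x K binary membership matrix).
#' @export
partition_from_support <- function(A, V) {
  if (length(V) == 0L) stop("`V` must contain at least the root node")
  if (is.character(V)) {
    miss <- setdiff(V, colnames(A))
    if (length(miss)) stop("unknown node id(s): ", paste(miss, collapse = ", "))
    cols <- match(V, colnames(A))
  } else {
    cols <- as.integer(V)
  }
  cols <- union(cols, attr(A, "root_column"))
  keys <- apply(A[, cols, drop = FALSE], 1L, paste, collapse = "")
  membership <- match(keys, unique(keys))
  names(membership) <- rownames(A)
  partition(membership)
}

#' Construct a partition object from a membership vector
#'
#' @param membership integer (or factor/character) vector assigning each
#'   variable to a group; groups are relabelled `1..K` in order of first
#'   appearance.
#' @return A `taglasso_partition` with `membership`, `K`, `M`.
#' @export
partition <- function(membership) {
  nm <- names(membership)
  membership <- match(membership, unique(membership))
  names(membership) <- nm
  K <- max(membership)
  M <- membership_matrix(membership, K)
  structure(list(membership = membership, K = K, M = M),
            class = "taglasso_partition")
}

#' @export
print.taglasso_partition <- function(x, ...) {
  cat("partition of", length(x$membership), "variables into", x$K, "blocks\n")
  invisible(x)
}

#' Binary membership matrix of a partition
#'
#' @param membership integer vector with values in `1..K`.
#' @param K number of groups (defaults to `max(membership)`).
#' @return p x K binary matrix `M` with `M[j, k] = 1` iff variable `j` is in
#'   group `k`.
#' @export
membership_matrix <- function(membership, K = max(membership)) {
  p <- length(membership)
  M <- matrix(0, p, K)
  M[cbind(seq_len(p), membership)] <- 1
  rownames(M) <- names(membership)
  M
}
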