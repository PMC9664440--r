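# Guide trees are strictly binary rooted trees built from nested lists:
# a leaf is list(leaf = "<id>"), an internal node list(left = , right = ).
# The nesting order records the progressive joining order.

gt_leaf <- function(id) structure(list(leaf = id), class = "guide_tree")

gt_join <- function(left, right) structure(list(left = left, right = right),
                                           class = "guide_tree")

gt_is_leaf <- function(node) !is.null(node$leaf)

#' Leaves of a guide tree
#' @param tree A `guide_tree`.
#' @return Character vector of leaf ids in tree order.
#' @export
gt_leaves <- function(tree) {
  if (gt_is_leaf(tree)) return(tree$leaf)
  c(gt_leaves(tree$left), gt_leaves(tree$right))
}

#' Newick rendering of a guide tree
#' @param tree A `guide_tree`.
#' @return Newick string (no branch lengths), terminated by ";".
#' @export
gt_newick <- function(tree) paste0(gt_newick_rec(tree), ";")

gt_newick_rec <- function(node) {
  if (gt_is_leaf(node)) return(node$leaf)
  paste0("(", gt_newick_rec(node$left), ",", gt_newick_rec(node$right), ")")
}

#' @export
print.guide_tree <- function(x, ...) {
  cat("guide_tree:", gt_newick(x), "\n")
  invisible(x)
}

# Enumerate all proper subtrees (every node except the root); each entry is
# list(path = integer vector of 1/2 steps, leaves = character vector).
gt_subtrees <- function(tree) {
  out <- list()
  rec <- function(node, path) {
    if (length(path) > 0)
      out[[length(out) + 1]] <<- list(path = path, leaves = gt_leaves(node))
    if (!gt_is_leaf(node)) {
      rec(node$left, c(path, 1L))
      rec(node$right, c(path, 2L))
    }
  }
  rec(tree, integer(0))
  out
}

gt_at <- function(tree, path) {
  node <- tree
  for (s in path) node <- if (s == 1L) node$left else node$right
  node
}

# Remove the subtree at `path`; the sibling is promoted into the parent.
gt_delete <- function(tree, path) {
  stopifnot(length(path) >= 1)
  if (length(path) == 1) {
    return(if (path == 1L) tree$right else tree$left)
  }
  parent_path <- path[-length(path)]
  rec <- function(node, p) {
    if (length(p) == 0) {
      child <- if (path[length(path)] == 1L) node$right else node$left
      return(child)
    }
    if (p[1] == 1L) node$left <- rec(node$left, p[-1])
    else node$right <- rec(node$right, p[-1])
    node
  }
  rec(tree, parent_path)
}

# Pick, among proper subtrees, the one whose leaf count is closest to
# `target`; ties resolved toward the smaller subtree, then lexicographically
# by the sorted contained leaf ids.
gt_pick_closest <- function(tree, target) {
  subs <- gt_subtrees(tree)
  sizes <- vapply(subs, function(s) length(s$leaves), 0L)
  keys <- vapply(subs, function(s) paste(sort(s$leaves), collapse = "\r"), "")
  d <- abs(sizes - target)
  best <- order(d, sizes, keys)[1]
  subs[[best]]
}

#' Split a guide tree into three subtrees of roughly equal size
#'
#' Identifies the edge dividing the leaves into subsets `a` and `bc` such
#' that `|a|` is as close as achievable to n/3 over all edges, then splits
#' the remaining tree `bc` into `b` and `c` as evenly as achievable.  Joining
#' order within each subtree is preserved.  Ties are resolved toward the
#' smaller subtree, then lexicographically by contained leaf ids.
#'
#' @param tree A `guide_tree` with at least 3 leaves.
#' @return A list with `guide_tree` components `a`, `b`, `c`; their leaf sets
#'   partition the input leaf set.
#' @export
split_tree_abc <- function(tree) {
  n <- length(gt_leaves(tree))
  if (n < 3) stop("split requires a tree with at least 3 leaves")
  pick_a <- gt_pick_closest(tree, n / 3)
  a <- gt_at(tree, pick_a$path)
  bc <- gt_delete(tree, pick_a$path)
  n_bc <- length(gt_leaves(bc))
  pick_b <- gt_pick_closest(bc, n_bc / 2)
  b <- gt_at(bc, pick_b$path)
  cc <- gt_delete(bc, pick_b$path)
  list(a = a, b = b, c = cc)
}

#' Permute a split guide tree
#'
#' Reassembles the subtrees from [split_tree_abc()] in a permuted joining
#' order: `"none"` returns the original tree unchanged, `"abc"` gives
#' ((a,b),c), `"acb"` gives ((a,c),b) and `"bca"` gives ((b,c),a).
#'
#' @param a,b,c `guide_tree` subtrees from [split_tree_abc()].
#' @param perm One of `"none"`, `"abc"`, `"acb"`, `"bca"`.
#' @param original The original tree (required for `perm = "none"`).
#' @return A `guide_tree` over the same leaf set.
#' @export
permute_guide_tree <- function(a, b, c, perm, original = NULL) {
  switch(perm,
         none = {
           if (is.null(original)) stop("perm 'none' requires the original tree")
           original
         },
         abc = gt_join(gt_join(a, b), c),
         acb = gt_join(gt_join(a, c), b),
         bca = gt_join(gt_join(b, c), a),
         stop("unknown guide tree permutation: '", perm, "'"))
}

#' Greedy maximum-expected-accuracy guide tree
#'
#' Agglomerative construction: starting from singleton clusters, repeatedly
#' join the pair of clusters with the highest average expected accuracy
#' (UPGMA-style average linkage on the similarity matrix).  Ties are broken
#' lexicographically by the joined clusters' sorted member ids, so the result
#' is deterministic.
#'
#' @param pairwise_scores Symmetric numeric matrix of pairwise expected
#'   accuracies with row/column names set to the sequence ids.
#' @return A `guide_tree` whose leaves are the sequence ids.
#' @export
build_guide_tree <- function(pairwise_scores) {
  ids <- rownames(pairwise_scores)
  K <- length(ids)
  if (K < 2) stop("need at least 2 sequences")
  if (is.null(ids) || !identical(ids, colnames(pairwise_scores)))
    stop("pairwise_scores must have matching row and column names")
  if (any(is.na(pairwise_scores[upper.tri(pairwise_scores)])))
    stop("missing pairwise score")
  sim <- pairwise_scores
  clusters <- lapply(ids, gt_leaf)
  sizes <- rep(1L, K)
  keys <- ids
  active <- rep(TRUE, K)
  for (step in seq_len(K - 1)) {
    best <- NULL
    idx <- which(active)
    for (ii in seq_along(idx)) for (jj in seq_along(idx)) {
      if (jj <= ii) next
      i <- idx[ii]; j <- idx[jj]
      cand_key <- paste(sort(c(keys[i], keys[j])), collapse = "\r")
      if (is.null(best) || sim[i, j] > best$s + 1e-15 ||
          (abs(sim[i, j] - best$s) <= 1e-15 && cand_key < best$key)) {
        best <- list(i = i, j = j, s = sim[i, j], key = cand_key)
      }
    }
    i <- best$i; j <- best$j
    clusters[[i]] <- gt_join(clusters[[i]], clusters[[j]])
    # average linkage update (weighted by cluster sizes)
    for (k in idx) {
      if (k == i || k == j) next
      sim[i, k] <- sim[k, i] <-
        (sizes[i] * sim[i, k] + sizes[j] * sim[j, k]) / (sizes[i] + sizes[j])
    }
    sizes[i] <- sizes[i] + sizes[j]
    keys[i] <- paste(sort(c(keys[i], keys[j])), collapse = "\r")
    active[j] <- FALSE
  }
  clusters[[which(active)]]
}
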