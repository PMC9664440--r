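# Category maps are named character vectors: names are leaf labels, values
# are category names.  Maps may be partial (unlabelled leaves allowed).

check_category_map <- function(tree, cat) {
  if (is.null(names(cat))) stop("category map must be named by leaf label")
  missing <- setdiff(names(cat), tree$tip.label)
  if (length(missing))
    stop("category map refers to leaves absent from the tree: ",
         paste(missing, collapse = ", "))
  invisible(cat)
}

# Tip-label set under every node (tips and internals), by postorder sweep.
node_tip_sets <- function(phy) {
  nt <- length(phy$tip.label)
  sets <- vector("list", nt + phy$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- phy$tip.label[i]
  ed <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(ed)))
    sets[[ed[k, 1]]] <- c(sets[[ed[k, 1]]], sets[[ed[k, 2]]])
  sets
}

# Canonical keys for the non-trivial bipartitions (internal edges) of a
# tree, viewed as unrooted: each internal edge splits the leaves in two;
# the key is the sorted side not containing the overall smallest label, so
# it is invariant under re-rooting.
bipartition_keys <- function(phy) {
  tips <- sort(phy$tip.label)
  anchor <- tips[1]
  sets <- node_tip_sets(phy)
  nt <- length(phy$tip.label)
  children <- phy$edge[, 2]
  keys <- character(0)
  for (ch in children[children > nt]) {
    side <- sets[[ch]]
    if (length(side) < 2 || length(side) > nt - 2) next
    if (anchor %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Edge confidence (EC)
#'
#' The H-ensemble confidence of each internal edge of a reference tree: an
#' edge is identified with its (unrooted) leaf bipartition and EC is the
#' fraction of replicate trees containing the same bipartition.  Pendant
#' edges, trivially present in every tree, are excluded.
#'
#' @param ref_tree A `phylo` tree.
#' @param trees A list of `phylo` trees (or a `multiPhylo`) over the
#'   identical leaf set.
#' @return A data frame with columns `node` (the child node of the edge in
#'   `ref_tree`), `split` (the bipartition key) and `ec`.
#' @export
edge_confidence <- function(ref_tree, trees) {
  trees <- as_tree_list(trees)
  for (t in trees) {
    if (!setequal(t$tip.label, ref_tree$tip.label)) {
      d <- c(setdiff(t$tip.label, ref_tree$tip.label),
             setdiff(ref_tree$tip.label, t$tip.label))
      stop("leaf sets differ; symmetric difference: ",
           paste(d, collapse = ", "))
    }
  }
  key_sets <- lapply(trees, bipartition_keys)
  tips <- sort(ref_tree$tip.label)
  anchor <- tips[1]
  sets <- node_tip_sets(ref_tree)
  nt <- length(ref_tree$tip.label)
  out <- data.frame(node = integer(0), split = character(0), ec = numeric(0))
  seen <- character(0)
  for (ch in ref_tree$edge[, 2][ref_tree$edge[, 2] > nt]) {
    side <- sets[[ch]]
    if (length(side) < 2 || length(side) > nt - 2) next
    if (anchor %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    ec <- mean(vapply(key_sets, function(s) key %in% s, TRUE))
    out <- rbind(out, data.frame(node = ch, split = key, ec = ec))
  }
  out
}

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) return(list(trees))
  if (inherits(trees, "multiPhylo")) return(unclass(trees))
  stopifnot(is.list(trees), length(trees) >= 1,
            all(vapply(trees, inherits, TRUE, "phylo")))
  trees
}

# Preorder rank of every node (used as the final deterministic tie-break).
preorder_ranks <- function(phy) {
  nt <- length(phy$tip.label)
  ed <- ape::reorder.phylo(phy, "cladewise")$edge
  seq_nodes <- c(nt + 1L, ed[, 2])
  rank <- integer(nt + phy$Nnode)
  rank[seq_nodes] <- seq_along(seq_nodes)
  rank
}

#' Best-fit subtree for a leaf category
#'
#' Scans every node of a rooted tree and returns the node whose subtree
#' minimises the number of category errors: false positives (leaves under
#' the node not in category C) plus false negatives (leaves of C not under
#' the node); true positives are the leaves of C under the node.  Ties on
#' the error count are broken toward larger TP, then by preorder position.
#' By default unlabelled leaves under the node count as false positives
#' (they are not in C); set `ignore_unlabelled = TRUE` to exclude them.
#'
#' @param tree A rooted `phylo` tree.
#' @param cat Named character vector mapping leaf labels to category names.
#' @param category Category name (must occur in `cat`).
#' @param ignore_unlabelled Exclude unlabelled leaves from the FP count.
#' @return An object of class `subtree_fit`: a list with `node`, `tips`,
#'   `TP`, `FP`, `FN` and monophyly `m = TP / (TP + FP + FN)`.
#' @export
best_fit_subtree <- function(tree, cat, category, ignore_unlabelled = FALSE) {
  if (!ape::is.rooted(tree)) stop("best-fit subtree requires a rooted tree")
  check_category_map(tree, cat)
  C <- names(cat)[cat == category]
  if (length(C) == 0) stop("category '", category, "' has no leaves in the map")
  labelled <- names(cat)
  sets <- node_tip_sets(tree)
  rank <- preorder_ranks(tree)
  best <- NULL
  for (node in seq_along(sets)) {
    under <- sets[[node]]
    TP <- sum(under %in% C)
    not_C <- if (ignore_unlabelled) setdiff(intersect(under, labelled), C)
             else setdiff(under, C)
    FP <- length(not_C)
    FN <- length(C) - TP
    err <- FP + FN
    if (is.null(best) || err < best$err ||
        (err == best$err && TP > best$TP) ||
        (err == best$err && TP == best$TP && rank[node] < rank[best$node])) {
      best <- list(node = node, TP = TP, FP = FP, FN = FN, err = err)
    }
  }
  structure(list(node = best$node, tips = sets[[best$node]],
                 TP = best$TP, FP = best$FP, FN = best$FN,
                 m = best$TP / (best$TP + best$FP + best$FN)),
            class = "subtree_fit")
}

#' Monophyly of a category
#'
#' `m = TP / (TP + FP + FN)` computed at the best-fit subtree; `m = 1`
#' exactly when the category forms a clade, and decreases with increasing
#' errors.
#'
#' @inheritParams best_fit_subtree
#' @return A single numeric value in (0, 1\].
#' @export
monophyly <- function(tree, cat, category, ignore_unlabelled = FALSE) {
  best_fit_subtree(tree, cat, category, ignore_unlabelled)$m
}

#' Ensemble monophyly (EM)
#'
#' The mean monophyly of a category over an ensemble of trees.
#'
#' @param trees List of rooted `phylo` trees (or a `multiPhylo`).
#' @inheritParams best_fit_subtree
#' @return A single numeric value in (0, 1\].
#' @export
ensemble_monophyly <- function(trees, cat, category, ignore_unlabelled = FALSE) {
  trees <- as_tree_list(trees)
  mean(vapply(trees, monophyly, 0, cat = cat, category = category,
              ignore_unlabelled = ignore_unlabelled))
}

#' Root a tree by an outgroup category
#'
#' Assigns all leaves not in the outgroup category to a second category,
#' identifies the best-fit side for the outgroup over every edge of the
#' unrooted tree, and places the root on that edge, splitting its length
#' equally.  This handles both a monophyletic outgroup and the harder case
#' where the outgroup is polyphyletic in the estimated tree.
#'
#' @param tree A `phylo` tree (rooted input is unrooted first).
#' @param cat Named character vector mapping leaves to categories.
#' @param outgroup Outgroup category name.
#' @return A rooted `phylo` tree with the same leaf set.
#' @export
root_by_outgroup <- function(tree, cat, outgroup) {
  check_category_map(tree, cat)
  C <- names(cat)[cat == outgroup]
  if (length(C) == 0) stop("outgroup category has no leaves")
  if (setequal(C, tree$tip.label))
    stop("outgroup cannot be the entire leaf set")
  had_lengths <- !is.null(tree$edge.length)
  if (!had_lengths) tree$edge.length <- rep(1, nrow(tree$edge))
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  sets <- node_tip_sets(utree)
  all_tips <- utree$tip.label
  nC <- length(C)
  best <- NULL
  for (k in seq_len(nrow(utree$edge))) {
    ch <- utree$edge[k, 2]
    for (side_id in 1:2) {
      side <- if (side_id == 1) sets[[ch]] else setdiff(all_tips, sets[[ch]])
      if (length(side) == 0 || length(side) == length(all_tips)) next
      TP <- sum(side %in% C)
      FP <- length(side) - TP
      FN <- nC - TP
      err <- FP + FN
      if (is.null(best) || err < best$err ||
          (err == best$err && TP > best$TP)) {
        best <- list(k = k, node = ch, err = err, TP = TP)
      }
    }
  }
  rooted <- phytools::reroot(utree, node.number = best$node,
                             position = utree$edge.length[best$k] / 2)
  if (!had_lengths) rooted$edge.length <- NULL
  rooted
}

edge_above <- function(phy) {
  # length and support of the edge above each node; internal-node labels are
  # read as numeric supports of the edge above that node.
  nt <- length(phy$tip.label)
  n_all <- nt + phy$Nnode
  len <- rep(NA_real_, n_all)
  if (!is.null(phy$edge.length)) len[phy$edge[, 2]] <- phy$edge.length
  sup <- rep(NA_real_, n_all)
  if (!is.null(phy$node.label)) {
    lab <- suppressWarnings(as.numeric(phy$node.label))
    sup[nt + seq_len(phy$Nnode)] <- lab
  }
  list(len = len, sup = sup)
}

#' Condensed tree of category best-fit nodes
#'
#' Reduces a rooted tree to the branching order of its categories: the
#' best-fit node of each category becomes a leaf named after the category,
#' only edges on the paths from best-fit nodes to the root are preserved,
#' and unary nodes are collapsed repeatedly, summing the lengths and taking
#' the larger support of the two merged edges.
#'
#' @param tree A rooted `phylo` tree, optionally with edge lengths and
#'   numeric internal-node support labels.
#' @param cat Named character vector mapping leaves to categories.
#' @param categories Categories to condense on; default all in `cat`
#'   (at least 2 required).
#' @param ignore_unlabelled Passed to [best_fit_subtree()].
#' @return A rooted `phylo` tree whose leaf labels are the category names;
#'   collapsed supports ending at internal nodes become node labels, and the
#'   supports of the pendant category edges are returned in the
#'   `"leaf_support"` attribute (named by category).
#' @export
condensed_tree <- function(tree, cat, categories = sort(unique(cat)),
                           ignore_unlabelled = FALSE) {
  if (!ape::is.rooted(tree)) stop("condensed tree requires a rooted tree")
  if (length(categories) < 2) stop("need at least 2 categories")
  fits <- lapply(categories, function(cc)
    best_fit_subtree(tree, cat, cc, ignore_unlabelled))
  bf_nodes <- vapply(fits, `[[`, 0L, "node")
  if (anyDuplicated(bf_nodes)) {
    dup <- categories[duplicated(bf_nodes) | duplicated(bf_nodes, fromLast = TRUE)]
    stop("degenerate condensation: categories ", paste(dup, collapse = ", "),
         " share the same best-fit node")
  }
  nt <- length(tree$tip.label)
  root <- nt + 1L
  parent <- integer(nt + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path_to_root <- function(node) {
    p <- node
    while (node != root) { node <- parent[node]; p <- c(p, node) }
    p
  }
  paths <- lapply(bf_nodes, path_to_root)
  for (i in seq_along(bf_nodes)) {
    if (bf_nodes[i] %in% unlist(paths[-i])) {
      stop("degenerate condensation: best-fit node of '", categories[i],
           "' is an ancestor of another category's best-fit node")
    }
  }
  kept <- sort(unique(unlist(paths)))
  ea <- edge_above(tree)
  children <- lapply(seq_len(nt + tree$Nnode), function(i) integer(0))
  for (node in kept) {
    if (node == root) next
    children[[parent[node]]] <- c(children[[parent[node]]], node)
  }
  leaf_name <- setNames(categories, bf_nodes)
  # Recursively emit the condensed structure, collapsing unary chains:
  # carry (length, support) accumulated from the edge above.
  emit <- function(node, len_acc, sup_acc) {
    is_bf <- as.character(node) %in% names(leaf_name)
    kids <- children[[node]]
    if (is_bf) {
      return(list(label = leaf_name[[as.character(node)]],
                  len = len_acc, sup = sup_acc, leaf = TRUE))
    }
    if (length(kids) == 1) {
      k <- kids
      return(emit(k, sum_na(len_acc, ea$len[k]), max_na(sup_acc, ea$sup[k])))
    }
    subs <- lapply(kids, function(k) emit(k, ea$len[k], ea$sup[k]))
    list(label = NULL, len = len_acc, sup = sup_acc, leaf = FALSE, subs = subs)
  }
  top <- emit(root, NA_real_, NA_real_)
  if (top$leaf) stop("degenerate condensation: a single category spans the root")
  nwk <- paste0(render_condensed(top, is_root = TRUE), ";")
  out <- ape::read.tree(text = nwk)
  # supports of pendant (category) edges cannot be carried by Newick node
  # labels; expose them separately, keyed by category name
  leaf_sup <- numeric(0)
  collect <- function(node) {
    if (node$leaf) leaf_sup[[node$label]] <<- node$sup
    else for (s in node$subs) collect(s)
  }
  collect(top)
  attr(out, "leaf_support") <- leaf_sup
  out
}

sum_na <- function(a, b) {
  if (is.na(a)) b else if (is.na(b)) a else a + b
}
max_na <- function(a, b) {
  if (is.na(a)) b else if (is.na(b)) a else max(a, b)
}

render_condensed <- function(node, is_root = FALSE) {
  body <- if (node$leaf) node$label
  else paste0("(", paste(vapply(node$subs, render_condensed, ""),
                         collapse = ","),
              ")", if (!is.na(node$sup)) format(node$sup) else "")
  if (!is_root && !is.na(node$len))
    body <- paste0(body, ":", format(node$len, digits = 15))
  body
}

#' Canonical topology string of a tree
#'
#' Newick-like encoding of the branching order only: branch lengths and
#' supports are ignored and the children of every node are sorted by the
#' smallest leaf label they contain, so two trees have equal canonical
#' strings iff they have the same rooted topology.
#'
#' @param tree A `phylo` tree.
#' @return A character string.
#' @export
canonical_topology <- function(tree) {
  nt <- length(tree$tip.label)
  children <- lapply(seq_len(nt + tree$Nnode), function(i) integer(0))
  for (k in seq_len(nrow(tree$edge)))
    children[[tree$edge[k, 1]]] <- c(children[[tree$edge[k, 1]]], tree$edge[k, 2])
  rec <- function(node) {
    if (node <= nt) return(list(str = tree$tip.label[node],
                                min = tree$tip.label[node]))
    subs <- lapply(children[[node]], rec)
    mins <- vapply(subs, `[[`, "", "min")
    o <- order(mins)
    list(str = paste0("(", paste(vapply(subs[o], `[[`, "", "str"),
                                 collapse = ","), ")"),
         min = mins[o[1]])
  }
  paste0(rec(nt + 1L)$str, ";")
}

#' Topology confidence (TC)
#'
#' Condenses every tree of an ensemble to the branching order of the
#' designated categories and reports the relative frequency of each distinct
#' condensed topology.  The frequency of a topology is the fraction of
#' replicate trees supporting that branching order.
#'
#' @param trees List of rooted `phylo` trees (or a `multiPhylo`).
#' @param cat Named character vector mapping leaves to categories.
#' @param categories Categories to condense on; default all in `cat`.
#' @param on_error `"stop"` (default) aborts if any tree fails to condense;
#'   `"drop"` excludes failing trees (reported via a warning).
#' @param ignore_unlabelled Passed to [best_fit_subtree()].
#' @return Named numeric vector of frequencies (summing to 1 over the trees
#'   that condensed), sorted decreasingly, named by canonical topology.
#' @export
topology_confidence <- function(trees, cat, categories = sort(unique(cat)),
                                on_error = c("stop", "drop"),
                                ignore_unlabelled = FALSE) {
  on_error <- match.arg(on_error)
  trees <- as_tree_list(trees)
  strs <- character(0)
  failed <- integer(0)
  for (i in seq_along(trees)) {
    res <- tryCatch(
      canonical_topology(condensed_tree(trees[[i]], cat, categories,
                                        ignore_unlabelled)),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "stop")
        stop("tree ", i, " failed to condense: ", conditionMessage(res))
      failed <- c(failed, i)
    } else {
      strs <- c(strs, res)
    }
  }
  if (length(failed))
    warning("excluded ", length(failed), " tree(s) that failed to condense: ",
            paste(failed, collapse = ", "))
  if (length(strs) == 0) stop("no tree could be condensed")
  tab <- sort(table(strs), decreasing = TRUE)
  setNames(as.numeric(tab) / length(strs), names(tab))
}
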