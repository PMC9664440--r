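#' Specification for simulating a toy sequence family
#'
#' Describes how to evolve a root sequence down a tree: per-site
#' substitution and indel probabilities are `1 - exp(-rate * branch_length)`
#' so rates act per site and per unit branch length; indel lengths are
#' geometric with the given mean, insertions and deletions equiprobable.
#' These fixtures test code correctness; they make no attempt at realistic
#' evolutionary simulation.
#'
#' @param tree A rooted `phylo` tree with edge lengths and tip labels.
#' @param root_seq Root sequence (single string, non-empty).
#' @param sub_rate Substitution rate per site per unit branch length, in \[0, 1).
#' @param indel_rate Indel initiation rate per site per unit branch length,
#'   in \[0, 1).
#' @param mean_indel_len Mean indel length (>= 1).
#' @param seed Integer seed; the simulation is deterministic per seed.
#' @return An object of class `evolution_spec`.
#' @export
evolution_spec <- function(tree, root_seq, sub_rate = 0.1, indel_rate = 0.02,
                           mean_indel_len = 2, seed = 1) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (!ape::is.rooted(tree)) stop("evolution tree must be rooted")
  if (nchar(root_seq) == 0) stop("root sequence must be non-empty")
  if (sub_rate < 0 || sub_rate >= 1 || indel_rate < 0 || indel_rate >= 1)
    stop("rates must lie in [0, 1)")
  if (mean_indel_len < 1) stop("mean indel length must be >= 1")
  structure(list(tree = tree, root_seq = root_seq, sub_rate = sub_rate,
                 indel_rate = indel_rate, mean_indel_len = mean_indel_len,
                 seed = as.integer(seed)),
            class = "evolution_spec")
}

#' Evolve a toy sequence family with a known true alignment
#'
#' Simulates substitutions and indels down the tree of an
#' [evolution_spec()], maintaining column-homology bookkeeping through
#' insertions and deletions, and returns the leaf sequences together with
#' the implied true multiple alignment.  Deterministic for a given seed.
#'
#' @param spec An `evolution_spec`.
#' @return A list with `seqs` (named character vector of leaf sequences) and
#'   `true_msa` (an `msa`); degapping `true_msa` reproduces `seqs` exactly.
#' @export
evolve_family <- function(spec) {
  stopifnot(inherits(spec, "evolution_spec"))
  alphabet <- AA_ALPHABET
  tree <- spec$tree
  nt <- length(tree$tip.label)
  root <- nt + 1L
  children <- lapply(seq_len(nt + tree$Nnode), function(i) integer(0))
  edge_len <- lapply(seq_len(nt + tree$Nnode), function(i) NA_real_)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    children[[p]] <- c(children[[p]], tree$edge[k, 2])
    edge_len[[tree$edge[k, 2]]] <- tree$edge.length[k]
  }
  # Global homology column registry: `col_order` is the left-to-right order
  # of every column ever created; sequences carry per-residue column ids.
  env <- new.env()
  env$col_order <- seq_len(nchar(spec$root_seq))
  env$next_id <- nchar(spec$root_seq) + 1L
  leaves <- list()
  with_local_seed(spec$seed, {
    root_letters <- strsplit(spec$root_seq, "")[[1]]
    root_state <- list(cols = seq_len(nchar(spec$root_seq)),
                       letters = root_letters)
    walk <- function(node, state) {
      if (node != root) state <- evolve_branch(state, edge_len[[node]], spec,
                                               alphabet, env)
      if (node <= nt) {
        leaves[[tree$tip.label[node]]] <<- state
      } else {
        for (ch in children[[node]]) walk(ch, state)
      }
    }
    walk(root, root_state)
  })
  seqs <- vapply(tree$tip.label, function(id)
    paste(leaves[[id]]$letters, collapse = ""), character(1))
  used <- sort(unique(unlist(lapply(leaves, `[[`, "cols"))))
  col_pos <- intersect(env$col_order, used)
  rows <- vapply(tree$tip.label, function(id) {
    st <- leaves[[id]]
    ch <- rep("-", length(col_pos))
    hit <- match(st$cols, col_pos)
    ch[hit] <- st$letters
    paste(ch, collapse = "")
  }, character(1))
  list(seqs = seqs, true_msa = new_msa(rows))
}

evolve_branch <- function(state, len, spec, alphabet, env) {
  L <- length(state$letters)
  if (L > 0) {
    # substitutions: each hit site is replaced by a different letter
    p_sub <- 1 - exp(-spec$sub_rate * len)
    hits <- which(runif(L) < p_sub)
    for (i in hits) {
      others <- setdiff(alphabet, state$letters[i])
      state$letters[i] <- others[sample.int(length(others), 1)]
    }
  }
  # indels: scan sites right-to-left so indices stay valid
  p_ind <- 1 - exp(-spec$indel_rate * len)
  L <- length(state$letters)
  if (L > 0 && p_ind > 0) {
    events <- which(runif(L) < p_ind)
    for (i in rev(events)) {
      glen <- stats::rgeom(1, 1 / spec$mean_indel_len) + 1L
      if (runif(1) < 0.5) {
        # deletion of glen residues starting at i
        drop <- i:min(i + glen - 1L, length(state$letters))
        state$cols <- state$cols[-drop]
        state$letters <- state$letters[-drop]
      } else {
        # insertion of glen fresh residues after site i
        new_ids <- env$next_id + seq_len(glen) - 1L
        env$next_id <- env$next_id + glen
        anchor <- match(state$cols[i], env$col_order)
        env$col_order <- append(env$col_order, new_ids, after = anchor)
        new_letters <- alphabet[sample.int(length(alphabet), glen,
                                           replace = TRUE)]
        state$cols <- append(state$cols, new_ids, after = i)
        state$letters <- append(state$letters, new_letters, after = i)
      }
    }
  }
  state
}

#' Labelled tree with controlled monophyly violations
#'
#' Builds a rooted tree in which every category is a perfect clade (a
#' caterpillar of caterpillar clades, unit branch lengths, leaves named
#' `<category><k>`), then performs `n_violations` random leaf re-grafts,
#' each moving a random leaf next to a random leaf of a different category.
#' With `n_violations = 0` every category has monophyly 1.
#'
#' @param n_per_category Leaves per category (single count or vector, >= 1).
#' @param categories Character vector of at least 2 category names.
#' @param n_violations Number of random re-grafts (>= 0).
#' @param seed Integer seed.
#' @return A list with `tree` (rooted `phylo`) and `cat` (named character
#'   vector mapping leaf labels to categories).
#' @export
make_labelled_tree <- function(n_per_category, categories, n_violations = 0,
                               seed = 1) {
  stopifnot(length(categories) >= 2, all(n_per_category >= 1))
  n_per <- rep(n_per_category, length.out = length(categories))
  caterpillar <- function(labels) {
    s <- paste0(labels[1], ":1")
    for (lb in labels[-1]) s <- paste0("(", s, ",", lb, ":1):1")
    s
  }
  clades <- mapply(function(cc, n) {
    labs <- paste0(cc, seq_len(n))
    if (n == 1) paste0(labs, ":1") else caterpillar(labs)
  }, categories, n_per)
  s <- clades[1]
  for (cl in clades[-1]) s <- paste0("(", s, ",", cl, ":1):1")
  tree <- ape::read.tree(text = paste0(s, ";"))
  cat_map <- setNames(rep(categories, n_per),
                      unlist(mapply(function(cc, n) paste0(cc, seq_len(n)),
                                    categories, n_per, SIMPLIFY = FALSE)))
  n_leaves <- length(tree$tip.label)
  if (n_violations > n_leaves) stop("n_violations exceeds the leaf count")
  if (n_violations > 0) {
    with_local_seed(seed, {
      for (v in seq_len(n_violations)) {
        leaf <- tree$tip.label[sample.int(length(tree$tip.label), 1)]
        other <- tree$tip.label[cat_map[tree$tip.label] != cat_map[leaf]]
        target <- other[sample.int(length(other), 1)]
        tree <- ape::drop.tip(tree, leaf)
        tree <- phytools::bind.tip(tree, leaf,
                                   where = which(tree$tip.label == target),
                                   position = 0.5, edge.length = 0.5)
      }
    })
  }
  list(tree = tree, cat = cat_map[tree$tip.label])
}

#' Neighbour-joining tree from an msa
#'
#' Minimal tree-estimation utility for fixtures and end-to-end tests:
#' computes pairwise p-distances over columns where both rows have residues
#' and runs neighbour joining.  Not a substitute for a real phylogeny
#' program.
#'
#' @param msa An `msa` with at least 4 rows.
#' @return An unrooted `phylo` tree.
#' @export
nj_from_msa <- function(msa) {
  K <- length(msa$row_ids)
  m <- msa_matrix(msa)
  D <- matrix(0, K, K, dimnames = list(msa$row_ids, msa$row_ids))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    keep <- m[i, ] != "-" & m[j, ] != "-"
    d <- if (any(keep)) mean(m[i, keep] != m[j, keep]) else 1
    D[i, j] <- D[j, i] <- d
  }
  ape::nj(as.dist(D))
}
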