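tr <- function(s) ape::read.tree(text = s)

test_that("EC is 1 on every internal edge when all trees equal the reference", {
  t <- tr("((A,B),(C,(D,E)));")
  ec <- edge_confidence(t, list(t, t, t))
  expect_gt(nrow(ec), 0)
  expect_true(all(ec$ec == 1))
})

test_that("EC matches brute-force bipartition counting on 5-leaf fixtures", {
  ref <- tr("((A,B),(C,(D,E)));")
  trees <- list(tr("((A,B),(C,(D,E)));"),
                tr("((A,C),(B,(D,E)));"),
                tr("(((A,B),C),(D,E));"),
                tr("((A,(B,C)),(D,E));"))
  ec <- edge_confidence(ref, trees)
  # independent oracle: unrooted bipartitions via ape::prop.part on unrooted
  # trees, counting the fraction of trees containing each reference split
  split_set <- function(t) {
    u <- ape::unroot(t)
    pp <- ape::prop.part(u)
    labs <- attr(pp, "labels")
    keys <- vapply(pp, function(idx) {
      side <- labs[idx]
      if (sort(labs)[1] %in% side) side <- setdiff(labs, side)
      paste(sort(side), collapse = "|")
    }, "")
    sizes <- lengths(pp)
    unique(keys[sizes >= 2 & sizes <= length(labs) - 2])
  }
  sets <- lapply(trees, split_set)
  for (r in seq_len(nrow(ec))) {
    expect_equal(ec$ec[r],
                 mean(vapply(sets, function(s) ec$split[r] %in% s, TRUE)),
                 label = ec$split[r])
  }
})

test_that("EC is invariant under re-rooting of the input trees", {
  ref <- tr("((A,B),(C,(D,E)));")
  t2 <- tr("((A,C),(B,(D,E)));")
  ec1 <- edge_confidence(ref, list(ref, t2))
  t2r <- ape::root(t2, outgroup = "D", resolve.root = TRUE)
  ec2 <- edge_confidence(ref, list(ref, t2r))
  expect_equal(ec1$ec[order(ec1$split)], ec2$ec[order(ec2$split)])
})

test_that("EC rejects trees with mismatched leaf sets, naming the difference", {
  ref <- tr("((A,B),(C,D));")
  bad <- tr("((A,B),(C,E));")
  expect_error(edge_confidence(ref, list(bad)), "D.*E|E.*D")
})

test_that("best-fit subtree finds a perfect clade with zero errors", {
  t <- tr("((A1,A2),B1);")
  cat_map <- c(A1 = "A", A2 = "A", B1 = "B")
  fit <- best_fit_subtree(t, cat_map, "A")
  expect_setequal(fit$tips, c("A1", "A2"))
  expect_identical(c(fit$TP, fit$FP, fit$FN), c(2L, 0L, 0L))
  expect_identical(fit$m, 1)
})

test_that("best-fit ties on errors resolve toward larger TP", {
  t <- tr("(((A1,A2),B1),A3);")
  cat_map <- c(A1 = "A", A2 = "A", A3 = "A", B1 = "B")
  fit <- best_fit_subtree(t, cat_map, "A")
  # node (A1,A2): FN = 1; root: FP = 1; both 1 error, root has TP = 3
  expect_setequal(fit$tips, c("A1", "A2", "A3", "B1"))
  expect_identical(fit$TP, 3L)
  expect_identical(fit$FP, 1L)
  expect_identical(fit$FN, 0L)
  expect_equal(fit$m, 3 / 4)
})

test_that("best-fit errors are minimal over an exhaustive node scan", {
  lt <- make_labelled_tree(4, c("X", "Y", "Z"), n_violations = 3, seed = 9)
  for (category in c("X", "Y", "Z")) {
    fit <- best_fit_subtree(lt$tree, lt$cat, category)
    C <- names(lt$cat)[lt$cat == category]
    sets <- msaensemble:::node_tip_sets(lt$tree)
    errs <- vapply(sets, function(under) {
      sum(!(under %in% C)) + sum(!(C %in% under))
    }, 0)
    expect_identical(fit$FP + fit$FN, as.integer(min(errs)))
  }
})

test_that("unlabelled leaves count as FP unless excluded", {
  t <- tr("(((A1,A2),U1),B1);")
  cat_map <- c(A1 = "A", A2 = "A", B1 = "B")
  fit_strict <- best_fit_subtree(t, cat_map, "A")
  expect_setequal(fit_strict$tips, c("A1", "A2"))
  fit_loose <- best_fit_subtree(t, cat_map, "A", ignore_unlabelled = TRUE)
  # with U1 free, the larger subtree has TP 2, FP 0, FN 0
  expect_setequal(fit_loose$tips, c("A1", "A2", "U1"))
  expect_identical(fit_loose$m, 1)
})

test_that("monophyly is 1 exactly for clades and decreases with errors", {
  lt0 <- make_labelled_tree(3, c("P", "Q"), n_violations = 0, seed = 4)
  expect_identical(monophyly(lt0$tree, lt0$cat, "P"), 1)
  expect_identical(monophyly(lt0$tree, lt0$cat, "Q"), 1)
  expect_error(best_fit_subtree(lt0$tree, lt0$cat, "R"), "no leaves")
})

test_that("ensemble monophyly is the mean over trees, order-invariant", {
  t1 <- tr("((A1,A2),(B1,B2));")                # m(A) = 1
  t2 <- tr("(((A1,B1),A2),B2);")                # m(A) < 1
  cat_map <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  m1 <- monophyly(t1, cat_map, "A")
  m2 <- monophyly(t2, cat_map, "A")
  expect_identical(m1, 1)
  expect_equal(ensemble_monophyly(list(t1, t2), cat_map, "A"), mean(c(m1, m2)))
  expect_equal(ensemble_monophyly(list(t2, t1), cat_map, "A"),
               ensemble_monophyly(list(t1, t2), cat_map, "A"))
  # two trees with m = 1 and m = 0.5 average to 0.75
  t3 <- tr("((A1,B1),(A2,B2));")
  expect_equal(monophyly(t3, cat_map, "A"), 0.5)
  expect_equal(ensemble_monophyly(list(t1, t3), cat_map, "A"), 0.75)
})

test_that("EM decreases on average as leaves are re-grafted", {
  em_at <- function(k) {
    trees <- lapply(1:6, function(s)
      make_labelled_tree(4, c("X", "Y", "Z"), n_violations = k,
                         seed = 100 + 10 * k + s)$tree)
    cat_map <- make_labelled_tree(4, c("X", "Y", "Z"), 0, 1)$cat
    mean(vapply(c("X", "Y", "Z"), function(cc)
      ensemble_monophyly(trees, cat_map, cc), 0))
  }
  e0 <- em_at(0)
  e2 <- em_at(2)
  e5 <- em_at(5)
  expect_identical(e0, 1)
  expect_gt(e0, e2)
  expect_gt(e2, e5)
})

test_that("outgroup rooting places the root on a single-leaf outgroup edge", {
  t <- tr("((A,B),(C,O));")
  cat_map <- c(A = "in", B = "in", C = "in", O = "out")
  rt <- root_by_outgroup(t, cat_map, "out")
  expect_true(ape::is.rooted(rt))
  expect_setequal(rt$tip.label, t$tip.label)
  # one child of the root is the outgroup leaf
  root_children <- rt$edge[rt$edge[, 1] == length(rt$tip.label) + 1L, 2]
  kids <- lapply(root_children, function(n)
    msaensemble:::node_tip_sets(rt)[[n]])
  expect_true(any(vapply(kids, function(k) identical(k, "O"), TRUE)))
  expect_error(root_by_outgroup(t, cat_map, "nope"), "no leaves")
  all_out <- c(A = "out", B = "out", C = "out", O = "out")
  expect_error(root_by_outgroup(t, all_out, "out"), "entire leaf set")
})

test_that("polyphyletic outgroups root at the best-fit edge of the scan", {
  t <- tr("(((O1,A1),(O2,O3)),(A2,A3));")
  cat_map <- c(O1 = "out", O2 = "out", O3 = "out",
               A1 = "in", A2 = "in", A3 = "in")
  rt <- root_by_outgroup(t, cat_map, "out")
  expect_true(ape::is.rooted(rt))
  # best single split for the outgroup is the clade {O1,A1,O2,O3}
  # (TP 3, FP 1, FN 0 -> 1 error; any pure-outgroup side has >= 1 error but
  # smaller TP)
  root_children <- rt$edge[rt$edge[, 1] == length(rt$tip.label) + 1L, 2]
  kids <- lapply(root_children, function(n)
    sort(msaensemble:::node_tip_sets(rt)[[n]]))
  expect_true(any(vapply(kids, function(k)
    identical(k, sort(c("O1", "A1", "O2", "O3"))), TRUE)))
})

test_that("condensed trees collapse unary chains with sum/max rules", {
  # the path above A's best-fit node is a chain of 3 edges with lengths
  # 1, 2, 3 and supports 50, 90, 70 once the unlabelled side leaves X1, X2
  # are pruned
  t <- tr("((((A1:1,A2:1)50:1,X1:9)90:2,X2:9)70:3,(B1:1,B2:1)88:4);")
  cat_map <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  ct <- condensed_tree(t, cat_map)
  expect_setequal(ct$tip.label, c("A", "B"))
  lenA <- ct$edge.length[ct$edge[, 2] == which(ct$tip.label == "A")]
  lenB <- ct$edge.length[ct$edge[, 2] == which(ct$tip.label == "B")]
  expect_equal(lenA, 6)   # 1 + 2 + 3
  expect_equal(lenB, 4)
  # collapsed supports are the max along each chain
  sup <- attr(ct, "leaf_support")
  expect_equal(unname(sup["A"]), 90)
  expect_equal(unname(sup["B"]), 88)
})

test_that("condensation preserves root-to-best-fit path lengths", {
  lt <- make_labelled_tree(3, c("D", "K", "L"), n_violations = 0, seed = 2)
  ct <- condensed_tree(lt$tree, lt$cat)
  expect_setequal(ct$tip.label, c("D", "K", "L"))
  depth_of <- function(phy, tip) {
    nt <- length(phy$tip.label)
    parent <- integer(nt + phy$Nnode)
    parent[phy$edge[, 2]] <- phy$edge[, 1]
    len <- rep(0, nt + phy$Nnode)
    len[phy$edge[, 2]] <- phy$edge.length
    node <- which(phy$tip.label == tip)
    d <- 0
    while (node != nt + 1L) {
      d <- d + len[node]
      node <- parent[node]
    }
    d
  }
  for (category in c("D", "K", "L")) {
    fit <- best_fit_subtree(lt$tree, lt$cat, category)
    nt <- length(lt$tree$tip.label)
    parent <- integer(nt + lt$tree$Nnode)
    parent[lt$tree$edge[, 2]] <- lt$tree$edge[, 1]
    len <- rep(0, nt + lt$tree$Nnode)
    len[lt$tree$edge[, 2]] <- lt$tree$edge.length
    node <- fit$node
    d <- 0
    while (node != nt + 1L) {
      d <- d + len[node]
      node <- parent[node]
    }
    expect_equal(depth_of(ct, category), d, label = category)
  }
})

test_that("degenerate condensations are rejected with a diagnostic", {
  # Q is a clade nested inside the best-fit subtree of the surrounding
  # category P, so P's condensed leaf would have to contain Q's: the
  # categories cannot be represented as distinct leaves
  t <- tr("((((p1,p2),(q1,q2)),(p3,p4)),z);")
  cm <- c(p1 = "P", p2 = "P", p3 = "P", p4 = "P", q1 = "Q", q2 = "Q")
  expect_setequal(best_fit_subtree(t, cm, "P")$tips,
                  c("p1", "p2", "p3", "p4", "q1", "q2"))
  expect_error(condensed_tree(t, cm), "degenerate")
  expect_error(condensed_tree(tr("(A,B);"), c(A = "Z", B = "Z")),
               "at least 2")
})

test_that("topology confidence counts condensed topologies", {
  make_tree <- function(s) tr(s)
  cat_map <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B", G1 = "G", D1 = "D")
  top1 <- "((((A1:1,A2:1):1,(B1:1,B2:1):1):1,G1:3):1,D1:4);"
  top2 <- "((((A1:1,A2:1):1,G1:2):1,(B1:1,B2:1):1):1,D1:4);"
  trees <- c(replicate(7, make_tree(top1), simplify = FALSE),
             replicate(3, make_tree(top2), simplify = FALSE))
  tc <- topology_confidence(trees, cat_map)
  expect_equal(sum(tc), 1)
  expect_equal(unname(tc[1]), 0.7)
  expect_equal(unname(tc[2]), 0.3)
  expect_identical(names(tc)[1], "(((A,B),G),D);")
  # all trees identical: a single topology with TC 1
  tc1 <- topology_confidence(replicate(4, make_tree(top1), simplify = FALSE),
                             cat_map)
  expect_identical(unname(tc1), 1)
  # two distinct topologies split 0.5 / 0.5
  tc2 <- topology_confidence(list(make_tree(top1), make_tree(top2)), cat_map)
  expect_identical(unname(tc2), c(0.5, 0.5))
})

test_that("canonical topology strings sort children deterministically", {
  t1 <- tr("((B,A),C);")
  t2 <- tr("((A,B),C);")
  t3 <- tr("(C,(A,B));")
  expect_identical(canonical_topology(t1), canonical_topology(t2))
  expect_identical(canonical_topology(t2), canonical_topology(t3))
  expect_false(canonical_topology(tr("((A,C),B);")) == canonical_topology(t1))
})
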