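caterpillar_tree <- function(ids) {
  t <- gt_leaf(ids[1])
  for (id in ids[-1]) t <- gt_join(t, gt_leaf(id))
  t
}

test_that("three-leaf trees split into singletons", {
  t <- gt_join(gt_join(gt_leaf("A"), gt_leaf("B")), gt_leaf("C"))
  sp <- split_tree_abc(t)
  expect_setequal(c(gt_leaves(sp$a), gt_leaves(sp$b), gt_leaves(sp$c)),
                  c("A", "B", "C"))
  expect_length(gt_leaves(sp$a), 1)
  expect_length(gt_leaves(sp$b), 1)
  expect_length(gt_leaves(sp$c), 1)
  expect_error(split_tree_abc(gt_join(gt_leaf("A"), gt_leaf("B"))), "3 leaves")
})

test_that("a nine-leaf caterpillar splits into three thirds", {
  t <- caterpillar_tree(paste0("L", 1:9))
  sp <- split_tree_abc(t)
  expect_length(gt_leaves(sp$a), 3)
  expect_length(gt_leaves(sp$b), 3)
  expect_length(gt_leaves(sp$c), 3)
  expect_setequal(c(gt_leaves(sp$a), gt_leaves(sp$b), gt_leaves(sp$c)),
                  paste0("L", 1:9))
})

test_that("the a-subset size is closest to n/3 over every edge", {
  # random join orders over 5..20 leaves; exhaustive edge scan as oracle
  msaensemble:::with_local_seed(13, {
    for (rep in 1:10) {
      n <- sample(5:20, 1)
      ids <- paste0("t", sample.int(99, n))
      nodes <- lapply(ids, gt_leaf)
      while (length(nodes) > 1) {
        k <- sample.int(length(nodes) - 1, 1)
        nodes[[k]] <- gt_join(nodes[[k]], nodes[[k + 1]])
        nodes[[k + 1]] <- NULL
      }
      tree <- nodes[[1]]
      sp <- split_tree_abc(tree)
      sizes <- vapply(msaensemble:::gt_subtrees(tree),
                      function(s) length(s$leaves), 0L)
      expect_equal(abs(length(gt_leaves(sp$a)) - n / 3), min(abs(sizes - n / 3)),
                   tolerance = 1e-12)
      expect_setequal(c(gt_leaves(sp$a), gt_leaves(sp$b), gt_leaves(sp$c)), ids)
    }
  })
})

test_that("guide tree permutations reassemble the split subtrees", {
  t <- gt_join(gt_join(gt_leaf("A"), gt_leaf("B")), gt_leaf("C"))
  sp <- split_tree_abc(t)
  a <- gt_leaf("A"); b <- gt_leaf("B"); c <- gt_leaf("C")
  expect_identical(permute_guide_tree(a, b, c, "none", original = t), t)
  expect_identical(gt_newick(permute_guide_tree(a, b, c, "bca")), "((B,C),A);")
  expect_identical(gt_newick(permute_guide_tree(a, b, c, "abc")), "((A,B),C);")
  expect_identical(gt_newick(permute_guide_tree(a, b, c, "acb")), "((A,C),B);")
  for (perm in c("abc", "acb", "bca"))
    expect_setequal(gt_leaves(permute_guide_tree(a, b, c, perm)),
                    c("A", "B", "C"))
  expect_error(permute_guide_tree(a, b, c, "cab"), "unknown")
  expect_error(permute_guide_tree(a, b, c, "none"), "original")
})

test_that("diversified ensembles cycle permutations while seeds increment", {
  seqs <- rand_aa_seqs(4, 10, seed = 21)
  e <- diversified_ensemble(seqs, n_replicates = 8)
  labels <- vapply(e$replicates, `[[`, "", "label")
  expect_identical(labels, c("none.0", "abc.1", "acb.2", "bca.3",
                             "none.4", "abc.5", "acb.6", "bca.7"))
  perms <- vapply(e$replicates, `[[`, "", "perm")
  expect_identical(sort(unique(perms)), sort(c("none", "abc", "acb", "bca")))
  expect_error(diversified_ensemble(seqs, n_replicates = 0), "n_replicates")
})

test_that("replicates are deterministic for a fixed (perm, seed)", {
  seqs <- rand_aa_seqs(4, 10, seed = 31)
  r1 <- align_replicate(seqs, perm = "abc", seed = 3)
  r2 <- align_replicate(seqs, perm = "abc", seed = 3)
  expect_identical(r1$msa$rows, r2$msa$rows)
  expect_identical(r1$label, "abc.3")
})

test_that("every replicate degaps back to the input sequences", {
  seqs <- rand_aa_seqs(4, 10, seed = 77)
  e <- diversified_ensemble(seqs, n_replicates = 5)
  for (r in e$replicates)
    expect_identical(degap(r$msa)[names(seqs)], seqs)
})

test_that("stratified ensembles encode stratum membership in the labels", {
  seqs <- rand_aa_seqs(4, 10, seed = 55)
  spec <- list(list(perm = "abc", seeds = 2), list(perm = "bca", seeds = 2))
  e1 <- stratified_ensemble(seqs, spec)
  expect_identical(vapply(e1$replicates, `[[`, "", "label"),
                   c("abc.2", "bca.2"))
  expect_identical(e1$kind, "stratified")
  e2 <- stratified_ensemble(seqs, spec)
  expect_identical(lapply(e1$replicates, `[[`, "msa"),
                   lapply(e2$replicates, `[[`, "msa"))
  single <- stratified_ensemble(seqs, list(list(perm = "none", seeds = 0)))
  expect_length(single$replicates, 1)
  expect_error(stratified_ensemble(seqs, list(list(perm = "abc",
                                                   seeds = integer(0)))),
               "empty stratum")
})

test_that("replicate labels follow the perm.s convention and must be unique", {
  m <- new_msa(c(a = "AR", b = "AR"))
  r <- new_replicate(m, "abc", 3)
  expect_identical(r$label, "abc.3")
  expect_error(new_replicate(m, "xyz", 1), "permutation")
  expect_error(new_ensemble(list(r, r)), "unique")
  m2 <- new_msa(c(a = "ARN", b = "ARN"))
  expect_error(new_ensemble(list(r, new_replicate(m2, "bca", 1))),
               "sequence set")
})

test_that("convergence heuristic counts singleton and reproduced signatures", {
  rows <- c(a = "ARND", b = "ARND")
  same <- new_ensemble(lapply(0:2, function(s)
    make_toy_replicate(rows, msaensemble:::PERMS[s + 1], s)))
  ck <- convergence_check(same)
  expect_identical(ck$n1, 0L)
  expect_true(ck$converged)
  # two replicates sharing no columns
  r1 <- make_toy_replicate(c(a = "-ARND", b = "ARND-"), "none", 0)
  r2 <- make_toy_replicate(c(a = "ARND", b = "ARND"), "abc", 1)
  diff2 <- new_ensemble(list(r1, r2))
  ck2 <- convergence_check(diff2)
  expect_identical(ck2$n2, 0L)
  expect_false(ck2$converged)
  # three handcrafted replicates vs a dictionary-count oracle
  reps <- list(make_toy_replicate(c(a = "ARN-", b = "AR-N"), "none", 0),
               make_toy_replicate(c(a = "ARN-", b = "AR-N"), "abc", 1),
               make_toy_replicate(c(a = "ARN", b = "ARN"), "acb", 2))
  ens <- new_ensemble(reps)
  sigs <- lapply(reps, function(r) unique(column_signatures(r$msa)))
  counts <- table(unlist(sigs))
  ck3 <- convergence_check(ens)
  expect_identical(ck3$n1, sum(counts == 1))
  expect_identical(ck3$n2, sum(counts >= 2))
  expect_error(convergence_check(new_ensemble(list(reps[[1]]))), "at least 2")
})
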