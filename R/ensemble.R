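PERMS <- c("none", "abc", "acb", "bca")

#' Construct a replicate
#'
#' A replicate is one msa from an ensemble, tagged with the guide-tree
#' permutation used to build it and the HMM perturbation seed; its label is
#' `perm.s` (for example `"abc.3"`).  Seed 0 means the unperturbed default
#' HMM parameters were used.
#'
#' @param msa An `msa`.
#' @param perm One of `"none"`, `"abc"`, `"acb"`, `"bca"`.
#' @param seed Non-negative integer perturbation seed.
#' @return An object of class `replicate_msa`.
#' @export
new_replicate <- function(msa, perm = "none", seed = 0) {
  if (!perm %in% PERMS) stop("unknown guide tree permutation: '", perm, "'")
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0) stop("seed must be a non-negative integer")
  structure(list(msa = msa, perm = perm, seed = seed,
                 label = paste0(perm, ".", seed)),
            class = "replicate_msa")
}

#' Construct an ensemble of replicates
#'
#' @param replicates List of `replicate_msa` objects over the same degapped
#'   sequence set, with unique labels.
#' @param kind `"diversified"` or `"stratified"`.
#' @return An object of class `msa_ensemble`.
#' @export
new_ensemble <- function(replicates, kind = c("diversified", "stratified")) {
  kind <- match.arg(kind)
  if (length(replicates) < 1) stop("ensemble must contain at least 1 replicate")
  stopifnot(all(vapply(replicates, inherits, TRUE, "replicate_msa")))
  labels <- vapply(replicates, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("replicate labels must be unique within the ensemble")
  ref <- degap(replicates[[1]]$msa)
  for (r in replicates[-1]) {
    d <- degap(r$msa)
    if (!identical(d[sort(names(d))], ref[sort(names(ref))]))
      stop("all replicates must share the identical degapped sequence set")
  }
  structure(list(replicates = replicates, kind = kind),
            class = "msa_ensemble")
}

#' @export
print.msa_ensemble <- function(x, ...) {
  cat("msa_ensemble (", x$kind, "): ", length(x$replicates),
      " replicates [", paste(vapply(x$replicates, `[[`, "", "label"),
                             collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Align one replicate
#'
#' Runs the full single-alignment pipeline for one (permutation, seed)
#' choice: perturb the HMM parameters with the given seed, compute all-pairs
#' posterior match probabilities, apply the iterative consistency
#' transformation, build the greedy maximum-expected-accuracy guide tree from
#' the pairwise expected accuracies, apply the requested guide-tree
#' permutation, align progressively and optionally refine.  The guide tree
#' (and its three-way split) is recomputed for every seed, since perturbation
#' changes the posteriors and hence the expected accuracies.
#'
#' @param seqs Named character vector of at least 2 unaligned sequences.
#' @param perm Guide-tree permutation, one of `"none"`, `"abc"`, `"acb"`,
#'   `"bca"` (the latter three require at least 3 sequences).
#' @param seed HMM perturbation seed; 0 = unperturbed.
#' @param amplitude Perturbation amplitude, default 0.25.
#' @param alphabet_kind `"aa"`, `"nt"`, or `NULL` to guess from the letters.
#' @param consistency_rounds Consistency transformation rounds, default 2.
#' @param refine_rounds Refinement rounds applied to this replicate.
#' @param cutoff Posterior sparsity cutoff, default 0.01.
#' @return A `replicate_msa`.
#' @export
align_replicate <- function(seqs, perm = "none", seed = 0, amplitude = 0.25,
                            alphabet_kind = NULL, consistency_rounds = 2,
                            refine_rounds = 0, cutoff = 0.01) {
  if (is.null(names(seqs))) stop("sequences must be named")
  if (is.null(alphabet_kind)) alphabet_kind <- guess_alphabet(seqs)
  params <- default_params(alphabet_kind)
  params <- perturb_params(params, perturbation_spec(amplitude, seed))
  ps <- all_pair_posteriors(params, seqs, cutoff)
  ps <- consistency_transform(ps, consistency_rounds)
  tree <- build_guide_tree(pairwise_ea_matrix(ps))
  if (perm != "none") {
    sp <- split_tree_abc(tree)
    tree <- permute_guide_tree(sp$a, sp$b, sp$c, perm, original = tree)
  } else if (!perm %in% PERMS) {
    stop("unknown guide tree permutation: '", perm, "'")
  }
  msa <- progressive_align(seqs, ps, tree)
  if (refine_rounds > 0)
    msa <- refine(msa, ps, rounds = refine_rounds, seed = seed + 1000000L)
  new_replicate(msa, perm, seed)
}

guess_alphabet <- function(seqs) {
  letters_used <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  if (all(letters_used %in% NT_ALPHABET)) "nt" else "aa"
}

#' Diversified ensemble
#'
#' Generates an ensemble designed to maximise variation among replicates:
#' replicate i (0-based) uses perturbation seed s = i while the guide-tree
#' permutation cycles through none, abc, acb, bca.  Replicate 0 is therefore
#' the default alignment `none.0`.
#'
#' @inheritParams align_replicate
#' @param n_replicates Number of replicates (seeds 0 .. n_replicates - 1).
#' @param ... Passed to [align_replicate()].
#' @return An `msa_ensemble` of kind `"diversified"`.
#' @export
diversified_ensemble <- function(seqs, n_replicates = 16, amplitude = 0.25, ...) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (length(seqs) < 3) stop("diversified ensemble requires at least 3 sequences")
  reps <- lapply(seq_len(n_replicates) - 1L, function(i) {
    align_replicate(seqs, perm = PERMS[(i %% 4L) + 1L], seed = i,
                    amplitude = amplitude, ...)
  })
  new_ensemble(reps, kind = "diversified")
}

#' Stratified ensemble
#'
#' Generates an ensemble organised into strata in which some parameters are
#' held fixed while others vary, so that a specific source of bias (for
#' example the guide tree) can be isolated by comparing strata.  A stratum
#' fixing `perm = "abc"` over seeds 0..k against a stratum fixing
#' `perm = "bca"` over the same seeds compares alignments that differ only in
#' guide-tree topology.
#'
#' @inheritParams align_replicate
#' @param strata_spec List of strata, each a list with elements `perm` (a
#'   single permutation label) and `seeds` (non-empty integer vector).
#' @param ... Passed to [align_replicate()].
#' @return An `msa_ensemble` of kind `"stratified"`; replicate labels
#'   (`perm.s`) encode stratum membership.
#' @export
stratified_ensemble <- function(seqs, strata_spec, amplitude = 0.25, ...) {
  if (length(strata_spec) < 1) stop("strata_spec must contain at least one stratum")
  reps <- list()
  for (stratum in strata_spec) {
    if (is.null(stratum$seeds) || length(stratum$seeds) == 0)
      stop("empty stratum: every stratum needs at least one seed")
    for (s in stratum$seeds) {
      reps[[length(reps) + 1]] <-
        align_replicate(seqs, perm = stratum$perm, seed = s,
                        amplitude = amplitude, ...)
    }
  }
  new_ensemble(reps, kind = "stratified")
}

#' Ensemble convergence heuristic
#'
#' Tests whether most of the potential diversity in an ensemble has been
#' sampled, by comparing the number of singleton distinct column signatures
#' (n1, found in exactly one replicate) with the number of reproduced
#' distinct signatures (n2, found in two or more replicates, so that an
#' ensemble of identical replicates has n1 = 0 and n2 > 0).  The ensemble is
#' considered converged when n2 > n1, or when the ensemble size has reached
#' the cap of m replicates where m is the median column count.
#'
#' @param ensemble An `msa_ensemble` with at least 2 replicates.
#' @return A list with `converged`, `n1`, `n2`.
#' @export
convergence_check <- function(ensemble) {
  stopifnot(inherits(ensemble, "msa_ensemble"))
  n_rep <- length(ensemble$replicates)
  if (n_rep < 2) stop("convergence check requires at least 2 replicates")
  sig_sets <- lapply(ensemble$replicates,
                     function(r) unique(column_signatures(r$msa)))
  counts <- table(unlist(sig_sets))
  n1 <- sum(counts == 1)
  n2 <- sum(counts >= 2)
  med_cols <- stats::median(vapply(ensemble$replicates,
                                   function(r) msa_ncol(r$msa), 0L))
  list(converged = (n2 > n1) || (n_rep >= med_cols), n1 = n1, n2 = n2)
}
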