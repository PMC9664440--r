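#' Total log-probability of a sequence pair under the pair-HMM
#'
#' Runs the forward recursion of the double-affine pair HMM in log space and
#' returns the log of the total probability of emitting the pair (x, y),
#' summed over all state paths from the start state to the end state through
#' the match and gap states.  For two empty sequences this is the log of the
#' direct start-to-end probability.
#'
#' @param params A `pairhmm_params` object.
#' @param x,y Sequences: single strings or character vectors of letters over
#'   `params$alphabet`.  May be empty.
#' @return A single numeric log-probability.
#' @export
forward_total <- function(params, x, y) {
  validate_params(params)
  ex <- expand_params(params)
  xi <- encode_seq(x, params)
  yi <- encode_seq(y, params)
  pairhmm_forward_total(xi, yi, ex$T, ex$E, ex$lem, ex$lins)
}

#' Posterior match probabilities for a sequence pair
#'
#' Computes, for every residue pair (i, j), the posterior probability that
#' x_i is aligned to y_j given the pair-HMM, by the forward-backward
#' algorithm: P(i, j) = forward(i, j, M) * backward(i, j, M) / total.
#' Entries below the sparsity cutoff are set to zero.
#'
#' @inheritParams forward_total
#' @param cutoff Sparsity cutoff in \[0, 1); posteriors below it are dropped
#'   (zeroed).  Default 0.01.
#' @return A `posterior_matrix`: a dense numeric matrix of dimension
#'   `length(x) x length(y)` whose zero entries denote absent (sub-cutoff)
#'   values.
#' @export
posterior_match_probs <- function(params, x, y, cutoff = 0.01) {
  validate_params(params)
  if (cutoff < 0 || cutoff >= 1) stop("cutoff must lie in [0, 1)")
  ex <- expand_params(params)
  xi <- encode_seq(x, params)
  yi <- encode_seq(y, params)
  P <- pairhmm_posterior(xi, yi, ex$T, ex$E, ex$lem, ex$lins)
  P[P < cutoff] <- 0
  structure(P, class = c("posterior_matrix", "matrix"), cutoff = cutoff)
}

#' All-pairs posterior matrices
#'
#' Computes the posterior match-probability matrix for every unordered pair
#' of input sequences.
#'
#' @param params A `pairhmm_params` object.
#' @param seqs Named character vector of sequences.
#' @param cutoff Sparsity cutoff, see [posterior_match_probs()].
#' @return A list of class `posterior_set` with elements `matrices` (a list
#'   indexed by `"i|j"` for i < j over sequence positions), `lengths`, `ids`
#'   and `cutoff`.
#' @export
all_pair_posteriors <- function(params, seqs, cutoff = 0.01) {
  K <- length(seqs)
  if (K < 2) stop("need at least 2 sequences")
  mats <- list()
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    mats[[pair_key(i, j)]] <- posterior_match_probs(params, seqs[[i]], seqs[[j]], cutoff)
  }
  structure(list(matrices = mats, lengths = nchar(seqs),
                 ids = names(seqs), cutoff = cutoff),
            class = "posterior_set")
}

pair_key <- function(i, j) paste0(min(i, j), "|", max(i, j))

# Fetch P_{xy} as an oriented dense matrix (rows = sequence i, cols = j).
get_pair <- function(ps, i, j) {
  if (i == j) return(diag(1, ps$lengths[i]))
  m <- ps$matrices[[pair_key(i, j)]]
  if (is.null(m)) stop("missing posterior matrix for pair ", pair_key(i, j))
  if (i < j) unclass(m) else t(unclass(m))
}

#' Iterative consistency transformation
#'
#' Re-estimates pairwise posterior probabilities through third sequences:
#' each round replaces P_xy by (1/K) * sum_z P_xz %*% P_zy, where the sum
#' runs over all K sequences including z = x and z = y via identity
#' self-posteriors.  After each round entries below the sparsity cutoff are
#' dropped.  `rounds = 0` returns the input unchanged.
#'
#' @param posteriors A `posterior_set` from [all_pair_posteriors()].
#' @param rounds Number of rounds; default 2.
#' @return A transformed `posterior_set`.
#' @export
consistency_transform <- function(posteriors, rounds = 2) {
  stopifnot(inherits(posteriors, "posterior_set"))
  if (rounds < 0) stop("rounds must be >= 0")
  K <- length(posteriors$lengths)
  ps <- posteriors
  for (r in seq_len(rounds)) {
    new_mats <- list()
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      acc <- matrix(0, ps$lengths[i], ps$lengths[j])
      for (z in seq_len(K)) {
        acc <- acc + get_pair(ps, i, z) %*% get_pair(ps, z, j)
      }
      acc <- acc / K
      acc[acc < ps$cutoff] <- 0
      new_mats[[pair_key(i, j)]] <- structure(
        acc, class = c("posterior_matrix", "matrix"), cutoff = ps$cutoff)
    }
    ps$matrices <- new_mats
  }
  ps
}

#' Dump a posterior matrix as text triplets
#'
#' Writes the non-zero entries of a posterior matrix as whitespace-separated
#' `i j p` triplets (1-based indices), for inspection and debugging.
#'
#' @param post A `posterior_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_posterior_triplets <- function(post, path) {
  idx <- which(unclass(post) > 0, arr.ind = TRUE)
  lines <- sprintf("%d %d %.10g", idx[, 1], idx[, 2], post[idx])
  writeLines(lines, path)
  invisible(path)
}
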