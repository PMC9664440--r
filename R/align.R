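# Profiles used during progressive alignment: a profile is a list with
#   row_ids    character vector,
#   seq_idx    positions of the rows in the posterior set's sequence list,
#   cell_index rows x columns matrix of residue ordinals (0 = gap).
# Rows are materialised into gapped strings only when an msa is built.

profile_leaf <- function(id, seq_pos, len) {
  list(row_ids = id, seq_idx = seq_pos,
       cell_index = matrix(seq_len(len), nrow = 1))
}

profile_ncol <- function(prof) ncol(prof$cell_index)

# Sum over inter-profile row pairs of the posterior that the residues in a
# column pair align; gaps contribute 0.
profile_score_matrix <- function(profA, profB, posteriors) {
  LA <- profile_ncol(profA)
  LB <- profile_ncol(profB)
  S <- matrix(0, LA, LB)
  if (LA == 0 || LB == 0) return(S)
  for (u in seq_along(profA$row_ids)) for (v in seq_along(profB$row_ids)) {
    P <- get_pair(posteriors, profA$seq_idx[u], profB$seq_idx[v])
    va <- profA$cell_index[u, ]
    vb <- profB$cell_index[v, ]
    ma <- va > 0
    mb <- vb > 0
    if (any(ma) && any(mb))
      S[ma, mb] <- S[ma, mb] + P[va[ma], vb[mb], drop = FALSE]
  }
  S
}

# Merge two profiles along an alignment path (ix/iy column indices, 0 = gap).
profile_merge <- function(profA, profB, ix, iy) {
  nc <- length(ix)
  nA <- nrow(profA$cell_index)
  nB <- nrow(profB$cell_index)
  ci <- matrix(0L, nA + nB, nc)
  if (nc > 0) {
    ka <- ix > 0
    kb <- iy > 0
    ci[seq_len(nA), ka] <- profA$cell_index[, ix[ka], drop = FALSE]
    ci[nA + seq_len(nB), kb] <- profB$cell_index[, iy[kb], drop = FALSE]
  }
  # drop any all-gap columns produced by the merge
  keep <- colSums(ci > 0) > 0
  list(row_ids = c(profA$row_ids, profB$row_ids),
       seq_idx = c(profA$seq_idx, profB$seq_idx),
       cell_index = ci[, keep, drop = FALSE])
}

profile_align <- function(profA, profB, posteriors) {
  S <- profile_score_matrix(profA, profB, posteriors)
  if (nrow(S) == 0 || ncol(S) == 0) {
    ix <- c(seq_len(nrow(S)), integer(ncol(S)))
    iy <- c(integer(nrow(S)), seq_len(ncol(S)))
    return(profile_merge(profA, profB, ix, iy))
  }
  r <- mea_dp(S)
  profile_merge(profA, profB, r$ix, r$iy)
}

profile_to_msa <- function(prof, seqs) {
  letters_of <- strsplit(unname(seqs[prof$row_ids]), "")
  rows <- vapply(seq_along(prof$row_ids), function(u) {
    v <- prof$cell_index[u, ]
    ch <- rep("-", length(v))
    ch[v > 0] <- letters_of[[u]][v[v > 0]]
    paste(ch, collapse = "")
  }, character(1))
  new_msa(setNames(rows, prof$row_ids))
}

#' Maximum expected accuracy pairwise alignment
#'
#' Finds the global pairwise alignment maximising the sum of posterior match
#' probabilities over aligned residue pairs (gaps score 0), by dynamic
#' programming over the posterior matrix.  Traceback ties prefer a match,
#' then a gap in x, then a gap in y.
#'
#' @param post A `posterior_matrix` (or plain numeric matrix of pair scores).
#' @return A list with `ix`, `iy` (per-column 1-based residue indices, 0 for
#'   a gap), `score` (the achieved posterior sum) and `expected_accuracy`
#'   (`score / min(nrow, ncol)`; 0 when either sequence is empty, in which
#'   case the all-gap alignment is returned).
#' @export
mea_pairwise <- function(post) {
  P <- unclass(post)
  n <- nrow(P)
  m <- ncol(P)
  if (n == 0 || m == 0) {
    return(list(ix = c(seq_len(n), integer(m)), iy = c(integer(n), seq_len(m)),
                score = 0, expected_accuracy = 0))
  }
  r <- mea_dp(P)
  list(ix = r$ix, iy = r$iy, score = r$score,
       expected_accuracy = r$score / min(n, m))
}

#' All-pairs expected accuracy scores
#'
#' Runs [mea_pairwise()] on every pair of a posterior set and returns the
#' matrix of normalised expected accuracies, as used to build the guide tree.
#'
#' @param posteriors A `posterior_set`.
#' @return Symmetric numeric matrix with the sequence ids as dimnames.
#' @export
pairwise_ea_matrix <- function(posteriors) {
  K <- length(posteriors$ids)
  M <- matrix(0, K, K, dimnames = list(posteriors$ids, posteriors$ids))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    ea <- mea_pairwise(get_pair(posteriors, i, j))$expected_accuracy
    M[i, j] <- M[j, i] <- ea
  }
  M
}

#' Progressive profile alignment along a guide tree
#'
#' Aligns profiles bottom-up in the joining order of the guide tree; each
#' profile-profile alignment maximises the summed posterior probabilities
#' between inter-profile residue pairs, and gaps inserted into a profile are
#' propagated to all of its rows.
#'
#' @param seqs Named character vector of unaligned sequences.
#' @param posteriors A `posterior_set` over `seqs` (typically
#'   consistency-transformed).
#' @param tree A `guide_tree` whose leaves are `names(seqs)`.
#' @return An `msa`; degapping any row reproduces the input sequence.
#' @export
progressive_align <- function(seqs, posteriors, tree) {
  if (!setequal(gt_leaves(tree), names(seqs)))
    stop("guide tree leaves do not match the sequence ids")
  rec <- function(node) {
    if (gt_is_leaf(node)) {
      pos <- match(node$leaf, posteriors$ids)
      return(profile_leaf(node$leaf, pos, nchar(seqs[[node$leaf]])))
    }
    profile_align(rec(node$left), rec(node$right), posteriors)
  }
  profile_to_msa(rec(tree), seqs)
}

msa_to_profile <- function(msa, posteriors, rows = seq_along(msa$row_ids)) {
  ci <- msa$cell_index[rows, , drop = FALSE]
  keep <- colSums(ci > 0) > 0
  list(row_ids = msa$row_ids[rows],
       seq_idx = match(msa$row_ids[rows], posteriors$ids),
       cell_index = ci[, keep, drop = FALSE])
}

#' Refinement by randomised partitioning
#'
#' Each round draws a random bipartition of the alignment rows, extracts the
#' two induced profiles (dropping all-gap columns), re-aligns them by maximum
#' expected accuracy profile alignment and keeps the result iff the
#' sum-of-pairs expected-accuracy objective does not decrease.  Deterministic
#' for a given seed; the objective never decreases across rounds.
#'
#' @param msa An `msa`.
#' @param posteriors A `posterior_set` over the msa's sequences.
#' @param rounds Number of rounds, default 100.
#' @param seed Seed for the partition generator.
#' @return The refined `msa`.
#' @export
refine <- function(msa, posteriors, rounds = 100, seed = 1) {
  if (rounds < 0) stop("rounds must be >= 0")
  if (rounds == 0) return(msa)
  K <- length(msa$row_ids)
  if (K < 2) return(msa)
  seqs <- degap(msa)
  cur <- msa
  cur_obj <- msa_objective(cur, posteriors)
  with_local_seed(seed, {
    for (r in seq_len(rounds)) {
      repeat {
        side <- runif(K) < 0.5
        if (any(side) && !all(side)) break
      }
      profA <- msa_to_profile(cur, posteriors, which(side))
      profB <- msa_to_profile(cur, posteriors, which(!side))
      merged <- profile_align(profA, profB, posteriors)
      cand <- profile_to_msa(merged, seqs)
      # restore the original row order
      cand <- new_msa(setNames(cand$rows, cand$row_ids)[msa$row_ids])
      cand_obj <- msa_objective(cand, posteriors)
      if (cand_obj >= cur_obj) {
        cur <- cand
        cur_obj <- cand_obj
      }
    }
  })
  cur
}
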