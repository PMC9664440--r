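# Independent brute-force oracles used across the test files.  These
# enumerate alignments and state paths explicitly and share no code with the
# dynamic-programming implementations they check.

# A tiny two-letter parameter set for exhaustive path enumeration.
toy_params2 <- function() {
  ab <- c("A", "C")
  em <- matrix(c(0.35, 0.15, 0.15, 0.35), 2, 2, dimnames = list(ab, ab))
  structure(list(
    alphabet_kind = "nt",
    alphabet = ab,
    start_transitions = c(M = 0.85, I = 0.04, J = 0.02, E = 0.03),
    match_transitions = c(M = 0.93, I = 0.02, J = 0.01, E = 0.01),
    short_gap_transitions = c(M = 0.19, I = 0.80, E = 0.01),
    long_gap_transitions = c(M = 0.09, J = 0.90, E = 0.01),
    match_emissions = em,
    insert_emissions = rowSums(em)
  ), class = "pairhmm_params")
}

# All sequences of length 0..max_len over an alphabet.
all_seqs_upto <- function(alphabet, max_len) {
  out <- list("")
  for (L in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), L))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  unlist(out)
}

# Exhaustive path enumeration: every monotone column sequence combined with
# every admissible gap-state assignment, probabilities multiplied explicitly.
# Returns log total probability and the per-pair match posterior matrix.
enum_pair_bruteforce <- function(params, x, y) {
  ex <- msaensemble:::expand_params(params)
  TT <- exp(ex$T)
  EE <- exp(ex$E)
  em <- params$match_emissions
  ins <- params$insert_emissions
  xs <- if (nchar(x)) strsplit(x, "")[[1]] else character(0)
  ys <- if (nchar(y)) strsplit(y, "")[[1]] else character(0)
  n <- length(xs)
  m <- length(ys)
  total <- 0
  post_num <- matrix(0, n, m)
  rec <- function(i, j, state, prob, pairs) {
    if (prob == 0) return()
    if (i == n && j == m) {
      p_end <- unname(prob * EE[state])
      total <<- total + p_end
      if (nrow(pairs) > 0)
        for (r in seq_len(nrow(pairs)))
          post_num[pairs[r, 1], pairs[r, 2]] <<- post_num[pairs[r, 1], pairs[r, 2]] + p_end
    }
    if (i < n && j < m)
      rec(i + 1, j + 1, "M",
          unname(prob * TT[state, "M"] * em[xs[i + 1], ys[j + 1]]),
          rbind(pairs, c(i + 1, j + 1)))
    if (i < n)
      for (s in c("Ix", "Jx"))
        rec(i + 1, j, s, unname(prob * TT[state, s] * ins[xs[i + 1]]), pairs)
    if (j < m)
      for (s in c("Iy", "Jy"))
        rec(i, j + 1, s, unname(prob * TT[state, s] * ins[ys[j + 1]]), pairs)
  }
  rec(0, 0, "S", 1, matrix(0, 0, 2))
  list(log_total = log(total),
       posterior = if (n > 0 && m > 0) post_num / total else post_num)
}

# Exhaustive maximum over all monotone alignments of a score matrix
# (plain recursion, no memoisation: enumerates every alignment).
enum_best_alignment <- function(S) {
  n <- nrow(S)
  m <- ncol(S)
  rec <- function(i, j) {
    best <- 0
    if (i < n && j < m) best <- max(best, S[i + 1, j + 1] + rec(i + 1, j + 1))
    if (i < n) best <- max(best, rec(i + 1, j))
    if (j < m) best <- max(best, rec(i, j + 1))
    best
  }
  rec(0, 0)
}

# Best sum-of-pairs objective over all MSAs of the given sequences with at
# most max_cols columns, by enumerating all monotone column embeddings.
enum_best_msa_objective <- function(seqs, posteriors, max_cols) {
  lens <- nchar(seqs)
  best <- -Inf
  for (C in max(lens):max_cols) {
    embs <- lapply(lens, function(L) utils::combn(C, L, simplify = FALSE))
    grid <- expand.grid(lapply(embs, seq_along))
    for (g in seq_len(nrow(grid))) {
      sel <- lapply(seq_along(seqs), function(k) embs[[k]][[grid[g, k]]])
      if (length(unique(unlist(sel))) != C) next  # all-gap column
      rows <- mapply(function(emb, s) {
        ch <- rep("-", C)
        ch[emb] <- strsplit(s, "")[[1]]
        paste(ch, collapse = "")
      }, sel, seqs)
      o <- msa_objective(new_msa(setNames(rows, names(seqs))), posteriors)
      if (o > best) best <- o
    }
  }
  best
}

# Deterministic random amino-acid sequences for fixtures.
rand_aa_seqs <- function(n, len, seed) {
  ab <- msaensemble:::AA_ALPHABET
  msaensemble:::with_local_seed(seed, {
    setNames(vapply(seq_len(n), function(i)
      paste(ab[sample.int(20, len, replace = TRUE)], collapse = ""),
      character(1)), paste0("s", seq_len(n)))
  })
}

# Manually-built replicate ensembles for the confidence metric oracles.
make_toy_replicate <- function(rows, perm = "none", seed = 0) {
  new_replicate(new_msa(rows), perm = perm, seed = seed)
}
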