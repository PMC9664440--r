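#' @useDynLib msaensemble, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif setNames as.dist
NULL

.pkg_env <- new.env(parent = emptyenv())

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
NT_ALPHABET <- c("A", "C", "G", "T")

# Transition defaults.  The underlying model is a double-affine pair HMM with
# states S (start), M (match), I_x/I_y (short gaps), J_x/J_y (long gaps) and
# an end state.  x/y symmetry is enforced, so each per-side probability is
# stored once.  The values below are round numbers; nearby values are equally
# admissible -- alignment quality is insensitive to small changes, and no
# training is performed.
#   set sums: start/match: M + 2I + 2J + E = 1; short: M + I + E = 1;
#             long: M + J + E = 1; emissions: sum over ordered pairs = 1.
DEFAULT_START <- c(M = 0.85, I = 0.04, J = 0.02, E = 0.03)
DEFAULT_MATCH <- c(M = 0.93, I = 0.02, J = 0.01, E = 0.01)  # short-gap open 0.02, long-gap open 0.01
DEFAULT_SHORT <- c(M = 0.19, I = 0.80, E = 0.01)            # short-gap extend 0.80
DEFAULT_LONG  <- c(M = 0.09, J = 0.90, E = 0.01)            # long-gap extend 0.90

# Joint-probability form of BLOSUM62, reconstructed from the half-bit
# log-odds matrix shipped with Biostrings.  The log-odds relation is
#   s_ij = 2 log2( q_ij / (p_i p_j) ),  so  q_ij = c p_i p_j 2^(s_ij / 2).
# Requiring the background frequencies to be the marginals of the joint
# (p_i = sum_j q_ij) gives, with M_ij = 2^(s_ij / 2), the linear condition
# M p proportional to 1; p is obtained by solving M p = 1 and normalising.
# The recovered p match the published BLOSUM62 backgrounds to the precision
# permitted by the rounded integer scores.
blosum62_joint <- function() {
  if (!is.null(.pkg_env$blosum62_joint)) return(.pkg_env$blosum62_joint)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  s <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  M <- 2^(s / 2)
  p <- solve(M, rep(1, nrow(M)))
  if (any(p <= 0)) stop("BLOSUM62 background solve produced non-positive frequencies")
  p <- p / sum(p)
  q <- outer(p, p) * M
  q <- q / sum(q)
  q <- (q + t(q)) / 2
  dimnames(q) <- list(AA_ALPHABET, AA_ALPHABET)
  .pkg_env$blosum62_joint <- q
  q
}

# Simple nucleotide joint emission matrix: 60% of the mass on identities,
# spread uniformly, uniform marginals.  Experimental -- no published values
# exist for this parameterisation.
nucleotide_joint <- function() {
  q <- matrix(0.4 / 12, 4, 4, dimnames = list(NT_ALPHABET, NT_ALPHABET))
  diag(q) <- 0.6 / 4
  q
}

#' Default pair-HMM parameters
#'
#' Returns the default parameter set of the double-affine pair hidden Markov
#' model: five independent sets of mutually exclusive probabilities
#' (transitions from the start state, from the match state M, from the
#' short-gap states I, from the long-gap states J, and the letter-pair
#' emissions of M), plus the insert-state letter marginals derived from the
#' joint emission matrix.  Amino-acid emissions are the joint-probability form
#' of BLOSUM62; insert states emit according to its marginals.
#'
#' @param alphabet_kind `"aa"` (amino acid) or `"nt"` (nucleotide,
#'   experimental).
#' @return An object of class `pairhmm_params`.
#' @export
default_params <- function(alphabet_kind = c("aa", "nt")) {
  alphabet_kind <- match.arg(alphabet_kind)
  em <- if (alphabet_kind == "aa") blosum62_joint() else nucleotide_joint()
  p <- structure(list(
    alphabet_kind = alphabet_kind,
    alphabet = rownames(em),
    start_transitions = DEFAULT_START,
    match_transitions = DEFAULT_MATCH,
    short_gap_transitions = DEFAULT_SHORT,
    long_gap_transitions = DEFAULT_LONG,
    match_emissions = em,
    insert_emissions = rowSums(em)
  ), class = "pairhmm_params")
  validate_params(p)
  p
}

set_sum <- function(v, doubled = character()) {
  w <- v
  w[doubled] <- 2 * w[doubled]
  sum(w)
}

#' Validate a pair-HMM parameter set
#'
#' Checks the invariants: each of the five mutually exclusive probability sets
#' sums to 1 within 1e-9, all probabilities lie strictly in (0, 1), the match
#' emission matrix is symmetric and the insert emissions equal its marginals.
#'
#' @param params A `pairhmm_params` object.
#' @return `params`, invisibly; errors otherwise.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "pairhmm_params"))
  tol <- 1e-9
  sums <- c(
    start = set_sum(params$start_transitions, c("I", "J")),
    match = set_sum(params$match_transitions, c("I", "J")),
    short = sum(params$short_gap_transitions),
    long = sum(params$long_gap_transitions),
    emissions = sum(params$match_emissions)
  )
  bad <- names(sums)[abs(sums - 1) > tol]
  if (length(bad))
    stop("probability set(s) not normalised: ", paste(bad, collapse = ", "))
  all_p <- c(params$start_transitions, params$match_transitions,
             params$short_gap_transitions, params$long_gap_transitions,
             params$match_emissions, params$insert_emissions)
  if (any(all_p <= 0 | all_p >= 1))
    stop("all probabilities must lie strictly in (0, 1)")
  if (max(abs(params$match_emissions - t(params$match_emissions))) > tol)
    stop("match_emissions must be symmetric")
  if (max(abs(params$insert_emissions - rowSums(params$match_emissions))) > 1e-8)
    stop("insert_emissions must equal the marginals of match_emissions")
  invisible(params)
}

#' Perturbation specification
#'
#' @param amplitude Perturbation amplitude `alpha`, with `0 <= alpha < 1`:
#'   each probability P is multiplied by `(1 + alpha * delta)` with delta
#'   uniform on `-1..1`.  Default 0.25 (perturbations up to +/- 25 percent).
#' @param seed Non-negative integer seed; `seed = 0` means no perturbation
#'   (the default parameters are used bit-exactly).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(amplitude = 0.25, seed = 0) {
  if (!is.numeric(amplitude) || length(amplitude) != 1 || amplitude < 0 ||
      amplitude >= 1)
    stop("amplitude must lie in [0, 1): probabilities could go non-positive")
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0) stop("seed must be a non-negative integer")
  structure(list(amplitude = amplitude, seed = seed),
            class = "perturbation_spec")
}

# Run code with a deterministic, self-contained RNG stream (Mersenne-Twister,
# inversion, rejection sampling), restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

#' Perturb pair-HMM parameters
#'
#' Applies the replicate-generating perturbation rule: every probability P in
#' the five independent sets is multiplied by (1 + alpha * delta), delta drawn
#' independently and uniformly from \[-1, +1\] by a deterministic generator
#' seeded with `spec$seed`; afterwards each mutually exclusive set is
#' renormalised to sum 1.  The match emission matrix is perturbed on its upper
#' triangle and mirrored, so symmetry is preserved; insert emissions are
#' recomputed as marginals of the perturbed joint matrix.  `seed = 0` returns
#' the input unchanged, bit-exactly.
#'
#' The canonical draw order is: start transitions (M, I, J, E), match
#' transitions (M, I, J, E), short-gap transitions (M, I, E), long-gap
#' transitions (M, J, E), then the emission upper triangle (including the
#' diagonal) in column-major order.
#'
#' @param params A `pairhmm_params` object.
#' @param spec A `perturbation_spec`.
#' @return A perturbed, renormalised `pairhmm_params` object.
#' @export
perturb_params <- function(params, spec = perturbation_spec()) {
  validate_params(params)
  if (!inherits(spec, "perturbation_spec")) stop("spec must be a perturbation_spec")
  if (spec$seed == 0L) return(params)
  a <- spec$amplitude
  ut <- upper.tri(params$match_emissions, diag = TRUE)
  n_em <- sum(ut)
  deltas <- perturbation_relative_changes(params, spec) / a
  k <- 0L
  take <- function(n) {
    d <- deltas[(k + 1L):(k + n)]
    k <<- k + n
    d
  }
  scale_set <- function(v, doubled = character()) {
    w <- v * (1 + a * take(length(v)))
    w / set_sum(w, doubled)
  }
  out <- params
  out$start_transitions <- scale_set(params$start_transitions, c("I", "J"))
  out$match_transitions <- scale_set(params$match_transitions, c("I", "J"))
  out$short_gap_transitions <- scale_set(params$short_gap_transitions)
  out$long_gap_transitions <- scale_set(params$long_gap_transitions)
  em <- params$match_emissions
  # perturb the symmetric representation once (upper triangle) and mirror
  em_new <- em
  em_new[ut] <- em[ut] * (1 + a * take(n_em))
  em_new[lower.tri(em_new)] <- t(em_new)[lower.tri(em_new)]
  em_new <- em_new / sum(em_new)
  out$match_emissions <- em_new
  out$insert_emissions <- rowSums(em_new)
  validate_params(out)
  out
}

#' Pre-normalisation relative changes of a perturbation
#'
#' Returns the signed relative change `alpha * delta` that [perturb_params()]
#' applies to each stored probability before the renormalisation step, in the
#' canonical draw order (start, match, short-gap, long-gap transitions, then
#' the emission upper triangle).  Useful for diagnosing the perturbation
#' contract: every value is bounded by the amplitude in absolute value, and
#' `seed = 0` gives all zeros.
#'
#' @inheritParams perturb_params
#' @return Numeric vector of relative changes, one per stored probability.
#' @export
perturbation_relative_changes <- function(params, spec = perturbation_spec()) {
  stopifnot(inherits(spec, "perturbation_spec"))
  n <- 4L + 4L + 3L + 3L + sum(upper.tri(params$match_emissions, diag = TRUE))
  if (spec$seed == 0L) return(numeric(n))
  spec$amplitude * with_local_seed(spec$seed, runif(n, -1, 1))
}

# Expand the symmetric stored parameterisation into the 6-state log-space
# matrices consumed by the C++ kernels: T[s, d] = log P(s -> d) over states
# (S, M, Ix, Iy, Jx, Jy); E[s] = log P(s -> end).
expand_params <- function(params) {
  TT <- matrix(-Inf, 6, 6,
               dimnames = list(c("S", "M", "Ix", "Iy", "Jx", "Jy"),
                               c("S", "M", "Ix", "Iy", "Jx", "Jy")))
  st <- params$start_transitions
  mt <- params$match_transitions
  it <- params$short_gap_transitions
  jt <- params$long_gap_transitions
  TT["S", c("M", "Ix", "Iy", "Jx", "Jy")] <- log(c(st["M"], st["I"], st["I"], st["J"], st["J"]))
  TT["M", c("M", "Ix", "Iy", "Jx", "Jy")] <- log(c(mt["M"], mt["I"], mt["I"], mt["J"], mt["J"]))
  TT["Ix", c("M", "Ix")] <- log(c(it["M"], it["I"]))
  TT["Iy", c("M", "Iy")] <- log(c(it["M"], it["I"]))
  TT["Jx", c("M", "Jx")] <- log(c(jt["M"], jt["J"]))
  TT["Jy", c("M", "Jy")] <- log(c(jt["M"], jt["J"]))
  EE <- log(c(S = unname(st["E"]), M = unname(mt["E"]),
              Ix = unname(it["E"]), Iy = unname(it["E"]),
              Jx = unname(jt["E"]), Jy = unname(jt["E"])))
  list(T = TT, E = EE, lem = log(params$match_emissions),
       lins = log(params$insert_emissions))
}

encode_seq <- function(s, params) {
  if (length(s) == 1 && is.character(s)) s <- strsplit(s, "")[[1]]
  if (length(s) == 0) return(integer(0))
  idx <- match(s, params$alphabet)
  if (anyNA(idx))
    stop("letter outside alphabet at position ", which(is.na(idx))[1],
         ": '", s[which(is.na(idx))[1]], "'")
  idx - 1L
}

#' Write / read pair-HMM parameters as plain text
#'
#' Serialises a parameter set to a `key=value` text file (full double
#' precision) and reads it back; `read_params(write_params(p))` reproduces the
#' parameters exactly.
#'
#' @param params A `pairhmm_params` object.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   `pairhmm_params`.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c(
    paste0("alphabet_kind=", params$alphabet_kind),
    paste0("alphabet=", paste(params$alphabet, collapse = "")),
    paste0("start.", names(params$start_transitions), "=", fmt(params$start_transitions)),
    paste0("match.", names(params$match_transitions), "=", fmt(params$match_transitions)),
    paste0("short.", names(params$short_gap_transitions), "=", fmt(params$short_gap_transitions)),
    paste0("long.", names(params$long_gap_transitions), "=", fmt(params$long_gap_transitions))
  )
  ab <- params$alphabet
  for (i in seq_along(ab)) for (j in i:length(ab))
    lines <- c(lines, paste0("emit.", ab[i], ".", ab[j], "=",
                             fmt(params$match_emissions[i, j])))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  getv <- function(prefix, fields) {
    setNames(as.numeric(vals[match(paste0(prefix, ".", fields), keys)]), fields)
  }
  ab <- strsplit(vals[keys == "alphabet"], "")[[1]]
  em <- matrix(0, length(ab), length(ab), dimnames = list(ab, ab))
  for (i in seq_along(ab)) for (j in i:length(ab)) {
    v <- as.numeric(vals[keys == paste0("emit.", ab[i], ".", ab[j])])
    em[i, j] <- v
    em[j, i] <- v
  }
  p <- structure(list(
    alphabet_kind = vals[keys == "alphabet_kind"],
    alphabet = ab,
    start_transitions = getv("start", c("M", "I", "J", "E")),
    match_transitions = getv("match", c("M", "I", "J", "E")),
    short_gap_transitions = getv("short", c("M", "I", "E")),
    long_gap_transitions = getv("long", c("M", "J", "E")),
    match_emissions = em,
    insert_emissions = rowSums(em)
  ), class = "pairhmm_params")
  validate_params(p)
  p
}
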