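ensemble_signature_sets <- function(ensemble, ignore_gaps = FALSE) {
  lapply(ensemble$replicates,
         function(r) unique(column_signatures(r$msa, ignore_gaps)))
}

check_same_seqs <- function(ref, ensemble) {
  d_ref <- degap(ref$msa)
  d_ens <- degap(ensemble$replicates[[1]]$msa)
  if (!identical(d_ref[sort(names(d_ref))], d_ens[sort(names(d_ens))]))
    stop("reference replicate and ensemble do not share the same sequence set")
}

#' Column confidence (CC)
#'
#' The column confidence of a reference replicate's column is its
#' H-ensemble confidence: the fraction of ensemble replicates containing a
#' column with an equal signature (the reference replicate itself counts,
#' and a signature is counted at most once per replicate).  A column is
#' "reproduced" under exact signature equality including the gap pattern;
#' set `ignore_gaps = TRUE` to compare only the non-gap cells.
#'
#' @param ref A `replicate_msa`, normally a member of `ensemble`.
#' @param ensemble An `msa_ensemble` over the same sequences.
#' @param ignore_gaps Relaxed column identity (non-gap cells only).
#' @return Numeric vector in \[0, 1\], one CC per column of `ref`.
#' @export
column_confidence <- function(ref, ensemble, ignore_gaps = FALSE) {
  stopifnot(inherits(ref, "replicate_msa"), inherits(ensemble, "msa_ensemble"))
  check_same_seqs(ref, ensemble)
  sigs <- column_signatures(ref$msa, ignore_gaps)
  sig_sets <- ensemble_signature_sets(ensemble, ignore_gaps)
  hits <- vapply(sig_sets, function(s) sigs %in% s, logical(length(sigs)))
  if (length(sigs) == 1) hits <- matrix(hits, nrow = 1)
  rowMeans(hits)
}

#' Alignment confidence (AC)
#'
#' The mean column confidence over the columns of one replicate.
#'
#' @inheritParams column_confidence
#' @return A single numeric value in \[0, 1\].
#' @export
alignment_confidence <- function(ref, ensemble, ignore_gaps = FALSE) {
  if (msa_ncol(ref$msa) == 0) stop("AC is undefined for a zero-column msa")
  mean(column_confidence(ref, ensemble, ignore_gaps))
}

#' Mean alignment confidence (MAC)
#'
#' The mean AC over all replicates of the ensemble.  MAC = 1 exactly when
#' all replicates are column-identical; smaller values indicate that the
#' alignment is sensitive to parameter perturbations, and since two
#' different alignments of the same sequences cannot both be correct, lower
#' MAC necessarily indicates a higher error rate in a typical replicate.
#'
#' @inheritParams column_confidence
#' @return A single numeric value in \[0, 1\].
#' @export
mac <- function(ensemble, ignore_gaps = FALSE) {
  stopifnot(inherits(ensemble, "msa_ensemble"))
  acs <- vapply(ensemble$replicates, alignment_confidence, 0,
                ensemble = ensemble, ignore_gaps = ignore_gaps)
  mean(acs)
}

#' Replicate with maximal alignment confidence
#'
#' Returns the ensemble replicate with the highest AC; ties are broken by
#' replicate order (the first maximal replicate wins).
#'
#' @inheritParams column_confidence
#' @return A `replicate_msa` with attribute `"ac"` carrying its AC.
#' @export
max_ac_replicate <- function(ensemble, ignore_gaps = FALSE) {
  stopifnot(inherits(ensemble, "msa_ensemble"))
  acs <- vapply(ensemble$replicates, alignment_confidence, 0,
                ensemble = ensemble, ignore_gaps = ignore_gaps)
  best <- which.max(acs)
  r <- ensemble$replicates[[best]]
  attr(r, "ac") <- acs[best]
  r
}
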