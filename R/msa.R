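#' Construct a multiple sequence alignment object
#'
#' An `msa` stores equal-length gapped rows over an alphabet plus the gap
#' character `-`, together with a per-cell residue-ordinal index used for
#' column signatures: `cell_index[r, c]` is the 1-based count of non-gap
#' letters of row r up to and including column c, or 0 for a gap.
#'
#' @param rows Named character vector of gapped strings (equal length).
#' @return An object of class `msa` with fields `row_ids`, `rows`,
#'   `cell_index`.
#' @export
new_msa <- function(rows) {
  if (is.null(names(rows)) || anyNA(names(rows)) || any(names(rows) == ""))
    stop("rows must be named by sequence id")
  if (anyDuplicated(names(rows))) stop("duplicate row ids")
  w <- unique(nchar(rows))
  if (length(w) != 1) stop("all rows must have equal length")
  if (w == 0) {
    m <- matrix("", length(rows), 0)
    ci <- matrix(0L, length(rows), 0)
  } else {
    m <- do.call(rbind, strsplit(unname(rows), ""))
    if (any(colSums(m != "-") == 0)) stop("no column may be all-gaps")
    ci <- if (w == 1) matrix(as.integer(m != "-"), ncol = 1)
          else t(apply(m != "-", 1, cumsum))
    ci[m == "-"] <- 0L
  }
  structure(list(row_ids = names(rows), rows = unname(rows),
                 cell_index = ci), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa: ", length(x$row_ids), " rows x ", msa_ncol(x), " columns\n", sep = "")
  for (i in seq_along(x$row_ids))
    cat(sprintf("%-12s %s\n", x$row_ids[i], x$rows[i]))
  invisible(x)
}

#' Number of columns of an msa
#' @param msa An `msa`.
#' @return Integer column count.
#' @export
msa_ncol <- function(msa) if (length(msa$rows) == 0) 0L else nchar(msa$rows[1])

#' Remove gaps from the rows of an msa
#'
#' @param msa An `msa`.
#' @return Named character vector of ungapped sequences.
#' @export
degap <- function(msa) {
  setNames(gsub("-", "", msa$rows, fixed = TRUE), msa$row_ids)
}

# Character matrix view (rows x columns).
msa_matrix <- function(msa) {
  if (msa_ncol(msa) == 0) return(matrix("", length(msa$row_ids), 0))
  do.call(rbind, strsplit(msa$rows, ""))
}

#' Column signatures of an msa
#'
#' A column signature canonically encodes one alignment column: for each
#' sequence id (in sorted id order) either the residue ordinal it contributes
#' (1-based index into the ungapped sequence) or 0 for a gap.  Two columns in
#' different alignments of the same sequences are "the same column" iff their
#' signatures are equal.  With `ignore_gaps = TRUE` the gap entries are
#' dropped from the encoding, so columns are compared on their non-gap cells
#' only.
#'
#' @param msa An `msa`.
#' @param ignore_gaps Compare only non-gap cells (relaxed variant).
#' @return Character vector of signature keys, one per column.
#' @export
column_signatures <- function(msa, ignore_gaps = FALSE) {
  nc <- msa_ncol(msa)
  if (nc == 0) return(character(0))
  ord <- order(msa$row_ids)
  ci <- msa$cell_index[ord, , drop = FALSE]
  ids <- msa$row_ids[ord]
  vapply(seq_len(nc), function(cc) {
    v <- ci[, cc]
    if (ignore_gaps) {
      keep <- v > 0
      paste(ids[keep], v[keep], sep = ":", collapse = ",")
    } else {
      paste(v, collapse = ",")
    }
  }, character(1))
}

#' Sum-of-pairs expected accuracy of an msa
#'
#' The objective maximised by progressive alignment and refinement: the sum,
#' over all unordered row pairs and all columns where both rows have a
#' residue, of the posterior probability that those two residues align.
#'
#' @param msa An `msa` whose row ids match `posteriors$ids`.
#' @param posteriors A `posterior_set` (typically consistency-transformed).
#' @return A single numeric score.
#' @export
msa_objective <- function(msa, posteriors) {
  idx <- match(msa$row_ids, posteriors$ids)
  if (anyNA(idx)) stop("msa row ids not found in posterior set")
  total <- 0
  K <- length(msa$row_ids)
  for (u in seq_len(K - 1)) for (v in (u + 1):K) {
    P <- get_pair(posteriors, idx[u], idx[v])
    a <- msa$cell_index[u, ]
    b <- msa$cell_index[v, ]
    keep <- a > 0 & b > 0
    if (any(keep)) total <- total + sum(P[cbind(a[keep], b[keep])])
  }
  total
}
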