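#' Read and write FASTA files
#'
#' `read_fasta` parses (optionally wrapped) FASTA into a named character
#' vector, order-preserving, case preserved verbatim; for aligned FASTA the
#' `.` gap character is normalised to `-`.  `write_fasta` writes sequences
#' wrapped at 60 columns.  Duplicate ids and empty records are rejected.
#'
#' @param path File path.
#' @param seqs Named character vector of (possibly gapped) sequences.
#' @return `read_fasta`: named character vector; `write_fasta`: `path`,
#'   invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(x), "[ \t]"), `[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  seqs <- as.character(x)
  if (any(nchar(seqs) == 0))
    stop("empty record: ", ids[nchar(seqs) == 0][1])
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  setNames(seqs, ids)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) stop("sequences must be named")
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read an msa from aligned FASTA
#' @param path File path.
#' @return An `msa`.
#' @export
read_msa <- function(path) new_msa(read_fasta(path))

#' Write an msa as aligned FASTA
#' @param msa An `msa`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) write_fasta(setNames(msa$rows, msa$row_ids), path)

#' Read and write Newick tree files
#'
#' Thin wrappers around the ape Newick parser/writer supporting branch
#' lengths and numeric internal-node support labels; multi-tree files hold
#' one Newick string per line.  Unbalanced parentheses are rejected with the
#' offending position.
#'
#' @param path File path.
#' @param tree A `phylo` tree, or a list of trees / `multiPhylo` for
#'   multi-tree files.
#' @return `read_newick`: a `phylo` (single tree) or list of `phylo`;
#'   `write_newick`: `path`, invisibly.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path), collapse = "\n")
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0) stop("unbalanced parentheses at position ", i)
  }
  if (depth != 0) stop("unbalanced parentheses: ", depth, " unclosed '('")
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick input")
  if (inherits(tr, "multiPhylo")) unclass(tr) else tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "phylo")) tree <- list(tree)
  lines <- vapply(tree, function(t) ape::write.tree(t), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column category map
#'
#' Whitespace-delimited text: leaf label, category name.  Lines starting
#' with `#` are ignored.
#'
#' @param path File path.
#' @return Named character vector (names = leaf labels).
#' @export
read_category_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("category map must have two columns")
  setNames(tab[[2]], tab[[1]])
}

#' Write a category map
#' @param cat Named character vector.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_category_map <- function(cat, path) {
  writeLines(paste(names(cat), cat, sep = "\t"), path)
  invisible(path)
}

#' Read and write ensemble files
#'
#' The ensemble container is plain text: for each replicate a header line
#' `#replicate <label>` (label = `perm.s`) followed by its alignment as
#' aligned FASTA wrapped at 60 columns.  `read_ensemble(write_ensemble(E))`
#' reproduces the ensemble including labels and row order.
#'
#' @param ensemble An `msa_ensemble`.
#' @param path File path.
#' @param kind Ensemble kind tag to use when reading.
#' @return `write_ensemble`: `path`, invisibly; `read_ensemble`: an
#'   `msa_ensemble`.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "msa_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  for (r in ensemble$replicates) {
    writeLines(paste0("#replicate ", r$label), con)
    for (i in seq_along(r$msa$row_ids)) {
      writeLines(paste0(">", r$msa$row_ids[i]), con)
      row <- r$msa$rows[i]
      starts <- seq(1, nchar(row), by = 60)
      writeLines(substring(row, starts, pmin(starts + 59, nchar(row))), con)
    }
  }
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path, kind = "diversified") {
  lines <- readLines(path)
  rep_starts <- grep("^#replicate ", lines)
  if (length(rep_starts) == 0) stop("not an ensemble file: no replicate headers")
  bounds <- c(rep_starts, length(lines) + 1L)
  reps <- vector("list", length(rep_starts))
  for (k in seq_along(rep_starts)) {
    label <- sub("^#replicate ", "", lines[rep_starts[k]])
    parts <- strsplit(label, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("malformed replicate label: '", label, "'")
    block <- lines[(rep_starts[k] + 1L):(bounds[k + 1L] - 1L)]
    hdr <- grep("^>", block)
    if (length(hdr) == 0) stop("replicate '", label, "' has no sequences")
    ends <- c(hdr[-1] - 1L, length(block))
    rows <- vapply(seq_along(hdr), function(i) {
      paste(block[(hdr[i] + 1L):ends[i]], collapse = "")
    }, character(1))
    ids <- sub("^>", "", block[hdr])
    ids <- vapply(strsplit(ids, "[ \t]"), `[`, "", 1)
    rows <- gsub(".", "-", rows, fixed = TRUE)
    reps[[k]] <- new_replicate(new_msa(setNames(rows, ids)),
                               perm = parts[1], seed = as.integer(parts[2]))
  }
  new_ensemble(reps, kind = kind)
}
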