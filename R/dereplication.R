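#' Collapse identical heptapeptides into non-redundant representatives
#'
#' Exact-string grouping of a heptapeptide pool: clones displaying the
#' same 7-mer are merged into one representative carrying the
#' multiplicity and the parent clone ids. This is the de-redundancy step
#' usually run with CD-HIT; for 7-mers exact identity is the meaningful
#' resolution and is the only mode supported — requesting a clustering
#' identity below 1.0 is an explicit error rather than a silent
#' approximation.
#'
#' @param peptides Either a character vector of 7-letter peptides or a
#'   data frame with columns \code{peptide} and (optionally)
#'   \code{clone_id}.
#' @param identity Clustering identity fraction; only \code{1.0} is
#'   supported.
#' @return A data frame with columns \code{peptide},
#'   \code{multiplicity}, and \code{parent_clone_ids} (comma-joined),
#'   sorted by multiplicity descending then peptide lexicographically.
#'   The multiplicities sum to the input count.
#' @examples
#' dereplicate(c("AAAAAAA", "AAAAAAA", "AAAAAAC"))
#' @export
dereplicate <- function(peptides, identity = 1.0) {
  if (identity <= 0 || identity > 1) {
    stop("identity must be in (0, 1]")
  }
  if (identity < 1.0) {
    stop("not implemented: sub-identity clustering (CD-HIT style) is not ",
         "supported; only exact-identity (1.0) dereplication of 7-mers")
  }
  if (is.data.frame(peptides)) {
    seqs <- peptides$peptide
    ids <- if ("clone_id" %in% names(peptides)) peptides$clone_id else
      sprintf("clone_%d", seq_along(seqs))
  } else {
    seqs <- as.character(peptides)
    ids <- sprintf("clone_%d", seq_along(seqs))
  }
  if (!length(seqs)) {
    return(data.frame(peptide = character(0), multiplicity = integer(0),
                      parent_clone_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  if (any(nchar(seqs) != 7L)) {
    stop("all peptides must have length 7")
  }
  groups <- split(ids, seqs)
  out <- data.frame(
    peptide = names(groups),
    multiplicity = lengths(groups),
    parent_clone_ids = vapply(groups, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  out <- out[order(-out$multiplicity, out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}
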