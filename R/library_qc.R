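#' Validate a 21-nt insert against the NNK codon design rule
#'
#' C7C library inserts are built from seven NNK degenerate codons, so
#' the third nucleotide of every codon in the random region must be G or
#' T. A codon whose third base is A or C cannot come from the designed
#' library and points to wild-type phage contamination or a sequencing
#' error.
#'
#' @param insert_dna A 21-nt DNA string without \code{N}.
#' @return A list with \code{valid} (logical) and \code{failed_codons}
#'   (integer vector of 1-based codon indices whose third base is not
#'   G/T; empty when valid).
#' @examples
#' validate_nnk("TATCAGCTTGCTTTCGAGGTG")  # fifth codon fails (TTC)
#' @export
validate_nnk <- function(insert_dna) {
  stopifnot(is.character(insert_dna), length(insert_dna) == 1L)
  insert_dna <- toupper(insert_dna)
  if (nchar(insert_dna) != 21L) {
    stop("length error: insert must be exactly 21 nt, got ",
         nchar(insert_dna))
  }
  if (grepl("N", insert_dna, fixed = TRUE)) {
    stop("insert contains ambiguous base N")
  }
  third <- substring(insert_dna, seq(3L, 21L, 3L), seq(3L, 21L, 3L))
  failed <- which(!third %in% c("G", "T"))
  list(valid = length(failed) == 0L, failed_codons = as.integer(failed))
}

#' Filter an insert pool on the NNK rule and translate survivors
#'
#' Applies the third-position G/T rule codon by codon, excludes every
#' clone that violates it (or whose insert could not be extracted
#' cleanly), translates the survivors with amber suppression, and
#' accounts for every input record in a QC report. A clone failing for
#' several reasons is excluded once with all reasons listed; exclusion
#' is per clone, not per codon.
#'
#' @param inserts Insert record data frame as produced by
#'   \code{\link{extract_inserts}} (columns \code{clone_id},
#'   \code{insert_dna}, \code{status}); a frame with just
#'   \code{clone_id} and \code{insert_dna} is also accepted, in which
#'   case \code{status} is assumed \code{"ok"}.
#' @param amber_as Amino-acid letter used for the amber codon TAG.
#' @return A list with
#'   \describe{
#'     \item{peptides}{data frame of passing clones: \code{clone_id},
#'       \code{insert_dna}, \code{peptide} (7 residues).}
#'     \item{report}{list with \code{n_input}, \code{n_excluded},
#'       \code{n_passed} and an \code{exclusions} data frame
#'       (\code{clone_id}, \code{reasons} comma-joined,
#'       \code{failed_codons} comma-joined 1-based indices).}
#'   }
#' @export
filter_library <- function(inserts, amber_as = "Q") {
  n_input <- nrow(inserts)
  status <- if ("status" %in% names(inserts)) inserts$status else
    rep("ok", n_input)

  keep <- logical(n_input)
  excl_id <- character(0)
  excl_reason <- character(0)
  excl_codons <- character(0)
  peptide <- rep(NA_character_, n_input)

  for (i in seq_len(n_input)) {
    reasons <- character(0)
    failed <- integer(0)
    if (status[i] != "ok") {
      reasons <- status[i]
    } else {
      ins <- toupper(inserts$insert_dna[i])
      if (nchar(ins) != 21L) {
        reasons <- "length-mismatch"
      } else if (grepl("N", ins, fixed = TRUE)) {
        reasons <- "ambiguous-base"
      } else {
        chk <- validate_nnk(ins)
        if (!chk$valid) {
          reasons <- c(reasons, "third-base-not-GT")
          failed <- chk$failed_codons
        }
        codons <- substring(ins, seq(1L, 21L, 3L), seq(3L, 21L, 3L))
        if (any(codons %in% c("TAA", "TGA"))) {
          reasons <- c(reasons, "premature-stop")
        }
        if (!length(reasons)) {
          peptide[i] <- translate_codons(ins, amber_as = amber_as)
          keep[i] <- TRUE
        }
      }
    }
    if (!keep[i]) {
      excl_id <- c(excl_id, inserts$clone_id[i])
      excl_reason <- c(excl_reason, paste(reasons, collapse = ","))
      excl_codons <- c(excl_codons, paste(failed, collapse = ","))
    }
  }

  peptides <- data.frame(
    clone_id = inserts$clone_id[keep],
    insert_dna = toupper(inserts$insert_dna[keep]),
    peptide = peptide[keep],
    stringsAsFactors = FALSE)
  report <- list(
    n_input = n_input,
    n_excluded = n_input - sum(keep),
    n_passed = sum(keep),
    exclusions = data.frame(clone_id = excl_id, reasons = excl_reason,
                            failed_codons = excl_codons,
                            stringsAsFactors = FALSE))
  list(peptides = peptides, report = report)
}

#' Write a QC exclusion report as TSV plus a JSON summary
#'
#' @param report The \code{report} element returned by
#'   \code{\link{filter_library}}.
#' @param tsv_path,json_path Output paths (either may be \code{NULL} to
#'   skip that file).
#' @return Invisibly, a list of the paths written.
#' @export
write_qc_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(report$exclusions, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      report[c("n_input", "n_excluded", "n_passed")],
      json_path, auto_unbox = TRUE)
  }
  invisible(list(tsv = tsv_path, json = json_path))
}
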