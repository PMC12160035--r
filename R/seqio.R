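#' Read sequence data from FASTA, FASTQ or plain DNA lines
#'
#' Loads phage insert amplicon reads into a data frame, one row per
#' record. FASTA and FASTQ (Sanger Phred+33) parsing is delegated to
#' \pkg{Biostrings}; \code{"raw-lines"} treats every non-empty line of
#' the file as one DNA string. Ambiguous \code{N} bases are retained.
#'
#' @param path Path to the input file.
#' @param format One of \code{"fasta"}, \code{"fastq"}, \code{"raw-lines"}.
#' @return A data frame of class \code{sequence_reads} with columns
#'   \code{read_id}, \code{dna}, and \code{quality} (a list column of
#'   integer Phred vectors, \code{NULL} where no qualities exist).
#'   An empty file yields a zero-row data frame.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGTACGT", ">r2", "TTTT"), fa)
#' read_sequences(fa, "fasta")
#' @export
read_sequences <- function(path, format = c("fasta", "fastq", "raw-lines")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("input file does not exist: ", path)
  }
  if (file.size(path) == 0L) {
    return(.sequence_reads(character(0), character(0), list()))
  }
  switch(format,
    "fasta" = .read_fasta(path),
    "fastq" = .read_fastq(path),
    "raw-lines" = .read_raw_lines(path)
  )
}

.sequence_reads <- function(read_id, dna, quality) {
  out <- data.frame(read_id = read_id, dna = dna, stringsAsFactors = FALSE)
  out$quality <- quality
  class(out) <- c("sequence_reads", "data.frame")
  out
}

.read_fasta <- function(path) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) {
      stop("parse error in FASTA file ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  # first whitespace-delimited token of the header is the id, as usual
  ids <- sub("\\s.*$", "", names(seqs))
  .sequence_reads(ids, as.character(seqs), rep(list(NULL), length(seqs)))
}

.read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("parse error in FASTQ file ", path, ": truncated record near line ",
         (n %/% 4L) * 4L + 1L, call. = FALSE)
  }
  idx <- seq(1L, n, by = 4L)
  bad_hdr <- idx[!startsWith(lines[idx], "@")]
  if (length(bad_hdr)) {
    stop("parse error in FASTQ file ", path, ": expected '@' header at line ",
         bad_hdr[1L], call. = FALSE)
  }
  bad_sep <- idx[!startsWith(lines[idx + 2L], "+")]
  if (length(bad_sep)) {
    stop("parse error in FASTQ file ", path, ": expected '+' separator at line ",
         bad_sep[1L] + 2L, call. = FALSE)
  }
  bad_len <- idx[nchar(lines[idx + 1L]) != nchar(lines[idx + 3L])]
  if (length(bad_len)) {
    stop("parse error in FASTQ file ", path,
         ": sequence/quality length mismatch at line ", bad_len[1L] + 3L,
         call. = FALSE)
  }
  ids <- sub("\\s.*$", "", sub("^@", "", lines[idx]))
  dna <- toupper(lines[idx + 1L])
  qual <- lapply(lines[idx + 3L], function(q) {
    as.integer(charToRaw(q)) - 33L   # Sanger Phred+33
  })
  .sequence_reads(ids, dna, qual)
}

.read_raw_lines <- function(path) {
  lines <- toupper(trimws(readLines(path)))
  lines <- lines[nzchar(lines)]
  bad <- grep("[^ACGTN]", lines)
  if (length(bad)) {
    stop("parse error in raw-lines file ", path,
         ": non-nucleotide characters at line ", bad[1L], call. = FALSE)
  }
  .sequence_reads(sprintf("read_%d", seq_along(lines)), lines,
                  rep(list(NULL), length(lines)))
}

#' Reverse-complement a DNA string
#'
#' Standard Watson-Crick complementation followed by reversal. \code{N}
#' maps to \code{N}; the operation is its own inverse.
#'
#' @param dna A string over \code{A,C,G,T,N} (case-insensitive).
#' @return The reverse complement, same length, upper case.
#' @examples
#' reverse_complement("ACGT")  # "ACGT"
#' @export
reverse_complement <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  if (!nzchar(dna)) return("")
  dna <- toupper(dna)
  if (grepl("[^ACGTN]", dna)) {
    stop("invalid nucleotide character in DNA string")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Extract the 21-nt random insert between fixed vector anchors
#'
#' Searches the read as given and, failing that, its reverse complement
#' for an exact \code{flank5 ... flank3} match and returns the enclosed
#' region. Anchor matching is exact (no mismatches): these are fixed
#' vector sequences in an amplicon, so exactness is the conservative
#' default. An insert containing \code{N}, of unexpected length, or with
#' no anchors on either strand is returned flagged, never raised as an
#' error; validity against the NNK codon rule is left to
#' \code{\link{validate_nnk}} / \code{\link{filter_library}}.
#'
#' @param read A one-row slice of a \code{sequence_reads} frame, or a
#'   list with elements \code{read_id} and \code{dna}.
#' @param flank5,flank3 Fixed anchor sequences flanking the random region.
#' @param expect_len Expected insert length in nucleotides (default 21).
#' @return A one-row data frame with columns \code{clone_id},
#'   \code{raw_dna}, \code{insert_dna} (\code{NA} on failure),
#'   \code{strand} (\code{"as-read"} or \code{"reverse-complemented"}),
#'   and \code{status} (\code{"ok"}, \code{"anchor-not-found"},
#'   \code{"length-mismatch"}, \code{"ambiguous-base"}).
#' @export
extract_insert <- function(read, flank5, flank3, expect_len = 21L) {
  stopifnot(nzchar(flank5), nzchar(flank3))
  clone_id <- as.character(read$read_id)
  raw_dna <- toupper(as.character(read$dna))

  hit <- .find_between(raw_dna, flank5, flank3)
  strand <- "as-read"
  if (is.null(hit)) {
    hit <- .find_between(reverse_complement(raw_dna), flank5, flank3)
    strand <- "reverse-complemented"
  }
  if (is.null(hit)) {
    return(.insert_record(clone_id, raw_dna, NA_character_, NA_character_,
                          "anchor-not-found"))
  }
  if (nchar(hit) != expect_len) {
    return(.insert_record(clone_id, raw_dna, hit, strand, "length-mismatch"))
  }
  if (grepl("N", hit, fixed = TRUE)) {
    return(.insert_record(clone_id, raw_dna, hit, strand, "ambiguous-base"))
  }
  .insert_record(clone_id, raw_dna, hit, strand, "ok")
}

# exact search for flank5 ... flank3; first flank5 hit, then first flank3
# hit after it; NULL when either anchor is missing
.find_between <- function(dna, flank5, flank3) {
  i5 <- regexpr(flank5, dna, fixed = TRUE)
  if (i5 < 0L) return(NULL)
  start <- i5 + nchar(flank5)
  rest <- substr(dna, start, nchar(dna))
  i3 <- regexpr(flank3, rest, fixed = TRUE)
  if (i3 < 0L) return(NULL)
  substr(rest, 1L, i3 - 1L)
}

.insert_record <- function(clone_id, raw_dna, insert_dna, strand, status) {
  data.frame(clone_id = clone_id, raw_dna = raw_dna, insert_dna = insert_dna,
             strand = strand, status = status, stringsAsFactors = FALSE)
}

#' Extract inserts from a whole read set
#'
#' Vectorised convenience wrapper around \code{\link{extract_insert}}.
#'
#' @inheritParams extract_insert
#' @param reads A \code{sequence_reads} data frame from
#'   \code{\link{read_sequences}}.
#' @return A data frame with one insert record per read, in input order.
#' @export
extract_inserts <- function(reads, flank5, flank3, expect_len = 21L) {
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    extract_insert(list(read_id = reads$read_id[i], dna = reads$dna[i]),
                   flank5, flank3, expect_len)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Translate codons to a peptide with amber suppression
#'
#' Standard genetic code, except that the amber stop \code{TAG} is read
#' as a sense codon (glutamine by default) because C7C libraries are
#' propagated in supE suppressor hosts such as ER2738, where TAG inserts
#' Gln. The ochre/opal stops \code{TAA}/\code{TGA} are genuine premature
#' stops and raise an error.
#'
#' @param dna DNA string, length a multiple of 3, no \code{N}.
#' @param amber_as Single amino-acid letter substituted for TAG
#'   (default \code{"Q"}).
#' @return The translated peptide, one letter per codon.
#' @examples
#' translate_codons("TATCAGCTTGCTTTCGAGGTG")  # "YQLAFEV"
#' @export
translate_codons <- function(dna, amber_as = "Q") {
  stopifnot(is.character(dna), length(dna) == 1L,
            is.character(amber_as), nchar(amber_as) == 1L)
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n %% 3L != 0L) {
    stop("frame error: sequence length ", n, " is not a multiple of 3")
  }
  if (n == 0L) return("")
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  if (any(grepl("N", codons, fixed = TRUE))) {
    stop("ambiguity error: N base inside codon ",
         which(grepl("N", codons, fixed = TRUE))[1L])
  }
  code <- .amber_code(amber_as)
  aa <- code[codons]
  if (anyNA(aa)) {
    stop("invalid codon: ", codons[which(is.na(aa))[1L]])
  }
  stops <- which(aa == "*")
  if (length(stops)) {
    stop("premature-stop error: ", codons[stops[1L]], " at codon ", stops[1L])
  }
  paste(aa, collapse = "")
}

.amber_code <- function(amber_as) {
  code <- Biostrings::GENETIC_CODE
  code["TAG"] <- amber_as
  code
}

#' Write insert records as TSV
#'
#' @param inserts Insert record frame from \code{\link{extract_inserts}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_insert_table <- function(inserts, path) {
  utils::write.table(
    inserts[, c("clone_id", "strand", "insert_dna", "status")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
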