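test_that("read_sequences parses FASTA, FASTQ and raw lines", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1 sample", "ACGTN", ">r2", "TTTTAAAA"), fa)
  reads <- read_sequences(fa, "fasta")
  expect_equal(nrow(reads), 2L)
  expect_equal(reads$read_id, c("r1", "r2"))
  expect_equal(reads$dna, c("ACGTN", "TTTTAAAA"))

  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@q1", "ACGTACGTACGTACGTACGTACGT",
               "+", strrep("I", 24)), fq)
  reads <- read_sequences(fq, "fastq")
  expect_equal(nchar(reads$dna), 24L)
  expect_length(reads$quality[[1L]], 24L)
  expect_true(all(reads$quality[[1L]] == 40L))  # 'I' is Phred 40

  raw <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("acgt", "", "NNNT"), raw)
  reads <- read_sequences(raw, "raw-lines")
  expect_equal(reads$dna, c("ACGT", "NNNT"))

  empty <- withr::local_tempfile()
  file.create(empty)
  expect_equal(nrow(read_sequences(empty, "fasta")), 0L)
})

test_that("malformed FASTQ reports a line number", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@q1", "ACGT", "+", "III"), fq)  # quality too short
  expect_error(read_sequences(fq, "fastq"), "line 4")
  writeLines(c("q1", "ACGT", "+", "IIII"), fq)  # missing '@'
  expect_error(read_sequences(fq, "fastq"), "line 1")
})

test_that("a large synthetic amplicon fixture round-trips record counts", {
  sim <- generate_nnk_library(723, rng_seed = 11)
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(rbind(paste0(">", sim$reads$read_id), sim$reads$dna), fa)
  # independent oracle: two lines per record
  expect_equal(length(readLines(fa)) / 2L, 723L)
  reads <- read_sequences(fa, "fasta")
  expect_equal(nrow(reads), 723L)
  expect_equal(reads$read_id, sim$reads$read_id)
})

test_that("reverse_complement matches a per-base oracle and is involutive", {
  primer <- "TGTCGGCGCAACTATCGGTATCAA"
  expect_equal(reverse_complement(primer), oracle_revcomp(primer))
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement(""), "")
  expect_equal(reverse_complement("N"), "N")
  expect_error(reverse_complement("ACGU"), "invalid nucleotide")

  set.seed(5)
  for (i in 1:25) {
    x <- paste(sample(c("A", "C", "G", "T", "N"),
                      sample(1:40, 1), replace = TRUE), collapse = "")
    expect_equal(reverse_complement(reverse_complement(x)), x)
    expect_equal(reverse_complement(x), oracle_revcomp(x))
  }
})

test_that("extract_insert finds the insert on either strand and flags failures", {
  f5 <- "GCTTGTTCCTTTGGAGCC"; f3 <- "GGGGCCGAAACTGTTGAA"
  insert <- "TATCAGCTTGCTTTCGAGGTG"
  fwd <- extract_insert(list(read_id = "a", dna = paste0(f5, insert, f3)),
                        f5, f3)
  expect_equal(fwd$insert_dna, insert)
  expect_equal(fwd$strand, "as-read")
  expect_equal(fwd$status, "ok")

  rc <- extract_insert(
    list(read_id = "b", dna = oracle_revcomp(paste0(f5, insert, f3))),
    f5, f3)
  expect_equal(rc$insert_dna, insert)
  expect_equal(rc$strand, "reverse-complemented")

  none <- extract_insert(list(read_id = "c", dna = "ACGTACGTACGT"), f5, f3)
  expect_equal(none$status, "anchor-not-found")
  expect_true(is.na(none$insert_dna))

  short <- extract_insert(
    list(read_id = "d", dna = paste0(f5, "ACGTAC", f3)), f5, f3)
  expect_equal(short$status, "length-mismatch")

  amb <- extract_insert(
    list(read_id = "e", dna = paste0(f5, sub("G", "N", insert), f3)), f5, f3)
  expect_equal(amb$status, "ambiguous-base")
})

test_that("extract_inserts recovers every simulated ground-truth insert", {
  sim <- generate_nnk_library(100, rng_seed = 3)
  ins <- extract_inserts(sim$reads, sim$flank5, sim$flank3)
  expect_equal(nrow(ins), 100L)
  expect_true(all(ins$status == "ok"))
  expect_identical(ins$insert_dna, sim$truth$insert_dna)
  expect_identical(
    ins$strand == "reverse-complemented",
    sim$truth$orientation == "reverse-complemented")
})

test_that("translate_codons applies the standard code with amber suppression", {
  expect_equal(translate_codons("TATCAGCTTGCTTTCGAGGTG"), "YQLAFEV")
  expect_equal(translate_codons("TAG"), "Q")
  # mapping TAG back onto '*' turns it into a genuine stop again
  expect_error(translate_codons("TAG", amber_as = "*"), "premature-stop")
  expect_error(translate_codons("ACGTA"), "frame error")
  expect_error(translate_codons("TAA"), "premature-stop")
  expect_error(translate_codons("ACGTGA"), "premature-stop")
  expect_error(translate_codons("ANG"), "ambiguity")

  # random NNK 21-mers: length 7, agrees with a Biostrings oracle on
  # TAG-free inserts
  set.seed(9)
  code <- Biostrings::GENETIC_CODE
  for (i in 1:30) {
    dna <- paste0(paste0(sample(c("A", "C", "G", "T"), 7, TRUE),
                         sample(c("A", "C", "G", "T"), 7, TRUE),
                         sample(c("G", "T"), 7, TRUE)), collapse = "")
    pep <- translate_codons(dna)
    expect_equal(nchar(pep), 7L)
    codons <- substring(dna, seq(1, 19, 3), seq(3, 21, 3))
    if (!any(codons == "TAG")) {
      expect_equal(
        pep,
        as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                           no.init.codon = TRUE)))
    }
  }
})
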