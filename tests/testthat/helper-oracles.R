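# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths: plain nested loops and lookup
# tables only.

# per-base reverse complement, no Biostrings
oracle_revcomp <- function(dna) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(dna, "", fixed = TRUE)[[1L]]]), collapse = "")
}

# brute-force bidirectional tripeptide abundance by nested window scan
oracle_abundance <- function(pool) {
  counts <- new.env(parent = emptyenv())
  bump <- function(key, slot) {
    cur <- if (exists(key, counts)) get(key, counts) else c(f = 0L, r = 0L)
    cur[slot] <- cur[slot] + 1L
    assign(key, cur, counts)
  }
  for (p in pool) {
    for (j in 1:5) bump(substr(p, j, j + 2L), "f")
    rp <- paste(rev(strsplit(p, "", fixed = TRUE)[[1L]]), collapse = "")
    for (j in 1:5) bump(substr(rp, j, j + 2L), "r")
  }
  keys <- ls(counts)
  data.frame(motif = keys,
             n_forward = vapply(keys, function(k) get(k, counts)[["f"]], 0L),
             n_reverse = vapply(keys, function(k) get(k, counts)[["r"]], 0L),
             stringsAsFactors = FALSE, row.names = NULL)
}

# all permutations of 1..n as an (n! x n) matrix, recursive construction
oracle_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- oracle_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# exact null probability that a motif's bidirectional abundance reaches
# `obs` under uniformly random orderings of a single peptide's residues
oracle_exact_single_peptide_p <- function(peptide, motif, obs) {
  res <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  perms <- oracle_permutations(length(res))
  hits <- 0L
  for (r in seq_len(nrow(perms))) {
    p <- paste(res[perms[r, ]], collapse = "")
    rp <- paste(rev(res[perms[r, ]]), collapse = "")
    cnt <- 0L
    for (j in 1:5) {
      if (substr(p, j, j + 2L) == motif) cnt <- cnt + 1L
      if (substr(rp, j, j + 2L) == motif) cnt <- cnt + 1L
    }
    if (cnt >= obs) hits <- hits + 1L
  }
  hits / nrow(perms)
}

# random heptapeptide pool over the 20 canonical residues
random_pool <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  vapply(seq_len(n),
         function(i) paste(sample(aa, 7, replace = TRUE), collapse = ""),
         "")
}
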