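#' @title Synthetic phage-display data generators
#' @description Seeded generators that emulate the statistical structure
#'   of a C7C biopanning screen: an NNK-encoded heptapeptide library
#'   with optional spiked motifs, wild-type / sequencing-error
#'   contamination, ELISA OD plates, and round-wise panning titers.
#'   Every generator returns a ground-truth table so downstream modules
#'   can be scored exactly.
#' @name simlib
NULL

# default synthetic vector anchors flanking the 21-nt random region;
# long enough that a chance match inside a random insert is negligible
.default_flank5 <- "GCTTGTTCCTTTGGAGCC"
.default_flank3 <- "GGGGCCGAAACTGTTGAA"

# NNK codon table: N = any base, K = G or T; TAG reads as Gln in the
# supE host, TAA/TGA cannot occur
.nnk_codons <- function() {
  codons <- as.vector(outer(
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("G", "T"), paste0))
  aa <- .amber_code("Q")[codons]
  split(codons, aa)
}

.random_nnk_insert <- function() {
  paste0(paste0(sample(c("A", "C", "G", "T"), 7, replace = TRUE),
                sample(c("A", "C", "G", "T"), 7, replace = TRUE),
                sample(c("G", "T"), 7, replace = TRUE)), collapse = "")
}

# back-translate a peptide through NNK-compatible codons, sampled
# uniformly so spikes are invisible at the DNA-composition level
.backtranslate_nnk <- function(peptide, nnk_by_aa) {
  res <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  paste(vapply(res, function(a) {
    opts <- nnk_by_aa[[a]]
    if (is.null(opts)) stop("residue ", a, " not encodable by NNK")
    opts[sample.int(length(opts), 1L)]
  }, "", USE.NAMES = FALSE), collapse = "")
}

#' Generate a synthetic NNK heptapeptide library with optional spikes
#'
#' Each non-spiked insert is seven i.i.d. NNK codons (third base G or T
#' by construction). Spiked clones embed the spike motif's residues at a
#' uniformly chosen offset, back-translated through randomly chosen
#' NNK-compatible codons; the remaining positions are random NNK codons.
#' Reads are \code{flank5 + insert + flank3}, each emitted
#' reverse-complemented with probability one half.
#'
#' @param n_clones Number of clones.
#' @param rng_seed Integer seed.
#' @param spikes Named numeric vector of motif target frequencies,
#'   e.g. \code{c(SPFPT = 0.15)}; frequencies must sum to at most 1 and
#'   motifs must be at most 7 residues. Each clone is independently
#'   assigned a spike (or none) at these probabilities.
#' @param flank5,flank3 Fixed anchor sequences (defaults are synthetic
#'   stand-ins for vector sequence).
#' @return A list with \code{reads} (a \code{sequence_reads} frame),
#'   \code{truth} (clone_id, insert_dna, peptide, spike, orientation,
#'   valid, wildtype), and the anchors used.
#' @export
generate_nnk_library <- function(n_clones, rng_seed = NULL, spikes = NULL,
                                 flank5 = .default_flank5,
                                 flank3 = .default_flank3) {
  stopifnot(n_clones >= 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (!is.null(spikes)) {
    if (is.null(names(spikes)) || any(!nzchar(names(spikes)))) {
      stop("spec error: spikes must be a named vector of frequencies")
    }
    if (any(nchar(names(spikes)) > 7L)) {
      stop("spec error: spike motif longer than 7 residues")
    }
    if (sum(spikes) > 1) stop("spec error: spike frequencies sum above 1")
  }
  nnk_by_aa <- .nnk_codons()
  labels <- c(names(spikes), "none")
  probs <- c(as.numeric(spikes), 1 - sum(as.numeric(spikes)))

  clone_id <- sprintf("clone_%04d", seq_len(n_clones))
  spike_of <- if (n_clones) {
    sample(labels, n_clones, replace = TRUE, prob = probs)
  } else character(0)
  insert <- character(n_clones)
  peptide <- character(n_clones)
  for (i in seq_len(n_clones)) {
    if (spike_of[i] == "none") {
      insert[i] <- .random_nnk_insert()
    } else {
      motif <- spike_of[i]
      k <- nchar(motif)
      off <- sample.int(7L - k + 1L, 1L)
      res <- strsplit(.random_nnk_insert(), "", fixed = TRUE)[[1L]]
      codons <- paste0(res[seq(1, 21, 3)], res[seq(2, 21, 3)],
                       res[seq(3, 21, 3)])
      spike_codons <- substring(.backtranslate_nnk(motif, nnk_by_aa),
                                seq(1L, 3L * k, 3L), seq(3L, 3L * k, 3L))
      codons[off:(off + k - 1L)] <- spike_codons
      insert[i] <- paste(codons, collapse = "")
    }
    peptide[i] <- translate_codons(insert[i])
  }
  orientation <- ifelse(stats::runif(n_clones) < 0.5,
                        "reverse-complemented", "as-read")
  dna <- paste0(flank5, insert, flank3)
  flip <- orientation == "reverse-complemented"
  dna[flip] <- vapply(dna[flip], reverse_complement, "", USE.NAMES = FALSE)

  truth <- data.frame(clone_id = clone_id, insert_dna = insert,
                      peptide = peptide, spike = spike_of,
                      orientation = orientation,
                      valid = rep(TRUE, n_clones),
                      wildtype = rep(FALSE, n_clones),
                      stringsAsFactors = FALSE)
  reads <- .sequence_reads(clone_id, dna, rep(list(NULL), n_clones))
  list(reads = reads, truth = truth, flank5 = flank5, flank3 = flank3)
}

#' Corrupt a synthetic library with rule violations and wild-type reads
#'
#' Emulates the two contamination modes seen in real screens: exactly
#' \code{n_invalid} clones get one randomly chosen codon's third base
#' flipped to A or C (breaking the NNK design rule), and exactly
#' \code{n_wildtype} clones have their read replaced by vector-like
#' sequence lacking both anchors (wild-type phage with no insert).
#' Counts are exact, not probabilistic, so fixture compositions are
#' deterministic.
#'
#' @param sim A library from \code{\link{generate_nnk_library}}.
#' @param n_invalid,n_wildtype Numbers of clones to corrupt; disjoint
#'   sets, together at most the pool size.
#' @param rng_seed Integer seed.
#' @return The library with \code{reads} mutated and \code{truth}
#'   updated (\code{valid}/\code{wildtype} flags, \code{failed_codon}
#'   column for invalid clones).
#' @export
corrupt_library <- function(sim, n_invalid, n_wildtype, rng_seed = NULL) {
  n <- nrow(sim$truth)
  if (n_invalid + n_wildtype > n) {
    stop("spec error: n_invalid + n_wildtype exceeds the pool size")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  picks <- sample.int(n, n_invalid + n_wildtype)
  inv <- picks[seq_len(n_invalid)]
  wt <- picks[n_invalid + seq_len(n_wildtype)]
  sim$truth$failed_codon <- NA_integer_

  for (i in inv) {
    codon <- sample.int(7L, 1L)
    pos <- 3L * codon
    ins <- sim$truth$insert_dna[i]
    substr(ins, pos, pos) <- sample(c("A", "C"), 1L)
    sim$truth$insert_dna[i] <- ins
    sim$truth$valid[i] <- FALSE
    sim$truth$failed_codon[i] <- codon
    dna <- paste0(sim$flank5, ins, sim$flank3)
    if (sim$truth$orientation[i] == "reverse-complemented") {
      dna <- reverse_complement(dna)
    }
    sim$reads$dna[i] <- dna
  }

  for (i in wt) {
    len <- nchar(sim$reads$dna[i])
    repeat {
      dna <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      rc <- reverse_complement(dna)
      hit <- any(vapply(c(sim$flank5, sim$flank3), function(a) {
        grepl(a, dna, fixed = TRUE) || grepl(a, rc, fixed = TRUE)
      }, logical(1)))
      if (!hit) break
    }
    sim$reads$dna[i] <- dna
    sim$truth$insert_dna[i] <- NA_character_
    sim$truth$peptide[i] <- NA_character_
    sim$truth$valid[i] <- FALSE
    sim$truth$wildtype[i] <- TRUE
  }
  sim
}

#' Simulate a cell-based ELISA plate with an exact positive count
#'
#' Generates stretched/static OD450 pairs for \code{n_clones} clones of
#' which exactly \code{n_positive} have a final ratio at or above
#' \code{fold_threshold}. Target ratios are drawn away from the
#' threshold and noisy ODs are rejection-resampled at the boundary, so
#' measurement noise cannot flip a label and the constructed count is
#' exact.
#'
#' @param n_clones,n_positive Plate size and number of positives.
#' @param fold_threshold Positivity threshold on the OD ratio.
#' @param noise_sd Gaussian noise SD added to the stretched OD.
#' @param rng_seed Integer seed.
#' @return A data frame: \code{clone_id}, \code{od_stretched},
#'   \code{od_static}, \code{true_positive}.
#' @export
simulate_elisa <- function(n_clones, n_positive, fold_threshold = 3.0,
                           noise_sd = 0.02, rng_seed = NULL) {
  if (n_positive > n_clones) {
    stop("spec error: n_positive exceeds n_clones")
  }
  if (noise_sd < 0) stop("spec error: negative noise_sd")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  # labels in random plate order
  truth <- sample(c(rep(TRUE, n_positive), rep(FALSE, n_clones - n_positive)))
  od_static <- stats::runif(n_clones, 0.20, 0.60)
  # margins around the threshold wide enough that noise cannot flip labels
  lo_pos <- fold_threshold * 1.15
  hi_neg <- fold_threshold * 0.85
  if (noise_sd > 0.05 * fold_threshold * min(od_static)) {
    stop("spec error: noise_sd too large for the label margins")
  }
  ratio <- ifelse(truth,
                  stats::runif(n_clones, lo_pos, fold_threshold * 3.0),
                  stats::runif(n_clones, 0.3, hi_neg))
  od_stretched <- od_static * ratio + stats::rnorm(n_clones, 0, noise_sd)
  # rejection-resample noise for any clone the noise pushed across
  bad <- which((od_stretched / od_static >= fold_threshold) != truth |
                 od_stretched < 0)
  guard <- 0L
  while (length(bad)) {
    od_stretched[bad] <- od_static[bad] * ratio[bad] +
      stats::rnorm(length(bad), 0, noise_sd)
    bad <- bad[(od_stretched[bad] / od_static[bad] >= fold_threshold) !=
                 truth[bad] | od_stretched[bad] < 0]
    guard <- guard + 1L
    if (guard > 1000L) stop("spec error: cannot satisfy margins at this noise")
  }
  data.frame(clone_id = sprintf("clone_%04d", seq_len(n_clones)),
             od_stretched = od_stretched, od_static = od_static,
             true_positive = truth, stringsAsFactors = FALSE)
}

#' Simulate round-wise panning titers with a recovery-rate plateau
#'
#' Recovery rates grow geometrically by \code{enrichment_factor} per
#' round and reach their plateau at \code{plateau_round}: from that
#' round on the rate holds at the preceding round's level within 5%
#' (so a trajectory with \code{plateau_round = n_rounds} saturates at
#' the final round, as a screen stopped at its saturation point
#' would). Plaque counts
#' are drawn Poisson around the expectation implied by the true
#' recovered titer at a ten-fold serial dilution chosen to keep plates
#' countable.
#'
#' @param n_rounds Number of rounds (>= 1).
#' @param base_recovery Round-1 recovery rate.
#' @param enrichment_factor Per-round geometric growth factor.
#' @param plateau_round Round at which the rate plateaus.
#' @param rng_seed Integer seed.
#' @param input_titer Input titer per round, pfu/ml.
#' @param volume_plated_ml Plated volume for titering, ml.
#' @return A data frame per round: \code{round_index},
#'   \code{input_titer}, \code{plaque_count}, \code{dilution_factor},
#'   \code{volume_plated_ml}, \code{recovered_titer} (measured from the
#'   plaque count), and \code{true_rate}.
#' @export
simulate_panning <- function(n_rounds, base_recovery = 1e-4,
                             enrichment_factor = 3.0, plateau_round = 4L,
                             rng_seed = NULL, input_titer = 2.5e9,
                             volume_plated_ml = 0.01) {
  stopifnot(n_rounds >= 1L, base_recovery > 0, enrichment_factor > 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  idx <- seq_len(n_rounds)
  growth_idx <- pmax(pmin(idx, plateau_round - 1L), 1L)
  rate <- base_recovery * enrichment_factor^(growth_idx - 1L)
  post <- idx >= plateau_round & idx > 1L
  rate[post] <- rate[post] * stats::runif(sum(post), 0.98, 1.02)
  true_recovered <- input_titer * rate
  # pick a ten-fold dilution putting the expected count near 10-100
  dilution <- 10^pmax(0, ceiling(log10(true_recovered * volume_plated_ml / 100)))
  expected_count <- true_recovered * volume_plated_ml / dilution
  plaque_count <- stats::rpois(n_rounds, expected_count)
  data.frame(round_index = idx, input_titer = input_titer,
             plaque_count = plaque_count, dilution_factor = dilution,
             volume_plated_ml = volume_plated_ml,
             recovered_titer = compute_titer(plaque_count, dilution,
                                             volume_plated_ml),
             true_rate = rate)
}
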