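#' Discovery configuration
#'
#' Bundles the tunable constants of the tripeptide-motif analysis. The
#' defaults encode the screen's operating point: a motif is carried
#' forward when its abundance exceeds 20 occurrences or its
#' Bonferroni-adjusted permutation p-value falls below 0.05.
#'
#' @param abundance_threshold Strict abundance cut-off; a motif is
#'   "abundant" when abundance is strictly greater than this (default 20).
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_permutations Number of residue-shuffle replicates for the
#'   permutation test (default 10000).
#' @param rng_seed Integer seed making the permutation test reproducible.
#' @param bonferroni_m Multiplicity for the Bonferroni correction:
#'   \code{"observed-distinct"} (the number of distinct tripeptides seen
#'   in the pool, the literal reading of testing each observed motif) or
#'   \code{"all-8000"} (all 20^3 possible tripeptides).
#' @param weight_by_multiplicity Count each peptide once (default,
#'   matching abundance computed on the non-redundant pool) or weight by
#'   clone multiplicity.
#' @param shuffle Null model for the permutation test:
#'   \code{"pooled"} shuffles all residues of the pool jointly and
#'   re-deals them into peptides of the original lengths (preserves the
#'   global residue composition — the default, weakest assumption), or
#'   \code{"within-peptide"} shuffles residues independently inside each
#'   peptide (additionally preserves per-peptide composition).
#' @return A list of class \code{discovery_config}.
#' @export
discovery_config <- function(abundance_threshold = 20L,
                             alpha = 0.05,
                             n_permutations = 10000L,
                             rng_seed = NULL,
                             bonferroni_m = c("observed-distinct", "all-8000"),
                             weight_by_multiplicity = FALSE,
                             shuffle = c("pooled", "within-peptide")) {
  stopifnot(abundance_threshold >= 0, alpha > 0, alpha < 1)
  if (n_permutations < 1L) stop("config error: n_permutations must be >= 1")
  structure(
    list(abundance_threshold = as.integer(abundance_threshold),
         alpha = alpha,
         n_permutations = as.integer(n_permutations),
         rng_seed = rng_seed,
         bonferroni_m = match.arg(bonferroni_m),
         weight_by_multiplicity = isTRUE(weight_by_multiplicity),
         shuffle = match.arg(shuffle)),
    class = "discovery_config")
}

#' Segment a heptapeptide into bidirectional tripeptide windows
#'
#' A 7-mer yields five overlapping tripeptide windows read left to
#' right, and five more read from the reversed sequence, ten in total.
#' A tripeptide and its reversal are distinct motifs throughout the
#' analysis (LHT and HTL are different keys), so the reverse windows are
#' genuine additional observations, not duplicates; palindromic
#' tripeptides accrue counts from both directions.
#'
#' @param peptide A 7-letter peptide string.
#' @return A list with character vectors \code{forward} and
#'   \code{reverse}, five windows each.
#' @examples
#' segment_tripeptides("ABCDEFG")
#' @export
segment_tripeptides <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  if (nchar(peptide) != 7L) {
    stop("peptide must have length 7, got ", nchar(peptide))
  }
  fwd <- substring(peptide, 1:5, 3:7)
  rev_pep <- paste(rev(strsplit(peptide, "", fixed = TRUE)[[1L]]),
                   collapse = "")
  rev <- substring(rev_pep, 1:5, 3:7)
  list(forward = fwd, reverse = rev)
}

# residue matrix (n x 7) of a heptapeptide pool
.residue_matrix <- function(peptides) {
  if (any(nchar(peptides) != 7L)) stop("all pool peptides must be 7-mers")
  matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
         ncol = 7L, byrow = TRUE)
}

# all forward (resp. reverse) windows of a pool, vectorised over rows:
# forward window j = columns j..j+2; reverse windows are the reversed
# triples, columns j+2..j
.pool_windows <- function(mat) {
  fwd <- lapply(1:5, function(j) paste0(mat[, j], mat[, j + 1L], mat[, j + 2L]))
  rev <- lapply(5:1, function(j) paste0(mat[, j + 2L], mat[, j + 1L], mat[, j]))
  list(forward = unlist(fwd), reverse = unlist(rev))
}

#' Count bidirectional tripeptide abundance over a peptide pool
#'
#' The abundance of a tripeptide is its total number of occurrences
#' among all forward and reverse windows of the pool; forward and
#' reverse tallies are also reported separately. By default each
#' (non-redundant) peptide contributes once; with
#' \code{weight_by_multiplicity} clones re-enter at their redundancy.
#'
#' @param peptides Character vector of 7-mers, or a data frame from
#'   \code{\link{dereplicate}} (columns \code{peptide},
#'   \code{multiplicity}).
#' @param config A \code{\link{discovery_config}}.
#' @return A data frame (class \code{tripeptide_stats}) with columns
#'   \code{motif}, \code{n_forward}, \code{n_reverse}, \code{abundance},
#'   and placeholder \code{p_raw}, \code{p_adj}, \code{selected},
#'   sorted by abundance descending then motif. The abundances sum to
#'   ten times the pool size.
#' @export
count_abundance <- function(peptides, config = discovery_config()) {
  pool <- .as_pool(peptides, config)
  if (!length(pool)) {
    out <- data.frame(motif = character(0), n_forward = integer(0),
                      n_reverse = integer(0), abundance = integer(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      selected = logical(0), stringsAsFactors = FALSE)
    class(out) <- c("tripeptide_stats", "data.frame")
    return(out)
  }
  win <- .pool_windows(.residue_matrix(pool))
  motifs <- sort(unique(c(win$forward, win$reverse)))
  nf <- table(factor(win$forward, levels = motifs))
  nr <- table(factor(win$reverse, levels = motifs))
  out <- data.frame(motif = motifs,
                    n_forward = as.integer(nf),
                    n_reverse = as.integer(nr),
                    stringsAsFactors = FALSE)
  out$abundance <- out$n_forward + out$n_reverse
  out$p_raw <- NA_real_
  out$p_adj <- NA_real_
  out$selected <- NA
  out <- out[order(-out$abundance, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pool_size") <- length(pool)
  class(out) <- c("tripeptide_stats", "data.frame")
  out
}

.as_pool <- function(peptides, config) {
  if (is.data.frame(peptides)) {
    if (isTRUE(config$weight_by_multiplicity) &&
        "multiplicity" %in% names(peptides)) {
      rep(peptides$peptide, peptides$multiplicity)
    } else {
      peptides$peptide
    }
  } else {
    as.character(peptides)
  }
}

#' Permutation test of tripeptide abundance under residue shuffling
#'
#' For each replicate the residues of the pool are shuffled (jointly
#' across the pool by default) and re-dealt into peptides of the
#' original lengths; the abundance of every observed motif is recounted
#' on the shuffled pool. The raw p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{b : A_b \ge A_{obs}\}) / (1 + B)}, which can never
#' be zero and is the honest Monte-Carlo p-value for a permutation
#' null.
#'
#' @param observed A \code{tripeptide_stats} frame from
#'   \code{\link{count_abundance}}, computed on the same pool.
#' @param peptides The pool the counts were computed on.
#' @param config A \code{\link{discovery_config}}; \code{rng_seed} makes
#'   the replicate stream reproducible, \code{shuffle} picks the null.
#' @return \code{observed} with \code{p_raw} filled in.
#' @export
permutation_test <- function(observed, peptides,
                             config = discovery_config()) {
  if (config$n_permutations < 1L) {
    stop("config error: n_permutations must be >= 1")
  }
  pool <- .as_pool(peptides, config)
  mat <- .residue_matrix(pool)
  residues <- as.vector(t(mat))   # row-major: peptide 1 residues first
  n_res <- length(residues)
  n_pep <- nrow(mat)
  motifs <- observed$motif
  m <- length(motifs)
  obs <- observed$abundance
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)

  exceed <- integer(m)
  B <- config$n_permutations
  within <- identical(config$shuffle, "within-peptide")
  for (b in seq_len(B)) {
    if (within) {
      null_mat <- t(apply(mat, 1L, sample))
    } else {
      null_mat <- matrix(residues[sample.int(n_res)], ncol = 7L,
                         byrow = TRUE)
    }
    win <- .pool_windows(null_mat)
    idx <- match(c(win$forward, win$reverse), motifs)
    cnt <- tabulate(idx[!is.na(idx)], nbins = m)
    exceed <- exceed + (cnt >= obs)
  }
  observed$p_raw <- (1 + exceed) / (1 + B)
  observed
}

#' Bonferroni adjustment of permutation p-values
#'
#' \code{p_adj = min(1, m * p_raw)}, with \code{m} either the number of
#' distinct observed tripeptides (default) or all 8000 possible
#' tripeptides, per the configuration.
#'
#' @param stats A \code{tripeptide_stats} frame with \code{p_raw} set.
#' @param config A \code{\link{discovery_config}}.
#' @return \code{stats} with \code{p_adj} filled; the multiplicity used
#'   is attached as attribute \code{"bonferroni_m"}.
#' @export
bonferroni_adjust <- function(stats, config = discovery_config()) {
  m <- if (identical(config$bonferroni_m, "all-8000")) 8000L else
    nrow(stats)
  stats$p_adj <- pmin(1, m * stats$p_raw)
  attr(stats, "bonferroni_m") <- m
  stats
}

#' Select motifs by abundance or adjusted significance
#'
#' A motif is carried forward when its abundance strictly exceeds the
#' threshold ("above twenty" is read strictly) or its adjusted p-value
#' is below alpha; the reason(s) are recorded. Ordering is abundance
#' descending, then adjusted p ascending, then motif — deterministic for
#' identical input.
#'
#' @param stats A \code{tripeptide_stats} frame with \code{abundance}
#'   and \code{p_adj} present.
#' @param config A \code{\link{discovery_config}}.
#' @return \code{stats} with \code{selected} and \code{selection_reason}
#'   filled and rows re-sorted.
#' @export
select_motifs <- function(stats, config = discovery_config()) {
  abundant <- stats$abundance > config$abundance_threshold
  significant <- !is.na(stats$p_adj) & stats$p_adj < config$alpha
  stats$selected <- abundant | significant
  stats$selection_reason <- ifelse(
    abundant & significant, "abundant,significant",
    ifelse(abundant, "abundant", ifelse(significant, "significant", "")))
  p_key <- ifelse(is.na(stats$p_adj), Inf, stats$p_adj)
  stats <- stats[order(-stats$abundance, p_key, stats$motif), , drop = FALSE]
  rownames(stats) <- NULL
  stats
}

#' Extend selected tripeptides into 4-6 residue consensus motifs
#'
#' For each selected tripeptide, the heptapeptides containing it
#' (forward, or as its reversal — those are reversed so the anchor reads
#' forward) are aligned without gaps by pinning the shared tripeptide:
#' 7-mers sharing an exact 3-mer admit a unique gap-free anchoring, so a
#' gapped aligner adds nothing but nondeterminism. A consensus residue
#' is called in a column when one residue is the unique mode and its
#' frequency over all supporters (supporters not covering the column
#' count as disagreement) reaches \code{column_support_min}. The
#' reported motif is the longest contiguous run of consensus columns
#' containing the anchor, clipped to \code{[min_len, max_len]}; when no
#' run reaches \code{min_len} the anchor is returned flagged unextended.
#'
#' @param selected Character vector of anchor tripeptides.
#' @param peptides Pool of 7-mers (character vector or data frame with a
#'   \code{peptide} column).
#' @param min_len,max_len Bounds on the reported consensus length
#'   (defaults 4 and 6).
#' @param column_support_min Minimum column agreement fraction for a
#'   consensus call (default 0.5).
#' @return A data frame with columns \code{anchor}, \code{consensus},
#'   \code{extended} (logical), \code{n_supporters}, plus list columns
#'   \code{supporters} (oriented parent 7-mers) and
#'   \code{column_support} (per-consensus-column agreement fractions).
#'   Anchors with fewer than two supporters are skipped with a message.
#' @export
extend_motifs <- function(selected, peptides, min_len = 4L, max_len = 6L,
                          column_support_min = 0.5) {
  pool <- if (is.data.frame(peptides)) peptides$peptide else
    as.character(peptides)
  rows <- lapply(selected, function(anchor) {
    .extend_one(anchor, pool, min_len, max_len, column_support_min)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(anchor = character(0), consensus = character(0),
                      extended = logical(0), n_supporters = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

.extend_one <- function(anchor, pool, min_len, max_len, support_min) {
  rev_anchor <- paste(rev(strsplit(anchor, "", fixed = TRUE)[[1L]]),
                      collapse = "")
  fwd_hit <- grepl(anchor, pool, fixed = TRUE)
  rev_hit <- !fwd_hit & grepl(rev_anchor, pool, fixed = TRUE)
  oriented <- c(pool[fwd_hit],
                vapply(pool[rev_hit], function(p) {
                  paste(rev(strsplit(p, "", fixed = TRUE)[[1L]]),
                        collapse = "")
                }, "", USE.NAMES = FALSE))
  n_sup <- length(oriented)
  if (n_sup < 2L) {
    message("motif ", anchor, " skipped: ", n_sup, " supporter(s)")
    return(NULL)
  }
  offset <- vapply(oriented,
                   function(p) as.integer(regexpr(anchor, p, fixed = TRUE)),
                   integer(1), USE.NAMES = FALSE)
  # alignment column of residue k (1-based in peptide) is k - offset;
  # the anchor occupies columns 0..2 in every supporter
  col_lo <- min(1L - offset)
  col_hi <- max(7L - offset)
  cols <- col_lo:col_hi
  cons <- rep(NA_character_, length(cols))
  support <- rep(0, length(cols))
  for (ci in seq_along(cols)) {
    k <- cols[ci] + offset            # residue index per supporter
    cover <- k >= 1L & k <= 7L
    res <- substring(oriented[cover], k[cover], k[cover])
    if (!length(res)) next
    tab <- sort(table(res), decreasing = TRUE)
    frac <- as.integer(tab[1L]) / n_sup
    unique_mode <- length(tab) == 1L || tab[1L] > tab[2L]
    if (unique_mode && frac >= support_min) {
      cons[ci] <- names(tab)[1L]
      support[ci] <- frac
    }
  }
  called <- !is.na(cons)
  anchor_cols <- which(cols %in% 0:2)
  run <- .run_containing(called, anchor_cols)
  run_len <- length(run)
  if (run_len < min_len) {
    out_cols <- anchor_cols
    extended <- FALSE
  } else if (run_len <= max_len) {
    out_cols <- run
    extended <- TRUE
  } else {
    out_cols <- .best_subwindow(run, anchor_cols, max_len, support)
    extended <- TRUE
  }
  consensus <- paste(cons[out_cols], collapse = "")
  row <- data.frame(anchor = anchor, consensus = consensus,
                    extended = extended, n_supporters = n_sup,
                    stringsAsFactors = FALSE)
  row$supporters <- list(oriented)
  row$column_support <- list(support[out_cols])
  row
}

# maximal contiguous run of TRUE containing all of `must` (which is
# itself contiguous and TRUE by construction)
.run_containing <- function(called, must) {
  lo <- min(must); hi <- max(must)
  while (lo > 1L && called[lo - 1L]) lo <- lo - 1L
  while (hi < length(called) && called[hi + 1L]) hi <- hi + 1L
  lo:hi
}

# width-`w` subwindow of `run` containing `must`, maximising mean column
# support; leftmost wins ties
.best_subwindow <- function(run, must, w, support) {
  starts <- seq(max(run[1L], max(must) - w + 1L),
                min(run[length(run)] - w + 1L, min(must)))
  means <- vapply(starts, function(s) mean(support[s:(s + w - 1L)]),
                  numeric(1))
  s <- starts[which.max(means)]
  s:(s + w - 1L)
}

#' Run the full tripeptide motif-discovery analysis
#'
#' Convenience orchestrator: abundance counting, permutation test,
#' Bonferroni adjustment, motif selection and consensus extension, in
#' one call on a (non-redundant) heptapeptide pool.
#'
#' @param peptides Pool of 7-mers (character vector or
#'   \code{\link{dereplicate}} output).
#' @param config A \code{\link{discovery_config}}.
#' @param column_support_min Passed to \code{\link{extend_motifs}}.
#' @return An object of class \code{phage_discovery}: a list with
#'   \code{stats} (the full tripeptide table), \code{extended} (the
#'   consensus-motif table for selected anchors), \code{config},
#'   \code{pool_size} and \code{bonferroni_m}.
#' @export
discover_motifs <- function(peptides, config = discovery_config(),
                            column_support_min = 0.5) {
  stats <- count_abundance(peptides, config)
  pool_size <- attr(stats, "pool_size")
  if (nrow(stats)) {
    stats <- permutation_test(stats, peptides, config)
    stats <- bonferroni_adjust(stats, config)
    stats <- select_motifs(stats, config)
    anchors <- stats$motif[stats$selected]
    extended <- extend_motifs(anchors, peptides,
                              column_support_min = column_support_min)
  } else {
    extended <- extend_motifs(character(0), character(0))
  }
  structure(
    list(stats = stats, extended = extended, config = config,
         pool_size = if (is.null(pool_size)) 0L else pool_size,
         bonferroni_m = attr(stats, "bonferroni_m")),
    class = "phage_discovery")
}

#' @export
print.phage_discovery <- function(x, ...) {
  cat("Tripeptide motif discovery\n")
  cat("  pool size:          ", x$pool_size, " heptapeptides\n", sep = "")
  cat("  segmented windows:  ", 10L * x$pool_size, "\n", sep = "")
  cat("  distinct tripeptides: ", nrow(x$stats), "\n", sep = "")
  cat("  permutations:       ", x$config$n_permutations,
      " (shuffle: ", x$config$shuffle, ")\n", sep = "")
  sel <- x$stats[x$stats$selected, , drop = FALSE]
  cat("  selected motifs:    ", nrow(sel),
      " (abundance > ", x$config$abundance_threshold,
      " or adjusted p < ", x$config$alpha, ")\n", sep = "")
  if (nrow(sel)) {
    print(sel[, c("motif", "abundance", "p_raw", "p_adj",
                  "selection_reason")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.phage_discovery <- function(object, ...) {
  st <- object$stats
  out <- list(
    pool_size = object$pool_size,
    n_windows = 10L * object$pool_size,
    n_distinct = nrow(st),
    n_abundant = sum(st$abundance > object$config$abundance_threshold),
    n_significant = sum(!is.na(st$p_adj) &
                          st$p_adj < object$config$alpha),
    n_selected = sum(st$selected),
    extended = object$extended[, intersect(
      c("anchor", "consensus", "extended", "n_supporters"),
      names(object$extended)), drop = FALSE])
  class(out) <- "summary.phage_discovery"
  out
}

#' @export
print.summary.phage_discovery <- function(x, ...) {
  cat("pool:", x$pool_size, "peptides;", x$n_windows, "windows;",
      x$n_distinct, "distinct tripeptides\n")
  cat("abundant:", x$n_abundant, " significant:", x$n_significant,
      " selected:", x$n_selected, "\n")
  if (nrow(x$extended)) {
    cat("extended motifs:\n")
    print(x$extended, row.names = FALSE)
  }
  invisible(x)
}

#' Write the tripeptide motif table as TSV
#'
#' @param stats A \code{tripeptide_stats} frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_motif_table <- function(stats, path) {
  cols <- intersect(c("motif", "n_forward", "n_reverse", "abundance",
                      "p_raw", "p_adj", "selected", "selection_reason"),
                    names(stats))
  utils::write.table(as.data.frame(stats)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
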