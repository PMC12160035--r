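#' Phage titer from a plaque count
#'
#' Titer in plaque-forming units per ml from a plate count on a serial
#' dilution: \code{plaque_count * dilution_factor / volume_plated_ml}.
#' A dilution factor of \code{1e6} means the plated aliquot was a
#' 10^-6 dilution of the stock. Counts above 300 plaques are outside
#' the reliable countable range (plaques begin to merge and clear the
#' lawn) and trigger a warning.
#'
#' @param plaque_count Non-negative plaque count.
#' @param dilution_factor Positive dilution factor.
#' @param volume_plated_ml Positive plated volume in ml.
#' @return Titer in pfu/ml.
#' @examples
#' compute_titer(23, 1e6, 0.01)  # 2.3e9 pfu/ml
#' @export
compute_titer <- function(plaque_count, dilution_factor, volume_plated_ml) {
  if (any(dilution_factor <= 0) || any(volume_plated_ml <= 0)) {
    stop("domain error: dilution factor and plated volume must be positive")
  }
  if (any(plaque_count < 0)) {
    stop("domain error: plaque count cannot be negative")
  }
  if (any(plaque_count > 300)) {
    warning("plaque count above 300: outside the countable range, ",
            "consider a higher dilution")
  }
  plaque_count * dilution_factor / volume_plated_ml
}

#' Recovery rate of one biopanning round
#'
#' Recovered (target-bound) phage titer divided by input titer; a
#' dimensionless ratio, invariant to rescaling both titers.
#'
#' @param recovered_titer Recovered titer, pfu/ml.
#' @param input_titer Input titer, pfu/ml; must be positive.
#' @return The recovery rate.
#' @examples
#' recovery_rate(2.3e6, 2.5e9)  # 9.2e-4
#' @export
recovery_rate <- function(recovered_titer, input_titer) {
  if (any(input_titer <= 0)) {
    stop("domain error: input titer must be positive")
  }
  recovered_titer / input_titer
}

#' Round-wise enrichment profile and saturation flag
#'
#' Computes per-round recovery rates, enrichment relative to round 1,
#' and whether the selection has reached its saturation point: the
#' relative change in recovery rate between the last two rounds is at
#' most \code{saturation_tol}. Enrichment is always reported against
#' round 1 (the screen's summary statistic); consecutive-round change
#' only drives the saturation flag.
#'
#' @param rounds Data frame with columns \code{round_index},
#'   \code{input_titer}, \code{recovered_titer}, sorted by round,
#'   starting at round 1.
#' @param saturation_tol Relative-change tolerance (default 0.10).
#' @return A list with \code{rounds} (the input augmented with
#'   \code{recovery_rate} and \code{enrichment_vs_r1}) and
#'   \code{saturated} (\code{TRUE}/\code{FALSE}, or \code{NA} with
#'   fewer than two rounds).
#' @export
enrichment_profile <- function(rounds, saturation_tol = 0.10) {
  stopifnot(all(c("round_index", "input_titer", "recovered_titer") %in%
                  names(rounds)))
  if (is.unsorted(rounds$round_index) || rounds$round_index[1L] != 1L) {
    stop("rounds must be sorted by round_index starting at 1")
  }
  rounds$recovery_rate <- recovery_rate(rounds$recovered_titer,
                                        rounds$input_titer)
  rounds$enrichment_vs_r1 <- rounds$recovery_rate / rounds$recovery_rate[1L]
  n <- nrow(rounds)
  saturated <- if (n < 2L) {
    NA
  } else {
    delta <- abs(rounds$recovery_rate[n] - rounds$recovery_rate[n - 1L]) /
      rounds$recovery_rate[n - 1L]
    delta <= saturation_tol
  }
  list(rounds = rounds, saturated = saturated)
}

#' Classify ELISA-positive clones by stretched/static OD ratio
#'
#' A clone is positive when its OD450 on cyclic-stretch-activated cells
#' is at least \code{fold_threshold} times its OD450 on static cells
#' ("3-fold higher" is read boundary-inclusive). Records with a
#' non-positive static OD cannot be evaluated; they are flagged,
#' excluded from the summary denominator, and reported with a warning.
#'
#' @param records Data frame with columns \code{clone_id},
#'   \code{od_stretched}, \code{od_static}.
#' @param fold_threshold Positivity fold cut-off (default 3.0).
#' @return A list with \code{records} (augmented with \code{ratio},
#'   \code{positive}, \code{evaluable}) and \code{summary}
#'   (\code{n_positive}, \code{n_evaluable}, \code{n_unevaluable}).
#' @export
classify_positive <- function(records, fold_threshold = 3.0) {
  stopifnot(all(c("clone_id", "od_stretched", "od_static") %in%
                  names(records)))
  evaluable <- records$od_static > 0
  if (any(!evaluable)) {
    warning(sum(!evaluable), " record(s) with non-positive static OD ",
            "flagged unevaluable")
  }
  records$ratio <- ifelse(evaluable,
                          records$od_stretched / records$od_static,
                          NA_real_)
  records$positive <- ifelse(evaluable, records$ratio >= fold_threshold, NA)
  records$evaluable <- evaluable
  list(records = records,
       summary = list(n_positive = sum(records$positive, na.rm = TRUE),
                      n_evaluable = sum(evaluable),
                      n_unevaluable = sum(!evaluable)))
}

#' Fold change between two binding titers
#'
#' Ratio of a test titer to a reference titer, e.g. injured-organ vs
#' normal-organ binding of a displayed peptide, or motif phage vs
#' control phage.
#'
#' @param titer_test Test titer, pfu/ml.
#' @param titer_reference Positive reference titer, pfu/ml.
#' @return The dimensionless fold change.
#' @export
binding_fold_change <- function(titer_test, titer_reference) {
  if (any(titer_reference <= 0)) {
    stop("domain error: reference titer must be positive")
  }
  titer_test / titer_reference
}
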