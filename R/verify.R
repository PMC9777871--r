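#' Check a vitals sample against a stored identity profile
#'
#' The bedside verification loop: given the trained profile and baseline
#' for the presumed patient and one or more freshly observed vitals rows,
#' compute the average deviation of the network outputs from the profile's
#' target value and return a verdict:
#'
#' * `"consistent"` - deviation below the margin; vitals support the
#'   presumed identity.
#' * `"alert"` - deviation at or above the margin; possible
#'   misidentification (or a change in medical condition - both warrant
#'   human follow-up).
#' * `"learning"` - no profile yet; the system is still collecting data
#'   for this patient and cannot alert.
#'
#' @param profile A `gdes_profile`, or `NULL` when no profile exists yet.
#' @param baseline The profile's `gdes_baseline` (ignored when `profile` is
#'   `NULL`).
#' @param sample A tibble of observed rows with the four vital columns.
#' @param margin Deviation threshold; defaults to 0.025, the strongest
#'   margin in the standout comparisons.
#' @return A one-row tibble: `verdict`, `avg_deviation`, `margin`, `n_rows`.
#' @export
verify_patient <- function(profile, baseline, sample, margin = 0.025) {
  stopifnot(margin > 0)
  if (is.null(profile)) {
    return(tibble::tibble(
      verdict = "learning", avg_deviation = NA_real_,
      margin = margin, n_rows = 0L
    ))
  }
  stopifnot(inherits(profile, "gdes_profile"), inherits(baseline, "gdes_baseline"))
  sample <- as_cohort_tibble(sample)
  if (nrow(sample) == 0) stop("sample has no rows", call. = FALSE)
  x <- normalized_matrix(sample, profile$conversion)
  out <- net_eval_fast(
    profile_weights(profile$network),
    design_pair_idx(profile$config$set_no), x
  )
  avg_dev <- mean(abs(out - baseline$target_value))
  tibble::tibble(
    verdict = if (avg_dev < margin) "consistent" else "alert",
    avg_deviation = avg_dev,
    margin = margin,
    n_rows = nrow(sample)
  )
}
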