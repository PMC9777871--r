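#' Error margins used throughout the experiment
#'
#' A patient "falls within" a margin when their average output deviation is
#' strictly less than it.
#'
#' @format Numeric vector `c(0.01, 0.025, 0.05, 0.1)`.
#' @export
error_margins <- c(0.01, 0.025, 0.05, 0.1)

margin_col <- function(prefix, margin) {
  # element-wise format(): vectorized format() pads to a common width
  sprintf("%s_%s", prefix, vapply(margin, format, character(1)))
}

# Strict-inequality margin membership, centralized: a deviation exactly equal
# to the margin is NOT within it, and "Lowest" requires a strict minimum
# (ties count as N).
within_margin <- function(deviation, margin) deviation < margin

#' Summarize one trial's deviations
#'
#' Reduces per-patient deviations to the published summary-row layout:
#' the mean deviation over all patients (`average_error`), the target
#' patient's deviation (`avg_err`), whether the target is the strict
#' minimum (`lowest`), and per-margin flags (`correct_*`: is the target
#' strictly within the margin) and counts (`false_*`: how many non-target
#' patients are strictly within it).
#'
#' @param deviations Either the per-row tibble from [evaluate_cohort()] or a
#'   tibble with one `avg_deviation` per `patient_id`.
#' @param target_patient The trial's trained patient.
#' @param margins Error margins (default [error_margins]).
#' @return A one-row tibble.
#' @export
summarize_trial <- function(deviations, target_patient, margins = error_margins) {
  stopifnot(is.data.frame(deviations), "patient_id" %in% names(deviations))
  if (!"avg_deviation" %in% names(deviations)) {
    stopifnot("deviation" %in% names(deviations))
    deviations <- dplyr::summarise(
      dplyr::group_by(deviations, .data$patient_id),
      avg_deviation = mean(.data$deviation), .groups = "drop"
    )
  }
  if (anyDuplicated(deviations$patient_id)) {
    stop("duplicate patient ids in deviation records", call. = FALSE)
  }
  if (sum(deviations$patient_id == target_patient) != 1) {
    stop("target patient ", target_patient, " must appear exactly once", call. = FALSE)
  }
  target_dev <- deviations$avg_deviation[deviations$patient_id == target_patient]
  other_dev <- deviations$avg_deviation[deviations$patient_id != target_patient]

  out <- tibble::tibble(
    average_error = mean(deviations$avg_deviation),
    avg_err = target_dev,
    lowest = all(target_dev < other_dev)
  )
  for (m in margins) {
    out[[margin_col("correct", m)]] <- within_margin(target_dev, m)
  }
  for (m in margins) {
    out[[margin_col("false", m)]] <- sum(within_margin(other_dev, m))
  }
  out
}

#' Correct-to-incorrect ratio of a trial collection at one margin
#'
#' Over a collection of ten trials (one per target patient), counts the
#' trials whose target fell within the margin (`total_correct`), averages
#' the per-trial counts of non-target patients within it (`mean_false`),
#' and forms the ratio `total_correct / mean_false`. A collection where no
#' patient ever enters the margin has `mean_false = 0`; the ratio is then
#' reported as `NA` (the published analyses never divide by zero) with
#' `total_correct` still shown.
#'
#' @param rows Summary rows of one collection (normally 10, one per trial).
#' @param margin One error margin.
#' @return A one-row tibble: `margin`, `total_correct`, `mean_false`,
#'   `ratio` (raw), `ratio_rounded` (half-up to 2 decimals, the reported
#'   precision).
#' @examples
#' # a collection with 2 correct trials and 0.8 mean false matches → 2.5
#' @export
ratio_at_margin <- function(rows, margin) {
  c_col <- margin_col("correct", margin)
  f_col <- margin_col("false", margin)
  if (!all(c(c_col, f_col) %in% names(rows))) {
    stop("no flags for margin ", margin, " in summary rows", call. = FALSE)
  }
  correct <- rows[[c_col]]
  if (is.character(correct)) correct <- correct %in% c("Y", "y", "TRUE")
  total_correct <- sum(correct)
  mean_false <- mean(rows[[f_col]])
  ratio <- if (mean_false > 0) total_correct / mean_false else NA_real_
  tibble::tibble(
    margin = margin,
    total_correct = total_correct,
    mean_false = mean_false,
    ratio = ratio,
    ratio_rounded = round_half_up(ratio, 2)
  )
}

#' Per-margin metrics for a trial collection
#'
#' @param rows Summary rows of one collection.
#' @param margins Error margins (default [error_margins]).
#' @return A tibble with one row per margin (see [ratio_at_margin()]).
#' @export
collection_metrics <- function(rows, margins = error_margins) {
  purrr::map_dfr(margins, ~ ratio_at_margin(rows, .x))
}

# Finite comparison score for a collection at a margin: floors mean_false at
# 0.1 (the smallest nonzero value a ten-trial collection can show) so
# configurations can be ranked even when no false matches occurred.
ratio_score <- function(rows, margin) {
  m <- ratio_at_margin(rows, margin)
  m$total_correct / max(m$mean_false, 0.1)
}

#' Standout comparison across collections
#'
#' For each trial collection, picks the error margin with the highest
#' correct-to-incorrect ratio (among margins with at least `floor` correct
#' trials and a nonzero false-match mean) and lays the winners out side by
#' side, sorted by ratio.
#'
#' @param results Experiment results from [run_experiment()], or any tibble
#'   of summary rows carrying `set_no`, `trials`, `pr_approach` and
#'   `default_fact_value` columns.
#' @param floor Minimum `total_correct` a margin needs to qualify
#'   (default 1).
#' @return A tibble with one row per collection that has a qualifying
#'   margin: `set_no`, `default_fact_value`, `pr_approach`, `best_margin`,
#'   `correct_patients`, `avg_incorrect`, `ratio`, `ratio_rounded`.
#' @export
standout_table <- function(results, floor = 1) {
  keys <- dplyr::distinct(
    results, .data$set_no, .data$trials, .data$pr_approach
  )
  rows <- purrr::pmap_dfr(keys, function(set_no, trials, pr_approach) {
    collection <- dplyr::filter(
      results,
      .data$set_no == !!set_no, .data$trials == !!trials,
      .data$pr_approach == !!pr_approach
    )
    metrics <- collection_metrics(collection)
    metrics <- dplyr::filter(
      metrics, .data$total_correct >= floor, !is.na(.data$ratio)
    )
    if (nrow(metrics) == 0) {
      return(NULL)
    }
    best <- metrics[order(-metrics$ratio, metrics$margin), ][1, ]
    tibble::tibble(
      set_no = set_no,
      trials = trials,
      default_fact_value = collection$default_fact_value[1],
      pr_approach = pr_approach,
      best_margin = best$margin,
      correct_patients = best$total_correct,
      avg_incorrect = best$mean_false,
      ratio = best$ratio,
      ratio_rounded = best$ratio_rounded
    )
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(
      set_no = integer(), trials = character(),
      default_fact_value = numeric(), pr_approach = character(),
      best_margin = numeric(), correct_patients = integer(),
      avg_incorrect = numeric(), ratio = numeric(), ratio_rounded = numeric()
    ))
  }
  dplyr::arrange(rows, dplyr::desc(.data$ratio), .data$set_no)
}

#' Published reference summary tables
#'
#' Transcription of the reference study's printed per-trial summary tables
#' (eleven collections across the three network designs), shipped as a
#' plain-text fixture for regression-testing the metric arithmetic.
#'
#' @return A tibble with one row per trial: collection identity columns
#'   (`table_id`, `set_no`, `trials`, `pr_approach`, `conversion_method`,
#'   `default_fact_value`), `trial_no`, `average_error`, `avg_err`,
#'   `lowest`, and per-margin `correct_*` / `false_*` columns.
#' @export
read_reference_tables <- function() {
  path <- system.file("extdata", "reference_trial_tables.csv", package = "vitalid")
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  dplyr::mutate(
    raw,
    lowest = .data$lowest == "Y",
    dplyr::across(dplyr::starts_with("correct_"), ~ .x == "Y")
  )
}
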