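#' Plot per-patient deviations from the profile target
#'
#' One point per patient and test row plus the per-patient mean, with the
#' error margins drawn as horizontal lines. The trained patient should sit
#' below the margin of interest; impostors above it.
#'
#' @param object The evaluation tibble from [evaluate_cohort()].
#' @param target_patient Patient id to highlight.
#' @param margins Margins to draw (default [error_margins]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gdes_evaluation <- function(object, target_patient = NULL,
                                     margins = error_margins, ...) {
  plot_deviations(object, target_patient = target_patient, margins = margins)
}

#' @rdname autoplot.gdes_evaluation
#' @param data The evaluation tibble from [evaluate_cohort()].
#' @export
plot_deviations <- function(data, target_patient = NULL, margins = error_margins) {
  stopifnot(all(c("patient_id", "deviation") %in% names(data)))
  means <- dplyr::summarise(
    dplyr::group_by(data, .data$patient_id),
    avg_deviation = mean(.data$deviation), .groups = "drop"
  )
  data$role <- if (is.null(target_patient)) {
    "patient"
  } else {
    ifelse(data$patient_id == target_patient, "target", "other")
  }
  ggplot2::ggplot(data, ggplot2::aes(
    x = factor(.data$patient_id), y = .data$deviation
  )) +
    ggplot2::geom_hline(
      yintercept = margins, linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$role), alpha = 0.6) +
    ggplot2::geom_point(
      data = dplyr::mutate(means, role = NULL),
      ggplot2::aes(y = .data$avg_deviation),
      shape = 3, size = 3, inherit.aes = TRUE
    ) +
    ggplot2::labs(
      x = "patient", y = "|output - target value|",
      colour = NULL,
      title = "Deviation from the trained profile's target value"
    ) +
    ggplot2::theme_minimal()
}

#' Plot correct-to-incorrect ratios across collections
#'
#' @param results Experiment results from [run_experiment()].
#' @param margins Margins to include (default [error_margins]).
#' @return A ggplot object: ratio by margin, faceted by network design.
#' @export
plot_collection_ratios <- function(results, margins = error_margins) {
  keys <- dplyr::distinct(
    results, .data$set_no, .data$trials, .data$pr_approach
  )
  ratios <- purrr::pmap_dfr(keys, function(set_no, trials, pr_approach) {
    rows <- dplyr::filter(
      results,
      .data$set_no == !!set_no, .data$trials == !!trials,
      .data$pr_approach == !!pr_approach
    )
    dplyr::mutate(
      collection_metrics(rows, margins),
      set_no = set_no, trials = trials, pr_approach = pr_approach
    )
  })
  finite <- dplyr::filter(ratios, !is.na(.data$ratio))
  if (nrow(finite) == 0) {
    return(
      ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0, label = "no finite ratios (no patients within any margin)") +
        ggplot2::theme_void()
    )
  }
  ggplot2::ggplot(
    finite,
    ggplot2::aes(
      x = factor(.data$margin), y = .data$ratio,
      colour = .data$pr_approach, shape = .data$trials
    )
  ) +
    ggplot2::geom_point(size = 2, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~set_no, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "error margin", y = "correct-to-incorrect ratio",
      title = "Collection performance by margin"
    ) +
    ggplot2::theme_minimal()
}
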