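pr_approaches <- c("fixed_single", "actual_last_bp", "fixed_all_facts", "averaged_facts")

#' One experimental trial cell
#'
#' Trial numbering fixes most of the cell: the target patient cycles 1-10
#' within each block of ten trials; trials 11-20 use the isolated data
#' conversion method and all others the comprehensive method; the default
#' fact value is 0.500 for trials 1-20, 0.600 for 21-30, 0.700 for 31-40 and
#' 0.550 for 41-50. The network design (`set_no`) and the baseline recipe
#' (`pr_approach`) are free axes: each trial is run for all three designs,
#' and each design for all four recipes.
#'
#' @param trial_no Trial number, 1-50.
#' @param set_no Network design, 1-3.
#' @param pr_approach One of `"fixed_single"` (PR with the default value as
#'   the blood-pressure input), `"actual_last_bp"` (PR with the last
#'   training row's blood pressure, other facts left at their last trained
#'   values), `"fixed_all_facts"` (all four inputs set to the default value
#'   before the PR) or `"averaged_facts"` (inputs set to their
#'   training-period means).
#' @return A `trial_config` list with the derived fields
#'   `conversion_method`, `default_fact_value` and `target_patient`.
#' @examples
#' trial_config(23, set_no = 3, pr_approach = "actual_last_bp")
#' @export
trial_config <- function(trial_no, set_no, pr_approach = "fixed_single") {
  stopifnot(length(trial_no) == 1, trial_no %in% 1:50, set_no %in% 1:3)
  pr_approach <- match.arg(pr_approach, pr_approaches)
  trial_no <- as.integer(trial_no)
  structure(
    list(
      trial_no = trial_no,
      set_no = as.integer(set_no),
      pr_approach = pr_approach,
      conversion_method = trial_conversion(trial_no),
      default_fact_value = trial_default_value(trial_no),
      target_patient = trial_target_patient(trial_no)
    ),
    class = "trial_config"
  )
}

trial_conversion <- function(trial_no) {
  ifelse(trial_no >= 11 & trial_no <= 20, "isolated", "comprehensive")
}

trial_default_value <- function(trial_no) {
  dplyr::case_when(
    trial_no <= 20 ~ 0.5,
    trial_no <= 30 ~ 0.6,
    trial_no <= 40 ~ 0.7,
    TRUE ~ 0.55
  )
}

trial_target_patient <- function(trial_no) {
  as.integer((trial_no - 1) %% 10 + 1)
}

trial_decade <- function(trial_no) {
  lo <- ((trial_no - 1) %/% 10) * 10 + 1
  sprintf("%d-%d", lo, lo + 9)
}

#' Build a grid of trial configurations
#'
#' @param sets Network designs to include (default all three).
#' @param trials Trial numbers to include (default 1-50).
#' @param approaches Baseline recipes to include (default all four).
#' @return A tibble with one row per trial execution (`sets` x `trials` x
#'   `approaches`) carrying all derived trial fields.
#' @export
trial_grid <- function(sets = 1:3, trials = 1:50, approaches = pr_approaches) {
  stopifnot(all(sets %in% 1:3), all(trials %in% 1:50))
  approaches <- match.arg(approaches, pr_approaches, several.ok = TRUE)
  tidyr::crossing(
    set_no = as.integer(sets),
    trial_no = as.integer(trials),
    pr_approach = approaches
  ) |>
    dplyr::mutate(
      conversion_method = trial_conversion(.data$trial_no),
      default_fact_value = trial_default_value(.data$trial_no),
      target_patient = trial_target_patient(.data$trial_no),
      trials = trial_decade(.data$trial_no)
    )
}

# Normalized + protocol-quantized (hr, etco2, rr, bp) matrix for a set of rows.
normalized_matrix <- function(rows, conversion) {
  rows <- normalize_cohort(rows, conversion)
  m <- cbind(
    rows$heart_rate, rows$etco2, rows$resp_rate, rows$blood_pressure
  )
  matrix(quantize_value(m), ncol = 4,
    dimnames = list(NULL, vital_channels)
  )
}

# Vectorized forward pass for the fixed two-level topology.
net_eval_fast <- function(weights, pair_idx, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  f1 <- weights[1] * x[, pair_idx$rule1[1]] + weights[2] * x[, pair_idx$rule1[2]]
  f2 <- weights[3] * x[, pair_idx$rule2[1]] + weights[4] * x[, pair_idx$rule2[2]]
  weights[5] * f1 + weights[6] * f2
}

profile_weights <- function(network) {
  c(rbind(network$rules$w1, network$rules$w2))
}

#' Train a patient identity profile
#'
#' Replays the training protocol over the target patient's training segment:
#' for each row in time order, the four normalized vitals are set (SF) and
#' one training update (TR) is run from the blood-pressure start fact toward
#' the fixed target 0.500, the midpoint of the output range. Normalized
#' values are quantized to the protocol's three decimals, so direct training
#' and command-script replay agree bit for bit.
#'
#' @param config A [trial_config()].
#' @param cohort A cohort tibble or `vitalid_cohort`.
#' @param velocity Learning rate (default 0.1).
#' @param every_k Train on every k-th row (default 1 = all rows); a
#'   reduced-scale mode for fast runs.
#' @param engine `"compiled"` (Rcpp loop over the fixed topology) or
#'   `"reference"` (the generic R network engine, one command at a time).
#'   Both produce identical weights.
#' @param emit_script If `TRUE`, attach the full SF/TR command script to the
#'   profile for audit/replay.
#' @param conversion Optional precomputed `conversion_spec`; computed from
#'   the cohort per the trial's conversion method when `NULL`.
#' @param training_segment Segment id holding training data (default 4).
#' @return A `gdes_profile`: trained network plus the conversion spec, the
#'   last and mean normalized training inputs, and bookkeeping.
#' @export
train_profile <- function(config, cohort, velocity = 0.1, every_k = 1L,
                          engine = c("compiled", "reference"),
                          emit_script = FALSE, conversion = NULL,
                          training_segment = 4L) {
  stopifnot(inherits(config, "trial_config"), velocity > 0, every_k >= 1)
  engine <- match.arg(engine)
  cohort <- as_cohort_tibble(cohort)
  conversion <- conversion %||% compute_divisors(
    cohort,
    method = config$conversion_method,
    target_patient = config$target_patient,
    training_segment = training_segment
  )
  series <- dplyr::filter(
    cohort,
    .data$patient_id == config$target_patient,
    .data$segment_id == training_segment
  )
  if (nrow(series) == 0) {
    stop("no training segment ", training_segment, " for patient ",
      config$target_patient,
      call. = FALSE
    )
  }
  rows <- select_rows(series, "training")
  keep <- seq(1L, nrow(rows), by = as.integer(every_k))
  x <- normalized_matrix(rows[keep, ], conversion)

  net <- build_network(config$set_no, default_fact_value = config$default_fact_value)
  pair_idx <- design_pair_idx(config$set_no)

  if (engine == "compiled") {
    fit <- gdes_train_loop_cpp(
      x, pair_idx$rule1, pair_idx$rule2,
      w0 = rep(0.5, 6), target = 0.5, velocity = velocity
    )
    net$rules$w1 <- fit$weights[c(1, 3, 5)]
    net$rules$w2 <- fit$weights[c(2, 4, 6)]
    for (ch in vital_channels) {
      net <- set_fact(net, unname(net$channel_map[ch]), x[nrow(x), ch])
    }
    net <- propagate(net)
  } else {
    for (i in seq_len(nrow(x))) {
      for (ch in vital_channels) {
        net <- set_fact(net, unname(net$channel_map[ch]), x[i, ch])
      }
      net <- train_step(net,
        start_value = x[i, "blood_pressure"],
        target = 0.5, velocity = velocity
      )$network
    }
  }

  script <- NULL
  if (emit_script) {
    sf <- sapply(vital_channels, function(ch) {
      sprintf("SF:{%s}=%s", net$channel_map[[ch]], format_gdes_value(x[, ch]))
    })
    tr <- sprintf(
      "TR:{%s},{%s}=%s", net$start_fact_guid, net$output_fact_guid,
      format_gdes_value(x[, "blood_pressure"])
    )
    script <- as.vector(t(cbind(sf, tr)))
  }

  structure(
    list(
      network = net,
      config = config,
      conversion = conversion,
      velocity = velocity,
      every_k = as.integer(every_k),
      n_rows_used = nrow(x),
      last_inputs = x[nrow(x), ],
      mean_inputs = colMeans(x),
      script = script
    ),
    class = "gdes_profile"
  )
}

#' @export
print.gdes_profile <- function(x, ...) {
  cat(
    "<gdes_profile> patient", x$config$target_patient,
    "- design", x$config$set_no,
    paste0("(", x$conversion$method, " conversion,"),
    x$n_rows_used, "training rows)\n"
  )
  invisible(x)
}

#' @export
tidy.gdes_profile <- function(x, ...) tidy(x$network)

#' @export
glance.gdes_profile <- function(x, ...) {
  tibble::tibble(
    target_patient = x$config$target_patient,
    design_id = x$config$set_no,
    conversion_method = x$conversion$method,
    velocity = x$velocity,
    n_training_rows = x$n_rows_used
  )
}

#' Generate the baseline target value for a trained profile
#'
#' After training, a single presentation (PR) produces the *initial training
#' output value* - the target every later test output is compared against.
#' Four recipes are supported (see [trial_config()] for their meanings).
#' Values set by fixed recipes are the trial's default fact value unless
#' overridden.
#'
#' @param profile A `gdes_profile` from [train_profile()].
#' @param approach Baseline recipe; defaults to the profile's configured
#'   one.
#' @param default_value Value used by the fixed recipes; defaults to the
#'   trial's default fact value.
#' @return A `gdes_baseline`: a list with `target_value`, the recipe used,
#'   and the trained network.
#' @export
compute_baseline <- function(profile, approach = NULL, default_value = NULL) {
  stopifnot(inherits(profile, "gdes_profile"))
  approach <- match.arg(approach %||% profile$config$pr_approach, pr_approaches)
  default_value <- default_value %||% profile$config$default_fact_value
  stopifnot(default_value >= 0, default_value <= 1)
  default_value <- quantize_value(default_value)

  x <- switch(approach,
    fixed_single = {
      inp <- profile$last_inputs
      inp["blood_pressure"] <- default_value
      inp
    },
    actual_last_bp = profile$last_inputs,
    fixed_all_facts = setNames(rep(default_value, 4), vital_channels),
    averaged_facts = setNames(
      quantize_value(profile$mean_inputs[vital_channels]), vital_channels
    )
  )
  target_value <- net_eval_fast(
    profile_weights(profile$network),
    design_pair_idx(profile$config$set_no),
    x[vital_channels]
  )
  structure(
    list(
      target_value = as.numeric(target_value),
      approach = approach,
      inputs = x[vital_channels],
      network = profile$network
    ),
    class = "gdes_baseline"
  )
}

#' Evaluate all patients against a trained profile
#'
#' Takes the seven fixed test rows of every patient's test segment,
#' normalizes them with the profile's conversion spec, presents each row to
#' the trained network (four SFs then a PR from the blood-pressure fact),
#' and records the absolute deviation of each output from the baseline
#' target value. Intermediate facts are reset to 0.500 between runs; since
#' every input fact is set fresh each run, this affects replayed scripts,
#' not outputs.
#'
#' @param profile A `gdes_profile`.
#' @param baseline A `gdes_baseline` from [compute_baseline()].
#' @param cohort A cohort tibble or `vitalid_cohort`.
#' @param test_segment Segment id holding test data (default 7).
#' @return A tibble with one row per patient x test row: `patient_id`,
#'   `test_row` (1-7), `output`, `deviation`.
#' @export
evaluate_cohort <- function(profile, baseline, cohort, test_segment = 7L) {
  stopifnot(inherits(profile, "gdes_profile"), inherits(baseline, "gdes_baseline"))
  cohort <- as_cohort_tibble(cohort)
  test <- dplyr::filter(cohort, .data$segment_id == test_segment)
  if (nrow(test) == 0) {
    stop("cohort has no rows for test segment ", test_segment, call. = FALSE)
  }
  weights <- profile_weights(profile$network)
  pair_idx <- design_pair_idx(profile$config$set_no)
  patients <- sort(unique(test$patient_id))
  out <- purrr::map_dfr(patients, function(p) {
    rows <- select_rows(dplyr::filter(test, .data$patient_id == p), "test")
    x <- normalized_matrix(rows, profile$conversion)
    out <- net_eval_fast(weights, pair_idx, x)
    tibble::tibble(
      patient_id = p,
      test_row = seq_along(out),
      output = out,
      deviation = abs(out - baseline$target_value)
    )
  })
  class(out) <- c("gdes_evaluation", class(out))
  out
}

#' Run one trial end to end
#'
#' Trains the target patient's profile, generates the baseline target value
#' and evaluates every patient, returning the trial's summary row.
#'
#' @inheritParams train_profile
#' @param margins Error margins for the summary flags.
#' @return A one-row tibble: trial identity columns plus the columns of
#'   [summarize_trial()].
#' @export
run_trial <- function(config, cohort, velocity = 0.1, every_k = 1L,
                      conversion = NULL, margins = error_margins) {
  profile <- train_profile(config, cohort,
    velocity = velocity,
    every_k = every_k, conversion = conversion
  )
  baseline <- compute_baseline(profile)
  evals <- evaluate_cohort(profile, baseline, cohort)
  summary <- summarize_trial(evals, config$target_patient, margins = margins)
  dplyr::bind_cols(
    tibble::tibble(
      set_no = config$set_no,
      trial_no = config$trial_no,
      trials = trial_decade(config$trial_no),
      pr_approach = config$pr_approach,
      conversion_method = config$conversion_method,
      default_fact_value = config$default_fact_value,
      target_patient = config$target_patient,
      target_value = baseline$target_value
    ),
    summary
  )
}

#' Run a grid of trials
#'
#' Executes every (design, trial, baseline recipe) cell of the grid. The
#' full grid is 50 trials x 3 designs x 4 recipes = 600 executions; since
#' training does not depend on the baseline recipe, each (design, trial)
#' pair is trained once and re-evaluated under each recipe.
#'
#' @param cohort A cohort tibble or `vitalid_cohort` with at least as many
#'   patients as the largest target patient in the grid.
#' @param grid A grid from [trial_grid()] (default: the full grid).
#' @inheritParams train_profile
#' @param margins Error margins for the summary flags.
#' @return A tibble with one summary row per execution; split it with
#'   [experiment_tables()] to get the per-collection tables.
#' @export
run_experiment <- function(cohort, grid = trial_grid(), velocity = 0.1,
                           every_k = 1L, margins = error_margins) {
  cohort <- as_cohort_tibble(cohort)
  needed <- unique(grid$target_patient)
  have <- unique(cohort$patient_id)
  if (!all(needed %in% have)) {
    stop("cohort is missing patient(s): ",
      paste(setdiff(needed, have), collapse = ", "),
      call. = FALSE
    )
  }
  # divisors are a pure function of (method, target); compute each once
  conversions <- list(
    comprehensive = compute_divisors(cohort, "comprehensive")
  )
  for (p in unique(grid$target_patient[grid$conversion_method == "isolated"])) {
    conversions[[paste0("isolated_", p)]] <-
      compute_divisors(cohort, "isolated", target_patient = p)
  }
  cells <- dplyr::distinct(grid, .data$set_no, .data$trial_no)
  purrr::pmap_dfr(cells, function(set_no, trial_no) {
    approaches <- grid$pr_approach[grid$set_no == set_no & grid$trial_no == trial_no]
    config <- trial_config(trial_no, set_no, approaches[1])
    conv_key <- if (config$conversion_method == "isolated") {
      paste0("isolated_", config$target_patient)
    } else {
      "comprehensive"
    }
    profile <- train_profile(config, cohort,
      velocity = velocity, every_k = every_k,
      conversion = conversions[[conv_key]]
    )
    purrr::map_dfr(approaches, function(appr) {
      cfg <- trial_config(trial_no, set_no, appr)
      baseline <- compute_baseline(profile, approach = appr)
      evals <- evaluate_cohort(profile, baseline, cohort)
      summary <- summarize_trial(evals, cfg$target_patient, margins = margins)
      dplyr::bind_cols(
        tibble::tibble(
          set_no = cfg$set_no,
          trial_no = cfg$trial_no,
          trials = trial_decade(cfg$trial_no),
          pr_approach = appr,
          conversion_method = cfg$conversion_method,
          default_fact_value = cfg$default_fact_value,
          target_patient = cfg$target_patient,
          target_value = baseline$target_value
        ),
        summary
      )
    })
  })
}

#' Split experiment results into per-collection tables
#'
#' A collection is a block of ten trials sharing a design, trial decade and
#' baseline recipe - one published-style summary table. The full grid
#' yields 60 tables.
#'
#' @param results Output of [run_experiment()].
#' @return A named list of tibbles in the published column layout
#'   (`Average Error`, `Avg Err`, `Lowest`, `Correct at` and `False at`
#'   each margin).
#' @export
experiment_tables <- function(results) {
  keys <- dplyr::distinct(
    results, .data$set_no, .data$trials, .data$pr_approach
  ) |>
    dplyr::arrange(.data$set_no, .data$trials, .data$pr_approach)
  tables <- purrr::pmap(keys, function(set_no, trials, pr_approach) {
    rows <- dplyr::filter(
      results,
      .data$set_no == !!set_no, .data$trials == !!trials,
      .data$pr_approach == !!pr_approach
    ) |>
      dplyr::arrange(.data$trial_no)
    render_summary_table(rows)
  })
  names(tables) <- sprintf(
    "set%d_trials%s_%s", keys$set_no, gsub("-", "_", keys$trials), keys$pr_approach
  )
  tables
}

render_summary_table <- function(rows) {
  yn <- function(x) ifelse(x, "Y", "N")
  out <- tibble::tibble(
    `Average Error` = round_half_up(rows$average_error, 3),
    `Avg Err` = round_half_up(rows$avg_err, 3),
    `Lowest` = yn(rows$lowest)
  )
  for (m in error_margins) {
    out[[sprintf("Correct at %s", format(m))]] <- yn(rows[[margin_col("correct", m)]])
  }
  for (m in error_margins) {
    out[[sprintf("False at %s", format(m))]] <- rows[[margin_col("false", m)]]
  }
  out
}

#' Write per-collection result tables to CSV
#'
#' @param results Output of [run_experiment()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the written paths.
#' @export
write_experiment_tables <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- experiment_tables(results)
  paths <- vapply(names(tables), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], path, progress = FALSE)
    path
  }, character(1))
  invisible(paths)
}
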