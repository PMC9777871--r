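vital_bounds <- list(
  heart_rate = c(30, 180),
  etco2 = c(15, 60),
  resp_rate = c(4, 40),
  blood_pressure = c(40, 200)
)

# Population resting/anesthesia means and, at separation = 1, the SD of the
# inter-patient baseline spread around them.
population_means <- c(heart_rate = 75, etco2 = 38, resp_rate = 14, blood_pressure = 85)
population_sds <- c(heart_rate = 15, etco2 = 4, resp_rate = 3, blood_pressure = 12)
# Per-step wander calibrated to the within-patient stability of anesthesia
# monitor records: a ~2 bpm random-walk SD per 10-minute segment for heart
# rate, with ventilator-controlled RR and ETCO2 nearly constant.
default_wander_sd <- c(heart_rate = 0.15, etco2 = 0.05, resp_rate = 0.03, blood_pressure = 0.15)

#' Parameters for one synthetic patient
#'
#' @param baselines Named per-vital means: `heart_rate` (bpm), `etco2`
#'   (mmHg), `resp_rate` (breaths/min), `blood_pressure` (mmHg). Must lie
#'   within physiological bounds (HR 30-180, ETCO2 15-60, RR 4-40,
#'   BP 40-200).
#' @param wander_sd Named per-vital SD of each step of the slow drift.
#' @param hold_duration Mean run length of repeated values, in seconds.
#'   Monitor exports hold a reading constant for seconds at a time, so a
#'   10-minute file contains only a handful of unique values per channel.
#' @param seed Integer RNG seed for this patient.
#' @return A `patient_params` list.
#' @export
patient_params <- function(baselines = population_means,
                           wander_sd = default_wander_sd,
                           hold_duration = 5, seed = 1L) {
  stopifnot(
    all(vital_channels %in% names(baselines)),
    all(vital_channels %in% names(wander_sd)),
    hold_duration > 0, all(wander_sd >= 0)
  )
  for (ch in vital_channels) {
    b <- vital_bounds[[ch]]
    if (baselines[[ch]] < b[1] || baselines[[ch]] > b[2]) {
      stop("baseline ", ch, " = ", baselines[[ch]],
        " outside physiological bounds [", b[1], ", ", b[2], "]",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      baselines = baselines[vital_channels],
      wander_sd = wander_sd[vital_channels],
      hold_duration = hold_duration,
      seed = as.integer(seed)
    ),
    class = "patient_params"
  )
}

# One channel: piecewise-constant random walk at 100 Hz.  The value is held
# for an exponentially distributed duration (mean hold_duration seconds),
# then stepped by a N(0, wander_sd) draw and clamped to the channel's
# physiological bounds.
generate_channel <- function(n_rows, baseline, wander_sd, hold_duration, bounds) {
  if (wander_sd == 0) {
    return(rep(baseline, n_rows))
  }
  values <- numeric(0)
  lengths <- integer(0)
  v <- baseline
  total <- 0L
  while (total < n_rows) {
    len <- max(1L, as.integer(round(rexp(1, rate = 1 / hold_duration) * 100)))
    values <- c(values, v)
    lengths <- c(lengths, len)
    total <- total + len
    v <- min(max(v + rnorm(1, 0, wander_sd), bounds[1]), bounds[2])
  }
  rep(values, lengths)[seq_len(n_rows)]
}

#' Generate one patient's 10-minute segment
#'
#' Each vital is an independent piecewise-constant random walk (see
#' [patient_params()]). Heart rate and respiratory rate are reported as
#' integers, ETCO2 and blood pressure to one decimal, matching monitor
#' export resolution. The RNG stream is derived from the patient seed and
#' the segment id, so any segment is reproducible in isolation.
#'
#' @param params A `patient_params`.
#' @param segment_id 10-minute file index: segment 4 covers 30:00.00 to
#'   39:59.99, segment 7 covers 1:00:00.00 to 1:09:59.99.
#' @param patient_id,case_id Identifiers stamped onto the rows.
#' @param n_rows Rows to generate (default the full 60,000).
#' @return A cohort tibble of one patient-segment.
#' @export
generate_patient <- function(params, segment_id, patient_id = 1L,
                             case_id = rah_case_ids(patient_id)[patient_id],
                             n_rows = 60000L) {
  stopifnot(inherits(params, "patient_params"), n_rows >= 1)
  withr_seed <- child_seed(params$seed, segment_id)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(withr_seed)

  start_cs <- (segment_id - 1L) * 60000L
  chans <- lapply(vital_channels, function(ch) {
    x <- generate_channel(
      n_rows, params$baselines[[ch]], params$wander_sd[[ch]],
      params$hold_duration, vital_bounds[[ch]]
    )
    if (ch %in% c("heart_rate", "resp_rate")) round(x) else round(x, 1)
  })
  names(chans) <- vital_channels
  tibble::tibble(
    case_id = as.integer(case_id),
    patient_id = as.integer(patient_id),
    segment_id = as.integer(segment_id),
    time_cs = start_cs + seq_len(n_rows) - 1L,
    heart_rate = chans$heart_rate,
    etco2 = chans$etco2,
    resp_rate = chans$resp_rate,
    blood_pressure = chans$blood_pressure
  )
}

#' Specification of a synthetic cohort
#'
#' @param n_patients Number of patients (>= 2 for misidentification
#'   experiments; a warning is raised below that).
#' @param separation Non-negative scalar scaling the inter-patient baseline
#'   spread; 0 gives identical baselines (the worst case for detection), 1
#'   gives realistic population spread.
#' @param segment_ids 10-minute files to emit (default training segment 4
#'   and test segment 7).
#' @param master_seed Integer seed; everything downstream is a pure function
#'   of it.
#' @param n_rows Rows per segment (default 60,000 = 10 min at 100 Hz).
#' @param hold_duration Mean run length of repeated values, seconds.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 10L, separation = 1,
                        segment_ids = c(4L, 7L), master_seed = 1L,
                        n_rows = 60000L, hold_duration = 5) {
  stopifnot(n_patients >= 1, separation >= 0, n_rows >= 1)
  if (n_patients < 2) {
    warning("misidentification experiments need at least 2 patients", call. = FALSE)
  }
  structure(
    list(
      n_patients = as.integer(n_patients), separation = separation,
      segment_ids = as.integer(segment_ids),
      master_seed = as.integer(master_seed),
      n_rows = as.integer(n_rows), hold_duration = hold_duration
    ),
    class = "cohort_spec"
  )
}

#' Generate a seeded synthetic cohort
#'
#' Draws per-patient baselines around the population means with spread
#' `separation * population SD` (clamped inside physiological bounds), then
#' generates every requested segment per patient. The manifest records the
#' ground-truth parameters and per-patient seeds.
#'
#' @param spec A [cohort_spec()].
#' @return A `vitalid_cohort`: a list with `vitals` (one tibble of all rows)
#'   and `manifest` (one row per patient with seeds and baselines).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 2, n_rows = 100))
#' cohort$manifest
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$master_seed)

  n <- spec$n_patients
  case_ids <- rah_case_ids(n)
  baselines <- sapply(vital_channels, function(ch) {
    b <- vital_bounds[[ch]]
    # keep a drift margin inside the hard bounds so walks rarely saturate
    margin <- 0.05 * (b[2] - b[1])
    pmin(
      pmax(
        population_means[[ch]] + spec$separation * population_sds[[ch]] * rnorm(n),
        b[1] + margin
      ),
      b[2] - margin
    )
  })
  baselines <- matrix(baselines, nrow = n, dimnames = list(NULL, vital_channels))
  seeds <- vapply(seq_len(n), function(i) child_seed(spec$master_seed, 7919L, i), integer(1))

  manifest <- tibble::tibble(
    patient_id = seq_len(n),
    case_id = case_ids,
    seed = seeds,
    hold_duration = spec$hold_duration,
    hr_baseline = baselines[, "heart_rate"],
    etco2_baseline = baselines[, "etco2"],
    rr_baseline = baselines[, "resp_rate"],
    bp_baseline = baselines[, "blood_pressure"],
    hr_wander_sd = default_wander_sd[["heart_rate"]],
    etco2_wander_sd = default_wander_sd[["etco2"]],
    rr_wander_sd = default_wander_sd[["resp_rate"]],
    bp_wander_sd = default_wander_sd[["blood_pressure"]]
  )

  vitals <- purrr::map_dfr(seq_len(n), function(i) {
    params <- patient_params(
      baselines = setNames(baselines[i, ], vital_channels),
      hold_duration = spec$hold_duration,
      seed = seeds[i]
    )
    purrr::map_dfr(
      spec$segment_ids,
      ~ generate_patient(params, .x,
        patient_id = i, case_id = case_ids[i],
        n_rows = spec$n_rows
      )
    )
  })
  structure(
    list(vitals = vitals, manifest = manifest, spec = spec),
    class = "vitalid_cohort"
  )
}

#' @export
print.vitalid_cohort <- function(x, ...) {
  cat(
    "<vitalid_cohort>", nrow(x$manifest), "patients,",
    length(unique(x$vitals$segment_id)), "segment(s),",
    nrow(x$vitals), "rows\n"
  )
  invisible(x)
}

#' Write a cohort to case CSV files
#'
#' Emits one `uq_vsd_caseNN_fulldata_MM.csv` per patient-segment (two header
#' lines, then one row per centisecond; a full segment file has 60,002
#' lines) plus a `manifest.yaml` with the ground-truth generator parameters.
#'
#' @param cohort A `vitalid_cohort` (or plain cohort tibble).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the written file paths.
#' @export
write_case_files <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vitals <- as_cohort_tibble(cohort)
  if (nrow(vitals) == 0) {
    warning("empty cohort; no files written", call. = FALSE)
    return(invisible(character(0)))
  }
  groups <- dplyr::group_split(dplyr::group_by(vitals, .data$case_id, .data$segment_id))
  paths <- vapply(groups, function(g) {
    path <- file.path(dir, case_file_name(g$case_id[1], g$segment_id[1]))
    header <- c(
      sprintf(
        "uq_vsd_case%02d,segment %02d,100 Hz,,",
        g$case_id[1], g$segment_id[1]
      ),
      "Time,HR,ETCO2,RR,MAP"
    )
    body <- sprintf(
      "%s,%s,%s,%s,%s",
      format_time_cs(g$time_cs),
      format(g$heart_rate, trim = TRUE, scientific = FALSE),
      format(g$etco2, trim = TRUE, scientific = FALSE),
      format(g$resp_rate, trim = TRUE, scientific = FALSE),
      format(g$blood_pressure, trim = TRUE, scientific = FALSE)
    )
    readr::write_lines(c(header, body), path)
    path
  }, character(1))
  if (inherits(cohort, "vitalid_cohort")) {
    yaml::write_yaml(
      list(
        spec = unclass(cohort$spec),
        patients = lapply(
          seq_len(nrow(cohort$manifest)),
          function(i) as.list(cohort$manifest[i, ])
        )
      ),
      file.path(dir, "manifest.yaml")
    )
  }
  invisible(paths)
}
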