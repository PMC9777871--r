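#' Column mapping for case CSV files
#'
#' Case files are 100 Hz monitor exports with two header lines (a metadata
#' line, then column names) and one row per centisecond. The reader is
#' tolerant of extra columns and takes the four vitals from named columns.
#' Monitor exports carry several pressure channels; which one stands in for
#' "blood pressure" is configurable and defaults to mean arterial pressure
#' (`MAP`).
#'
#' @param time,heart_rate,etco2,resp_rate,blood_pressure Column names in the
#'   file.
#' @return Named character vector of column names.
#' @export
vital_columns <- function(time = "Time", heart_rate = "HR", etco2 = "ETCO2",
                          resp_rate = "RR", blood_pressure = "MAP") {
  c(
    time = time, heart_rate = heart_rate, etco2 = etco2,
    resp_rate = resp_rate, blood_pressure = blood_pressure
  )
}

# Patients are numbered 1..n in trial tables while files are named by case;
# cases 02, 07, 08 and 10 (procedures shorter than 70 min) are absent, so
# patient 1 is case01, patient 2 is case03, and so on.
rah_case_ids <- function(n = 10) {
  base <- c(1L, 3L, 4L, 5L, 6L, 9L, 11L, 12L, 13L, 14L)
  if (n <= 10) base[seq_len(n)] else c(base, 14L + seq_len(n - 10L))
}

case_file_name <- function(case_id, segment_id) {
  sprintf("uq_vsd_case%02d_fulldata_%02d.csv", case_id, segment_id)
}

#' Read one case CSV file
#'
#' Parses a `uq_vsd_caseNN_fulldata_MM.csv`-style file: two header lines
#' followed by one data row per centisecond. Line numbering in the file is
#' 1-based and includes the headers, so the first data row is file line 3
#' (the convention [select_rows()] uses). A full 10-minute segment holds
#' 60,000 data rows.
#'
#' @param path Path to the CSV file.
#' @param columns Column mapping from [vital_columns()].
#' @return A tibble with columns `case_id`, `patient_id`, `segment_id`,
#'   `time_cs` (integer centiseconds from procedure start), `heart_rate`,
#'   `etco2`, `resp_rate`, `blood_pressure`.
#' @export
read_case_file <- function(path, columns = vital_columns()) {
  stopifnot(file.exists(path))
  header <- readr::read_lines(path, n_max = 2)
  if (length(header) < 2) {
    stop("file has fewer than 2 header lines: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(
    path,
    skip = 1, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(unname(columns), names(raw))
  if (length(missing) > 0) {
    stop("missing column(s) in ", basename(path), ": ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }

  m <- regexec("case([0-9]+)_fulldata_([0-9]+)", basename(path))
  g <- regmatches(basename(path), m)[[1]]
  case_id <- if (length(g) == 3) as.integer(g[2]) else NA_integer_
  segment_id <- if (length(g) == 3) as.integer(g[3]) else NA_integer_
  patient_id <- match(case_id, rah_case_ids(50))

  if (nrow(raw) == 0) {
    warning("no data rows in ", basename(path), call. = FALSE)
    return(tibble::tibble(
      case_id = integer(), patient_id = integer(), segment_id = integer(),
      time_cs = integer(), heart_rate = numeric(), etco2 = numeric(),
      resp_rate = numeric(), blood_pressure = numeric()
    ))
  }

  parse_num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[columns[[col]]]]))
    bad <- which(is.na(x) & !is.na(raw[[columns[[col]]]]))
    if (length(bad) > 0) {
      stop(
        "non-numeric value in column ", columns[[col]], " at file line ",
        bad[1] + 2L, " of ", basename(path),
        call. = FALSE
      )
    }
    x
  }
  out <- tibble::tibble(
    case_id = case_id,
    patient_id = patient_id,
    segment_id = segment_id,
    time_cs = parse_time_cs(raw[[columns[["time"]]]]),
    heart_rate = parse_num("heart_rate"),
    etco2 = parse_num("etco2"),
    resp_rate = parse_num("resp_rate"),
    blood_pressure = parse_num("blood_pressure")
  )
  if (anyNA(out$time_cs)) {
    stop("unparseable timestamp at file line ",
      which(is.na(out$time_cs))[1] + 2L, " of ", basename(path),
      call. = FALSE
    )
  }
  if (any(diff(out$time_cs) <= 0)) {
    stop("time offsets are not strictly increasing in ", basename(path),
      call. = FALSE
    )
  }
  out
}

#' Read a whole cohort directory
#'
#' Reads every `uq_vsd_case*_fulldata_*.csv` file under `dir` and binds the
#' rows.
#'
#' @param dir Directory containing case files.
#' @param columns Column mapping from [vital_columns()].
#' @return A cohort tibble (see [read_case_file()] for columns).
#' @export
read_cohort_dir <- function(dir, columns = vital_columns()) {
  paths <- sort(list.files(dir,
    pattern = "^uq_vsd_case[0-9]+_fulldata_[0-9]+\\.csv$",
    full.names = TRUE
  ))
  if (length(paths) == 0) stop("no case files found in ", dir, call. = FALSE)
  purrr::map_dfr(paths, read_case_file, columns = columns)
}

vital_channels <- c("heart_rate", "etco2", "resp_rate", "blood_pressure")

#' Compute per-vital normalization divisors
#'
#' Realizes the two data conversion methods. The *comprehensive* method
#' divides every vital by the maximum value observed across all patients'
#' training segments; the *isolated* method divides by the maximum in the
#' target patient's own training segment. Divisors are computed over the
#' training segment only, mirroring an operational system that can only use
#' the largest value recorded to date.
#'
#' @param cohort A cohort tibble (see [read_case_file()]).
#' @param method `"comprehensive"` or `"isolated"`.
#' @param target_patient Patient id whose data defines the divisors under
#'   the isolated method.
#' @param training_segment Segment id of the training files (default 4).
#' @return A `conversion_spec`: a list with `method` and a named `divisors`
#'   vector over the four vitals.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 3, n_rows = 200))
#' compute_divisors(cohort, "comprehensive")
#' @export
compute_divisors <- function(cohort, method = c("comprehensive", "isolated"),
                             target_patient = NULL, training_segment = 4L) {
  method <- match.arg(method)
  cohort <- as_cohort_tibble(cohort)
  train <- dplyr::filter(cohort, .data$segment_id == training_segment)
  if (nrow(train) == 0) {
    stop("cohort has no rows for training segment ", training_segment, call. = FALSE)
  }
  if (method == "isolated") {
    if (is.null(target_patient)) {
      stop("the isolated method needs `target_patient`", call. = FALSE)
    }
    train <- dplyr::filter(train, .data$patient_id == target_patient)
    if (nrow(train) == 0) {
      stop("no training rows for patient ", target_patient, call. = FALSE)
    }
  }
  divisors <- vapply(vital_channels, function(ch) max(train[[ch]]), numeric(1))
  if (any(divisors <= 0)) {
    stop(
      "channel(s) with non-positive maximum (divisor would be 0): ",
      paste(vital_channels[divisors <= 0], collapse = ", "),
      call. = FALSE
    )
  }
  structure(list(method = method, divisors = divisors), class = "conversion_spec")
}

#' Normalize a raw vital value to `[0, 1]`
#'
#' `value / divisor`, capped at 1 (an operational system can meet values
#' above the largest recorded to date). Rounding to the protocol's three
#' decimals happens only when values are formatted into commands.
#'
#' @param value Non-negative numeric vector of raw vitals.
#' @param divisor Positive divisor (a per-vital maximum).
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' normalize_vital(53, 135) # ~0.393
#' @export
normalize_vital <- function(value, divisor) {
  stopifnot(length(divisor) == 1, divisor > 0)
  if (any(value < 0)) stop("vital values must be non-negative", call. = FALSE)
  pmin(value / divisor, 1)
}

#' Normalize the four vital channels of a cohort tibble
#'
#' @param data A cohort tibble.
#' @param spec A `conversion_spec` from [compute_divisors()].
#' @return `data` with the four vital columns replaced by their normalized
#'   values.
#' @export
normalize_cohort <- function(data, spec) {
  stopifnot(inherits(spec, "conversion_spec"))
  data <- as_cohort_tibble(data)
  for (ch in vital_channels) {
    data[[ch]] <- normalize_vital(data[[ch]], spec$divisors[[ch]])
  }
  data
}

#' Select training or test rows from one patient segment
#'
#' Training uses every row of the training segment in time order. Testing
#' samples seven rows of the test segment at fixed 1-based *file line*
#' positions - 3 (the first data row; lines 1-2 are headers), 10,000,
#' 20,000, 30,000, 40,000, 50,000 and 60,000.
#'
#' @param series Tibble of one patient's one segment, ordered by time.
#' @param purpose `"training"` or `"test"`.
#' @return The selected rows.
#' @export
select_rows <- function(series, purpose = c("training", "test")) {
  purpose <- match.arg(purpose)
  series <- dplyr::arrange(as_cohort_tibble(series), .data$time_cs)
  if (purpose == "training") {
    return(series)
  }
  file_lines <- c(3L, seq(10000L, 60000L, by = 10000L))
  idx <- file_lines - 2L # data rows start at file line 3
  missing <- file_lines[idx > nrow(series)]
  if (length(missing) > 0) {
    stop(
      "segment too short (", nrow(series), " rows) for test file line(s) ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  series[idx, ]
}

as_cohort_tibble <- function(x) {
  if (inherits(x, "vitalid_cohort")) x <- x$vitals
  stopifnot(is.data.frame(x))
  missing <- setdiff(vital_channels, names(x))
  if (length(missing) > 0) {
    stop("not a cohort tibble; missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  tibble::as_tibble(x)
}

#' @export
print.conversion_spec <- function(x, ...) {
  cat("<conversion_spec>", x$method, "method\n")
  print(round(x$divisors, 3))
  invisible(x)
}
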