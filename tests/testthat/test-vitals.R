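test_that("normalization reproduces the worked heart-rate example and caps at 1", {
  expect_equal(format_gdes_value(normalize_vital(53, 135)), "000.393")
  expect_equal(normalize_vital(135, 135), 1)
  expect_equal(normalize_vital(140, 135), 1) # capped
  expect_error(normalize_vital(-1, 135), "non-negative")
  # scale invariance
  set.seed(9)
  v <- runif(50, 0, 200)
  d <- runif(50, 50, 250)
  k <- runif(50, 0.1, 10)
  expect_equal(
    normalize_vital(k[1] * v, k[1] * d[1]),
    normalize_vital(v, d[1])
  )
})

test_that("comprehensive divisors are cohort maxima and dominate isolated ones", {
  cohort <- tiny_cohort(n_patients = 4, n_rows = 300, seed = 21)
  comp <- compute_divisors(cohort, "comprehensive")
  train <- dplyr::filter(cohort$vitals, segment_id == 4)
  expect_equal(comp$divisors[["heart_rate"]], max(train$heart_rate))
  for (p in 1:4) {
    iso <- compute_divisors(cohort, "isolated", target_patient = p)
    expect_true(all(comp$divisors >= iso$divisors))
    own <- dplyr::filter(train, patient_id == p)
    expect_equal(iso$divisors[["blood_pressure"]], max(own$blood_pressure))
    # hence comprehensive-normalized values never exceed isolated ones
    expect_true(all(
      normalize_cohort(own, comp)$etco2 <= normalize_cohort(own, iso)$etco2 + 1e-12
    ))
  }
  # single-patient cohort: the two methods coincide
  solo <- dplyr::filter(cohort$vitals, patient_id == 2)
  expect_equal(
    compute_divisors(solo, "comprehensive")$divisors,
    compute_divisors(solo, "isolated", target_patient = 2)$divisors
  )
  zero <- dplyr::mutate(cohort$vitals, etco2 = 0)
  expect_error(compute_divisors(zero, "comprehensive"), "etco2")
})

test_that("row selection takes all training rows and the seven fixed test lines", {
  cohort <- generate_cohort(cohort_spec(n_patients = 2, n_rows = 60000, master_seed = 5))
  seg7 <- dplyr::filter(cohort$vitals, patient_id == 1, segment_id == 7)
  test_rows <- select_rows(seg7, "test")
  expect_equal(nrow(test_rows), 7)
  # file line 3 is data row 1; file line 10,000 is data row 9,998
  expect_identical(test_rows$time_cs, seg7$time_cs[c(1, seq(9998, 59998, by = 10000))])
  expect_equal(nrow(select_rows(seg7, "training")), 60000)
  # re-running yields identical rows
  expect_identical(test_rows, select_rows(seg7, "test"))
  short <- seg7[1:9000, ]
  expect_error(select_rows(short, "test"), "10000")
})

test_that("case files round-trip through the writer and reader", {
  cohort <- tiny_cohort(n_patients = 2, n_rows = 150, seed = 31)
  dir <- withr::local_tempdir()
  paths <- write_case_files(cohort, dir)
  expect_length(paths, 4) # 2 patients x 2 segments
  expect_true(all(grepl("uq_vsd_case[0-9]{2}_fulldata_[0-9]{2}\\.csv$", paths)))
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  # 2 header lines + one line per row
  expect_length(readr::read_lines(paths[1]), 152)

  back <- read_cohort_dir(dir)
  orig <- dplyr::arrange(cohort$vitals, case_id, segment_id, time_cs)
  back <- dplyr::arrange(back, case_id, segment_id, time_cs)
  for (col in c("time_cs", "heart_rate", "etco2", "resp_rate", "blood_pressure")) {
    expect_equal(back[[col]], orig[[col]], tolerance = 1e-12)
  }
  # patient numbering recovered from the case mapping (patient 2 = case03)
  expect_setequal(unique(back$patient_id), 1:2)
  expect_setequal(unique(back$case_id), c(1L, 3L))
})

test_that("the reader reports malformed files precisely", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "uq_vsd_case01_fulldata_04.csv")

  readr::write_lines(c("meta,,,,", "Time,HR,ETCO2,RR,MAP"), path)
  expect_warning(empty <- read_case_file(path), "no data rows")
  expect_equal(nrow(empty), 0)

  readr::write_lines(
    c("meta,,,,", "Time,HR,ETCO2,RR,MAP", "30:00.00,75,38,14,85", "30:00.01,xx,38,14,85"),
    path
  )
  expect_error(read_case_file(path), "file line 4")

  readr::write_lines(c("meta,,,", "Time,HR,ETCO2,RR", "30:00.00,75,38,14"), path)
  expect_error(read_case_file(path), "MAP")
})

test_that("timestamps render and parse across the hour boundary", {
  cs <- c(0L, 180000L, 359999L, 360000L, 395999L)
  txt <- vitalid:::format_time_cs(cs)
  expect_identical(txt[2], "30:00.00")
  expect_identical(txt[4], "1:00:00.00")
  expect_identical(vitalid:::parse_time_cs(txt), cs)
})
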