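test_that("trial numbering fixes conversion method, default value and target patient", {
  for (tr in c(1, 10, 11, 20, 21, 30, 31, 40, 41, 50)) {
    cfg <- trial_config(tr, 1)
    expect_equal(cfg$target_patient, (tr - 1) %% 10 + 1)
    expect_equal(
      cfg$conversion_method,
      if (tr %in% 11:20) "isolated" else "comprehensive"
    )
    expect_equal(
      cfg$default_fact_value,
      if (tr <= 20) 0.5 else if (tr <= 30) 0.6 else if (tr <= 40) 0.7 else 0.55
    )
  }
  expect_error(trial_config(51, 1), "trial_no")
  expect_error(trial_config(1, 4), "set_no")

  grid <- trial_grid()
  expect_equal(nrow(grid), 50 * 3 * 4)
  expect_equal(nrow(trial_grid(sets = 3, trials = 1:10, approaches = "fixed_single")), 10)
})

test_that("the compiled training loop matches command-by-command reference training", {
  cohort <- tiny_cohort(n_patients = 2, n_rows = 250, seed = 61)
  for (design in 1:3) {
    cfg <- trial_config(2, design)
    set.seed(100 + design)
    compiled <- train_profile(cfg, cohort, engine = "compiled")
    set.seed(100 + design)
    reference <- train_profile(cfg, cohort, engine = "reference")
    expect_identical(
      vitalid:::profile_weights(compiled$network),
      vitalid:::profile_weights(reference$network)
    )
    expect_identical(
      compiled$network$facts$value,
      reference$network$facts$value
    )
  }
})

test_that("replaying the emitted command script reproduces the trained weights", {
  cohort <- tiny_cohort(n_patients = 2, n_rows = 200, seed = 62)
  cfg <- trial_config(1, 3)
  profile <- train_profile(cfg, cohort, emit_script = TRUE)
  expect_length(profile$script, 5 * profile$n_rows_used)

  fresh <- profile$network
  fresh$facts$value <- cfg$default_fact_value
  fresh$rules$w1 <- 0.5
  fresh$rules$w2 <- 0.5
  replayed <- run_script(fresh, profile$script, target = 0.5, velocity = 0.1)
  expect_identical(
    vitalid:::profile_weights(replayed$network),
    vitalid:::profile_weights(profile$network)
  )
  expect_identical(replayed$network$facts$value, profile$network$facts$value)
})

test_that("patients with identical data train to identical weights", {
  base <- tiny_cohort(n_patients = 2, n_rows = 150, seed = 63)$vitals
  twin <- dplyr::mutate(
    dplyr::filter(base, patient_id == 1),
    patient_id = 2L, case_id = 3L
  )
  cohort <- dplyr::bind_rows(dplyr::filter(base, patient_id == 1), twin)
  conv <- compute_divisors(cohort, "comprehensive")
  w <- lapply(1:2, function(p) {
    cfg <- trial_config(p, 1)
    vitalid:::profile_weights(
      train_profile(cfg, cohort, conversion = conv)$network
    )
  })
  expect_identical(w[[1]], w[[2]])
})

test_that("training a zero-variance patient drives the output monotonically toward 0.5", {
  flat <- generate_patient(
    patient_params(
      wander_sd = setNames(rep(0, 4), vitalid:::vital_channels), seed = 1
    ),
    4,
    n_rows = 100
  )
  cohort <- dplyr::bind_rows(flat, dplyr::mutate(flat, patient_id = 2L, case_id = 3L))
  cfg <- trial_config(1, 3)
  conv <- compute_divisors(cohort, "comprehensive", training_segment = 4)
  x <- vitalid:::normalized_matrix(dplyr::filter(cohort, patient_id == 1), conv)

  net <- build_network(3)
  errs <- numeric(50)
  for (i in seq_len(50)) {
    for (ch in vitalid:::vital_channels) {
      net <- set_fact(net, unname(net$channel_map[ch]), x[1, ch])
    }
    step <- train_step(net, start_value = x[1, "blood_pressure"], target = 0.5)
    net <- step$network
    errs[i] <- step$error_after
  }
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("baseline recipes obey their closed-form special cases", {
  cohort <- tiny_cohort(n_patients = 2, n_rows = 120, seed = 64)
  cfg <- trial_config(1, 2)
  profile <- train_profile(cfg, cohort)

  # untrained network with all facts at the default: every fixed recipe is convex
  untrained <- profile
  untrained$network$rules$w1 <- 0.5
  untrained$network$rules$w2 <- 0.5
  b_all <- compute_baseline(untrained, "fixed_all_facts", default_value = 0.5)
  expect_equal(b_all$target_value, 0.5, tolerance = 1e-12)
  untrained$last_inputs <- setNames(rep(0.5, 4), vitalid:::vital_channels)
  expect_equal(
    compute_baseline(untrained, "fixed_single", default_value = 0.5)$target_value,
    b_all$target_value
  )

  # zero-variance patient: training means equal last values, so the averaged
  # recipe equals the actual-last-value recipe
  flat <- profile
  flat$mean_inputs <- flat$last_inputs
  expect_equal(
    compute_baseline(flat, "averaged_facts")$target_value,
    compute_baseline(flat, "actual_last_bp")$target_value,
    tolerance = 1e-12
  )
})

test_that("clone cohorts at separation zero yield equal deviations for every patient", {
  clones <- generate_cohort(cohort_spec(
    n_patients = 5, separation = 0, n_rows = 60000, master_seed = 17
  ))
  # identical generators still wander independently; force truly identical data
  p1 <- dplyr::filter(clones$vitals, patient_id == 1)
  vitals <- purrr::map_dfr(1:5, function(p) {
    dplyr::mutate(p1, patient_id = as.integer(p), case_id = vitalid:::rah_case_ids(5)[p])
  })
  cfg <- trial_config(1, 3)
  profile <- train_profile(cfg, vitals, every_k = 200)
  baseline <- compute_baseline(profile)
  evals <- evaluate_cohort(profile, baseline, vitals)
  devs <- dplyr::summarise(
    dplyr::group_by(evals, patient_id),
    d = mean(deviation), .groups = "drop"
  )
  expect_equal(length(unique(devs$d)), 1)
  # and the summary marks no strict minimum
  row <- summarize_trial(evals, target_patient = 1)
  expect_false(row$lowest)
  expect_equal(row$false_0.1, if (devs$d[1] < 0.1) 4L else 0L)
})

test_that("the experiment grid emits one summary row per execution with stable results", {
  cohort <- generate_cohort(cohort_spec(n_patients = 10, master_seed = 23))
  grid <- trial_grid(sets = 2, trials = c(1, 11), approaches = c("fixed_single", "averaged_facts"))
  res <- run_experiment(cohort, grid, every_k = 500)
  expect_equal(nrow(res), 4)
  expect_setequal(res$conversion_method, c("comprehensive", "isolated"))
  res2 <- run_experiment(cohort, grid, every_k = 500)
  expect_identical(res, res2)

  tables <- experiment_tables(res)
  expect_length(tables, 4)
  expect_identical(
    names(tables[[1]]),
    c(
      "Average Error", "Avg Err", "Lowest",
      "Correct at 0.01", "Correct at 0.025", "Correct at 0.05", "Correct at 0.1",
      "False at 0.01", "False at 0.025", "False at 0.05", "False at 0.1"
    )
  )
  expect_error(
    run_experiment(dplyr::filter(cohort$vitals, patient_id > 1), grid),
    "missing patient"
  )
})

test_that("correct-to-incorrect performance improves with cohort separation", {
  score <- function(sep) {
    mean(vapply(1:8, function(s) {
      cohort <- generate_cohort(cohort_spec(
        n_patients = 10, separation = sep, master_seed = 500 + s
      ))
      grid <- trial_grid(sets = 3, trials = 1:10, approaches = "fixed_single")
      res <- run_experiment(cohort, grid, every_k = 100)
      vitalid:::ratio_score(res, 0.025)
    }, numeric(1)))
  }
  expect_gt(score(1.5), score(0.2))
})
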