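test_that("all three designs build the 7-fact 3-rule topology with the right pairings", {
  set.seed(1)
  expected_pairs <- list(
    `1` = list(c("blood_pressure", "heart_rate"), c("resp_rate", "etco2")),
    `2` = list(c("heart_rate", "resp_rate"), c("blood_pressure", "etco2")),
    `3` = list(c("heart_rate", "etco2"), c("resp_rate", "blood_pressure"))
  )
  for (design in 1:3) {
    net <- build_network(design)
    expect_equal(nrow(net$facts), 7)
    expect_equal(nrow(net$rules), 3)
    expect_false(anyDuplicated(net$facts$guid) > 0)
    expect_true(all(vitalid:::is_guid(net$facts$guid)))
    # evaluation order exists => acyclic
    expect_length(vitalid:::rule_order(net), 3)

    td <- tidy(net)
    first_layer <- td[td$output != "output", ]
    got <- lapply(seq_len(2), function(i) c(first_layer$input1[i], first_layer$input2[i]))
    want <- expected_pairs[[as.character(design)]]
    expect_setequal(
      vapply(got, paste, character(1), collapse = "+"),
      vapply(want, paste, character(1), collapse = "+")
    )
    # both intermediates feed the final rule; every input feeds one rule
    final <- td[td$output == "output", ]
    expect_setequal(c(final$input1, final$input2), c("intermediate_1", "intermediate_2"))
    expect_setequal(
      c(first_layer$input1, first_layer$input2),
      c("heart_rate", "etco2", "resp_rate", "blood_pressure")
    )
    expect_true(all(net$rules$w1 == 0.5 & net$rules$w2 == 0.5))
    expect_true(all(net$facts$value == 0.5))
  }
  expect_error(build_network(4), "design_id")
  expect_error(build_network("a"), "design_id")
})

test_that("set_fact assigns, clamps, and rejects unknown facts", {
  set.seed(2)
  net <- build_network(1)
  hr <- fact_guid(net, "heart_rate")
  net <- set_fact(net, hr, 0.393)
  expect_equal(vitalid:::fact_value(net, hr), 0.393)
  net <- set_fact(net, hr, 0)
  expect_equal(vitalid:::fact_value(net, hr), 0)
  expect_warning(net <- set_fact(net, hr, 1.7), "clamped")
  expect_equal(vitalid:::fact_value(net, hr), 1)
  bogus <- vitalid:::new_guid(1)
  expect_error(set_fact(net, bogus, 0.5), bogus)
})

test_that("present equals a brute-force recursive evaluator on random networks", {
  set.seed(42)
  for (i in 1:120) {
    net <- random_network(
      n_inputs = sample(2:4, 1),
      n_rules = sample(1:6, 1)
    )
    expect_equal(present(net), brute_force_output(net), tolerance = 1e-12)
  }
})

test_that("present output stays within the convex hull of the input values", {
  set.seed(43)
  for (i in 1:50) {
    net <- random_network(n_inputs = 4, n_rules = sample(2:5, 1))
    out <- present(net)
    inputs <- net$facts$value[net$facts$kind == "input"]
    expect_gte(out, min(inputs) - 1e-12)
    expect_lte(out, max(inputs) + 1e-12)
  }
  # equal inputs collapse to the common value for any weights
  net <- random_network(n_inputs = 4, n_rules = 3)
  net$facts$value[net$facts$kind == "input"] <- 0.37
  expect_equal(present(net), 0.37, tolerance = 1e-12)
})

test_that("two-level network with symmetric weights averages pairwise", {
  set.seed(3)
  net <- build_network(1)
  for (ch in names(net$channel_map)) {
    net <- set_fact(net, unname(net$channel_map[ch]),
      c(heart_rate = 0.2, etco2 = 0.4, resp_rate = 0.6, blood_pressure = 0.8)[ch]
    )
  }
  expect_equal(present(net), 0.5, tolerance = 1e-12)
})

test_that("train_step matches the stand-alone single-rule oracle and reduces error", {
  set.seed(44)
  for (i in 1:50) {
    v <- runif(2)
    target <- runif(1)
    velocity <- runif(1, 0.01, 0.5)
    net <- one_rule_network(v[1], v[2])
    step <- train_step(net, target = target, velocity = velocity)
    expect_equal(
      c(step$network$rules$w1, step$network$rules$w2),
      single_rule_update(0.5, 0.5, v[1], v[2], target, velocity),
      tolerance = 1e-12
    )
    expect_lte(step$error_after, step$error_before + 1e-12)
  }
})

test_that("weights remain a unit partition after arbitrary training", {
  set.seed(45)
  net <- build_network(2)
  for (i in 1:200) {
    for (ch in names(net$channel_map)) {
      net <- set_fact(net, unname(net$channel_map[ch]), runif(1))
    }
    net <- train_step(net,
      start_value = runif(1), target = runif(1),
      velocity = runif(1, 0.05, 0.4)
    )$network
    expect_true(all(net$rules$w1 >= 0 & net$rules$w1 <= 1))
    expect_true(all(net$rules$w2 >= 0 & net$rules$w2 <= 1))
    expect_true(all(abs(net$rules$w1 + net$rules$w2 - 1) < 1e-9))
  }
})

test_that("repeated training on fixed inputs is error-non-increasing", {
  set.seed(46)
  net <- build_network(3)
  vals <- c(heart_rate = 0.2, etco2 = 0.9, resp_rate = 0.4, blood_pressure = 0.7)
  for (ch in names(vals)) net <- set_fact(net, unname(net$channel_map[ch]), vals[ch])
  errors <- numeric(40)
  for (i in seq_along(errors)) {
    step <- train_step(net, start_value = vals["blood_pressure"], target = 0.5, velocity = 0.1)
    net <- step$network
    errors[i] <- step$error_after
  }
  expect_true(all(diff(errors) <= 1e-12))
})

test_that("training is a no-op when output equals target or inputs are degenerate", {
  set.seed(47)
  # already at target: zero error apportions zero
  net <- one_rule_network(0.3, 0.7) # output 0.5
  step <- train_step(net, target = 0.5, velocity = 0.2)
  expect_equal(step$network$rules$w1, 0.5)
  expect_equal(step$error_after, 0)

  # all inputs equal: convexity makes the output weight-invariant
  net <- build_network(1)
  for (ch in names(net$channel_map)) net <- set_fact(net, unname(net$channel_map[ch]), 0.3)
  before <- net$rules
  step <- train_step(net, start_value = 0.3, target = 0.9, velocity = 0.2)
  expect_equal(step$network$rules$w1, before$w1)
  expect_equal(step$network$rules$w2, before$w2)
  expect_equal(step$error_before, step$error_after)
})

test_that("reset_facts touches only the selected kinds and preserves behavior", {
  set.seed(48)
  net <- build_network(2)
  for (ch in names(net$channel_map)) net <- set_fact(net, unname(net$channel_map[ch]), runif(1))
  net <- train_step(net, start_value = 0.8, target = 0.5)$network

  reset <- reset_facts(net, "intermediate", 0.5)
  expect_true(all(
    reset$facts$value[reset$facts$kind == "intermediate"] == 0.5
  ))
  expect_identical(reset$rules, net$rules)
  expect_identical(
    reset$facts$value[reset$facts$kind == "input"],
    net$facts$value[net$facts$kind == "input"]
  )
  # empty kind set: unchanged
  expect_identical(reset_facts(net, character(0), 0.1), net)
  # after a reset, presenting the same inputs matches a fresh network with
  # the same weights
  fresh <- net
  fresh$facts$value[fresh$facts$kind != "input"] <- 0.5
  expect_equal(present(reset, 0.6), present(fresh, 0.6), tolerance = 1e-15)
})
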