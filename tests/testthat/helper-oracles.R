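# Independent oracles and fixture builders, kept deliberately naive so they
# share no code with the implementation they check.

# Random acyclic rule-fact network: `n_inputs` leaf facts, then `n_rules`
# rules each combining two distinct already-existing facts into a new fact.
# The last fact created is the output.
random_network <- function(n_inputs = 4, n_rules = 3) {
  n_facts <- n_inputs + n_rules
  guids <- vitalid:::new_guid(n_facts + n_rules)
  fact_guids <- guids[seq_len(n_facts)]
  facts <- tibble::tibble(
    guid = fact_guids,
    name = paste0("f", seq_len(n_facts)),
    value = c(runif(n_inputs), rep(0, n_rules)),
    kind = c(
      rep("input", n_inputs), rep("intermediate", n_rules - 1), "output"
    )
  )
  rules <- purrr::map_dfr(seq_len(n_rules), function(k) {
    pool <- fact_guids[seq_len(n_inputs + k - 1)]
    ins <- sample(pool, 2)
    w1 <- runif(1)
    tibble::tibble(
      guid = guids[n_facts + k],
      input1 = ins[1], input2 = ins[2],
      w1 = w1, w2 = 1 - w1,
      output = fact_guids[n_inputs + k]
    )
  })
  vitalid:::new_gdes_network(
    facts, rules,
    start_fact_guid = fact_guids[1],
    output_fact_guid = fact_guids[n_facts]
  )
}

# Naive recursive weighted-sum evaluator: value of a fact is its stored value
# unless a rule produces it, in which case it is the weighted sum of the
# recursively evaluated inputs.
brute_force_output <- function(network, fact_guid = network$output_fact_guid) {
  rules <- network$rules
  eval_fact <- function(g) {
    k <- match(g, rules$output)
    if (is.na(k)) {
      return(network$facts$value[match(g, network$facts$guid)])
    }
    rules$w1[k] * eval_fact(rules$input1[k]) + rules$w2[k] * eval_fact(rules$input2[k])
  }
  eval_fact(fact_guid)
}

# Stand-alone single-rule training update: one rule (share 1), weights
# shifted by velocity * |error| toward the input moving the output in the
# error-reducing direction, clamped and renormalized.
single_rule_update <- function(w1, w2, v1, v2, target, velocity) {
  out <- w1 * v1 + w2 * v2
  e <- target - out
  if (e == 0 || v1 == v2) {
    return(c(w1, w2))
  }
  delta <- velocity * abs(e)
  toward_first <- if (e > 0) v1 > v2 else v1 < v2
  w1 <- w1 + if (toward_first) delta else -delta
  w2 <- w2 + if (toward_first) -delta else delta
  w1 <- min(max(w1, 0), 1)
  w2 <- min(max(w2, 0), 1)
  c(w1, w2) / (w1 + w2)
}

# Minimal one-rule network (two inputs -> output) with given values/weights.
one_rule_network <- function(v1, v2, w1 = 0.5) {
  guids <- vitalid:::new_guid(4)
  facts <- tibble::tibble(
    guid = guids[1:3],
    name = c("a", "b", "out"),
    value = c(v1, v2, 0),
    kind = c("input", "input", "output")
  )
  rules <- tibble::tibble(
    guid = guids[4], input1 = guids[1], input2 = guids[2],
    w1 = w1, w2 = 1 - w1, output = guids[3]
  )
  vitalid:::new_gdes_network(facts, rules, guids[1], guids[3])
}

# Tiny deterministic cohort for engine tests; full-length segments only
# where the fixed test-row positions require them.
tiny_cohort <- function(n_patients = 3, n_rows = 200, seed = 11,
                        separation = 1.5) {
  generate_cohort(cohort_spec(
    n_patients = n_patients, separation = separation,
    master_seed = seed, n_rows = n_rows
  ))
}

ref_tables <- read_reference_tables()
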