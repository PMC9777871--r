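#' Rule-fact expert networks for vital-sign identity profiles
#'
#' A `gdes_network` is a small acyclic rule-fact expert system. Facts hold
#' values in `[0, 1]`; each rule computes a convex (weights sum to one)
#' combination of exactly two input facts into an output fact. Training
#' never adds or removes rules - a gradient-descent style procedure only
#' re-weights rule inputs - which keeps every decision pathway inspectable.
#'
#' The three stock designs share one shape: seven facts (four vital-sign
#' inputs, two intermediates, one output) and three rules. They differ in
#' which vitals each first-layer rule pairs:
#'
#' * design 1: (blood pressure, heart rate) -> heart fact;
#'   (respiratory rate, end-tidal CO2) -> oxygen fact
#' * design 2: (heart rate, respiratory rate) -> rate fact;
#'   (blood pressure, end-tidal CO2) -> pressure-gas fact
#' * design 3: (heart rate, end-tidal CO2) -> fact;
#'   (respiratory rate, blood pressure) -> fact
#'
#' Both intermediates always feed the final rule. The blood-pressure fact is
#' the designated start fact of TR/PR commands.
#'
#' @param design_id Integer 1, 2 or 3 selecting the input pairing.
#' @param default_fact_value Initial value for every fact (default 0.5).
#' @return A `gdes_network` object.
#' @examples
#' net <- build_network(3)
#' glance(net)
#' @export
build_network <- function(design_id, default_fact_value = 0.5) {
  if (!(length(design_id) == 1 && design_id %in% 1:3)) {
    stop("`design_id` must be 1, 2 or 3, not ", deparse(design_id), call. = FALSE)
  }
  design_id <- as.integer(design_id)
  stopifnot(default_fact_value >= 0, default_fact_value <= 1)

  fact_names <- c(
    "heart_rate", "etco2", "resp_rate", "blood_pressure",
    "intermediate_1", "intermediate_2", "output"
  )
  guids <- new_guid(10)
  facts <- tibble::tibble(
    guid = guids[1:7],
    name = fact_names,
    value = default_fact_value,
    kind = c(rep("input", 4), rep("intermediate", 2), "output")
  )
  g <- setNames(facts$guid, facts$name)
  pairs <- design_pairs(design_id)
  rules <- tibble::tibble(
    guid = guids[8:10],
    input1 = c(g[pairs$rule1[1]], g[pairs$rule2[1]], g["intermediate_1"]),
    input2 = c(g[pairs$rule1[2]], g[pairs$rule2[2]], g["intermediate_2"]),
    w1 = 0.5,
    w2 = 0.5,
    output = c(g["intermediate_1"], g["intermediate_2"], g["output"])
  )
  structure(
    list(
      facts = facts,
      rules = rules,
      design_id = design_id,
      channel_map = g[c("heart_rate", "etco2", "resp_rate", "blood_pressure")],
      start_fact_guid = unname(g["blood_pressure"]),
      output_fact_guid = unname(g["output"]),
      default_fact_value = default_fact_value
    ),
    class = "gdes_network"
  )
}

# Channel pairing per design, by fact name.  Order within a pair matches the
# rule's (input1, input2) slots.
design_pairs <- function(design_id) {
  switch(design_id,
    `1` = list(
      rule1 = c("blood_pressure", "heart_rate"),
      rule2 = c("resp_rate", "etco2")
    ),
    `2` = list(
      rule1 = c("heart_rate", "resp_rate"),
      rule2 = c("blood_pressure", "etco2")
    ),
    `3` = list(
      rule1 = c("heart_rate", "etco2"),
      rule2 = c("resp_rate", "blood_pressure")
    ),
    stop("unknown design_id")
  )
}

# Column indices into an (hr, etco2, rr, bp) matrix for the two first-layer
# rules of a design; used by the compiled training loop and the vectorized
# evaluator.
design_pair_idx <- function(design_id) {
  chan <- c(heart_rate = 1L, etco2 = 2L, resp_rate = 3L, blood_pressure = 4L)
  p <- design_pairs(design_id)
  list(rule1 = unname(chan[p$rule1]), rule2 = unname(chan[p$rule2]))
}

# Construct a network from explicit fact/rule tables (used for generic DAGs
# in property tests; no fixed-design bookkeeping).
new_gdes_network <- function(facts, rules, start_fact_guid, output_fact_guid) {
  stopifnot(
    !anyDuplicated(facts$guid),
    all(rules$input1 %in% facts$guid),
    all(rules$input2 %in% facts$guid),
    all(rules$output %in% facts$guid),
    all(rules$output != rules$input1),
    all(rules$output != rules$input2),
    all(abs(rules$w1 + rules$w2 - 1) < 1e-9)
  )
  structure(
    list(
      facts = facts, rules = rules, design_id = NA_integer_,
      channel_map = NULL,
      start_fact_guid = start_fact_guid,
      output_fact_guid = output_fact_guid,
      default_fact_value = 0.5
    ),
    class = "gdes_network"
  )
}

#' @export
print.gdes_network <- function(x, ...) {
  cat(
    "<gdes_network> design", x$design_id, "-",
    nrow(x$facts), "facts,", nrow(x$rules), "rules\n"
  )
  cat("output:", format_gdes_value(fact_value(x, x$output_fact_guid)), "\n")
  invisible(x)
}

#' Look up a fact GUID by its role name
#'
#' @param network A `gdes_network`.
#' @param name Fact name, e.g. `"heart_rate"` or `"output"`.
#' @return The fact's GUID string.
#' @export
fact_guid <- function(network, name) {
  i <- match(name, network$facts$name)
  if (anyNA(i)) {
    stop("no fact named ", paste(name[is.na(i)], collapse = ", "), call. = FALSE)
  }
  network$facts$guid[i]
}

fact_value <- function(network, guid) {
  i <- match(guid, network$facts$guid)
  if (anyNA(i)) stop("unknown fact guid: ", guid[is.na(i)][1], call. = FALSE)
  network$facts$value[i]
}

#' Set a fact's value (SF)
#'
#' Assigns a value to one fact, clamped to `[0, 1]`. This is the programmatic
#' form of the protocol's `SF:{guid}=DDD.DDD` command.
#'
#' @param network A `gdes_network`.
#' @param fact A fact GUID, or a fact name which is resolved via
#'   [fact_guid()].
#' @param value Numeric scalar; values outside `[0, 1]` are clamped with a
#'   warning.
#' @return The updated network.
#' @export
set_fact <- function(network, fact, value) {
  stopifnot(is.numeric(value), length(value) == 1, !is.na(value))
  guid <- if (is_guid(fact)) fact else fact_guid(network, fact)
  i <- match(guid, network$facts$guid)
  if (is.na(i)) stop("unknown fact guid: ", guid, call. = FALSE)
  if (value < 0 || value > 1) {
    warning("fact value ", value, " clamped to [0, 1]", call. = FALSE)
  }
  network$facts$value[i] <- clamp01(value)
  network
}

#' Reset facts of selected kinds to a value
#'
#' Between presentation runs all intermediate facts are reset (the protocol
#' does this with SF commands) to the default value 0.500 so one run cannot
#' leak state into the next. Rule weights are untouched.
#'
#' @param network A `gdes_network`.
#' @param kinds Character vector drawn from `"input"`, `"intermediate"`,
#'   `"output"`.
#' @param value Value in `[0, 1]` to assign (default 0.5).
#' @return The updated network.
#' @export
reset_facts <- function(network, kinds = "intermediate", value = 0.5) {
  stopifnot(value >= 0, value <= 1, all(kinds %in% c("input", "intermediate", "output")))
  network$facts$value[network$facts$kind %in% kinds] <- value
  network
}

# Rules in evaluation order (Kahn's algorithm); errors on cycles.
rule_order <- function(network) {
  rules <- network$rules
  known <- network$facts$guid[!network$facts$guid %in% rules$output]
  ord <- integer(0)
  remaining <- seq_len(nrow(rules))
  while (length(remaining) > 0) {
    ready <- remaining[rules$input1[remaining] %in% known &
      rules$input2[remaining] %in% known]
    if (length(ready) == 0) {
      stop("rule graph contains a cycle", call. = FALSE)
    }
    ord <- c(ord, ready)
    known <- c(known, rules$output[ready])
    remaining <- setdiff(remaining, ready)
  }
  ord
}

# Forward pass: optionally set the start fact, then assign every rule's
# output fact its weighted input sum in topological order.
propagate <- function(network, start_value = NULL) {
  if (!is.null(start_value)) {
    network <- set_fact(network, network$start_fact_guid, start_value)
  }
  vals <- setNames(network$facts$value, network$facts$guid)
  rules <- network$rules
  for (k in rule_order(network)) {
    vals[rules$output[k]] <-
      rules$w1[k] * vals[rules$input1[k]] + rules$w2[k] * vals[rules$input2[k]]
  }
  network$facts$value <- unname(vals[network$facts$guid])
  network
}

#' Evaluate the network and return its output (PR)
#'
#' Sets the start fact, propagates all rules in dependency order (each rule's
#' output fact becomes the weighted sum of its two input facts) and returns
#' the output fact's value. Programmatic form of the `PR` command.
#'
#' @param network A `gdes_network`.
#' @param start_value Value assigned to the start (blood-pressure) fact
#'   before evaluation; `NULL` keeps its current value.
#' @return The output fact's value, in `[0, 1]`.
#' @export
present <- function(network, start_value = NULL) {
  net <- propagate(network, start_value)
  if (!network$output_fact_guid %in% network$facts$guid) {
    stop("network has no output fact", call. = FALSE)
  }
  fact_value(net, net$output_fact_guid)
}

# Contribution of each rule's output fact to the end fact: 1 for the rule
# feeding the end fact, and the sum over downstream paths of products of
# rule weights otherwise.  Rules that cannot reach the end fact contribute 0.
rule_contributions <- function(network, end_fact_guid) {
  rules <- network$rules
  contrib <- setNames(numeric(nrow(network$facts)), network$facts$guid)
  contrib[end_fact_guid] <- 1
  for (k in rev(rule_order(network))) {
    c_out <- contrib[rules$output[k]]
    if (c_out > 0) {
      contrib[rules$input1[k]] <- contrib[rules$input1[k]] + rules$w1[k] * c_out
      contrib[rules$input2[k]] <- contrib[rules$input2[k]] + rules$w2[k] * c_out
    }
  }
  unname(contrib[rules$output])
}

#' One training update (TR)
#'
#' Sets the start fact, evaluates the network, and apportions the signed
#' error `target - output` over the rules upstream of the end fact in
#' proportion to each rule's contribution to the output (the weight product
#' along its downstream paths). Each apportioned rule shifts weight toward
#' the input fact whose value moves the rule's output in the error-reducing
#' direction, by `velocity * share * |error|`; weights are then clamped to
#' `[0, 1]` and renormalized to sum to one. A rule whose two input values are
#' equal is skipped - no weight change can alter its output. Programmatic
#' form of the `TR` command.
#'
#' @param network A `gdes_network` whose input facts have been set.
#' @param start_value Value for the start fact (from the current data row).
#' @param target Training target in `[0, 1]`; profile training always uses
#'   0.5, the midpoint of the output range.
#' @param velocity Positive learning-rate scalar (default 0.1).
#' @param end_fact Fact GUID the error is measured at; defaults to the
#'   network's output fact.
#' @return A list with elements `network` (weights updated, facts left
#'   propagated under the new weights), `error_before` and `error_after`
#'   (absolute errors at the end fact).
#' @export
train_step <- function(network, start_value = NULL, target = 0.5,
                       velocity = 0.1, end_fact = NULL) {
  stopifnot(velocity > 0, target >= 0, target <= 1)
  end_fact <- end_fact %||% network$output_fact_guid
  net <- propagate(network, start_value)
  out <- fact_value(net, end_fact)
  err <- target - out

  contrib <- rule_contributions(net, end_fact)
  if (all(contrib == 0)) {
    stop("end fact is not reachable from any rule", call. = FALSE)
  }
  shares <- contrib / sum(contrib)

  rules <- net$rules
  vals <- setNames(net$facts$value, net$facts$guid)
  if (err != 0) {
    for (k in seq_len(nrow(rules))) {
      if (shares[k] == 0) next
      v1 <- vals[rules$input1[k]]
      v2 <- vals[rules$input2[k]]
      if (v1 == v2) next # degenerate: output is weight-invariant
      delta <- velocity * shares[k] * abs(err)
      toward_first <- if (err > 0) v1 > v2 else v1 < v2
      if (toward_first) {
        rules$w1[k] <- rules$w1[k] + delta
        rules$w2[k] <- rules$w2[k] - delta
      } else {
        rules$w1[k] <- rules$w1[k] - delta
        rules$w2[k] <- rules$w2[k] + delta
      }
      rules$w1[k] <- clamp01(rules$w1[k])
      rules$w2[k] <- clamp01(rules$w2[k])
      s <- rules$w1[k] + rules$w2[k]
      rules$w1[k] <- rules$w1[k] / s
      rules$w2[k] <- rules$w2[k] / s
    }
  }
  net$rules <- rules
  net <- propagate(net)
  list(
    network = net,
    error_before = abs(err),
    error_after = abs(target - fact_value(net, end_fact))
  )
}

#' @export
tidy.gdes_network <- function(x, ...) {
  name_of <- setNames(x$facts$name, x$facts$guid)
  dplyr::mutate(
    x$rules,
    input1 = unname(name_of[.data$input1]),
    input2 = unname(name_of[.data$input2]),
    output = unname(name_of[.data$output])
  )
}

#' @export
glance.gdes_network <- function(x, ...) {
  tibble::tibble(
    design_id = x$design_id,
    n_facts = nrow(x$facts),
    n_rules = nrow(x$rules),
    output_value = fact_value(x, x$output_fact_guid)
  )
}
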