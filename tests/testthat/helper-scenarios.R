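# Shared scenario builders for the test suite.

fixture_scenarios <- function() table1_fixture()$scenarios

# Minimal single-filter scenario: population 100, prevalence 1, so the
# target group is 100 and increments are easy to reason about by hand.
one_filter_scenario <- function(id, rate, cost) {
  scenario_spec(id, population_size = 100, prevalence = 1,
                filters = list(filter_spec("treatment", rate, cost)))
}

# Per-person micro-simulation of a scenario's cascade: independent
# pass/fail draws at each filter, unit costs charged per entrant.
# Returns per-person cost vector, per-person success indicator, and the
# per-person entrant indicator matrix (persons x stages).
simulate_cascade <- function(scenario, n_persons) {
  k <- length(scenario$filters)
  in_stage <- rep(TRUE, n_persons)
  cost <- numeric(n_persons)
  entrants <- matrix(FALSE, n_persons, k)
  for (i in seq_len(k)) {
    f <- scenario$filters[[i]]
    entrants[, i] <- in_stage
    cost <- cost + f$unit_cost * in_stage
    in_stage <- in_stage & (stats::runif(n_persons) < f$pass_rate)
  }
  list(cost = cost, success = in_stage, entrants = entrants)
}

write_temp_config <- function(text, ext = "yaml") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(text, path)
  path
}

# A config file with one out-of-range pass rate, for error-path tests.
bad_rate_config <- function() {
  write_temp_config('
baseline_id: base
scenarios:
- scenario_id: base
  population_size: 100
  prevalence: 0.5
  filters:
  - name: detection
    pass_rate: 1.2
    unit_cost: 5
')
}
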