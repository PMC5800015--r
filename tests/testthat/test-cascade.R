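test_that("baseline cascade reproduces the worked-example flows and costs", {
  res <- run_cascade(fixture_scenarios()[["baseline"]])
  expect_equal(res$target_group_size, 1500)
  expect_equal(res$stages$entrants, c(1500, 300, 210, 63))
  expect_equal(res$stages$passers, c(300, 210, 63, 18.9))
  expect_equal(res$stages$stage_cost, c(7500, 1500, 0, 6300))
  expect_equal(res$total_cost, 15300)
  expect_equal(res$n_receiving_care, 63)
  expect_equal(res$n_success, 18.9)
})

test_that("flows stay fractional internally (never pre-rounded)", {
  res <- run_cascade(fixture_scenarios()[["scenario1"]])
  # 525 detected -> 367.5 offered -> 110.25 accept treatment
  expect_equal(res$stages$entrants[4], 110.25)
  expect_equal(res$stages$stage_cost[4], 11025)  # $100 x 110.25, not x 110
  expect_equal(res$n_success, 33.075)
})

test_that("identity cascade passes everyone at zero cost", {
  sc <- scenario_spec("id", population_size = 777, prevalence = 0.3,
                      filters = list(filter_spec("a", 1, 0),
                                     filter_spec("b", 1, 0)))
  res <- run_cascade(sc)
  expect_equal(res$n_success, 777 * 0.3)
  expect_equal(res$total_cost, 0)
})

test_that("invalid scenarios fail validation naming the offending field", {
  f <- function(...) filter_spec(...)
  expect_error(filter_spec("det", 1.2, 5), "pass_rate",
               class = "cascade_validation_error")
  expect_error(filter_spec("det", 0.5, -1), "unit_cost",
               class = "cascade_validation_error")
  expect_error(filter_spec("", 0.5, 1), "name",
               class = "cascade_validation_error")
  expect_error(scenario_spec("s", 0, 0.5, list(f("a", 0.5, 1))),
               "population_size", class = "cascade_validation_error")
  expect_error(scenario_spec("s", 10, 1.5, list(f("a", 0.5, 1))),
               "prevalence", class = "cascade_validation_error")
  expect_error(scenario_spec("s", 10, 0.5, list()),
               "filters", class = "cascade_validation_error")
  expect_error(scenario_spec("s", 10, 0.5, list(f("a", 0.5, 1), f("a", 0.2, 0))),
               "unique", class = "cascade_validation_error")
})

test_that("outcome metrics divide total cost by the right denominators", {
  out <- compute_outcomes(run_cascade(fixture_scenarios()[["baseline"]]))
  expect_equal(out$cost_per_patient, 15300 / 63)     # 242.857...
  expect_equal(out$cost_per_success, 15300 / 18.9)   # 809.523...
  s4 <- compute_outcomes(run_cascade(fixture_scenarios()[["scenario4"]]))
  expect_equal(s4$cost_per_patient, 27900 / 63)      # 442.857...
  expect_equal(s4$cost_per_success, 27900 / 28.35)   # 984.126...
})

test_that("zero-cost cascade yields zero ratios; zero denominators are NA, not 0", {
  free <- scenario_spec("free", 100, 0.5,
                        list(filter_spec("a", 0.5, 0), filter_spec("b", 0.5, 0)))
  out <- compute_outcomes(run_cascade(free))
  expect_equal(out$cost_per_patient, 0)
  expect_equal(out$cost_per_success, 0)

  dead_end <- scenario_spec("dead", 100, 0.5,
                            list(filter_spec("a", 0.5, 10),
                                 filter_spec("b", 0, 10)))
  out2 <- compute_outcomes(run_cascade(dead_end))
  expect_true(is.na(out2$cost_per_success))
  expect_false(is.na(out2$cost_per_patient))

  all_blocked <- scenario_spec("blocked", 100, 0.5,
                               list(filter_spec("a", 0, 10),
                                    filter_spec("b", 0.5, 10)))
  out3 <- compute_outcomes(run_cascade(all_blocked))
  expect_true(is.na(out3$cost_per_patient))
  expect_true(is.na(out3$cost_per_success))
})

test_that("cascade invariants hold on seeded random scenarios", {
  for (seed in 1:200) {
    sc <- generate_random_scenario(seed)
    res <- run_cascade(sc)
    k <- nrow(res$stages)
    # flow conservation and monotone attrition
    expect_equal(res$stages$entrants[1], res$target_group_size)
    if (k > 1) {
      expect_equal(res$stages$entrants[-1], res$stages$passers[-k])
    }
    expect_true(all(res$stages$passers <= res$stages$entrants + 1e-12))
    # closed-form success count
    closed <- sc$population_size * sc$prevalence *
      prod(vapply(sc$filters, `[[`, numeric(1), "pass_rate"))
    expect_equal(res$n_success, closed, tolerance = 1e-9)
    # cost linearity: doubling unit costs doubles cost, leaves flows alone
    sc2 <- sc
    sc2$filters <- lapply(sc$filters, function(f) {
      f$unit_cost <- 2 * f$unit_cost; f
    })
    res2 <- run_cascade(sc2)
    expect_equal(res2$total_cost, 2 * res$total_cost, tolerance = 1e-12)
    expect_equal(res2$stages$passers, res$stages$passers)
    # scale equivariance in population size
    sc3 <- sc
    sc3$population_size <- 3 * sc$population_size
    res3 <- run_cascade(sc3)
    expect_equal(res3$total_cost, 3 * res$total_cost, tolerance = 1e-9)
    expect_equal(res3$n_success, 3 * res$n_success, tolerance = 1e-9)
    out <- compute_outcomes(res); out3 <- compute_outcomes(res3)
    expect_equal(out3$cost_per_success, out$cost_per_success, tolerance = 1e-9)
    expect_equal(out3$cost_per_patient, out$cost_per_patient, tolerance = 1e-9)
  }
})

test_that("the final filter's pass rate changes successes but not cost", {
  sc <- fixture_scenarios()[["baseline"]]
  res <- run_cascade(sc)
  sc_hi <- sc
  sc_hi$filters[[4]]$pass_rate <- 0.9
  res_hi <- run_cascade(sc_hi)
  expect_equal(res_hi$total_cost, res$total_cost)
  expect_gt(res_hi$n_success, res$n_success)
})
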