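test_that("sweeping the final filter's pass rate moves successes, never cost", {
  base <- fixture_scenarios()[["baseline"]]
  p <- parameter_path("pass_rate", "treatment")
  succ <- one_way_sweep(base, p, low = 0.30, high = 0.45, steps = 2,
                        metric = "n_success")
  expect_equal(succ$value, c(0.30, 0.45))
  expect_equal(succ$metric, c(18.9, 28.35))
  cost <- one_way_sweep(base, p, low = 0.30, high = 0.45, steps = 2,
                        metric = "total_cost")
  expect_equal(cost$metric, c(15300, 15300))
})

test_that("unit costs never affect flows; prevalence scales cost linearly", {
  base <- fixture_scenarios()[["baseline"]]
  s <- one_way_sweep(base, parameter_path("unit_cost", "detection"),
                     low = 0, high = 50, steps = 6, metric = "n_success")
  expect_equal(s$metric, rep(18.9, 6))
  s2 <- one_way_sweep(base, parameter_path("prevalence"),
                      low = 0.15, high = 0.30, steps = 2,
                      metric = "total_cost")
  expect_equal(s2$metric[2], 2 * s2$metric[1])
  expect_equal(s2$metric[1], 15300)
})

test_that("sweep ranges outside a field's domain are rejected before evaluation", {
  base <- fixture_scenarios()[["baseline"]]
  expect_error(
    one_way_sweep(base, parameter_path("pass_rate", "detection"),
                  low = 0.5, high = 1.2, steps = 3, metric = "n_success"),
    "validity domain", class = "cascade_validation_error")
  expect_error(
    one_way_sweep(base, parameter_path("unit_cost", "detection"),
                  low = -5, high = 5, steps = 3, metric = "total_cost"),
    class = "cascade_validation_error")
  expect_error(
    one_way_sweep(base, parameter_path("pass_rate", "nonexistent"),
                  low = 0.1, high = 0.2, steps = 2, metric = "n_success"),
    class = "cascade_validation_error")
})

test_that("sweeping a parameter through its current value reproduces the unmodified model", {
  fx <- fixture_scenarios()
  s <- one_way_sweep(fx[["scenario3"]], parameter_path("pass_rate", "acceptance"),
                     low = 0.30, high = 0.60, steps = 3, metric = "icer",
                     baseline = fx[["baseline"]])
  # midpoint of the grid is the scenario's own value, 0.45
  expect_equal(s$value[2], 0.45)
  expect_equal(s$metric[2],
               compare_scenarios(fx[["baseline"]], fx[["scenario3"]])$icer)
})

test_that("tornado ranks parameters by span, matching brute-force endpoints", {
  base <- fixture_scenarios()[["baseline"]]
  params <- list(
    list(parameter = parameter_path("pass_rate", "detection"),
         low = 0.10, high = 0.35),
    list(parameter = parameter_path("prevalence"), low = 0.10, high = 0.20),
    list(parameter = parameter_path("unit_cost", "treatment"),
         low = 50, high = 150)
  )
  tor <- tornado(base, params, metric = "n_success")
  # brute force: evaluate each endpoint independently
  brute <- vapply(params, function(p) {
    at <- function(v) {
      sc <- base
      if (is.null(p$parameter$filter_name)) {
        sc[[p$parameter$target]] <- v
      } else {
        i <- match(p$parameter$filter_name,
                   vapply(sc$filters, `[[`, character(1), "name"))
        sc$filters[[i]][[p$parameter$target]] <- v
      }
      run_cascade(sc)$n_success
    }
    abs(at(p$high) - at(p$low))
  }, numeric(1))
  expect_equal(tor$span, sort(brute, decreasing = TRUE))
  expect_equal(tor$parameter[tor$span == 0], "unit_cost[treatment]")
  # single parameter and empty input
  single <- tornado(base, params[1], metric = "n_success")
  expect_equal(nrow(single), 1L)
  expect_equal(single$span, abs(single$metric_at_high - single$metric_at_low))
  expect_equal(nrow(tornado(base, list(), metric = "n_success")), 0L)
})

test_that("tornado breaks span ties by parameter label, stably", {
  base <- fixture_scenarios()[["baseline"]]
  # two unit-cost parameters both have zero span on n_success
  params <- list(
    list(parameter = parameter_path("unit_cost", "treatment"), low = 1, high = 2),
    list(parameter = parameter_path("unit_cost", "detection"), low = 1, high = 2)
  )
  tor <- tornado(base, params, metric = "n_success")
  expect_equal(tor$parameter,
               c("unit_cost[detection]", "unit_cost[treatment]"))
})

test_that("threshold_solve recovers the acceptance rate giving ICER 500", {
  fx <- fixture_scenarios()
  solved <- threshold_solve(fx[["scenario3"]], fx[["baseline"]],
                            parameter_path("pass_rate", "acceptance"),
                            target_icer = 500, bracket = c(0.31, 0.9))
  # closed form: 21000 r - 4725 = 500 (63 r - 18.9)  =>  r = 4725/10500
  expect_equal(solved, 4725 / 10500, tolerance = 1e-6)
  # re-evaluation hits the target ICER
  sc <- fx[["scenario3"]]
  sc$filters[[3]]$pass_rate <- solved
  icer <- compare_scenarios(fx[["baseline"]], sc)$icer
  expect_lt(abs(icer - 500), 1e-3)
})

test_that("threshold_solve agrees with a grid scan and honours endpoints", {
  fx <- fixture_scenarios()
  p <- parameter_path("pass_rate", "acceptance")
  # target equal to the ICER at a bracket endpoint returns that endpoint
  sc_at <- function(v) {
    sc <- fx[["scenario3"]]; sc$filters[[3]]$pass_rate <- v; sc
  }
  icer_at <- function(v) compare_scenarios(fx[["baseline"]], sc_at(v))$icer
  expect_equal(threshold_solve(fx[["scenario3"]], fx[["baseline"]], p,
                               target_icer = icer_at(0.9),
                               bracket = c(0.31, 0.9)), 0.9)
  # 10,000-point grid scan oracle
  grid <- seq(0.31, 0.9, length.out = 10000)
  target <- 650
  best <- grid[which.min(abs(vapply(grid, icer_at, numeric(1)) - target))]
  solved <- threshold_solve(fx[["scenario3"]], fx[["baseline"]], p,
                            target_icer = target, bracket = c(0.31, 0.9))
  expect_lt(abs(solved - best), diff(grid[1:2]) + 1e-12)
})

test_that("threshold_solve rejects unreachable targets and non-monotone brackets", {
  fx <- fixture_scenarios()
  p <- parameter_path("pass_rate", "acceptance")
  expect_error(
    threshold_solve(fx[["scenario3"]], fx[["baseline"]], p,
                    target_icer = 10, bracket = c(0.31, 0.9)),
    "achieved range", class = "cascade_validation_error")
  # ICER with a pole inside the bracket: baseline and scenario differ only
  # in the first filter's unit cost, so incremental cost is constant and
  # incremental successes cross zero at rate 0.5
  mk <- function(cost1) {
    scenario_spec("s", 1000, 0.1,
                  filters = list(filter_spec("screen", 0.5, cost1),
                                 filter_spec("treat", 0.5, 0)))
  }
  expect_error(
    threshold_solve(mk(2), mk(1), parameter_path("pass_rate", "screen"),
                    target_icer = 10, bracket = c(0.2, 0.9)),
    "monotone", class = "cascade_validation_error")
})
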