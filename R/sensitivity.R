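#' Address one numeric field of a scenario
#'
#' A parameter path names exactly one tunable number of a scenario:
#' its prevalence, its population size, or one filter's pass rate or
#' unit cost. Paths drive the one-way sensitivity tools
#' ([one_way_sweep()], [tornado()], [threshold_solve()]).
#'
#' @param target One of `"prevalence"`, `"population_size"`,
#'   `"pass_rate"`, `"unit_cost"`.
#' @param filter_name Filter name; required when `target` is a
#'   filter-level field.
#' @return An object of class `cascade_parameter`.
#' @examples
#' parameter_path("pass_rate", "treatment")
#' parameter_path("prevalence")
#' @export
parameter_path <- function(target = c("prevalence", "population_size",
                                      "pass_rate", "unit_cost"),
                           filter_name = NULL) {
  target <- match.arg(target)
  filter_level <- target %in% c("pass_rate", "unit_cost")
  if (filter_level) {
    check_string(filter_name, "filter_name")
  } else if (!is.null(filter_name)) {
    stop_validation(sprintf("`filter_name` is not used for target \"%s\"", target))
  }
  structure(
    list(target = target, filter_name = filter_name),
    class = "cascade_parameter"
  )
}

parameter_label <- function(parameter) {
  if (is.null(parameter$filter_name)) parameter$target
  else sprintf("%s[%s]", parameter$target, parameter$filter_name)
}

#' @export
print.cascade_parameter <- function(x, ...) {
  cat("<parameter ", parameter_label(x), ">\n", sep = "")
  invisible(x)
}

parameter_domain <- function(parameter) {
  switch(parameter$target,
         prevalence = c(0, 1),
         pass_rate = c(0, 1),
         population_size = c(.Machine$double.xmin, Inf),
         unit_cost = c(0, Inf))
}

get_parameter <- function(scenario, parameter) {
  if (is.null(parameter$filter_name)) {
    scenario[[parameter$target]]
  } else {
    i <- match(parameter$filter_name, filter_names(scenario))
    if (is.na(i)) {
      stop_validation(sprintf("scenario %s has no filter named \"%s\"",
                              scenario$scenario_id, parameter$filter_name),
                      field = "filter_name")
    }
    scenario$filters[[i]][[parameter$target]]
  }
}

set_parameter <- function(scenario, parameter, value) {
  dom <- parameter_domain(parameter)
  if (!is_scalar_number(value) || value < dom[1] || value > dom[2]) {
    stop_validation(
      sprintf("value %s for %s is outside its validity domain [%g, %g]",
              deparse1(value), parameter_label(parameter), dom[1], dom[2]),
      field = parameter_label(parameter)
    )
  }
  if (is.null(parameter$filter_name)) {
    scenario[[parameter$target]] <- as.numeric(value)
  } else {
    i <- match(parameter$filter_name, filter_names(scenario))
    if (is.na(i)) {
      stop_validation(sprintf("scenario %s has no filter named \"%s\"",
                              scenario$scenario_id, parameter$filter_name),
                      field = "filter_name")
    }
    scenario$filters[[i]][[parameter$target]] <- as.numeric(value)
  }
  scenario
}

eval_metric <- function(scenario, metric, baseline_result = NULL) {
  res <- run_cascade(scenario)
  switch(metric,
         total_cost = res$total_cost,
         n_success = res$n_success,
         cost_per_success = compute_outcomes(res)$cost_per_success,
         icer = {
           if (is.null(baseline_result)) {
             stop_validation("metric \"icer\" requires a baseline scenario")
           }
           compare_scenarios(baseline_result, res)$icer
         })
}

#' One-way deterministic sensitivity sweep
#'
#' Re-evaluates a scenario over an evenly spaced grid of values for a
#' single parameter, all other fields held fixed, and records a chosen
#' outcome metric at each grid point. The whole grid is validated
#' against the parameter's domain (rates in `[0, 1]`, costs >= 0,
#' population > 0) before any evaluation.
#'
#' @param scenario The [scenario_spec()] whose parameter is varied.
#' @param parameter A [parameter_path()].
#' @param low,high Sweep range, `low < high`.
#' @param steps Number of grid points, >= 2.
#' @param metric One of `"total_cost"`, `"n_success"`,
#'   `"cost_per_success"`, `"icer"`.
#' @param baseline Fixed comparator [scenario_spec()]; required when
#'   `metric = "icer"`, ignored otherwise.
#' @return data.frame with columns `value` (the swept parameter value)
#'   and `metric` (the metric at that value).
#' @examples
#' base <- table1_fixture()$scenarios[["baseline"]]
#' one_way_sweep(base, parameter_path("pass_rate", "treatment"),
#'               low = 0.30, high = 0.45, steps = 2, metric = "n_success")
#' @export
one_way_sweep <- function(scenario, parameter, low, high, steps = 11L,
                          metric = c("total_cost", "n_success",
                                     "cost_per_success", "icer"),
                          baseline = NULL) {
  metric <- match.arg(metric)
  if (!inherits(parameter, "cascade_parameter")) {
    stop_validation("`parameter` must come from parameter_path()")
  }
  if (!is_scalar_number(low) || !is_scalar_number(high) || low >= high) {
    stop_validation("`low` must be strictly less than `high`")
  }
  if (!is_scalar_number(steps) || steps < 2) {
    stop_validation("`steps` must be an integer >= 2")
  }
  dom <- parameter_domain(parameter)
  if (low < dom[1] || high > dom[2]) {
    stop_validation(
      sprintf("sweep range [%g, %g] for %s leaves its validity domain [%g, %g]",
              low, high, parameter_label(parameter), dom[1], dom[2]),
      field = parameter_label(parameter)
    )
  }
  base_res <- if (metric == "icer") as_cascade_result(baseline) else NULL
  grid <- seq(low, high, length.out = as.integer(steps))
  vals <- vapply(grid, function(v) {
    eval_metric(set_parameter(scenario, parameter, v), metric, base_res)
  }, numeric(1))
  data.frame(value = grid, metric = vals)
}

#' Tornado analysis over several parameters
#'
#' Evaluates a metric at the low and high end of each parameter's
#' plausible range and ranks parameters by the absolute span of the
#' metric, largest first (the standard tornado-diagram ordering). Ties
#' are broken by parameter label, alphabetically, so the ordering is
#' stable.
#'
#' @param scenario The scenario being analysed.
#' @param parameters List of entries, each a list with elements
#'   `parameter` (a [parameter_path()]), `low` and `high`.
#' @param metric As in [one_way_sweep()].
#' @param baseline Comparator scenario, required for `metric = "icer"`.
#' @return data.frame with columns `parameter`, `low`, `high`,
#'   `metric_at_low`, `metric_at_high`, `span`, sorted by decreasing
#'   span; empty input gives an empty data.frame.
#' @examples
#' base <- table1_fixture()$scenarios[["baseline"]]
#' tornado(base, list(
#'   list(parameter = parameter_path("pass_rate", "detection"),
#'        low = 0.10, high = 0.35),
#'   list(parameter = parameter_path("prevalence"), low = 0.10, high = 0.20)
#' ), metric = "n_success")
#' @export
tornado <- function(scenario, parameters,
                    metric = c("total_cost", "n_success",
                               "cost_per_success", "icer"),
                    baseline = NULL) {
  metric <- match.arg(metric)
  empty <- data.frame(parameter = character(), low = numeric(),
                      high = numeric(), metric_at_low = numeric(),
                      metric_at_high = numeric(), span = numeric(),
                      stringsAsFactors = FALSE)
  if (length(parameters) == 0L) return(empty)
  base_res <- if (metric == "icer") as_cascade_result(baseline) else NULL
  rows <- lapply(parameters, function(p) {
    if (!inherits(p$parameter, "cascade_parameter")) {
      stop_validation("each entry needs a `parameter` from parameter_path()")
    }
    dom <- parameter_domain(p$parameter)
    if (!is_scalar_number(p$low) || !is_scalar_number(p$high) ||
        p$low >= p$high || p$low < dom[1] || p$high > dom[2]) {
      stop_validation(
        sprintf("range [%s, %s] invalid for %s",
                deparse1(p$low), deparse1(p$high),
                parameter_label(p$parameter)),
        field = parameter_label(p$parameter)
      )
    }
    at_low <- eval_metric(set_parameter(scenario, p$parameter, p$low),
                          metric, base_res)
    at_high <- eval_metric(set_parameter(scenario, p$parameter, p$high),
                           metric, base_res)
    data.frame(parameter = parameter_label(p$parameter),
               low = p$low, high = p$high,
               metric_at_low = at_low, metric_at_high = at_high,
               span = abs(at_high - at_low), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Solve a parameter value for a target ICER
#'
#' Finds, by bisection, the value of one scenario parameter at which
#' the scenario's ICER versus a fixed baseline equals a target
#' willingness-to-pay. The ICER must be strictly monotone in the
#' parameter over the bracket; monotonicity is checked at the bracket
#' endpoints and midpoint rather than assumed, because mixed cost
#' structures can make the ICER non-monotone.
#'
#' @param scenario Scenario whose parameter is solved for.
#' @param baseline Fixed comparator scenario.
#' @param parameter A [parameter_path()] into `scenario`.
#' @param target_icer Target ICER in currency per success.
#' @param bracket Numeric length-2 `(low, high)` bracketing the
#'   solution; both ends must be in the parameter's validity domain.
#' @param tol Absolute tolerance on the parameter (default `1e-6`).
#' @param max_iter Bisection iteration cap (default 200; the cascade is
#'   cheap and smooth so this is never binding at the default `tol`).
#' @return The solved parameter value (a single number).
#' @examples
#' fx <- table1_fixture()
#' threshold_solve(fx$scenarios[["scenario3"]], fx$scenarios[["baseline"]],
#'                 parameter_path("pass_rate", "acceptance"),
#'                 target_icer = 500, bracket = c(0.31, 0.9))  # 0.45
#' @export
threshold_solve <- function(scenario, baseline, parameter, target_icer,
                            bracket, tol = 1e-6, max_iter = 200L) {
  if (!inherits(parameter, "cascade_parameter")) {
    stop_validation("`parameter` must come from parameter_path()")
  }
  if (!is.numeric(bracket) || length(bracket) != 2L || bracket[1] >= bracket[2]) {
    stop_validation("`bracket` must be c(low, high) with low < high")
  }
  check_nonneg(tol, "tol")
  dom <- parameter_domain(parameter)
  if (bracket[1] < dom[1] || bracket[2] > dom[2]) {
    stop_validation(
      sprintf("bracket [%g, %g] leaves the validity domain [%g, %g] of %s",
              bracket[1], bracket[2], dom[1], dom[2],
              parameter_label(parameter)),
      field = parameter_label(parameter)
    )
  }
  base_res <- as_cascade_result(baseline)
  icer_at <- function(v) {
    val <- eval_metric(set_parameter(scenario, parameter, v), "icer", base_res)
    if (is.na(val)) {
      stop_validation(
        sprintf("ICER undefined (zero incremental successes) at %s = %g",
                parameter_label(parameter), v)
      )
    }
    val
  }
  lo <- bracket[1]; hi <- bracket[2]; mid <- (lo + hi) / 2
  f_lo <- icer_at(lo); f_hi <- icer_at(hi); f_mid <- icer_at(mid)
  increasing <- f_hi > f_lo
  mono_ok <- if (increasing) (f_lo < f_mid && f_mid < f_hi)
             else (f_lo > f_mid && f_mid > f_hi)
  if (!mono_ok) {
    stop_validation(
      sprintf(paste0("ICER is not strictly monotone in %s over [%g, %g] ",
                     "(endpoint/midpoint check); try a narrower bracket"),
              parameter_label(parameter), lo, hi)
    )
  }
  rng <- range(f_lo, f_hi)
  if (target_icer < rng[1] || target_icer > rng[2]) {
    stop_validation(
      sprintf("target ICER %g outside the achieved range [%g, %g] on the bracket",
              target_icer, rng[1], rng[2])
    )
  }
  if (target_icer == f_lo) return(lo)
  if (target_icer == f_hi) return(hi)
  g <- function(v) icer_at(v) - target_icer
  s_lo <- g(lo)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if ((hi - lo) / 2 < tol) break
    s_mid <- g(mid)
    if (s_mid == 0) return(mid)
    if (sign(s_mid) == sign(s_lo)) {
      lo <- mid; s_lo <- s_mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}
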