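#' Define a single cascade filter
#'
#' A filter is one stage of a care pathway: a fraction `pass_rate` of the
#' people entering the stage pass through to the next stage, and a unit
#' cost is charged for every person who *enters* the stage (passers and
#' non-passers alike).
#'
#' @param name Identifier, unique within a scenario (e.g. `"detection"`).
#' @param pass_rate Proportion of stage entrants who pass, in `[0, 1]`.
#' @param unit_cost Non-negative cost per stage entrant, in opaque
#'   currency units.
#' @param description Free-text description of how the stage is delivered
#'   (e.g. `"Clinician judgement"`, `"Computerised short screening tool"`).
#'
#' @return An object of class `cascade_filter`.
#' @seealso [scenario_spec()], [run_cascade()]
#' @examples
#' filter_spec("detection", pass_rate = 0.20, unit_cost = 5,
#'             description = "Clinician judgement")
#' @export
filter_spec <- function(name, pass_rate, unit_cost, description = "") {
  check_string(name, "name")
  check_proportion(pass_rate, sprintf("filters[%s].pass_rate", name))
  check_nonneg(unit_cost, sprintf("filters[%s].unit_cost", name))
  if (!is_scalar_string(description)) {
    stop_validation(sprintf("`filters[%s].description` must be a string", name),
                    field = "description")
  }
  structure(
    list(name = name, description = description,
         pass_rate = as.numeric(pass_rate),
         unit_cost = as.numeric(unit_cost)),
    class = "cascade_filter"
  )
}

#' Define a complete scenario
#'
#' A scenario is one configuration of the cascade model: a population, a
#' prevalence of the target condition, and an ordered list of filters.
#' The target group (population x prevalence) enters the first filter;
#' by convention the final filter is the treatment stage, and its passers
#' are the successful outcomes.
#'
#' @param scenario_id Identifier, unique within a [model_config()].
#' @param population_size Positive number of persons in the population.
#' @param prevalence Proportion of the population in the target group,
#'   in `[0, 1]`.
#' @param filters List of [filter_spec()] objects, length >= 1, with
#'   unique names.
#' @param label Free-text label for display.
#'
#' @return An object of class `cascade_scenario`.
#' @examples
#' scenario_spec(
#'   "baseline", population_size = 10000, prevalence = 0.15,
#'   filters = list(
#'     filter_spec("detection", 0.20, 5),
#'     filter_spec("treatment", 0.30, 100)
#'   )
#' )
#' @export
scenario_spec <- function(scenario_id, population_size, prevalence,
                          filters, label = scenario_id) {
  check_string(scenario_id, "scenario_id")
  check_string(label, "label", allow_empty = TRUE)
  check_positive(population_size, "population_size")
  check_proportion(prevalence, "prevalence")
  if (!is.list(filters) || length(filters) < 1L) {
    stop_validation("`filters` must be a non-empty list of filter_spec objects",
                    field = "filters")
  }
  filters <- lapply(filters, function(f) {
    if (!inherits(f, "cascade_filter")) {
      if (is.list(f)) {
        return(do.call(filter_spec, f))
      }
      stop_validation("each element of `filters` must be a filter_spec",
                      field = "filters")
    }
    f
  })
  nm <- vapply(filters, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop_validation(
      sprintf("filter names must be unique within a scenario; duplicated: %s",
              paste(unique(nm[duplicated(nm)]), collapse = ", ")),
      field = "filters"
    )
  }
  structure(
    list(scenario_id = scenario_id, label = label,
         population_size = as.numeric(population_size),
         prevalence = as.numeric(prevalence),
         filters = filters),
    class = "cascade_scenario"
  )
}

filter_names <- function(scenario) {
  vapply(scenario$filters, `[[`, character(1), "name")
}

#' Evaluate a scenario's expected flow and cost through the cascade
#'
#' Propagates the expected (fractional) number of persons through the
#' ordered filters. The target group (`population_size * prevalence`)
#' enters the first filter; each stage's passers (`entrants * pass_rate`)
#' become the next stage's entrants. Each stage's cost is
#' `unit_cost * entrants`. All flows are kept unrounded; rounding happens
#' only at display time via [display_round()].
#'
#' @param scenario A [scenario_spec()] object.
#'
#' @return An object of class `cascade_result`, a list with:
#' \describe{
#'   \item{scenario_id, label}{copied from the scenario}
#'   \item{target_group_size}{`population_size * prevalence`}
#'   \item{stages}{data.frame with one row per filter: `filter_name`,
#'     `pass_rate`, `unit_cost`, `entrants`, `passers`, `stage_cost`}
#'   \item{total_cost}{sum of stage costs}
#'   \item{n_receiving_care}{entrants to the final (treatment) filter}
#'   \item{n_success}{passers of the final filter}
#' }
#' @examples
#' res <- run_cascade(table1_fixture()$scenarios[["baseline"]])
#' res$stages
#' res$total_cost   # 15300
#' res$n_success    # 18.9
#' @export
run_cascade <- function(scenario) {
  if (!inherits(scenario, "cascade_scenario")) {
    stop_validation("`scenario` must be a cascade_scenario (see scenario_spec())")
  }
  target <- scenario$population_size * scenario$prevalence
  k <- length(scenario$filters)
  entrants <- passers <- stage_cost <- numeric(k)
  flow <- target
  for (i in seq_len(k)) {
    f <- scenario$filters[[i]]
    entrants[i] <- flow
    passers[i] <- flow * f$pass_rate
    stage_cost[i] <- f$unit_cost * flow
    flow <- passers[i]
  }
  stages <- data.frame(
    filter_name = filter_names(scenario),
    pass_rate = vapply(scenario$filters, `[[`, numeric(1), "pass_rate"),
    unit_cost = vapply(scenario$filters, `[[`, numeric(1), "unit_cost"),
    entrants = entrants,
    passers = passers,
    stage_cost = stage_cost,
    stringsAsFactors = FALSE
  )
  structure(
    list(scenario_id = scenario$scenario_id, label = scenario$label,
         population_size = scenario$population_size,
         prevalence = scenario$prevalence,
         target_group_size = target,
         stages = stages,
         total_cost = sum(stage_cost),
         n_receiving_care = entrants[k],
         n_success = passers[k]),
    class = "cascade_result"
  )
}

#' Per-scenario outcome metrics
#'
#' Computes the cost summaries for one evaluated scenario: total pathway
#' cost, cost per patient receiving care (total cost divided by entrants
#' to the final filter, i.e. those who accepted treatment), and cost per
#' successful outcome (total cost divided by expected successes). Ratios
#' are computed on unrounded flows. A ratio whose denominator is zero is
#' undefined and returned as `NA`, never silently zeroed.
#'
#' @param result A `cascade_result` from [run_cascade()].
#' @return An object of class `cascade_outcomes`: a list with
#'   `scenario_id`, `total_cost`, `n_receiving_care`, `n_success`,
#'   `cost_per_patient`, `cost_per_success`.
#' @examples
#' out <- compute_outcomes(run_cascade(table1_fixture()$scenarios[["baseline"]]))
#' out$cost_per_patient  # 242.8571...
#' out$cost_per_success  # 809.5238...
#' @export
compute_outcomes <- function(result) {
  if (!inherits(result, "cascade_result")) {
    stop_validation("`result` must come from run_cascade()")
  }
  cpp <- if (result$n_receiving_care > 0) {
    result$total_cost / result$n_receiving_care
  } else NA_real_
  cps <- if (result$n_success > 0) {
    result$total_cost / result$n_success
  } else NA_real_
  structure(
    list(scenario_id = result$scenario_id,
         total_cost = result$total_cost,
         n_receiving_care = result$n_receiving_care,
         n_success = result$n_success,
         cost_per_patient = cpp,
         cost_per_success = cps),
    class = "cascade_outcomes"
  )
}

#' @export
print.cascade_filter <- function(x, ...) {
  cat(sprintf("<filter %s> pass rate %.4g, unit cost %.4g%s\n",
              x$name, x$pass_rate, x$unit_cost,
              if (nzchar(x$description)) paste0(" (", x$description, ")") else ""))
  invisible(x)
}

#' @export
print.cascade_scenario <- function(x, ...) {
  cat(sprintf("<scenario %s> \"%s\"\n", x$scenario_id, x$label))
  cat(sprintf("  population %s, prevalence %.4g (target group %s)\n",
              format(x$population_size, big.mark = ","), x$prevalence,
              format(x$population_size * x$prevalence, big.mark = ",")))
  for (f in x$filters) {
    cat("  "); print(f)
  }
  invisible(x)
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("<cascade result %s>\n", x$scenario_id))
  print(x$stages, row.names = FALSE)
  cat(sprintf("total cost %.2f | receiving care %.4g | successes %.4g\n",
              x$total_cost, x$n_receiving_care, x$n_success))
  invisible(x)
}

#' @export
print.cascade_outcomes <- function(x, ...) {
  cat(sprintf("<outcomes %s> total %.2f, per patient %s, per success %s\n",
              x$scenario_id, x$total_cost,
              ifelse(is.na(x$cost_per_patient), "undefined",
                     sprintf("%.2f", x$cost_per_patient)),
              ifelse(is.na(x$cost_per_success), "undefined",
                     sprintf("%.2f", x$cost_per_success))))
  invisible(x)
}
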