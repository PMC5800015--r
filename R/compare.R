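#' Cost-effectiveness plane quadrant labels
#'
#' The five mutually exclusive classifications of a scenario relative to
#' its baseline by the signs of incremental cost and incremental
#' effectiveness. Boundary cases (one increment exactly zero) are
#' assigned by the sign of the non-zero increment: equally effective at
#' higher cost is weakly dominated, equally costly with more successes is
#' weakly dominant.
#'
#' @format Character vector of the five labels.
#' @export
QUADRANTS <- c(
  "MORE_EXPENSIVE_MORE_EFFECTIVE",
  "MORE_EXPENSIVE_LESS_EFFECTIVE",
  "CHEAPER_MORE_EFFECTIVE",
  "CHEAPER_LESS_EFFECTIVE",
  "EQUIVALENT"
)

classify_quadrant <- function(d_cost, d_succ) {
  if (d_cost == 0 && d_succ == 0) return("EQUIVALENT")
  if (d_succ > 0) {
    if (d_cost > 0) "MORE_EXPENSIVE_MORE_EFFECTIVE" else "CHEAPER_MORE_EFFECTIVE"
  } else if (d_succ < 0) {
    if (d_cost < 0) "CHEAPER_LESS_EFFECTIVE" else "MORE_EXPENSIVE_LESS_EFFECTIVE"
  } else {
    # d_succ == 0, d_cost != 0: cost-only difference
    if (d_cost > 0) "MORE_EXPENSIVE_LESS_EFFECTIVE" else "CHEAPER_MORE_EFFECTIVE"
  }
}

#' Compare a scenario to a baseline
#'
#' Computes incremental cost (scenario total cost minus baseline total
#' cost), incremental successes (difference of unrounded expected
#' success counts), the incremental cost-effectiveness ratio
#' (ICER = incremental cost / incremental successes, on *unrounded*
#' increments), and the cost-effectiveness-plane quadrant. When the
#' incremental success count is exactly zero the ICER is undefined
#' (`NA`), not infinite and not zero: division by a zero effect carries
#' no decision meaning. A negative ICER can arise in the off-diagonal
#' quadrants; the quadrant label is the primary decision signal and the
#' raw ratio is retained for transparency.
#'
#' @param baseline,scenario Either `cascade_result` objects from
#'   [run_cascade()] or `cascade_scenario` objects (evaluated
#'   internally).
#' @return An object of class `cascade_comparison`: list with
#'   `baseline_id`, `scenario_id`, `incremental_cost`,
#'   `incremental_successes`, `icer`, `quadrant`, `advice`.
#' @examples
#' fx <- table1_fixture()
#' cmp <- compare_scenarios(fx$scenarios[["baseline"]],
#'                          fx$scenarios[["scenario3"]])
#' cmp$incremental_cost       # 4725
#' cmp$incremental_successes  # 9.45
#' cmp$icer                   # 500
#' @export
compare_scenarios <- function(baseline, scenario) {
  baseline <- as_cascade_result(baseline)
  scenario <- as_cascade_result(scenario)
  d_cost <- scenario$total_cost - baseline$total_cost
  d_succ <- scenario$n_success - baseline$n_success
  icer <- if (d_succ != 0) d_cost / d_succ else NA_real_
  quadrant <- classify_quadrant(d_cost, d_succ)
  out <- structure(
    list(baseline_id = baseline$scenario_id,
         scenario_id = scenario$scenario_id,
         incremental_cost = d_cost,
         incremental_successes = d_succ,
         icer = icer,
         quadrant = quadrant,
         advice = NA_character_),
    class = "cascade_comparison"
  )
  out$advice <- policy_advice(out)
  out
}

as_cascade_result <- function(x) {
  if (inherits(x, "cascade_result")) return(x)
  if (inherits(x, "cascade_scenario")) return(run_cascade(x))
  stop_validation("expected a cascade_result or cascade_scenario")
}

#' Policy advice from a comparison
#'
#' Deterministic mapping from the quadrant of a comparison to an advice
#' sentence in the style of published cascade-model reports: whether the
#' scenario is MORE EXPENSIVE or CHEAPER, and has BETTER or WORSE
#' EFFECTIVENESS, than the baseline; dominant/dominated cases are
#' labelled as such.
#'
#' @param comparison A `cascade_comparison` from [compare_scenarios()].
#' @return A single advice string.
#' @examples
#' fx <- table1_fixture()
#' cmp <- compare_scenarios(fx$scenarios[["baseline"]],
#'                          fx$scenarios[["scenario1"]])
#' policy_advice(cmp)
#' @export
policy_advice <- function(comparison) {
  if (!inherits(comparison, "cascade_comparison")) {
    stop_validation("`comparison` must come from compare_scenarios()")
  }
  body <- switch(
    comparison$quadrant,
    MORE_EXPENSIVE_MORE_EFFECTIVE =
      "MORE EXPENSIVE and has BETTER EFFECTIVENESS",
    MORE_EXPENSIVE_LESS_EFFECTIVE =
      "MORE EXPENSIVE and has WORSE EFFECTIVENESS (dominated)",
    CHEAPER_MORE_EFFECTIVE =
      "CHEAPER and has BETTER EFFECTIVENESS (dominant)",
    CHEAPER_LESS_EFFECTIVE =
      "CHEAPER and has WORSE EFFECTIVENESS",
    EQUIVALENT =
      "EQUIVALENT in cost and effectiveness"
  )
  paste0("Compared to the baseline this scenario is ", body)
}

#' Compare every scenario in a configuration to its baseline
#'
#' Runs each scenario and compares it to the designated baseline,
#' preserving input order and omitting the baseline-vs-itself
#' comparison.
#'
#' @param scenarios A [model_config()], or a list of
#'   [scenario_spec()] objects.
#' @param baseline_id Identifier of the baseline scenario; defaults to
#'   the config's `baseline_id` when `scenarios` is a `cascade_config`.
#' @return List of `cascade_comparison` objects, one per non-baseline
#'   scenario, named by scenario id.
#' @examples
#' cmps <- compare_all(table1_fixture())
#' sapply(cmps, `[[`, "icer")
#' @export
compare_all <- function(scenarios, baseline_id = NULL) {
  if (inherits(scenarios, "cascade_config")) {
    if (is.null(baseline_id)) baseline_id <- scenarios$baseline_id
    scenarios <- scenarios$scenarios
  }
  if (!is.list(scenarios) || !all(vapply(scenarios, inherits, logical(1),
                                         "cascade_scenario"))) {
    stop_config("`scenarios` must be a cascade_config or a list of scenario_spec objects")
  }
  ids <- vapply(scenarios, `[[`, character(1), "scenario_id")
  if (anyDuplicated(ids)) {
    stop_config(sprintf("duplicated scenario ids: %s",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (is.null(baseline_id) || !baseline_id %in% ids) {
    stop_config(sprintf("baseline_id %s not found among scenario ids (%s)",
                        deparse1(baseline_id), paste(ids, collapse = ", ")))
  }
  base_res <- run_cascade(scenarios[[match(baseline_id, ids)]])
  others <- scenarios[ids != baseline_id]
  out <- lapply(others, function(sc) compare_scenarios(base_res, run_cascade(sc)))
  names(out) <- ids[ids != baseline_id]
  out
}

#' @export
print.cascade_comparison <- function(x, ...) {
  cat(sprintf("<comparison %s vs %s>\n", x$scenario_id, x$baseline_id))
  cat(sprintf("  incremental cost %.2f | incremental successes %.4g | ICER %s\n",
              x$incremental_cost, x$incremental_successes,
              ifelse(is.na(x$icer), "undefined", sprintf("%.2f", x$icer))))
  cat("  ", x$advice, "\n", sep = "")
  invisible(x)
}
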