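#' Bundle scenarios and a designated baseline
#'
#' A model configuration carries everything one analysis needs: a
#' currency symbol for display, the id of the baseline scenario, and the
#' ordered scenarios themselves. Scenario ids must be unique and the
#' baseline id must be among them. When the scenarios do not all share
#' the same filter-name sequence a warning is issued (batch comparison
#' still works via the final-stage convention), never an error.
#'
#' @param scenarios List of [scenario_spec()] objects.
#' @param baseline_id Id of the baseline scenario.
#' @param currency_symbol Display symbol for currency values.
#' @return Object of class `cascade_config`; `$scenarios` is a list
#'   named by scenario id, in input order.
#' @examples
#' cfg <- table1_fixture()
#' names(cfg$scenarios)
#' @export
model_config <- function(scenarios, baseline_id, currency_symbol = "$") {
  check_string(currency_symbol, "currency_symbol", allow_empty = TRUE)
  check_string(baseline_id, "baseline_id")
  if (!is.list(scenarios) || length(scenarios) < 1L ||
      !all(vapply(scenarios, inherits, logical(1), "cascade_scenario"))) {
    stop_config("`scenarios` must be a non-empty list of scenario_spec objects",
                field = "scenarios")
  }
  ids <- vapply(scenarios, `[[`, character(1), "scenario_id")
  if (anyDuplicated(ids)) {
    stop_config(sprintf("duplicated scenario ids: %s",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                field = "scenarios")
  }
  if (!baseline_id %in% ids) {
    stop_config(sprintf("baseline_id \"%s\" not among scenario ids (%s)",
                        baseline_id, paste(ids, collapse = ", ")),
                field = "baseline_id")
  }
  seqs <- vapply(scenarios, function(s) paste(filter_names(s), collapse = "|"),
                 character(1))
  if (length(unique(seqs)) > 1L) {
    warning("scenarios do not all share the same filter-name sequence; ",
            "comparisons use the final-stage convention", call. = FALSE)
  }
  names(scenarios) <- ids
  structure(
    list(currency_symbol = currency_symbol,
         baseline_id = baseline_id,
         scenarios = scenarios),
    class = "cascade_config"
  )
}

#' @export
print.cascade_config <- function(x, ...) {
  cat(sprintf("<cascade config> %d scenario(s), baseline \"%s\"\n",
              length(x$scenarios), x$baseline_id))
  for (s in x$scenarios) {
    cat(sprintf("  %s%s: \"%s\"\n", s$scenario_id,
                if (s$scenario_id == x$baseline_id) " (baseline)" else "",
                s$label))
  }
  invisible(x)
}

# ---- worked-example fixture -------------------------------------------------

#' Built-in worked example: depression care in cancer
#'
#' The packaged four-filter depression-in-cancer configuration: a
#' population of 10,000 cancer patients with 15% depression prevalence
#' (target group 1,500), filtered through detection, provider response,
#' patient acceptance and treatment. Baseline pass rates are
#' 0.20/0.70/0.30/0.30 at unit costs $5/$5/$0/$100 per stage entrant.
#' Four intervention scenarios each raise exactly one filter's pass rate
#' by 15 percentage points at a higher unit cost: detection to 0.35 at
#' $10, provider response to 0.85 at $10, acceptance to 0.45 at $7.50,
#' treatment effectiveness to 0.45 at $300.
#'
#' The published table this example reproduces prints the target group
#' as "n = 55,500", which is arithmetically inconsistent with 15% of
#' 10,000; every downstream figure confirms 1,500, which is what this
#' fixture encodes.
#'
#' @return A [model_config()] with five scenarios, baseline designated.
#' @examples
#' fx <- table1_fixture()
#' run_cascade(fx$scenarios[["baseline"]])$total_cost  # 15300
#' @export
table1_fixture <- function() {
  base_filters <- function(detection = filter_spec(
                             "detection", 0.20, 5, "Clinician judgement"),
                           provider = filter_spec(
                             "provider_response", 0.70, 5, "Clinician judgement"),
                           acceptance = filter_spec(
                             "acceptance", 0.30, 0, "Patient judgement"),
                           treatment = filter_spec(
                             "treatment", 0.30, 100, "Referral to primary care")) {
    list(detection, provider, acceptance, treatment)
  }
  mk <- function(id, label, filters) {
    scenario_spec(id, population_size = 10000, prevalence = 0.15,
                  filters = filters, label = label)
  }
  model_config(
    baseline_id = "baseline",
    currency_symbol = "$",
    scenarios = list(
      mk("baseline",
         "Usual care (target group 1,500 = 15% of 10,000)",
         base_filters()),
      mk("scenario1", "Increase detection",
         base_filters(detection = filter_spec(
           "detection", 0.35, 10, "Computerised short screening tool"))),
      mk("scenario2", "Increase provider response",
         base_filters(provider = filter_spec(
           "provider_response", 0.85, 10,
           paste("Provision of patient distress screening scores and",
                 "recommendation to clinician")))),
      mk("scenario3", "Increase patient acceptance",
         base_filters(acceptance = filter_spec(
           "acceptance", 0.45, 7.50,
           "Distress scores & recommendation provided to patient"))),
      mk("scenario4", "Increase treatment effectiveness",
         base_filters(treatment = filter_spec(
           "treatment", 0.45, 300, "Collaborative care model")))
    )
  )
}

# ---- file I/O ---------------------------------------------------------------

config_keys <- c("currency_symbol", "baseline_id", "scenarios")
scenario_keys <- c("scenario_id", "label", "population_size",
                   "prevalence", "filters")
filter_keys <- c("name", "description", "pass_rate", "unit_cost")

check_known_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop_config(sprintf("unknown key(s) %s in %s (allowed: %s)",
                        paste(sprintf("\"%s\"", extra), collapse = ", "),
                        where, paste(allowed, collapse = ", ")),
                field = where)
  }
  missing <- setdiff(setdiff(allowed, c("label", "description",
                                        "currency_symbol")), names(x))
  if (length(missing)) {
    stop_config(sprintf("missing required key(s) %s in %s",
                        paste(sprintf("\"%s\"", missing), collapse = ", "),
                        where),
                field = where)
  }
  invisible(x)
}

config_from_list <- function(raw) {
  if (!is.list(raw)) stop_config("config root must be a mapping")
  check_known_keys(raw, config_keys, "config")
  scenarios <- lapply(seq_along(raw$scenarios), function(i) {
    sc <- raw$scenarios[[i]]
    where <- sprintf("scenarios[%d]", i)
    if (!is.list(sc)) stop_config(sprintf("%s must be a mapping", where))
    check_known_keys(sc, scenario_keys, where)
    filters <- lapply(seq_along(sc$filters), function(j) {
      fl <- sc$filters[[j]]
      fwhere <- sprintf("%s.filters[%d]", where, j)
      if (!is.list(fl)) stop_config(sprintf("%s must be a mapping", fwhere))
      check_known_keys(fl, filter_keys, fwhere)
      filter_spec(name = fl$name,
                  pass_rate = fl$pass_rate,
                  unit_cost = fl$unit_cost,
                  description = fl$description %||% "")
    })
    scenario_spec(scenario_id = sc$scenario_id,
                  population_size = sc$population_size,
                  prevalence = sc$prevalence,
                  filters = filters,
                  label = sc$label %||% sc$scenario_id)
  })
  model_config(scenarios = scenarios,
               baseline_id = raw$baseline_id,
               currency_symbol = raw$currency_symbol %||% "$")
}

config_to_list <- function(config) {
  list(
    currency_symbol = config$currency_symbol,
    baseline_id = config$baseline_id,
    scenarios = lapply(unname(config$scenarios), function(sc) {
      list(
        scenario_id = sc$scenario_id,
        label = sc$label,
        population_size = sc$population_size,
        prevalence = sc$prevalence,
        filters = lapply(sc$filters, function(f) {
          list(name = f$name, description = f$description,
               pass_rate = f$pass_rate, unit_cost = f$unit_cost)
        })
      )
    })
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) "yaml"
  else if (ext == "json") "json"
  else stop_config(sprintf("unrecognised config extension \".%s\" (use .yaml/.yml/.json)", ext),
                   field = "path")
}

#' Read a scenario configuration from YAML or JSON
#'
#' The format is chosen by file extension (`.yaml`/`.yml` or `.json`);
#' both carry the same schema. Every violation — parse failure, unknown
#' key, out-of-range rate or cost, duplicate or missing id — raises a
#' classed validation error naming the offending field. Unknown keys are
#' errors rather than warnings: a silently ignored typo in a pass rate
#' would corrupt a decision analysis.
#'
#' @param path Path to the config file.
#' @return A validated [model_config()].
#' @examples
#' path <- system.file("extdata", "depression_cancer_table1.yaml",
#'                     package = "carecascade")
#' load_config(path)
#' @export
load_config <- function(path) {
  if (!is_scalar_string(path) || !file.exists(path)) {
    stop_config(sprintf("config file not found: %s", deparse1(path)),
                field = "path")
  }
  fmt <- config_format(path)
  raw <- tryCatch(
    if (fmt == "yaml") yaml::read_yaml(path)
    else jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop_config(sprintf("failed to parse %s as %s: %s",
                          path, fmt, conditionMessage(e)))
    })
  config_from_list(raw)
}

#' Write a scenario configuration to YAML or JSON
#'
#' Inverse of [load_config()]; a round trip through either format
#' reproduces an identical configuration.
#'
#' @param config A [model_config()].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (!inherits(config, "cascade_config")) {
    stop_config("`config` must be a cascade_config (see model_config())")
  }
  fmt <- config_format(path)
  lst <- config_to_list(config)
  if (fmt == "yaml") {
    yaml::write_yaml(lst, path, precision = 15L)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

# ---- random scenarios for property testing ---------------------------------

#' Generate a random but valid scenario
#'
#' Draws a scenario uniformly within the given bounds: the number of
#' filters, each pass rate, each unit cost, the population size and the
#' prevalence. Deterministic for a given seed; the session RNG state is
#' saved and restored, so generation does not disturb other random
#' draws. Intended as an input source for property tests.
#'
#' @param seed Integer seed.
#' @param n_filters_range Integer length-2 bounds on the number of
#'   filters (inclusive), min >= 1.
#' @param rate_bounds Length-2 bounds on pass rates, within `[0, 1]`.
#' @param cost_bounds Length-2 non-negative bounds on unit costs.
#' @param population_range Length-2 positive bounds on population size.
#' @param prevalence_range Length-2 bounds on prevalence, within `[0, 1]`.
#' @return A valid [scenario_spec()].
#' @examples
#' identical(generate_random_scenario(7), generate_random_scenario(7))
#' @export
generate_random_scenario <- function(seed,
                                     n_filters_range = c(1L, 6L),
                                     rate_bounds = c(0, 1),
                                     cost_bounds = c(0, 500),
                                     population_range = c(100, 100000),
                                     prevalence_range = c(0.01, 0.5)) {
  check_bounds <- function(b, field, lo_ok, hi_ok) {
    if (!is.numeric(b) || length(b) != 2L || any(!is.finite(b)) ||
        b[1] > b[2] || b[1] < lo_ok || b[2] > hi_ok) {
      stop_validation(sprintf("`%s` must be c(low, high) within [%g, %g]",
                              field, lo_ok, hi_ok), field = field)
    }
  }
  if (!is_scalar_number(seed)) stop_validation("`seed` must be a number")
  check_bounds(n_filters_range, "n_filters_range", 1, Inf)
  check_bounds(rate_bounds, "rate_bounds", 0, 1)
  check_bounds(cost_bounds, "cost_bounds", 0, Inf)
  check_bounds(population_range, "population_range", .Machine$double.eps, Inf)
  check_bounds(prevalence_range, "prevalence_range", 0, 1)

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  runif2 <- function(n, b) stats::runif(n, b[1], b[2])
  k <- sample(seq(n_filters_range[1], n_filters_range[2]), 1L)
  filters <- lapply(seq_len(k), function(i) {
    filter_spec(sprintf("filter%02d", i),
                pass_rate = runif2(1, rate_bounds),
                unit_cost = runif2(1, cost_bounds),
                description = sprintf("random stage %d", i))
  })
  scenario_spec(
    scenario_id = sprintf("random_seed%d", as.integer(seed)),
    population_size = runif2(1, population_range),
    prevalence = runif2(1, prevalence_range),
    filters = filters,
    label = sprintf("random scenario (seed %d)", as.integer(seed))
  )
}
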