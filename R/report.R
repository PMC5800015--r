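report_metrics <- c("total_cost", "cost_per_patient", "cost_per_success",
                    "incremental_cost", "incremental_successes", "icer",
                    "policy_advice")

report_row_labels <- c(
  total_cost = "Total cost",
  cost_per_patient = "Cost per patient receiving care",
  cost_per_success = "Cost per successful outcome",
  incremental_cost = "Incremental total cost vs baseline",
  incremental_successes = "Incremental successes vs baseline",
  icer = "ICER",
  policy_advice = "Policy advice"
)

fmt_currency <- function(x, symbol, cents = FALSE) {
  if (is.na(x)) return("n/a")
  r <- display_round(x, if (cents) "currency_cents" else "currency_whole")
  neg <- r < 0
  s <- formatC(abs(r), format = "f", digits = if (cents) 2L else 0L,
               big.mark = ",")
  paste0(if (neg) "-" else "", symbol, s)
}

fmt_count <- function(x) {
  if (is.na(x)) return("n/a")
  formatC(display_round(x, "count"), format = "f", digits = 0L, big.mark = ",")
}

#' Build a comparison report for a configuration
#'
#' Runs every scenario, compares each to the baseline, and assembles the
#' outcome block of a cascade comparison table: total cost, cost per
#' patient receiving care, cost per successful outcome, incremental
#' cost, incremental successes, ICER and policy advice, one column per
#' scenario. Every cell carries both the unrounded value and a display
#' string produced by [display_round()]; the baseline's incremental
#' cells display as `"n/a"`.
#'
#' Currency displays to whole units by default; `cents = TRUE` renders
#' cost per patient at 2 decimal places instead (published tables mix
#' the two conventions).
#'
#' @param config A [model_config()].
#' @param cents Render cost per patient with cents?
#' @return Object of class `cascade_report`: list with `values` (numeric
#'   matrix, metrics x scenarios, unrounded; `NA` where undefined or not
#'   applicable), `display` (character matrix, same shape), `results`,
#'   `outcomes`, `comparisons`, `currency_symbol`, `baseline_id`.
#' @examples
#' render_report(table1_fixture())
#' @export
render_report <- function(config, cents = FALSE) {
  if (!inherits(config, "cascade_config")) {
    stop_config("`config` must be a cascade_config (see model_config())")
  }
  ids <- names(config$scenarios)
  results <- lapply(config$scenarios, run_cascade)
  outcomes <- lapply(results, compute_outcomes)
  comparisons <- compare_all(config)

  values <- matrix(NA_real_, nrow = length(report_metrics), ncol = length(ids),
                   dimnames = list(report_metrics, ids))
  display <- matrix("n/a", nrow = length(report_metrics), ncol = length(ids),
                    dimnames = list(report_metrics, ids))
  sym <- config$currency_symbol
  for (id in ids) {
    o <- outcomes[[id]]
    values["total_cost", id] <- o$total_cost
    display["total_cost", id] <- fmt_currency(o$total_cost, sym)
    values["cost_per_patient", id] <- o$cost_per_patient
    display["cost_per_patient", id] <- fmt_currency(o$cost_per_patient, sym,
                                                    cents = cents)
    values["cost_per_success", id] <- o$cost_per_success
    display["cost_per_success", id] <- fmt_currency(o$cost_per_success, sym)
    if (id != config$baseline_id) {
      cmp <- comparisons[[id]]
      values["incremental_cost", id] <- cmp$incremental_cost
      display["incremental_cost", id] <- fmt_currency(cmp$incremental_cost, sym)
      values["incremental_successes", id] <- cmp$incremental_successes
      display["incremental_successes", id] <- fmt_count(cmp$incremental_successes)
      values["icer", id] <- cmp$icer
      display["icer", id] <- fmt_currency(cmp$icer, sym)
      display["policy_advice", id] <- cmp$advice
    }
  }
  structure(
    list(values = values, display = display,
         results = results, outcomes = outcomes, comparisons = comparisons,
         currency_symbol = sym, baseline_id = config$baseline_id),
    class = "cascade_report"
  )
}

#' @export
print.cascade_report <- function(x, ...) {
  ids <- colnames(x$values)
  # policy advice strings are long; print them under the table
  tab_metrics <- setdiff(rownames(x$display), "policy_advice")
  tab <- x$display[tab_metrics, , drop = FALSE]
  rownames(tab) <- report_row_labels[tab_metrics]
  widths <- pmax(nchar(ids), apply(nchar(tab), 2, max))
  label_w <- max(nchar(rownames(tab)))
  pad <- function(s, w) formatC(s, width = w)
  cat(pad("", label_w), " ",
      paste(mapply(pad, ids, widths), collapse = "  "), "\n", sep = "")
  for (m in rownames(tab)) {
    cat(pad(m, label_w), " ",
        paste(mapply(pad, tab[m, ], widths), collapse = "  "), "\n", sep = "")
  }
  cat("\nPolicy advice:\n")
  for (id in ids) {
    cat(sprintf("  %s: %s\n", id, x$display["policy_advice", id]))
  }
  invisible(x)
}

#' Export report results to CSV or JSON
#'
#' CSV: one row per scenario x metric with columns `scenario_id`,
#' `metric`, `value` (unrounded, full precision), `display`. JSON: a
#' nested structure per scenario carrying unrounded values and display
#' strings side by side. Format is chosen by file extension.
#'
#' @param report A `cascade_report` from [render_report()].
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
export_results <- function(report, path) {
  if (!inherits(report, "cascade_report")) {
    stop_config("`report` must come from render_report()")
  }
  ext <- tolower(tools::file_ext(path))
  long <- report_long(report)
  if (ext == "csv") {
    utils::write.csv(long, path, row.names = FALSE, quote = TRUE)
  } else if (ext == "json") {
    ids <- colnames(report$values)
    nested <- lapply(ids, function(id) {
      metrics <- lapply(report_metrics, function(m) {
        list(value = unname(report$values[m, id]),
             display = unname(report$display[m, id]))
      })
      names(metrics) <- report_metrics
      list(scenario_id = id, metrics = metrics)
    })
    jsonlite::write_json(nested, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    stop_config(sprintf("unrecognised export extension \".%s\" (use .csv/.json)", ext),
                field = "path")
  }
  invisible(path)
}

report_long <- function(report) {
  ids <- colnames(report$values)
  do.call(rbind, lapply(ids, function(id) {
    data.frame(scenario_id = id,
               metric = report_metrics,
               value = report$values[, id],
               display = report$display[, id],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
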