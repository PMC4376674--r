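# Incremental cost-effectiveness of each active strategy versus no
# prophylaxis: incremental cost, deaths averted, cost per death averted,
# dominance classification.

#' Compare a strategy outcome with a comparator
#'
#' Computes the incremental quantities of a prophylaxis strategy against a
#' comparator evaluated on the same cohort. Savings are negative
#' incremental costs. A strategy that is cheaper and averts deaths is
#' dominant; more expensive and harmful is dominated; equal deaths makes
#' the cost-per-death-averted ratio undefined and the pair equivalent.
#'
#' @param strategy_outcome,comparator_outcome `vte_cohort_outcome` objects
#'   sharing `cohort_size`.
#' @return A `vte_cea_result` with `strategy_id`, `comparator_id`,
#'   `incremental_cost`, `deaths_averted` (unrounded),
#'   `cost_per_death_averted`, `dominance`, `death_rate_reduction` and
#'   `cohort_size`.
#' @export
compare_strategies <- function(strategy_outcome, comparator_outcome) {
  stopifnot(inherits(strategy_outcome, "vte_cohort_outcome"),
            inherits(comparator_outcome, "vte_cohort_outcome"))
  if (strategy_outcome$cohort_size != comparator_outcome$cohort_size) {
    stop("cohort sizes differ (", strategy_outcome$cohort_size, " vs ",
         comparator_outcome$cohort_size, "); comparison refused")
  }
  inc_cost <- strategy_outcome$expected_total_cost -
    comparator_outcome$expected_total_cost
  averted <- comparator_outcome$expected_deaths -
    strategy_outcome$expected_deaths
  if (averted != 0) {
    cpda <- inc_cost / averted
    dominance <- if (inc_cost < 0 && averted > 0) {
      "dominant"
    } else if (inc_cost > 0 && averted < 0) {
      "dominated"
    } else {
      "tradeoff"
    }
  } else {
    cpda <- NA_real_
    dominance <- "equivalent"
  }
  structure(list(
    strategy_id = strategy_outcome$strategy_id,
    comparator_id = comparator_outcome$strategy_id,
    cohort_size = strategy_outcome$cohort_size,
    incremental_cost = inc_cost,
    deaths_averted = averted,
    cost_per_death_averted = cpda,
    dominance = dominance,
    death_rate_reduction = averted / strategy_outcome$cohort_size),
    class = "vte_cea_result")
}

#' Death-rate reduction as a percentage
#'
#' @param result A `vte_cea_result`.
#' @return `100 * deaths_averted / cohort_size`, rounded to one decimal.
#' @export
death_rate_reduction_percent <- function(result) {
  stopifnot(inherits(result, "vte_cea_result"))
  round(100 * result$death_rate_reduction, 1)
}

#' @export
print.vte_cea_result <- function(x, ...) {
  cat(sprintf(
    "%s vs %s: incremental cost $%s, %.1f deaths averted (%s)\n",
    x$strategy_id, x$comparator_id,
    format(round(x$incremental_cost), big.mark = ","),
    x$deaths_averted, x$dominance))
  if (!is.na(x$cost_per_death_averted)) {
    cat(sprintf("  cost per death averted: $%s\n",
                format(round(x$cost_per_death_averted), big.mark = ",")))
  }
  invisible(x)
}

#' Base-case cost-effectiveness table
#'
#' Evaluates the three strategy trees on the bundle's cohort and assembles
#' the base-case comparison of each active strategy against no
#' prophylaxis, with full-precision values (display rounding belongs to
#' the report layer).
#'
#' @param bundle A validated `vte_params` bundle.
#' @param cohort_size Cohort size; defaults to the bundle's
#'   `population$cohort_size`.
#' @return `data.frame` with one row per strategy: `strategy`,
#'   `total_cost`, `deaths`, `incremental_cost`, `deaths_averted`,
#'   `cost_per_death_averted`, `dominance` (comparator columns are `NA`
#'   for the no-prophylaxis row).
#' @export
basecase_table <- function(bundle, cohort_size = NULL) {
  stopifnot(inherits(bundle, "vte_params"))
  cohort_size <- cohort_size %||% bundle$population$cohort_size
  outcomes <- lapply(build_all_trees(bundle), evaluate_tree,
                     cohort_size = cohort_size)
  ref <- outcomes$NONE
  rows <- lapply(c("NONE", "LMWH", "UFH"), function(sid) {
    o <- outcomes[[sid]]
    if (sid == "NONE") {
      data.frame(strategy = sid, total_cost = o$expected_total_cost,
                 deaths = o$expected_deaths, incremental_cost = NA_real_,
                 deaths_averted = NA_real_,
                 cost_per_death_averted = NA_real_,
                 dominance = NA_character_)
    } else {
      cea <- compare_strategies(o, ref)
      data.frame(strategy = sid, total_cost = o$expected_total_cost,
                 deaths = o$expected_deaths,
                 incremental_cost = cea$incremental_cost,
                 deaths_averted = cea$deaths_averted,
                 cost_per_death_averted = cea$cost_per_death_averted,
                 dominance = cea$dominance)
    }
  })
  do.call(rbind, rows)
}
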