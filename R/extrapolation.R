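# National extrapolation: the hospital-survey eligibility funnel applied to
# the national inpatient denominator, annual impact of full prophylaxis
# adherence, per-1%-improvement figures, and the hospital-variation
# (interquartile-range) scenario.

#' Construct eligibility-funnel counts
#'
#' @param enrolled,medical_ward,at_vte_risk,receiving_prophylaxis Counts of
#'   patients surviving each successive eligibility stage.
#' @param contraindicated Patients with a recognized contraindication to
#'   anticoagulation, tallied among those at VTE risk.
#' @return A validated `vte_funnel_counts` list.
#' @export
funnel_counts <- function(enrolled, medical_ward, at_vte_risk,
                          receiving_prophylaxis, contraindicated) {
  fc <- list(enrolled = enrolled, medical_ward = medical_ward,
             at_vte_risk = at_vte_risk,
             receiving_prophylaxis = receiving_prophylaxis,
             contraindicated = contraindicated)
  if (any(unlist(fc) < 0)) stop("funnel counts must be non-negative")
  if (!(enrolled >= medical_ward && medical_ward >= at_vte_risk &&
        at_vte_risk >= receiving_prophylaxis)) {
    stop("funnel counts must be monotone non-increasing")
  }
  if (contraindicated > at_vte_risk) {
    stop("contraindicated exceeds at_vte_risk")
  }
  structure(fc, class = "vte_funnel_counts")
}

#' Stage-to-stage funnel rates
#'
#' @param counts A `vte_funnel_counts` (or a plain list with the same
#'   fields, e.g. `bundle$population$endorse_counts`).
#' @return Named numeric vector of exact proportions: `medical_ward_rate`
#'   (of enrolled), `at_risk_rate` (of medical-ward patients),
#'   `receiving_rate` and `contraindicated_rate` (both of at-risk
#'   patients).
#' @export
funnel_rates <- function(counts) {
  if (counts$enrolled == 0 || counts$medical_ward == 0 ||
      counts$at_vte_risk == 0) {
    stop("zero denominator in funnel counts; rates refused")
  }
  c(medical_ward_rate = counts$medical_ward / counts$enrolled,
    at_risk_rate = counts$at_vte_risk / counts$medical_ward,
    receiving_rate = counts$receiving_prophylaxis / counts$at_vte_risk,
    contraindicated_rate = counts$contraindicated / counts$at_vte_risk)
}

#' Apply the eligibility funnel to the national denominator
#'
#' Scales the national count of eligible medical discharges by the at-risk
#' fraction, removes patients already receiving recommended prophylaxis,
#' and excludes those with recognized contraindications, yielding the
#' eligible-but-unprotected population. All arithmetic is unrounded.
#'
#' @param nis_total National count of eligible medical discharges.
#' @param at_risk_fraction Fraction at ACCP-defined VTE risk.
#' @param receiving_fraction Fraction of at-risk patients already receiving
#'   recommended prophylaxis.
#' @param contraindicated_fraction Fraction of at-risk patients with a
#'   contraindication to anticoagulants.
#' @return List with `at_risk`, `receiving`, `not_receiving`,
#'   `eligible_unprotected`.
#' @export
apply_funnel <- function(nis_total, at_risk_fraction, receiving_fraction,
                         contraindicated_fraction) {
  stopifnot(nis_total >= 0,
            at_risk_fraction >= 0, at_risk_fraction <= 1,
            receiving_fraction >= 0, receiving_fraction <= 1,
            contraindicated_fraction >= 0, contraindicated_fraction <= 1)
  at_risk <- nis_total * at_risk_fraction
  receiving <- at_risk * receiving_fraction
  not_receiving <- at_risk - receiving
  list(at_risk = at_risk,
       receiving = receiving,
       not_receiving = not_receiving,
       eligible_unprotected = not_receiving * (1 - contraindicated_fraction))
}

#' National annual impact of closing the prophylaxis gap
#'
#' Projects the cohort-level deaths-averted rate of a strategy onto the
#' eligible-but-unprotected national population: total annual deaths
#' averted, total cost saving (for cost-saving strategies), and the
#' per-1%-adherence-improvement figures (totals divided by 100).
#'
#' @param eligible_unprotected Count of at-risk patients neither protected
#'   nor contraindicated (from [apply_funnel()]).
#' @param cea A `vte_cea_result` versus no prophylaxis.
#' @return A `vte_extrapolation` list: `strategy_id`,
#'   `eligible_unprotected`, `deaths_averted_total`, `cost_saved_total`,
#'   `deaths_averted_per_1pct`, `cost_saved_per_1pct`, `applicable`
#'   (`FALSE` with zero totals when the strategy averts no deaths).
#' @export
national_impact <- function(eligible_unprotected, cea) {
  stopifnot(inherits(cea, "vte_cea_result"), eligible_unprotected >= 0)
  if (cea$deaths_averted <= 0) {
    return(structure(list(
      strategy_id = cea$strategy_id,
      eligible_unprotected = eligible_unprotected,
      deaths_averted_total = 0, cost_saved_total = 0,
      deaths_averted_per_1pct = 0, cost_saved_per_1pct = 0,
      applicable = FALSE, dominance = cea$dominance),
      class = "vte_extrapolation"))
  }
  deaths_total <- eligible_unprotected * cea$deaths_averted / cea$cohort_size
  cost_total <- if (cea$incremental_cost < 0) {
    deaths_total * abs(cea$cost_per_death_averted)
  } else {
    0
  }
  structure(list(
    strategy_id = cea$strategy_id,
    eligible_unprotected = eligible_unprotected,
    deaths_averted_total = deaths_total,
    cost_saved_total = cost_total,
    deaths_averted_per_1pct = deaths_total / 100,
    cost_saved_per_1pct = cost_total / 100,
    applicable = TRUE, dominance = cea$dominance),
    class = "vte_extrapolation")
}

#' @export
print.vte_extrapolation <- function(x, ...) {
  cat(sprintf(
    "%s: %.0f deaths averted/year nationally, $%s saved (%.0f and $%s per 1%% adherence gain)\n",
    x$strategy_id, x$deaths_averted_total,
    format(round(x$cost_saved_total), big.mark = ","),
    x$deaths_averted_per_1pct,
    format(round(x$cost_saved_per_1pct), big.mark = ",")))
  invisible(x)
}

#' Hospital-variation scenario over the at-risk interquartile range
#'
#' Reruns the funnel and national projection at the low and high ends of
#' the observed between-hospital at-risk fraction, holding every other
#' input at base case.
#'
#' @param at_risk_range Length-2 numeric, low and high at-risk fractions.
#' @param nis_total,receiving_fraction,contraindicated_fraction As in
#'   [apply_funnel()].
#' @param cea A `vte_cea_result` versus no prophylaxis.
#' @return `data.frame` with rows `low` and `high`: `at_risk_fraction`,
#'   `eligible_unprotected`, `deaths_averted_total`, `cost_saved_total`,
#'   `deaths_averted_per_1pct`, `cost_saved_per_1pct`.
#' @export
iqr_scenario <- function(at_risk_range, nis_total, receiving_fraction,
                         contraindicated_fraction, cea) {
  stopifnot(length(at_risk_range) == 2, at_risk_range[1] <= at_risk_range[2],
            all(at_risk_range >= 0 & at_risk_range <= 1))
  rows <- lapply(at_risk_range, function(fr) {
    fun <- apply_funnel(nis_total, fr, receiving_fraction,
                        contraindicated_fraction)
    imp <- national_impact(fun$eligible_unprotected, cea)
    data.frame(at_risk_fraction = fr,
               eligible_unprotected = fun$eligible_unprotected,
               deaths_averted_total = imp$deaths_averted_total,
               cost_saved_total = imp$cost_saved_total,
               deaths_averted_per_1pct = imp$deaths_averted_per_1pct,
               cost_saved_per_1pct = imp$cost_saved_per_1pct)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- c("low", "high")
  out
}
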