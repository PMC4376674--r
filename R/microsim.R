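# Synthetic data: (a) patient-level Monte Carlo walks through the decision
# tree, the simulation twin of the analytic evaluator; (b) synthetic
# admission records resembling a national discharge sample, to exercise the
# eligibility filters end to end.

#' Microsimulate a cohort through a decision tree
#'
#' Each patient walks the tree from the root, sampling a branch at every
#' internal node with the branch probabilities, and accrues the node costs
#' along the way. The empirical death rate and mean cost converge on the
#' analytic expectations of [evaluate_tree()]; the function reports both
#' with standard errors, making it an independent oracle for the analytic
#' route.
#'
#' @param root Tree root from [build_tree()].
#' @param n Number of simulated patients.
#' @param seed Integer seed.
#' @param record_paths Attach the slash-separated node path to each
#'   record (readable audit trail; off by default for large `n`).
#' @return List with `records` (data frame: `patient_id`, `strategy_id`,
#'   `died`, `death_cause`, `accrued_cost`, and `path` when requested) and
#'   `outcome` (list: `death_rate`, `death_rate_se`, `mean_cost`,
#'   `mean_cost_se`, `deaths_by_cause`, `n`).
#' @export
simulate_cohort <- function(root, n, seed = 1, record_paths = FALSE) {
  stopifnot(n >= 1)
  set.seed(seed)
  cost <- numeric(n)
  cause <- character(n)
  path <- if (record_paths) character(n) else NULL

  walk <- function(node, idx, acc_cost, acc_path) {
    acc_cost <- acc_cost + node$cost
    if (record_paths) acc_path <- paste0(acc_path, "/", node$label)
    if (is.null(node$children)) {
      cost[idx] <<- acc_cost
      cause[idx] <<- node$payoff$cause %||% "none"
      if (record_paths) path[idx] <<- acc_path
      return(invisible())
    }
    probs <- vapply(node$children, function(k) k$prob, 0)
    .check_branch_probs(probs, node$label)
    pick <- sample.int(length(probs), length(idx), replace = TRUE,
                       prob = probs)
    for (j in seq_along(probs)) {
      sub <- idx[pick == j]
      if (length(sub) > 0) {
        walk(node$children[[j]]$node, sub, acc_cost, acc_path)
      }
    }
  }
  walk(root, seq_len(n), 0, "")

  died <- cause != "none"
  records <- data.frame(
    patient_id = seq_len(n),
    strategy_id = attr(root, "strategy_id") %||% "custom",
    died = died, death_cause = cause, accrued_cost = cost)
  if (record_paths) records$path <- sub("^/", "", path)
  rate <- mean(died)
  outcome <- list(
    death_rate = rate,
    death_rate_se = sqrt(rate * (1 - rate) / n),
    mean_cost = mean(cost),
    mean_cost_se = stats::sd(cost) / sqrt(n),
    deaths_by_cause = table(factor(cause[died], levels = .death_causes)),
    n = n)
  list(records = records, outcome = outcome)
}

#' Default admission-mix configuration
#'
#' Marginal distributions for the synthetic admission generator: age is
#' truncated normal (mean 65, sd 15, support 18-105 years); length of stay
#' is 1 + geometric with mean 5 days; the remaining fields are Bernoulli
#' with the survey-derived fractions (44% surgical, 52.3% of eligible
#' medical patients at VTE risk, 47.5% of at-risk receiving prophylaxis,
#' 12.2% of at-risk contraindicated).
#'
#' @param surgical_fraction,at_risk_fraction,prophylaxis_fraction,contraindicated_fraction
#'   Bernoulli marginals.
#' @param age_mean,age_sd,los_mean Age and length-of-stay marginals.
#' @return Named list of marginals.
#' @export
default_mix_config <- function(surgical_fraction = 0.439,
                               at_risk_fraction = 0.523,
                               prophylaxis_fraction = 0.475,
                               contraindicated_fraction = 0.122,
                               age_mean = 65, age_sd = 15, los_mean = 5) {
  list(surgical_fraction = surgical_fraction,
       at_risk_fraction = at_risk_fraction,
       prophylaxis_fraction = prophylaxis_fraction,
       contraindicated_fraction = contraindicated_fraction,
       age_mean = age_mean, age_sd = age_sd, los_mean = los_mean)
}

.accp_risk_categories <- c("heart_failure", "respiratory_failure", "sepsis",
  "pneumonia", "cancer", "stroke", "acute_mi", "nonsurgical_trauma",
  "arthropathy", "paralysis_coma")

#' Generate synthetic admission records
#'
#' Draws independent admission records from the configured marginals:
#' age, length of stay, an operating-room flag, a VTE-risk diagnosis flag
#' (standing in for the guideline's ten diagnosis categories, with a
#' category label carried for realism), a contraindication flag and a
#' prophylaxis flag.
#'
#' @param n Number of records (0 gives an empty frame).
#' @param mix_config From [default_mix_config()].
#' @param seed Integer seed.
#' @return `data.frame` with columns `admission_id`, `age`,
#'   `length_of_stay`, `went_to_operating_room`, `vte_risk_diagnosis`,
#'   `risk_category`, `contraindicated`, `received_prophylaxis`.
#' @export
generate_admissions <- function(n, mix_config = default_mix_config(),
                                seed = 1) {
  stopifnot(n >= 0)
  m <- mix_config
  fracs <- unlist(m[c("surgical_fraction", "at_risk_fraction",
                      "prophylaxis_fraction", "contraindicated_fraction")])
  if (any(fracs < 0 | fracs > 1)) {
    stop("invalid mix_config: fractions must lie in [0, 1]")
  }
  if (m$age_sd <= 0 || m$los_mean < 1) {
    stop("invalid mix_config: age_sd must be positive and los_mean >= 1")
  }
  set.seed(seed)
  if (n == 0) {
    return(data.frame(admission_id = integer(0), age = numeric(0),
                      length_of_stay = numeric(0),
                      went_to_operating_room = logical(0),
                      vte_risk_diagnosis = logical(0),
                      risk_category = character(0),
                      contraindicated = logical(0),
                      received_prophylaxis = logical(0)))
  }
  age <- pmin(pmax(stats::rnorm(n, m$age_mean, m$age_sd), 18), 105)
  los <- 1 + stats::rgeom(n, prob = 1 / m$los_mean)
  at_risk <- stats::runif(n) < m$at_risk_fraction
  data.frame(
    admission_id = seq_len(n),
    age = round(age),
    length_of_stay = los,
    went_to_operating_room = stats::runif(n) < m$surgical_fraction,
    vte_risk_diagnosis = at_risk,
    risk_category = ifelse(at_risk,
      sample(.accp_risk_categories, n, replace = TRUE), "none"),
    contraindicated = stats::runif(n) < m$contraindicated_fraction,
    received_prophylaxis = stats::runif(n) < m$prophylaxis_fraction)
}

#' Apply the survey eligibility filters to admission records
#'
#' Pure tabulation, in filter order: medical (no operating room),
#' eligible (age at least 40 years and length of stay at least 2 days,
#' both inclusive), at VTE risk (diagnosis flag), receiving prophylaxis;
#' contraindications are tallied among at-risk patients.
#'
#' @param records Admission records from [generate_admissions()] (or any
#'   frame with the same columns).
#' @return A `vte_funnel_counts`, plus an `eligible` attribute carrying
#'   the intermediate age/length-of-stay stage count.
#' @export
apply_endorse_filters <- function(records) {
  medical <- records[!records$went_to_operating_room, , drop = FALSE]
  eligible <- medical[medical$age >= 40 & medical$length_of_stay >= 2, ,
                      drop = FALSE]
  at_risk <- eligible[eligible$vte_risk_diagnosis, , drop = FALSE]
  fc <- funnel_counts(
    enrolled = nrow(records),
    medical_ward = nrow(medical),
    at_vte_risk = nrow(at_risk),
    receiving_prophylaxis = sum(at_risk$received_prophylaxis),
    contraindicated = sum(at_risk$contraindicated))
  attr(fc, "eligible") <- nrow(eligible)
  fc
}
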