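# Parameter bundle: strategy probabilities, shared probabilities, unit costs
# and population constants, loaded from a YAML config with shipped defaults.

.strategy_ids <- c("LMWH", "UFH", "NONE")

.strategy_fields <- c("p_dvt", "p_bleed", "p_hit", "prophylaxis_cost")

.shared_fields <- c(
  "p_major_given_bleed", "p_death_given_major_bleed",
  "p_symptomatic_given_hit", "p_death_given_symptomatic_hit",
  "p_bleed_given_dvt_tx", "p_hit_given_dvt_tx", "p_pe_given_dvt_tx",
  "p_death_given_pe_tx_pos", "p_death_given_pe_tx_neg",
  "p_sudden_death_given_pe", "p_pe_given_untreated_dvt",
  "p_death_given_untreated_pe", "p_death_underlying",
  "dvt_clin_sens", "dvt_clin_spec", "dvt_us_sens", "dvt_us_spec",
  "pe_clin_sens", "pe_clin_spec",
  "pe_ct_sens", "pe_ct_spec", "pe_vq_sens", "pe_vq_spec",
  "pe_scan_avg_sens", "pe_scan_avg_spec")

.cost_fields <- c("major_bleed", "minor_bleed", "asymptomatic_hit",
  "symptomatic_hit", "treated_dvt", "treated_pe", "dvt_diagnosis",
  "pe_diagnosis")

.funnel_fields <- c("enrolled", "medical_ward", "at_vte_risk",
  "receiving_prophylaxis", "contraindicated")

#' Locate the shipped default parameter file
#'
#' @return Path to the YAML file holding the model's default probabilities,
#'   unit costs and population constants.
#' @export
default_parameter_file <- function() {
  system.file("extdata", "params_default.yaml", package = "vteprophy",
              mustWork = TRUE)
}

#' Load and validate the model parameter bundle
#'
#' Reads a YAML configuration holding the three strategy parameter sets
#' (LMWH, UFH, no prophylaxis), the shared event and diagnostic
#' probabilities, the unit costs in 2013 US$, and the population constants
#' used for national extrapolation. When `base` is supplied, keys absent
#' from the file fall back to it; otherwise every key is required.
#'
#' @param config_path Path to a YAML parameter file.
#' @param base Optional complete bundle supplying defaults for absent keys
#'   (typically [default_parameters()]). `NULL` makes every key mandatory.
#' @return A validated `vte_params` bundle: a list with elements
#'   `strategies` (named list of per-strategy parameters), `shared`,
#'   `costs` and `population`.
#' @export
load_parameters <- function(config_path, base = NULL) {
  if (!file.exists(config_path)) {
    stop("parameter file not found: ", config_path)
  }
  raw <- tryCatch(yaml::read_yaml(config_path), error = function(e) {
    stop("cannot parse parameter file '", config_path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  bundle <- .assemble_bundle(raw, base, source = config_path)
  viol <- validate_parameters(bundle)
  if (length(viol) > 0) {
    stop("invalid parameters in '", config_path, "':\n  ",
         paste(viol, collapse = "\n  "), call. = FALSE)
  }
  bundle
}

#' Shipped default parameter bundle
#'
#' @return The `vte_params` bundle built from the packaged default
#'   configuration (all values as published).
#' @export
default_parameters <- function() {
  load_parameters(default_parameter_file(), base = NULL)
}

#' Write a parameter bundle back to YAML
#'
#' Inverse of [load_parameters()]: a bundle written with this function and
#' reloaded compares equal field by field.
#'
#' @param bundle A `vte_params` bundle.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(bundle, path) {
  stopifnot(inherits(bundle, "vte_params"))
  out <- list(
    strategies = lapply(bundle$strategies, function(s)
      s[.strategy_fields]),
    shared = bundle$shared[.shared_fields],
    costs = bundle$costs[.cost_fields],
    population = list(
      cohort_size = bundle$population$cohort_size,
      endorse_counts = bundle$population$endorse_counts[.funnel_fields],
      nis_eligible_total = bundle$population$nis_eligible_total,
      at_risk_fraction = bundle$population$at_risk_fraction,
      at_risk_iqr = bundle$population$at_risk_iqr))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

.take <- function(raw_section, base_section, field, where) {
  if (!is.null(raw_section) && field %in% names(raw_section)) {
    val <- raw_section[[field]]
    if (!is.numeric(val) || length(val) == 0) {
      stop("configuration error: '", where, ".", field,
           "' is not numeric", call. = FALSE)
    }
    val
  } else if (!is.null(base_section)) {
    base_section[[field]]
  } else {
    stop("configuration error: missing key '", where, ".", field, "'",
         call. = FALSE)
  }
}

.check_unknown <- function(raw_section, known, where) {
  extra <- setdiff(names(raw_section), known)
  if (length(extra) > 0) {
    stop("configuration error: unknown key(s) in '", where, "': ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
}

.assemble_bundle <- function(raw, base, source = "<config>") {
  .check_unknown(raw, c("strategies", "shared", "costs", "population"),
                 "top level")
  strategies <- list()
  for (sid in .strategy_ids) {
    raw_s <- raw$strategies[[sid]]
    .check_unknown(raw_s, .strategy_fields, paste0("strategies.", sid))
    base_s <- if (is.null(base)) NULL else base$strategies[[sid]]
    s <- lapply(.strategy_fields, function(f)
      .take(raw_s, base_s, f, paste0("strategies.", sid)))
    names(s) <- .strategy_fields
    s$strategy_id <- sid
    strategies[[sid]] <- s
  }
  .check_unknown(raw$shared, .shared_fields, "shared")
  shared <- lapply(.shared_fields, function(f)
    .take(raw$shared, base$shared, f, "shared"))
  names(shared) <- .shared_fields
  .check_unknown(raw$costs, .cost_fields, "costs")
  costs <- lapply(.cost_fields, function(f)
    .take(raw$costs, base$costs, f, "costs"))
  names(costs) <- .cost_fields

  raw_pop <- raw$population
  .check_unknown(raw_pop, c("cohort_size", "endorse_counts",
    "nis_eligible_total", "at_risk_fraction", "at_risk_iqr"), "population")
  base_pop <- if (is.null(base)) NULL else base$population
  .check_unknown(raw_pop$endorse_counts, .funnel_fields,
                 "population.endorse_counts")
  endorse <- lapply(.funnel_fields, function(f)
    .take(raw_pop$endorse_counts, base_pop$endorse_counts, f,
          "population.endorse_counts"))
  names(endorse) <- .funnel_fields
  population <- list(
    cohort_size = .take(raw_pop, base_pop, "cohort_size", "population"),
    endorse_counts = endorse,
    nis_eligible_total = .take(raw_pop, base_pop, "nis_eligible_total",
                               "population"),
    at_risk_fraction = .take(raw_pop, base_pop, "at_risk_fraction",
                             "population"),
    at_risk_iqr = .take(raw_pop, base_pop, "at_risk_iqr", "population"))

  structure(list(strategies = strategies, shared = shared, costs = costs,
                 population = population, source = source),
            class = "vte_params")
}

#' Validate a parameter bundle
#'
#' Checks every structural invariant of the bundle: probabilities in
#' \[0, 1\], mutual exclusivity of first-level adverse events
#' (`p_bleed + p_hit <= 1`), the structural zero `p_hit = 0` for the
#' no-prophylaxis arm, non-negative costs, consistency of the averaged
#' scan sensitivity/specificity with the CT and V/Q values, and the
#' population-constant invariants (monotone funnel counts, fractions in
#' \[0, 1\], ordered at-risk interquartile range).
#'
#' Violations are returned, not raised.
#'
#' @param bundle A `vte_params` bundle (structurally complete).
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_parameters <- function(bundle) {
  v <- character(0)
  say <- function(...) v <<- c(v, paste0(...))

  for (sid in .strategy_ids) {
    s <- bundle$strategies[[sid]]
    for (f in c("p_dvt", "p_bleed", "p_hit")) {
      if (s[[f]] < 0 || s[[f]] > 1) {
        say(sid, ".", f, " = ", s[[f]], " outside [0, 1]")
      }
    }
    if (s$p_bleed + s$p_hit > 1) {
      say(sid, ": p_bleed + p_hit = ", s$p_bleed + s$p_hit,
          " violates mutual exclusivity (must be <= 1)")
    }
    if (s$prophylaxis_cost < 0) {
      say(sid, ".prophylaxis_cost = ", s$prophylaxis_cost, " is negative")
    }
  }
  if (bundle$strategies$NONE$p_hit != 0) {
    say("NONE.p_hit = ", bundle$strategies$NONE$p_hit,
        " must be 0 (no drug exposure, no HIT)")
  }
  for (f in .shared_fields) {
    p <- bundle$shared[[f]]
    if (p < 0 || p > 1) say("shared.", f, " = ", p, " outside [0, 1]")
  }
  avg_sens <- (bundle$shared$pe_ct_sens + bundle$shared$pe_vq_sens) / 2
  if (abs(bundle$shared$pe_scan_avg_sens - avg_sens) > 5e-4) {
    say("pe_scan_avg_sens = ", bundle$shared$pe_scan_avg_sens,
        " is not the mean of CT and V/Q sensitivities (", avg_sens, ")")
  }
  avg_spec <- (bundle$shared$pe_ct_spec + bundle$shared$pe_vq_spec) / 2
  if (abs(bundle$shared$pe_scan_avg_spec - avg_spec) > 5e-4) {
    say("pe_scan_avg_spec = ", bundle$shared$pe_scan_avg_spec,
        " is not the mean of CT and V/Q specificities (", avg_spec, ")")
  }
  for (f in .cost_fields) {
    if (bundle$costs[[f]] < 0) {
      say("costs.", f, " = ", bundle$costs[[f]], " is negative")
    }
  }

  pop <- bundle$population
  if (pop$cohort_size < 1 || pop$cohort_size != round(pop$cohort_size)) {
    say("population.cohort_size = ", pop$cohort_size,
        " must be a positive integer")
  }
  fc <- pop$endorse_counts
  if (any(unlist(fc) < 0)) say("endorse_counts must be non-negative")
  if (!(fc$enrolled >= fc$medical_ward &&
        fc$medical_ward >= fc$at_vte_risk &&
        fc$at_vte_risk >= fc$receiving_prophylaxis)) {
    say("endorse_counts not monotone non-increasing along the funnel")
  }
  if (fc$contraindicated > fc$at_vte_risk) {
    say("endorse_counts.contraindicated = ", fc$contraindicated,
        " exceeds at_vte_risk")
  }
  if (pop$nis_eligible_total < 0) say("nis_eligible_total is negative")
  if (pop$at_risk_fraction < 0 || pop$at_risk_fraction > 1) {
    say("at_risk_fraction = ", pop$at_risk_fraction, " outside [0, 1]")
  }
  iqr <- pop$at_risk_iqr
  if (length(iqr) != 2 || any(iqr < 0 | iqr > 1)) {
    say("at_risk_iqr must be two fractions in [0, 1]")
  } else if (iqr[1] > iqr[2]) {
    say("at_risk_iqr low (", iqr[1], ") exceeds high (", iqr[2], ")")
  }
  v
}

#' @export
print.vte_params <- function(x, ...) {
  cat("VTE prophylaxis model parameters (", x$source, ")\n", sep = "")
  for (sid in .strategy_ids) {
    s <- x$strategies[[sid]]
    cat(sprintf("  %-4s p_dvt=%.3f p_bleed=%.3f p_hit=%.3f drug=$%g\n",
                sid, s$p_dvt, s$p_bleed, s$p_hit, s$prophylaxis_cost))
  }
  cat("  ", length(.shared_fields), " shared probabilities, ",
      length(.cost_fields), " unit costs, cohort size ",
      x$population$cohort_size, "\n", sep = "")
  invisible(x)
}

# flat named vector of every numeric in the bundle (stable order); used for
# checksums and field-by-field comparisons
.flatten_bundle <- function(bundle) {
  out <- c()
  for (sid in .strategy_ids) {
    s <- unlist(bundle$strategies[[sid]][.strategy_fields])
    names(s) <- paste0(sid, ".", .strategy_fields)
    out <- c(out, s)
  }
  sh <- unlist(bundle$shared[.shared_fields])
  co <- unlist(bundle$costs[.cost_fields])
  names(co) <- paste0("costs.", .cost_fields)
  pop <- bundle$population
  fc <- unlist(pop$endorse_counts[.funnel_fields])
  names(fc) <- paste0("endorse.", .funnel_fields)
  c(out, sh, co, fc,
    cohort_size = pop$cohort_size,
    nis_eligible_total = pop$nis_eligible_total,
    at_risk_fraction = pop$at_risk_fraction,
    at_risk_iqr_low = pop$at_risk_iqr[1],
    at_risk_iqr_high = pop$at_risk_iqr[2])
}
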