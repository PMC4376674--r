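# Sensitivity analyses: one-way scans with threshold finding by bisection,
# probabilistic sensitivity analysis (Monte Carlo over beta/gamma parameter
# distributions), and cost-effectiveness acceptability curves.

# Parameter addressing: shared fields by bare name ("p_pe_given_untreated_dvt"),
# strategy fields as "<STRATEGY>.<field>" ("LMWH.p_dvt"), costs as
# "costs.<field>".

.resolve_parameter <- function(bundle, name) {
  if (name %in% .shared_fields) {
    return(list(section = "shared", field = name, strategy = NULL))
  }
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2 && parts[1] %in% .strategy_ids &&
      parts[2] %in% .strategy_fields) {
    return(list(section = "strategies", field = parts[2],
                strategy = parts[1]))
  }
  if (length(parts) == 2 && parts[1] == "costs" &&
      parts[2] %in% .cost_fields) {
    return(list(section = "costs", field = parts[2], strategy = NULL))
  }
  stop("unknown parameter name: '", name, "'")
}

#' Set a single model parameter
#'
#' @param bundle A `vte_params` bundle.
#' @param name Parameter address: a shared-probability name, a
#'   `"STRATEGY.field"` pair, or `"costs.field"`.
#' @param value New value (validated for its field: probabilities must lie
#'   in \[0, 1\], costs must be non-negative).
#' @return The modified bundle.
#' @export
set_parameter <- function(bundle, name, value) {
  stopifnot(inherits(bundle, "vte_params"), is.numeric(value),
            length(value) == 1)
  loc <- .resolve_parameter(bundle, name)
  is_cost <- loc$section == "costs" ||
    (loc$section == "strategies" && loc$field == "prophylaxis_cost")
  if (is_cost) {
    if (value < 0) stop("invalid value for '", name, "': negative cost")
  } else if (value < 0 || value > 1) {
    stop("invalid value for '", name, "': probability outside [0, 1]")
  }
  if (loc$section == "shared") {
    bundle$shared[[loc$field]] <- value
  } else if (loc$section == "costs") {
    bundle$costs[[loc$field]] <- value
  } else {
    bundle$strategies[[loc$strategy]][[loc$field]] <- value
  }
  bundle
}

.scan_point <- function(bundle, cohort_size) {
  outcomes <- lapply(build_all_trees(bundle), evaluate_tree,
                     cohort_size = cohort_size)
  ref <- outcomes$NONE
  rows <- lapply(c("LMWH", "UFH", "NONE"), function(sid) {
    o <- outcomes[[sid]]
    if (sid == "NONE") {
      data.frame(strategy = sid, deaths = o$expected_deaths,
                 total_cost = o$expected_total_cost,
                 incremental_cost = NA_real_, deaths_averted = NA_real_,
                 cost_per_death_averted = NA_real_)
    } else {
      cea <- compare_strategies(o, ref)
      data.frame(strategy = sid, deaths = o$expected_deaths,
                 total_cost = o$expected_total_cost,
                 incremental_cost = cea$incremental_cost,
                 deaths_averted = cea$deaths_averted,
                 cost_per_death_averted = cea$cost_per_death_averted)
    }
  })
  do.call(rbind, rows)
}

#' One-way sensitivity scan
#'
#' Rebuilds and re-evaluates the full model at each grid value of one
#' parameter, all other parameters held at base case.
#'
#' @param parameter_name Parameter address (see [set_parameter()]).
#' @param grid Strictly increasing numeric grid of values for the
#'   parameter.
#' @param bundle Base-case `vte_params` bundle.
#' @param cohort_size Cohort size; defaults to the bundle's value.
#' @return A `vte_oneway` data frame in long format: `parameter`, `value`,
#'   `strategy`, `deaths`, `total_cost`, and the incremental columns
#'   versus no prophylaxis.
#' @export
one_way_scan <- function(parameter_name, grid, bundle, cohort_size = NULL) {
  stopifnot(is.numeric(grid), length(grid) >= 1)
  if (length(grid) > 1 && any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing")
  }
  cohort_size <- cohort_size %||% bundle$population$cohort_size
  rows <- lapply(grid, function(v) {
    b <- set_parameter(bundle, parameter_name, v)
    cbind(parameter = parameter_name, value = v,
          .scan_point(b, cohort_size))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("vte_oneway", class(out))
  out
}

.threshold_criteria <- c("cost_saving:LMWH", "cost_saving:UFH",
  "both_cost_saving", "effective:LMWH", "effective:UFH", "both_effective",
  "both_dominant")

.criterion_predicate <- function(criterion) {
  if (!(criterion %in% .threshold_criteria)) {
    stop("unknown criterion '", criterion, "'; must be one of: ",
         paste(.threshold_criteria, collapse = ", "))
  }
  function(point) {
    inc <- point$incremental_cost[match(c("LMWH", "UFH"), point$strategy)]
    av <- point$deaths_averted[match(c("LMWH", "UFH"), point$strategy)]
    switch(criterion,
      "cost_saving:LMWH" = inc[1] <= 0,
      "cost_saving:UFH" = inc[2] <= 0,
      "both_cost_saving" = all(inc <= 0),
      "effective:LMWH" = av[1] > 0,
      "effective:UFH" = av[2] > 0,
      "both_effective" = all(av > 0),
      "both_dominant" = all(inc <= 0) && all(av > 0))
  }
}

#' Threshold analysis by bisection
#'
#' Finds the parameter value at which a named cost-effectiveness criterion
#' switches truth value, by bisection between bounds. The criterion is
#' checked at both endpoints and on a coarse interior grid: if it holds
#' identically, `"none-in-range"` is returned with a flag; if it switches
#' more than once the configuration is reported as non-monotone rather
#' than silently answered.
#'
#' @param parameter_name Parameter address (see [set_parameter()]).
#' @param criterion One of `"cost_saving:LMWH"`, `"cost_saving:UFH"`,
#'   `"both_cost_saving"`, `"effective:LMWH"`, `"effective:UFH"`,
#'   `"both_effective"`, `"both_dominant"` — all judged versus no
#'   prophylaxis.
#' @param bounds Length-2 numeric `(low, high)` search interval.
#' @param bundle Base-case `vte_params` bundle.
#' @param tol Absolute tolerance on the threshold location.
#' @param cohort_size Cohort size; defaults to the bundle's value.
#' @return A `vte_threshold` list: `status` (`"ok"` or
#'   `"none-in-range"`), `value` (threshold, `NA` when none), `flag`
#'   (`"always satisfied"`/`"never satisfied"` when none in range),
#'   `criterion`, `parameter`, `bounds`, `tol`.
#' @export
find_threshold <- function(parameter_name, criterion, bounds, bundle,
                           tol = 1e-4, cohort_size = NULL) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2], tol > 0)
  cohort_size <- cohort_size %||% bundle$population$cohort_size
  pred <- .criterion_predicate(criterion)
  eval_at <- function(x) {
    b <- set_parameter(bundle, parameter_name, x)
    pred(.scan_point(b, cohort_size))
  }
  coarse_x <- seq(bounds[1], bounds[2], length.out = 9)
  coarse <- vapply(coarse_x, eval_at, TRUE)
  switches <- sum(diff(coarse) != 0)
  if (switches == 0) {
    return(structure(list(
      status = "none-in-range", value = NA_real_,
      flag = if (coarse[1]) "always satisfied" else "never satisfied",
      criterion = criterion, parameter = parameter_name,
      bounds = bounds, tol = tol), class = "vte_threshold"))
  }
  if (switches > 1) {
    stop("criterion '", criterion, "' is not monotone in '",
         parameter_name, "' over the given bounds (", switches,
         " sign changes on a coarse grid); no threshold reported")
  }
  i <- which(diff(coarse) != 0)
  lo <- coarse_x[i]
  hi <- coarse_x[i + 1]
  f_lo <- coarse[i]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (eval_at(mid) == f_lo) lo <- mid else hi <- mid
  }
  structure(list(
    status = "ok", value = (lo + hi) / 2, flag = NA_character_,
    criterion = criterion, parameter = parameter_name,
    bounds = bounds, tol = tol), class = "vte_threshold")
}

#' @export
print.vte_threshold <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("threshold for '%s' (%s): %.4f\n", x$parameter,
                x$criterion, x$value))
  } else {
    cat(sprintf("no threshold for '%s' (%s) in [%g, %g]: %s\n",
                x$parameter, x$criterion, x$bounds[1], x$bounds[2], x$flag))
  }
  invisible(x)
}

# ---- probabilistic sensitivity analysis ------------------------------------

# probability parameters sampled in the PSA; the averaged-scan rows are
# recomputed from the sampled CT and V/Q values, never sampled directly
.psa_prob_params <- function() {
  shared <- setdiff(.shared_fields, c("pe_scan_avg_sens", "pe_scan_avg_spec"))
  strat <- as.vector(outer(.strategy_ids, c("p_dvt", "p_bleed", "p_hit"),
                           paste, sep = "."))
  c(shared, strat)
}

.psa_cost_params <- function() {
  c(paste0("costs.", .cost_fields),
    paste0(.strategy_ids, ".prophylaxis_cost"))
}

.diag_fields <- c("dvt_clin_sens", "dvt_clin_spec", "dvt_us_sens",
  "dvt_us_spec", "pe_clin_sens", "pe_clin_spec", "pe_ct_sens", "pe_ct_spec",
  "pe_vq_sens", "pe_vq_spec")

#' Default PSA spread configuration
#'
#' Beta distributions for probabilities are parameterized by an effective
#' sample size `n` (`alpha = p * n`, `beta = (1 - p) * n`); gamma
#' distributions for costs by a coefficient of variation `cv`
#' (`shape = 1 / cv^2`, `scale = mean * cv^2`). Defaults: `n = 300` for
#' event probabilities (the scale of the source prophylaxis-trial arms),
#' `n = 1000` for diagnostic sensitivities/specificities (pooled imaging
#' studies), `cv = 0.25` for every cost. All entries are overridable.
#'
#' @param prob_ess,diag_ess,cost_cv Default spreads (see above).
#' @return A `list(ess = , cv = )` of named numeric vectors covering every
#'   sampled parameter.
#' @export
default_spread_config <- function(prob_ess = 300, diag_ess = 1000,
                                  cost_cv = 0.25) {
  probs <- .psa_prob_params()
  ess <- ifelse(probs %in% .diag_fields, diag_ess, prob_ess)
  names(ess) <- probs
  cv <- rep(cost_cv, length(.psa_cost_params()))
  names(cv) <- .psa_cost_params()
  list(ess = ess, cv = cv)
}

#' Zero-spread (degenerate) PSA configuration
#'
#' Every draw returns the base value; useful for collapse-to-base-case
#' checks.
#'
#' @return A spread configuration with infinite effective sample sizes and
#'   zero cost CVs.
#' @export
zero_spread_config <- function() {
  sc <- default_spread_config()
  sc$ess[] <- Inf
  sc$cv[] <- 0
  sc
}

.get_parameter <- function(bundle, name) {
  loc <- .resolve_parameter(bundle, name)
  if (loc$section == "shared") {
    bundle$shared[[loc$field]]
  } else if (loc$section == "costs") {
    bundle$costs[[loc$field]]
  } else {
    bundle$strategies[[loc$strategy]][[loc$field]]
  }
}

#' Draw one PSA parameter bundle
#'
#' Samples every probability from its beta distribution and every cost
#' from its gamma distribution. Structural values (probabilities exactly 0
#' or 1, zero costs) and zero-spread entries are returned unchanged; the
#' averaged-scan sensitivity/specificity are recomputed from the sampled
#' CT and V/Q values so the bundle stays internally consistent.
#'
#' @param bundle Base `vte_params` bundle.
#' @param spread_config From [default_spread_config()]; must contain an
#'   entry for every sampled parameter.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A sampled `vte_params` bundle.
#' @export
sample_psa_bundle <- function(bundle, spread_config = default_spread_config(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probs <- .psa_prob_params()
  costs <- .psa_cost_params()
  missing_e <- setdiff(probs, names(spread_config$ess))
  missing_c <- setdiff(costs, names(spread_config$cv))
  if (length(missing_e) || length(missing_c)) {
    stop("spread_config is missing entries for: ",
         paste(c(missing_e, missing_c), collapse = ", "))
  }
  out <- bundle
  for (nm in probs) {
    p <- .get_parameter(bundle, nm)
    n <- spread_config$ess[[nm]]
    if (p > 0 && p < 1 && is.finite(n)) {
      out <- set_parameter(out, nm, stats::rbeta(1, p * n, (1 - p) * n))
    }
  }
  out$shared$pe_scan_avg_sens <-
    (out$shared$pe_ct_sens + out$shared$pe_vq_sens) / 2
  out$shared$pe_scan_avg_spec <-
    (out$shared$pe_ct_spec + out$shared$pe_vq_spec) / 2
  for (nm in costs) {
    m <- .get_parameter(bundle, nm)
    cv <- spread_config$cv[[nm]]
    if (m > 0 && cv > 0) {
      out <- set_parameter(out, nm,
                           stats::rgamma(1, shape = 1 / cv^2,
                                         scale = m * cv^2))
    }
  }
  out
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte Carlo over the parameter distributions: each iteration draws a
#' full bundle, rebuilds the three strategy trees and evaluates the
#' cohort, recording deaths, costs and the incremental quantities versus
#' no prophylaxis. Per-iteration seeds are derived deterministically from
#' the master seed, so results are reproducible end to end.
#'
#' @param bundle Base `vte_params` bundle.
#' @param spread_config From [default_spread_config()].
#' @param n_iter Number of iterations (the published analysis uses
#'   10,000).
#' @param seed Master integer seed.
#' @param cohort_size Cohort size; defaults to the bundle's value.
#' @return A `vte_psa` list: `samples` (long data frame: iteration,
#'   strategy, deaths, total_cost, incremental_cost, deaths_averted),
#'   `summary` (2.5/50/97.5 percentiles of deaths and total cost per
#'   strategy), `n_iter`, `seed`.
#' @export
run_psa <- function(bundle, spread_config = default_spread_config(),
                    n_iter = 10000, seed = 1, cohort_size = NULL) {
  stopifnot(n_iter >= 1)
  cohort_size <- cohort_size %||% bundle$population$cohort_size
  set.seed(seed)
  it_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)
  sids <- c("NONE", "LMWH", "UFH")
  deaths <- matrix(0, n_iter, 3, dimnames = list(NULL, sids))
  cost <- matrix(0, n_iter, 3, dimnames = list(NULL, sids))
  for (i in seq_len(n_iter)) {
    b <- sample_psa_bundle(bundle, spread_config, seed = it_seeds[i])
    for (sid in sids) {
      o <- evaluate_tree(build_tree(b$strategies[[sid]], b$shared, b$costs),
                         cohort_size)
      deaths[i, sid] <- o$expected_deaths
      cost[i, sid] <- o$expected_total_cost
    }
  }
  samples <- data.frame(
    iteration = rep(seq_len(n_iter), times = 3),
    strategy = rep(sids, each = n_iter),
    deaths = as.vector(deaths),
    total_cost = as.vector(cost))
  samples$incremental_cost <- as.vector(cost - cost[, "NONE"])
  samples$deaths_averted <- as.vector(deaths[, "NONE"] - deaths)
  samples$incremental_cost[samples$strategy == "NONE"] <- NA_real_
  samples$deaths_averted[samples$strategy == "NONE"] <- NA_real_
  qs <- c(0.025, 0.5, 0.975)
  summ <- do.call(rbind, lapply(sids, function(sid) {
    data.frame(strategy = sid, quantile = c("2.5%", "50%", "97.5%"),
               deaths = unname(stats::quantile(deaths[, sid], qs)),
               total_cost = unname(stats::quantile(cost[, sid], qs)))
  }))
  structure(list(samples = samples, summary = summ, n_iter = n_iter,
                 seed = seed, cohort_size = cohort_size),
            class = "vte_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, ranks the strategies within every
#' PSA iteration by net monetary benefit (`wtp * deaths averted -
#' incremental cost`, with no prophylaxis as the zero-benefit reference)
#' and reports the fraction of iterations in which each strategy is
#' optimal. Ties go to the cheaper strategy. Fractions sum to 1 at every
#' willingness-to-pay value.
#'
#' @param psa A `vte_psa` from [run_psa()].
#' @param wtp_grid Non-negative increasing willingness-to-pay grid (US$
#'   per death averted).
#' @return A `vte_ceac` data frame: `wtp`, `strategy`, `probability`.
#' @export
build_ceac <- function(psa, wtp_grid) {
  stopifnot(inherits(psa, "vte_psa"))
  if (nrow(psa$samples) == 0 || psa$n_iter < 1) {
    stop("empty PSA sample set; CEAC refused")
  }
  stopifnot(is.numeric(wtp_grid), all(wtp_grid >= 0),
            all(diff(wtp_grid) > 0) || length(wtp_grid) == 1)
  s <- psa$samples
  sids <- c("NONE", "LMWH", "UFH")
  av <- sapply(sids, function(sid) {
    x <- s$deaths_averted[s$strategy == sid]
    if (sid == "NONE") rep(0, psa$n_iter) else x
  })
  ic <- sapply(sids, function(sid) {
    x <- s$incremental_cost[s$strategy == sid]
    if (sid == "NONE") rep(0, psa$n_iter) else x
  })
  tc <- sapply(sids, function(sid) s$total_cost[s$strategy == sid])
  if (psa$n_iter == 1) {
    av <- matrix(av, nrow = 1, dimnames = list(NULL, sids))
    ic <- matrix(ic, nrow = 1, dimnames = list(NULL, sids))
    tc <- matrix(tc, nrow = 1, dimnames = list(NULL, sids))
  }
  rows <- lapply(wtp_grid, function(l) {
    nmb <- l * av - ic
    best <- do.call(pmax, as.data.frame(nmb))
    # among strategies tied on net benefit, prefer the cheaper one
    tc_tied <- ifelse(nmb >= best - 1e-9, tc, Inf)
    win <- max.col(-tc_tied, ties.method = "first")
    data.frame(wtp = l, strategy = sids,
               probability = tabulate(win, nbins = 3) / psa$n_iter)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("vte_ceac", class(out))
  out
}
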