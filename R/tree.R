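# Decision-tree engine: construction of the per-strategy 30-day event tree,
# recursive expectation evaluation, and full path enumeration as an
# independent second evaluation route.

.death_causes <- c("major_bleed", "symptomatic_hit", "sudden_pe",
  "treated_pe", "untreated_pe", "false_positive_pe_tx", "dvt_tx_ae",
  "underlying")

#' Construct a decision-tree node
#'
#' @param label Short node label used in path listings and tree outlines.
#' @param children List of branches, each a `list(prob = , node = )`; `NULL`
#'   for a leaf.
#' @param cost Incremental cost (2013 US$) incurred by every patient whose
#'   path passes through this node.
#' @param payoff For leaves only: `list(is_death = , cause = )`, where
#'   `cause` is one of the model's death causes or `"none"`.
#' @return A `vte_tree_node`.
#' @export
tree_node <- function(label, children = NULL, cost = 0, payoff = NULL) {
  if (is.null(children) && is.null(payoff)) {
    stop("a leaf must carry a payoff")
  }
  if (!is.null(payoff)) {
    if (!is.null(children)) stop("payoffs are only allowed on leaves")
    if (isTRUE(payoff$is_death) && !(payoff$cause %in% .death_causes)) {
      stop("unknown death cause: ", payoff$cause)
    }
  }
  structure(list(label = label, cost = cost, children = children,
                 payoff = payoff),
            class = "vte_tree_node")
}

.edge <- function(prob, node) list(prob = prob, node = node)

.leaf <- function(label, cause, cost = 0) {
  list(label = label, cost = cost, children = NULL,
       payoff = list(is_death = cause != "none", cause = cause))
}

.node <- function(label, children, cost = 0) {
  list(label = label, cost = cost, children = children, payoff = NULL)
}

# terminal branch every survivor faces: death from the underlying medical
# condition competes with discharge alive
.underlying_exit <- function(p_underlying) {
  .node("endpoint", list(
    .edge(p_underlying, .leaf("death_underlying", "underlying")),
    .edge(1 - p_underlying, .leaf("alive", "none"))))
}

# bleed severity subtree: major (possibly fatal) vs minor
.bleed_subtree <- function(sh, co, cause) {
  .node("bleed", list(
    .edge(sh$p_major_given_bleed,
      .node("major_bleed", cost = co$major_bleed, list(
        .edge(sh$p_death_given_major_bleed, .leaf("death_major_bleed", cause)),
        .edge(1 - sh$p_death_given_major_bleed,
              .underlying_exit(sh$p_death_underlying))))),
    .edge(1 - sh$p_major_given_bleed,
      .node("minor_bleed", cost = co$minor_bleed, list(
        .edge(1, .underlying_exit(sh$p_death_underlying)))))))
}

# HIT severity subtree: symptomatic (possibly fatal) vs asymptomatic
.hit_subtree <- function(sh, co, cause) {
  .node("hit", list(
    .edge(sh$p_symptomatic_given_hit,
      .node("symptomatic_hit", cost = co$symptomatic_hit, list(
        .edge(sh$p_death_given_symptomatic_hit,
              .leaf("death_symptomatic_hit", cause)),
        .edge(1 - sh$p_death_given_symptomatic_hit,
              .underlying_exit(sh$p_death_underlying))))),
    .edge(1 - sh$p_symptomatic_given_hit,
      .node("asymptomatic_hit", cost = co$asymptomatic_hit, list(
        .edge(1, .underlying_exit(sh$p_death_underlying)))))))
}

# one pulmonary embolism episode: sudden death, then clinical suspicion and
# averaged-scan confirmation among immediate survivors.  The published case
# fatalities for treated and untreated PE are proportions of all PE episodes
# (additional to sudden death), so branch probabilities conditional on
# surviving the immediate window divide by (1 - p_sudden).
.pe_subtree <- function(sh, co) {
  surv <- 1 - sh$p_sudden_death_given_pe
  q_tx <- if (surv > 0) sh$p_death_given_pe_tx_pos / surv else 0
  q_untx <- if (surv > 0) sh$p_death_given_untreated_pe / surv else 0
  undiagnosed <- function(label) {
    .node(label, list(
      .edge(q_untx, .leaf("death_untreated_pe", "untreated_pe")),
      .edge(1 - q_untx, .underlying_exit(sh$p_death_underlying))))
  }
  .node("pe", list(
    .edge(sh$p_sudden_death_given_pe, .leaf("sudden_death", "sudden_pe")),
    .edge(surv,
      .node("pe_acute_survivor", list(
        .edge(sh$pe_clin_sens,
          .node("pe_suspected", cost = co$pe_diagnosis, list(
            .edge(sh$pe_scan_avg_sens,
              .node("pe_treated", cost = co$treated_pe, list(
                .edge(q_tx, .leaf("death_treated_pe", "treated_pe")),
                .edge(1 - q_tx, .underlying_exit(sh$p_death_underlying))))),
            .edge(1 - sh$pe_scan_avg_sens, undiagnosed("pe_scan_missed"))))),
        .edge(1 - sh$pe_clin_sens, undiagnosed("pe_unsuspected")))))))
}

# false-positive PE workup among DVT-pathway patients without PE: a false
# clinical suspicion triggers a scan; a false-positive scan triggers
# anticoagulant treatment with its (small) fatality risk
.pe_fp_subtree <- function(sh, co) {
  .node("no_pe", list(
    .edge(1 - sh$pe_clin_spec,
      .node("pe_workup_fp", cost = co$pe_diagnosis, list(
        .edge(1 - sh$pe_scan_avg_spec,
          .node("pe_fp_treated", cost = co$treated_pe, list(
            .edge(sh$p_death_given_pe_tx_neg,
                  .leaf("death_pe_fp_tx", "false_positive_pe_tx")),
            .edge(1 - sh$p_death_given_pe_tx_neg,
                  .underlying_exit(sh$p_death_underlying))))),
        .edge(sh$pe_scan_avg_spec,
              .underlying_exit(sh$p_death_underlying))))),
    .edge(sh$pe_clin_spec, .underlying_exit(sh$p_death_underlying))))
}

# anticoagulant treatment of (true or false positive) DVT: treatment AEs
# with the shared severity subtrees; survivors of an AE face no further
# VTE risk.  `pe_risk` is the residual PE probability (0 for false
# positives, who have no DVT).
.dvt_tx_subtree <- function(sh, co, pe_risk) {
  p_no_ae <- 1 - sh$p_bleed_given_dvt_tx - sh$p_hit_given_dvt_tx
  after_ae_free <- if (pe_risk > 0 || TRUE) {
    .node("post_tx", list(
      .edge(pe_risk, .pe_subtree(sh, co)),
      .edge(1 - pe_risk, .pe_fp_subtree(sh, co))))
  }
  .node("dvt_treated", cost = co$treated_dvt, list(
    .edge(sh$p_bleed_given_dvt_tx, .bleed_subtree(sh, co, "dvt_tx_ae")),
    .edge(sh$p_hit_given_dvt_tx, .hit_subtree(sh, co, "dvt_tx_ae")),
    .edge(p_no_ae, after_ae_free)))
}

# false-positive DVT cascade among non-DVT patients: false clinical
# suspicion costs the workup; a false-positive ultrasound additionally
# triggers treatment and its AE risk (no PE risk: there is no thrombus)
.dvt_fp_subtree <- function(sh, co) {
  p_no_ae <- 1 - sh$p_bleed_given_dvt_tx - sh$p_hit_given_dvt_tx
  .node("no_dvt", list(
    .edge(1 - sh$dvt_clin_spec,
      .node("dvt_workup_fp", cost = co$dvt_diagnosis, list(
        .edge(1 - sh$dvt_us_spec,
          .node("dvt_fp_treated", cost = co$treated_dvt, list(
            .edge(sh$p_bleed_given_dvt_tx,
                  .bleed_subtree(sh, co, "dvt_tx_ae")),
            .edge(sh$p_hit_given_dvt_tx, .hit_subtree(sh, co, "dvt_tx_ae")),
            .edge(p_no_ae, .underlying_exit(sh$p_death_underlying))))),
        .edge(sh$dvt_us_spec, .underlying_exit(sh$p_death_underlying))))),
    .edge(sh$dvt_clin_spec, .underlying_exit(sh$p_death_underlying))))
}

.validate_tree_inputs <- function(strategy, shared, costs) {
  v <- character(0)
  for (f in c("p_dvt", "p_bleed", "p_hit")) {
    p <- strategy[[f]]
    if (is.null(p) || p < 0 || p > 1) v <- c(v, paste0(f, " outside [0, 1]"))
  }
  if (strategy$p_bleed + strategy$p_hit > 1) {
    v <- c(v, "p_bleed + p_hit > 1")
  }
  if (strategy$prophylaxis_cost < 0) v <- c(v, "negative prophylaxis_cost")
  probs <- unlist(shared[grep("^(p_|dvt_|pe_)", names(shared))])
  if (any(probs < 0 | probs > 1)) v <- c(v, "shared probability outside [0, 1]")
  if (any(unlist(costs) < 0)) v <- c(v, "negative cost")
  surv <- 1 - shared$p_sudden_death_given_pe
  if (shared$p_death_given_untreated_pe > surv ||
      shared$p_death_given_pe_tx_pos > surv) {
    v <- c(v, paste0("PE case fatality exceeds 1 - p_sudden_death_given_pe;",
                     " the episode-level death probabilities are incoherent"))
  }
  if (shared$p_bleed_given_dvt_tx + shared$p_hit_given_dvt_tx > 1) {
    v <- c(v, "p_bleed_given_dvt_tx + p_hit_given_dvt_tx > 1")
  }
  v
}

#' Build the decision tree for one prophylaxis strategy
#'
#' Constructs the 30-day event tree: mutually exclusive first-level drug
#' adverse events (bleed, HIT, neither; AE survivors face no further VTE
#' risk), incident DVT with a clinical-diagnosis gate and ultrasound
#' confirmation, anticoagulant treatment with its own AE and residual-PE
#' risks, pulmonary embolism with sudden death and a
#' clinical-plus-averaged-scan diagnostic cascade, false-positive DVT and
#' PE workups, and a terminal competing branch for death from the
#' underlying medical condition.
#'
#' @param strategy Per-strategy parameters (element of
#'   `bundle$strategies`): `p_dvt`, `p_bleed`, `p_hit`, `prophylaxis_cost`,
#'   `strategy_id`.
#' @param shared Shared event and diagnostic probabilities
#'   (`bundle$shared`).
#' @param costs Unit costs (`bundle$costs`).
#' @return The root `vte_tree_node`; the prophylaxis course cost is carried
#'   on the root so it accrues to every patient.
#' @export
build_tree <- function(strategy, shared, costs) {
  viol <- .validate_tree_inputs(strategy, shared, costs)
  if (length(viol) > 0) {
    stop("refusing to build tree: ", paste(viol, collapse = "; "))
  }
  sh <- shared
  co <- costs

  untreated_dvt <- .node("dvt_untreated", list(
    .edge(sh$p_pe_given_untreated_dvt, .pe_subtree(sh, co)),
    .edge(1 - sh$p_pe_given_untreated_dvt, .pe_fp_subtree(sh, co))))

  dvt <- .node("dvt", list(
    .edge(sh$dvt_clin_sens,
      .node("dvt_suspected", cost = co$dvt_diagnosis, list(
        .edge(sh$dvt_us_sens, .dvt_tx_subtree(sh, co, sh$p_pe_given_dvt_tx)),
        .edge(1 - sh$dvt_us_sens, untreated_dvt)))),
    .edge(1 - sh$dvt_clin_sens, untreated_dvt)))

  no_ae <- .node("no_drug_ae", list(
    .edge(strategy$p_dvt, dvt),
    .edge(1 - strategy$p_dvt, .dvt_fp_subtree(sh, co))))

  root <- .node("admission", cost = strategy$prophylaxis_cost, list(
    .edge(strategy$p_bleed, .bleed_subtree(sh, co, "major_bleed")),
    .edge(strategy$p_hit, .hit_subtree(sh, co, "symptomatic_hit")),
    .edge(1 - strategy$p_bleed - strategy$p_hit, no_ae)))
  attr(root, "strategy_id") <- strategy$strategy_id
  class(root) <- "vte_tree_node"
  root
}

#' Build the trees for all three strategies
#'
#' @param bundle A validated `vte_params` bundle.
#' @return Named list of root nodes (LMWH, UFH, NONE).
#' @export
build_all_trees <- function(bundle) {
  stopifnot(inherits(bundle, "vte_params"))
  lapply(bundle$strategies, build_tree, shared = bundle$shared,
         costs = bundle$costs)
}

.check_branch_probs <- function(probs, label) {
  if (any(probs < 0 | probs > 1) || abs(sum(probs) - 1) > 1e-12) {
    stop("malformed tree: branch probabilities at '", label,
         "' do not form a distribution (sum = ", sum(probs), ")")
  }
}

# recursive expectation: numeric vector of death probability by cause
# followed by expected cost
.eval_node <- function(node) {
  kids <- node$children
  if (is.null(kids)) {
    out <- numeric(9L)
    if (isTRUE(node$payoff$is_death)) {
      out[match(node$payoff$cause, .death_causes)] <- 1
    }
    out[9L] <- node$cost
    return(out)
  }
  probs <- vapply(kids, function(k) k$prob, 0)
  .check_branch_probs(probs, node$label)
  acc <- numeric(9L)
  for (i in seq_along(kids)) {
    if (probs[i] > 0) {
      acc <- acc + probs[i] * .eval_node(kids[[i]]$node)
    }
  }
  acc[9L] <- acc[9L] + node$cost
  acc
}

#' Evaluate expected deaths and costs for a cohort
#'
#' Rolls the cohort forward through the tree analytically: expected deaths
#' are the cohort size times the total probability mass on death leaves,
#' split by cause; expected cost is the cohort size times the
#' probability-weighted sum of costs accumulated along each path
#' (including the prophylaxis course carried on the root).
#'
#' @param root Tree root from [build_tree()].
#' @param cohort_size Number of patients (default 10,000).
#' @return A `vte_cohort_outcome`: `strategy_id`, `cohort_size`,
#'   `expected_deaths`, `deaths_by_cause`, `expected_total_cost`,
#'   `cost_per_patient`.
#' @export
evaluate_tree <- function(root, cohort_size = 10000) {
  stopifnot(cohort_size >= 1)
  res <- .eval_node(root)
  by_cause <- res[1:8] * cohort_size
  names(by_cause) <- .death_causes
  structure(list(
    strategy_id = attr(root, "strategy_id") %||% "custom",
    cohort_size = cohort_size,
    expected_deaths = sum(by_cause),
    deaths_by_cause = by_cause,
    expected_total_cost = res[9L] * cohort_size,
    cost_per_patient = res[9L]),
    class = "vte_cohort_outcome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vte_cohort_outcome <- function(x, ...) {
  cat(sprintf("%s cohort of %d: %.1f expected deaths, total cost $%s\n",
              x$strategy_id, x$cohort_size, x$expected_deaths,
              format(round(x$expected_total_cost), big.mark = ",")))
  invisible(x)
}

#' Enumerate every terminal path of a tree
#'
#' Independent evaluation route: exhaustively lists each root-to-leaf path
#' with its probability and accumulated cost. Path probabilities sum to 1;
#' the expectation computed from the listing equals [evaluate_tree()] up to
#' floating-point error.
#'
#' @param root Tree root.
#' @return `data.frame` with columns `path_probability`, `path_cost`,
#'   `is_death`, `death_cause`, `path` (slash-separated labels).
#' @export
enumerate_paths <- function(root) {
  rows <- vector("list", 256L)
  n <- 0L
  walk <- function(node, prob, cost, labels) {
    cost <- cost + node$cost
    labels <- c(labels, node$label)
    if (is.null(node$children)) {
      n <<- n + 1L
      rows[[n]] <<- list(prob, cost,
                         isTRUE(node$payoff$is_death),
                         node$payoff$cause %||% "none",
                         paste(labels, collapse = "/"))
      return(invisible())
    }
    probs <- vapply(node$children, function(k) k$prob, 0)
    .check_branch_probs(probs, node$label)
    for (k in node$children) walk(k$node, prob * k$prob, cost, labels)
  }
  walk(root, 1, 0, character(0))
  rows <- rows[seq_len(n)]
  data.frame(
    path_probability = vapply(rows, `[[`, 0, 1L),
    path_cost = vapply(rows, `[[`, 0, 2L),
    is_death = vapply(rows, `[[`, TRUE, 3L),
    death_cause = vapply(rows, `[[`, "", 4L),
    path = vapply(rows, `[[`, "", 5L))
}

#' Drop zero-probability branches from a tree
#'
#' Removes branches carried with probability exactly 0 (e.g. the HIT branch
#' of the no-prophylaxis strategy). The expectation is unchanged.
#'
#' @param root Tree root.
#' @return The pruned tree.
#' @export
prune_zero_branches <- function(root) {
  prune <- function(node) {
    if (is.null(node$children)) return(node)
    kept <- Filter(function(k) k$prob > 0, node$children)
    node$children <- lapply(kept, function(k) {
      k$node <- prune(k$node)
      k
    })
    node
  }
  prune(root)
}

#' Render a tree as an indented text outline
#'
#' @param root Tree root.
#' @param digits Probability digits.
#' @return Character vector, one line per node, suitable for
#'   `writeLines()` and for diffing tree structures.
#' @export
format_tree <- function(root, digits = 4) {
  lines <- character(0)
  walk <- function(node, prob, depth) {
    tag <- if (is.null(node$children)) {
      if (isTRUE(node$payoff$is_death)) {
        paste0(" [death: ", node$payoff$cause, "]")
      } else " [alive]"
    } else ""
    cost <- if (node$cost != 0) sprintf(" $%g", node$cost) else ""
    lines <<- c(lines, sprintf("%s%s p=%s%s%s",
      strrep("  ", depth), node$label,
      format(prob, digits = digits), cost, tag))
    for (k in node$children %||% list()) walk(k$node, k$prob, depth + 1)
  }
  walk(root, 1, 0)
  lines
}

#' Export a tree as JSON
#'
#' Machine-readable nested structure for audit and diffing.
#'
#' @param root Tree root.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
tree_to_json <- function(root, path = NULL) {
  strip <- function(node) {
    out <- list(label = node$label)
    if (node$cost != 0) out$cost <- node$cost
    if (!is.null(node$payoff)) out$payoff <- node$payoff
    if (!is.null(node$children)) {
      out$children <- lapply(node$children, function(k)
        list(prob = k$prob, node = strip(k$node)))
    }
    out
  }
  js <- jsonlite::toJSON(strip(root), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
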