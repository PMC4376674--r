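walk_nodes <- function(node, fn) {
  fn(node)
  for (k in node$children %||% list()) walk_nodes(k$node, fn)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("branch probabilities form a distribution at every internal node", {
  for (root in build_all_trees(base_bundle())) {
    walk_nodes(root, function(n) {
      if (!is.null(n$children)) {
        probs <- vapply(n$children, function(k) k$prob, 0)
        expect_true(all(probs >= 0 & probs <= 1))
        expect_lt(abs(sum(probs) - 1), 1e-12)
      } else {
        expect_false(is.null(n$payoff))
      }
    })
  }
})

test_that("first-level adverse-event branching carries the strategy probabilities", {
  b <- base_bundle()
  root <- build_tree(b$strategies$NONE, b$shared, b$costs)
  probs <- vapply(root$children, function(k) k$prob, 0)
  expect_equal(probs, c(0.020, 0.000, 0.980))
  root_l <- build_tree(b$strategies$LMWH, b$shared, b$costs)
  expect_equal(vapply(root_l$children, function(k) k$prob, 0),
               c(0.031, 0.001, 0.968))
})

test_that("every strategy tree has the frozen number of terminal paths", {
  # 87 determined once by exhaustive recursive enumeration of the topology
  for (root in build_all_trees(base_bundle())) {
    expect_identical(count_leaves(root), 87L)
    expect_identical(nrow(enumerate_paths(root)), 87L)
  }
})

test_that("path enumeration and recursive evaluation are equivalent routes", {
  cohort <- 10000
  for (root in build_all_trees(base_bundle())) {
    paths <- enumerate_paths(root)
    expect_lt(abs(sum(paths$path_probability) - 1), 1e-10)
    o <- evaluate_tree(root, cohort)
    deaths_paths <- cohort * sum(paths$path_probability[paths$is_death])
    cost_paths <- cohort * sum(paths$path_probability * paths$path_cost)
    expect_equal(deaths_paths, o$expected_deaths, tolerance = 1e-9)
    expect_equal(cost_paths, o$expected_total_cost, tolerance = 1e-9)
    # per-cause tallies agree too
    for (cause in unique(paths$death_cause[paths$is_death])) {
      expect_equal(
        cohort * sum(paths$path_probability[paths$death_cause == cause]),
        unname(o$deaths_by_cause[cause]), tolerance = 1e-9)
    }
    # dropping zero-probability branches does not move the expectation
    pruned <- evaluate_tree(prune_zero_branches(root), cohort)
    expect_equal(pruned$expected_deaths, o$expected_deaths)
    expect_equal(pruned$expected_total_cost, o$expected_total_cost)
  }
})

test_that("cohort outcome satisfies its structural invariants", {
  b <- base_bundle()
  for (sid in c("LMWH", "UFH", "NONE")) {
    o <- evaluate_tree(build_tree(b$strategies[[sid]], b$shared, b$costs))
    expect_equal(o$expected_deaths, sum(o$deaths_by_cause))
    expect_gte(o$expected_deaths, 0)
    expect_lte(o$expected_deaths, o$cohort_size)
    expect_gte(o$expected_total_cost,
               o$cohort_size * b$strategies[[sid]]$prophylaxis_cost)
  }
})

test_that("degenerate trees evaluate exactly", {
  # forced single path with a cost and certain death
  forced <- tree_node("root", cost = 123, children = list(
    list(prob = 1, node = tree_node("end", cost = 77,
      payoff = list(is_death = TRUE, cause = "underlying")))))
  o <- evaluate_tree(forced, 500)
  expect_equal(o$expected_deaths, 500)
  expect_equal(o$expected_total_cost, 500 * 200)

  # zeroing every fatality parameter empties the death mass
  b <- base_bundle()
  for (f in c("p_death_given_major_bleed", "p_death_given_symptomatic_hit",
              "p_death_given_pe_tx_pos", "p_death_given_pe_tx_neg",
              "p_sudden_death_given_pe", "p_death_given_untreated_pe",
              "p_death_underlying")) {
    b <- set_parameter(b, f, 0)
  }
  o0 <- evaluate_tree(build_tree(b$strategies$NONE, b$shared, b$costs))
  expect_equal(o0$expected_deaths, 0)
})

test_that("conservation and route agreement hold for random valid bundles", {
  for (seed in 1:20) {
    b <- random_valid_bundle(seed)
    root <- build_tree(b$strategies$UFH, b$shared, b$costs)
    paths <- enumerate_paths(root)
    expect_lt(abs(sum(paths$path_probability) - 1), 1e-10)
    o <- evaluate_tree(root, 1000)
    expect_equal(1000 * sum(paths$path_probability[paths$is_death]),
                 o$expected_deaths, tolerance = 1e-9)
    expect_equal(1000 * sum(paths$path_probability * paths$path_cost),
                 o$expected_total_cost, tolerance = 1e-9)
  }
})

test_that("expected deaths are monotone in the late-fatality parameters", {
  b <- base_bundle()
  for (f in c("p_pe_given_untreated_dvt", "p_death_given_untreated_pe",
              "p_death_underlying")) {
    hi <- if (f == "p_pe_given_untreated_dvt") 0.8 else 0.5
    deaths <- vapply(seq(0, hi, length.out = 6), function(v) {
      bb <- set_parameter(b, f, v)
      evaluate_tree(build_tree(bb$strategies$NONE, bb$shared,
                               bb$costs))$expected_deaths
    }, 0)
    expect_true(all(diff(deaths) >= 0))
  }
})

test_that("a drug with no effect and no cost reproduces no prophylaxis exactly", {
  b <- base_bundle()
  neutral <- b$strategies$NONE
  neutral$strategy_id <- "LMWH"
  o_neutral <- evaluate_tree(build_tree(neutral, b$shared, b$costs))
  o_none <- evaluate_tree(build_tree(b$strategies$NONE, b$shared, b$costs))
  expect_identical(o_neutral$expected_deaths, o_none$expected_deaths)
  expect_identical(o_neutral$expected_total_cost, o_none$expected_total_cost)
  expect_identical(o_neutral$deaths_by_cause, o_none$deaths_by_cause)
})

test_that("invalid parameters and malformed trees are refused", {
  b <- base_bundle()
  bad <- b$strategies$LMWH
  bad$p_dvt <- 1.2
  expect_error(build_tree(bad, b$shared, b$costs), "refusing")
  bad2 <- b$shared
  bad2$p_death_given_untreated_pe <- 0.95  # exceeds 1 - p_sudden
  expect_error(build_tree(b$strategies$NONE, bad2, b$costs), "refusing")

  root <- build_tree(b$strategies$NONE, b$shared, b$costs)
  root$children[[1]]$prob <- 0.5  # break conservation at the root
  expect_error(evaluate_tree(root), "malformed")
  expect_error(enumerate_paths(root), "malformed")
})

test_that("tree exports are well formed", {
  root <- build_all_trees(base_bundle())$LMWH
  outline <- format_tree(root)
  expect_gt(length(outline), 87L)  # one line per node, leaves included
  expect_match(outline[1], "admission")
  expect_length(grep("\\[death|\\[alive", outline), 87L)
  js <- tree_to_json(root)
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(parsed$label, "admission")
  expect_length(parsed$children, 3)
})
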