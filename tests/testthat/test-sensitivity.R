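test_that("a single-point scan at the base value reproduces the base case exactly", {
  b <- base_bundle()
  scan <- one_way_scan("p_pe_given_untreated_dvt", 0.511, b)
  base <- basecase_table(b)
  for (sid in c("LMWH", "UFH", "NONE")) {
    expect_identical(scan$deaths[scan$strategy == sid],
                     base$deaths[base$strategy == sid])
    expect_identical(scan$total_cost[scan$strategy == sid],
                     base$total_cost[base$strategy == sid])
  }
})

test_that("deaths averted rise monotonically with the untreated-DVT PE risk", {
  scan <- one_way_scan("p_pe_given_untreated_dvt",
                       seq(0, 0.511, length.out = 8), base_bundle())
  for (sid in c("LMWH", "UFH")) {
    averted <- scan$deaths_averted[scan$strategy == sid]
    expect_true(all(diff(averted) >= 0))
  }
})

test_that("scans refuse unknown parameters and bad grids", {
  b <- base_bundle()
  expect_error(one_way_scan("p_nonexistent", c(0.1, 0.2), b),
               "unknown parameter")
  expect_error(one_way_scan("p_dvt", c(0.1, 0.2), b), "unknown parameter")
  expect_error(one_way_scan("p_pe_given_untreated_dvt", c(0.2, 0.1), b),
               "strictly increasing")
  expect_error(one_way_scan("p_pe_given_untreated_dvt", c(0.1, 1.5), b),
               "outside")
  expect_error(find_threshold("p_pe_given_untreated_dvt", "no_such",
                              c(0, 0.5), b), "unknown criterion")
})

test_that("strategy-addressed parameters scan through the named strategy only", {
  scan <- one_way_scan("LMWH.p_dvt", c(0.02, 0.142), base_bundle())
  none_deaths <- scan$deaths[scan$strategy == "NONE"]
  expect_equal(none_deaths[1], none_deaths[2])  # comparator untouched
  lm <- scan$deaths[scan$strategy == "LMWH"]
  expect_lt(lm[1], lm[2])
  # at the comparator's own DVT risk the two arms differ only by drug effects
  expect_gt(scan$deaths_averted[scan$strategy == "LMWH"][2], -5)
})

test_that("criteria holding over the whole range are reported, not solved", {
  thr <- find_threshold("p_pe_given_untreated_dvt", "both_cost_saving",
                        c(1e-6, 0.511), base_bundle())
  expect_identical(thr$status, "none-in-range")
  expect_identical(thr$flag, "always satisfied")
  expect_true(is.na(thr$value))
})

test_that("bisection agrees with a dense-grid oracle", {
  b <- base_bundle()
  tol <- 5e-4
  thr <- find_threshold("p_pe_given_untreated_dvt", "effective:UFH",
                        c(1e-6, 0.511), b, tol = tol)
  expect_identical(thr$status, "ok")
  # oracle: finest value on a dense grid at which the criterion first holds
  grid <- seq(1e-6, 0.511, length.out = 1001)
  averted_u <- vapply(grid, function(x) {
    bb <- set_parameter(b, "p_pe_given_untreated_dvt", x)
    outs <- all_outcomes(bb)
    outs$NONE$expected_deaths - outs$UFH$expected_deaths
  }, 0)
  first_true <- grid[which(averted_u > 0)[1]]
  expect_lt(abs(thr$value - first_true), tol + diff(grid[1:2]))
  # the same crossing governs joint dominance at base case
  thr2 <- find_threshold("p_pe_given_untreated_dvt", "both_dominant",
                         c(1e-6, 0.511), b, tol = tol)
  expect_equal(thr2$value, thr$value, tolerance = 1e-3)
})

test_that("zero-spread sampling returns the base bundle exactly", {
  b <- base_bundle()
  s <- sample_psa_bundle(b, zero_spread_config(), seed = 11)
  expect_equal(vteprophy:::.flatten_bundle(s),
               vteprophy:::.flatten_bundle(b))
})

test_that("PSA draws have the configured means and respect structural zeros", {
  b <- base_bundle()
  sc <- default_spread_config()
  n <- 2000
  draws <- matrix(0, n, 4,
                  dimnames = list(NULL, c("LMWH.p_dvt", "NONE.p_hit",
                                          "p_death_given_untreated_pe",
                                          "costs.treated_dvt")))
  set.seed(99)
  for (i in seq_len(n)) {
    s <- sample_psa_bundle(b, sc)
    draws[i, ] <- c(s$strategies$LMWH$p_dvt, s$strategies$NONE$p_hit,
                    s$shared$p_death_given_untreated_pe,
                    s$costs$treated_dvt)
  }
  expect_true(all(draws[, "NONE.p_hit"] == 0))       # structural zero
  # beta mean p, sd sqrt(p(1-p)/(n+1)); gamma mean m, sd m*cv
  check_mean <- function(x, mean, sd) {
    expect_lt(abs(mean(x) - mean), 3 * sd / sqrt(n))
  }
  check_mean(draws[, "LMWH.p_dvt"], 0.055, sqrt(0.055 * 0.945 / 301))
  check_mean(draws[, "p_death_given_untreated_pe"], 0.26,
             sqrt(0.26 * 0.74 / 301))
  check_mean(draws[, "costs.treated_dvt"], 10758, 10758 * 0.25)
  expect_true(all(draws[, "LMWH.p_dvt"] >= 0 & draws[, "LMWH.p_dvt"] <= 1))
  expect_true(all(draws[, "costs.treated_dvt"] >= 0))
  # averaged-scan rows stay consistent with the sampled scan rows
  s <- sample_psa_bundle(b, sc, seed = 5)
  expect_equal(s$shared$pe_scan_avg_sens,
               (s$shared$pe_ct_sens + s$shared$pe_vq_sens) / 2)
})

test_that("an incomplete spread configuration is refused", {
  sc <- default_spread_config()
  sc$ess <- sc$ess[-1]
  expect_error(sample_psa_bundle(base_bundle(), sc), "missing entries")
})

test_that("the PSA is reproducible from its seed and collapses at zero spread", {
  b <- base_bundle()
  p1 <- run_psa(b, default_spread_config(), n_iter = 30, seed = 7)
  p2 <- run_psa(b, default_spread_config(), n_iter = 30, seed = 7)
  expect_identical(p1$samples, p2$samples)
  p3 <- run_psa(b, default_spread_config(), n_iter = 30, seed = 8)
  expect_false(identical(p1$samples$deaths, p3$samples$deaths))

  base <- basecase_table(b)
  pz <- run_psa(b, zero_spread_config(), n_iter = 1, seed = 1)
  for (sid in c("NONE", "LMWH", "UFH")) {
    expect_equal(pz$samples$deaths[pz$samples$strategy == sid],
                 base$deaths[base$strategy == sid])
    expect_equal(pz$samples$total_cost[pz$samples$strategy == sid],
                 base$total_cost[base$strategy == sid])
  }
})

test_that("PSA percentile summaries are ordered", {
  p <- run_psa(base_bundle(), default_spread_config(), n_iter = 80, seed = 3)
  for (sid in unique(p$summary$strategy)) {
    s <- p$summary[p$summary$strategy == sid, ]
    expect_true(all(diff(s$deaths) >= 0))
    expect_true(all(diff(s$total_cost) >= 0))
  }
})

test_that("CEAC fractions partition the iterations at every willingness to pay", {
  p <- run_psa(base_bundle(), default_spread_config(), n_iter = 60, seed = 21)
  ceac <- build_ceac(p, c(0, 5000, 20000, 50000))
  sums <- tapply(ceac$probability, ceac$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, 4))
  expect_true(all(ceac$probability >= 0 & ceac$probability <= 1))
})

test_that("a zero-spread CEAC is the step function of base-case net benefit", {
  b <- base_bundle()
  p <- run_psa(b, zero_spread_config(), n_iter = 5, seed = 1)
  ceac <- build_ceac(p, c(0, 10000))
  base <- basecase_table(b)
  # LMWH dominates at base case, so it is optimal with probability 1
  expect_equal(ceac$probability[ceac$strategy == "LMWH"], c(1, 1))
  expect_equal(ceac$probability[ceac$strategy == "NONE"], c(0, 0))
  expect_true(base$incremental_cost[base$strategy == "LMWH"] < 0)
})

test_that("an empty PSA sample set is refused by the CEAC", {
  p <- run_psa(base_bundle(), zero_spread_config(), n_iter = 1, seed = 1)
  p$samples <- p$samples[0, ]
  expect_error(build_ceac(p, c(0, 1000)), "empty")
})
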