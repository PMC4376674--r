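# Shared fixtures: the base bundle (loaded once) and a generator of random
# valid parameter bundles for property-style tests.

.base_env <- new.env()

base_bundle <- function() {
  if (is.null(.base_env$bundle)) .base_env$bundle <- default_parameters()
  .base_env$bundle
}

# Random bundle drawn inside the model's validity region: probabilities
# perturbed around plausible ranges, costs rescaled, structural constraints
# (AE exclusivity, NONE has no HIT, PE episode coherence, monotone funnel)
# preserved.  Always passes validate_parameters().
random_valid_bundle <- function(seed) {
  set.seed(seed)
  b <- base_bundle()
  u <- function(lo, hi) stats::runif(1, lo, hi)
  for (sid in c("LMWH", "UFH", "NONE")) {
    b$strategies[[sid]]$p_dvt <- u(0, 0.3)
    p_bleed <- u(0, 0.15)
    p_hit <- if (sid == "NONE") 0 else u(0, min(0.05, 1 - p_bleed))
    b$strategies[[sid]]$p_bleed <- p_bleed
    b$strategies[[sid]]$p_hit <- p_hit
    if (sid != "NONE") {
      b$strategies[[sid]]$prophylaxis_cost <- u(50, 800)
    }
  }
  sh <- b$shared
  sh$p_major_given_bleed <- u(0, 0.5)
  sh$p_death_given_major_bleed <- u(0, 0.5)
  sh$p_symptomatic_given_hit <- u(0, 1)
  sh$p_death_given_symptomatic_hit <- u(0, 0.5)
  sh$p_bleed_given_dvt_tx <- u(0, 0.2)
  sh$p_hit_given_dvt_tx <- u(0, min(0.2, 1 - sh$p_bleed_given_dvt_tx))
  sh$p_pe_given_dvt_tx <- u(0, 0.1)
  sh$p_sudden_death_given_pe <- u(0, 0.3)
  sh$p_death_given_pe_tx_pos <- u(0, (1 - sh$p_sudden_death_given_pe) / 2)
  sh$p_death_given_untreated_pe <- u(0, (1 - sh$p_sudden_death_given_pe) * 0.9)
  sh$p_pe_given_untreated_dvt <- u(0, 0.8)
  sh$p_death_given_pe_tx_neg <- u(0, 0.05)
  sh$p_death_underlying <- u(0, 0.3)
  for (f in c("dvt_clin_sens", "dvt_clin_spec", "dvt_us_sens", "dvt_us_spec",
              "pe_clin_sens", "pe_clin_spec")) {
    sh[[f]] <- u(0.1, 1)
  }
  sh$pe_ct_sens <- u(0.3, 1); sh$pe_vq_sens <- u(0.3, 1)
  sh$pe_ct_spec <- u(0.3, 1); sh$pe_vq_spec <- u(0.3, 1)
  sh$pe_scan_avg_sens <- (sh$pe_ct_sens + sh$pe_vq_sens) / 2
  sh$pe_scan_avg_spec <- (sh$pe_ct_spec + sh$pe_vq_spec) / 2
  b$shared <- sh
  for (f in names(b$costs)) b$costs[[f]] <- b$costs[[f]] * u(0.5, 1.5)
  stopifnot(length(validate_parameters(b)) == 0)
  b
}

# independent oracle: count leaves without going through enumerate_paths
count_leaves <- function(node) {
  if (is.null(node$children)) return(1L)
  sum(vapply(node$children, function(k) count_leaves(k$node), 1L))
}

# expected outcomes for every strategy of a bundle
all_outcomes <- function(bundle, cohort = 10000) {
  lapply(build_all_trees(bundle), evaluate_tree, cohort_size = cohort)
}
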