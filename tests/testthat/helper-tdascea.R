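# Shared fixtures: the bundled parameter set is read once per test run.
.params_cache <- new.env(parent = emptyenv())

base_params <- function() {
  if (is.null(.params_cache$p)) .params_cache$p <- load_params()
  .params_cache$p
}

# Random valid diagnostic-phase performance for property tests.
random_performance <- function() {
  list(
    p_test_positive  = runif(1, 0.05, 0.99),
    p_true_positive  = runif(1, 0.05, 0.99),
    p_false_positive = runif(1, 0.01, 0.95),
    p_delayed_tdas   = runif(1, 0, 0.3),
    p_diagnosed_clin = runif(1, 0.05, 0.99),
    p_delayed_clin   = runif(1, 0, 0.5)
  )
}

random_mix <- function() {
  m <- rgamma(3, shape = 1) + 1e-6
  m <- m / sum(m)
  names(m) <- c("mild", "moderate", "severe")
  m
}

# Random sub-stochastic annual severity transition rates.
random_rates <- function() {
  pair <- function() { x <- runif(2); x / sum(x) * runif(1, 0, 0.99) }
  mm <- pair(); om <- pair(); sm <- pair()
  list(mild_moderate = mm[1], mild_severe = mm[2],
       moderate_mild = om[1], moderate_severe = om[2],
       severe_mild = sm[1], severe_moderate = sm[2])
}

# Parameter set with every input frozen at its mean (no sampling).
all_fixed_params <- function(params = base_params()) {
  params$specs$family <- "fixed"
  params$specs$se <- NA_real_
  params$specs$cv20 <- FALSE
  params
}

# A params object where both diagnostic arms are operationally identical:
# same probability of entering ASD care, no false positives, no delayed
# diagnoses, same severity mix, same diagnostic cost.
identical_arm_params <- function(params = base_params()) {
  set <- function(p, nm, v) { p$specs$mean[match(nm, p$specs$name)] <- v; p }
  params <- set(params, "p_test_positive", 0.70)
  params <- set(params, "p_true_positive", 1.0)
  params <- set(params, "p_false_positive", 0.0)
  params <- set(params, "p_delayed_tdas", 0.0)
  params <- set(params, "p_diagnosed_clin", 0.70)
  params <- set(params, "p_delayed_clin", 0.0)
  for (s in c("mild", "moderate", "severe")) {
    params <- set(params, paste0("p_", s, "_clin"),
                  params$specs$mean[match(paste0("p_", s, "_tdas"),
                                          params$specs$name)])
  }
  params <- set(params, "c_tdas_training", 0)
  params <- set(params, "c_tdas_instruments", 0)
  params <- set(params, "c_tdas_maintenance", 0)
  params <- set(params, "c_cloud_service", 0)
  params <- set(params, "c_labor_tdas", 61)
  params
}
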