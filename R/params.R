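#' @keywords internal
"_PACKAGE"

# States are indexed in this order throughout the package.
STATES <- c("non_asd", "mild", "moderate", "severe", "dead")
SEVERITIES <- c("mild", "moderate", "severe")

# Master table of model inputs: one row per published input parameter.
# `cv20` marks inputs whose uncertainty was published only as a +/-20%
# variation; for those, the probabilistic dispersion is default_cv * mean.
default_param_table <- function() {
  row <- function(name, mean, se, family, group = NA_character_,
                  section, cv20 = FALSE) {
    data.frame(name = name, mean = mean, se = se, family = family,
               group = group, section = section, cv20 = cv20,
               stringsAsFactors = FALSE)
  }
  rbind(
    # -- diagnostic phase ------------------------------------------------
    row("p_test_positive",  0.8990, 0.0339, "beta", section = "diagnostic"),
    row("p_true_positive",  0.8286, 0.0368, "beta", section = "diagnostic"),
    row("p_false_positive", 0.1961, 0.0556, "beta", section = "diagnostic"),
    row("p_delayed_tdas",   0.0071, 0.0071, "beta", section = "diagnostic"),
    row("p_mild_tdas",     0.1111, 0.0786, "dirichlet", "mix_tdas", "diagnostic"),
    row("p_moderate_tdas", 0.5069, 0.0585, "dirichlet", "mix_tdas", "diagnostic"),
    row("p_severe_tdas",   0.3819, 0.0655, "dirichlet", "mix_tdas", "diagnostic"),
    row("p_diagnosed_clin", 0.6731, 0.0376, "beta", section = "diagnostic"),
    row("p_delayed_clin",   0.2000, 0.0332, "beta", section = "diagnostic"),
    row("p_mild_clin",     0.0608, 0.0797, "dirichlet", "mix_clin", "diagnostic"),
    row("p_moderate_clin", 0.3311, 0.0672, "dirichlet", "mix_clin", "diagnostic"),
    row("p_severe_clin",   0.6081, 0.0515, "dirichlet", "mix_clin", "diagnostic"),
    # -- follow-up phase transitions ------------------------------------
    row("tp_mild_moderate",    0.0620, 0.0538, "beta",  section = "transitions"),
    row("tp_mild_severe",      0.0000, 0.0000, "fixed", section = "transitions"),
    row("tp_moderate_mild",    0.2643, 0.0226, "beta",  section = "transitions"),
    row("tp_moderate_severe",  0.0218, 0.0087, "beta",  section = "transitions"),
    row("tp_severe_mild",      0.0025, 0.0044, "beta",  section = "transitions"),
    row("tp_severe_moderate",  0.2078, 0.1730, "beta",  section = "transitions"),
    row("rr_death_asd",        2.370,  0.0942, "lognormal", section = "transitions"),
    # -- utilities -------------------------------------------------------
    row("u_mild",     0.8659, 0.0085, "beta", section = "utilities"),
    row("u_moderate", 0.8410, 0.0098, "beta", section = "utilities"),
    row("u_severe",   0.7930, 0.0177, "beta", section = "utilities"),
    # -- direct medical cost (USD) --------------------------------------
    row("c_inpatient_mild",     387, 88, "gamma", section = "direct_medical"),
    row("c_inpatient_moderate", 416, 38, "gamma", section = "direct_medical"),
    row("c_inpatient_severe",   664, 53, "gamma", section = "direct_medical"),
    row("p_admission",          0.3460, 0.0280, "beta",  section = "direct_medical"),
    row("p_admitted_mild",      0.0585, NA, "fixed", section = "direct_medical"),
    row("p_admitted_moderate",  0.3032, NA, "fixed", section = "direct_medical"),
    row("p_admitted_severe",    0.6383, NA, "fixed", section = "direct_medical"),
    row("c_outpatient_mild",     66, 11, "gamma", section = "direct_medical"),
    row("c_outpatient_moderate", 133, 7, "gamma", section = "direct_medical"),
    row("c_outpatient_severe",   124, 12, "gamma", section = "direct_medical"),
    row("c_instruments_mild",     11, 26, "gamma", section = "direct_medical"),
    row("c_instruments_moderate", 197, 24, "gamma", section = "direct_medical"),
    row("c_instruments_severe",   199, 25, "gamma", section = "direct_medical"),
    row("p_instruments_mild",     0.5565, NA, "fixed", section = "direct_medical"),
    row("p_instruments_moderate", 0.6852, NA, "fixed", section = "direct_medical"),
    row("p_instruments_severe",   0.8966, NA, "fixed", section = "direct_medical"),
    row("c_activities_mild",     1314, 246, "gamma", section = "direct_medical"),
    row("c_activities_moderate", 1148, 188, "gamma", section = "direct_medical"),
    row("c_activities_severe",   1152, 216, "gamma", section = "direct_medical"),
    row("p_activities_mild",     0.2114, NA, "fixed", section = "direct_medical"),
    row("p_activities_moderate", 0.2243, NA, "fixed", section = "direct_medical"),
    row("p_activities_severe",   0.4561, NA, "fixed", section = "direct_medical"),
    # -- direct non-medical cost (USD) ----------------------------------
    row("c_travel_outpatient",         13, 0.9, "gamma", section = "direct_nonmedical"),
    row("c_food_outpatient",            8, 0.5, "gamma", section = "direct_nonmedical"),
    row("c_accommodation_outpatient",  24, 3.6, "gamma", section = "direct_nonmedical"),
    row("p_accommodation_outpatient",  0.60, 0.03, "beta", section = "direct_nonmedical"),
    row("n_visits_mild",     5.13, 0.49, "gamma", section = "direct_nonmedical"),
    row("n_visits_moderate", 4.89, 0.48, "gamma", section = "direct_nonmedical"),
    row("n_visits_severe",   6.65, 0.91, "gamma", section = "direct_nonmedical"),
    row("c_caregiver_outpatient", 38, 3, "gamma", section = "direct_nonmedical"),
    row("c_travel_admission_patient",        48, 6,   "gamma", section = "direct_nonmedical"),
    row("c_food_admission_patient",           9, 0.7, "gamma", section = "direct_nonmedical"),
    row("c_accommodation_admission_patient", 15, 1,   "gamma", section = "direct_nonmedical"),
    row("p_accommodation_admission",        0.385, 0.078, "beta", section = "direct_nonmedical"),
    row("c_travel_admission_caregiver",        63, 10, "gamma", section = "direct_nonmedical"),
    row("c_food_admission_caregiver",          80, 8,  "gamma", section = "direct_nonmedical"),
    row("c_accommodation_admission_caregiver", 183, 48, "gamma", section = "direct_nonmedical"),
    row("c_caregiver_admission", 225, 105, "gamma", section = "direct_nonmedical"),
    row("n_admissions_per_year", 1, NA, "fixed", section = "direct_nonmedical"),
    # -- caregiver cost at home (USD) -----------------------------------
    row("c_hired_caregiver", 196, 32, "gamma", section = "caregiver_home"),
    row("p_hired_caregiver", 0.058, NA, "fixed", section = "caregiver_home"),
    row("c_lost_income",     518, 53, "gamma", section = "caregiver_home"),
    row("p_quit_mild",     0.1778, NA, "fixed", section = "caregiver_home"),
    row("p_quit_moderate", 0.1348, NA, "fixed", section = "caregiver_home"),
    row("p_quit_severe",   0.2364, NA, "fixed", section = "caregiver_home"),
    # -- diagnostic strategy costs (USD) --------------------------------
    row("c_tdas_training",    151,  NA, "gamma", section = "strategy_costs", cv20 = TRUE),
    row("c_tdas_instruments", 323,  NA, "gamma", section = "strategy_costs", cv20 = TRUE),
    row("c_tdas_maintenance", 0.27, NA, "gamma", section = "strategy_costs", cv20 = TRUE),
    row("c_cloud_service",    1.43, NA, "gamma", section = "strategy_costs", cv20 = TRUE),
    row("c_labor_tdas",       134,  NA, "gamma", section = "strategy_costs", cv20 = TRUE),
    row("c_labor_clin",       61,   NA, "gamma", section = "strategy_costs", cv20 = TRUE),
    row("n_diagnoses_per_week", 2.0, NA, "fixed", section = "strategy_costs"),
    # -- scenario severity mix for clinical diagnosis -------------------
    row("p_mild_clin_scenario",     0.1139, NA, "fixed", "mix_clin_scenario", "scenario"),
    row("p_moderate_clin_scenario", 0.4557, NA, "fixed", "mix_clin_scenario", "scenario"),
    row("p_severe_clin_scenario",   0.4304, NA, "fixed", "mix_clin_scenario", "scenario")
  )
}

default_econ_settings <- function() {
  list(
    discount_rate = 0.03,     # per year, costs and QALYs alike
    wtp_thb = 160000,         # willingness-to-pay threshold, THB/QALY
    exchange_rate = 34.995,   # THB per USD
    wtp_usd_override = NULL,  # set to e.g. 4577 to override wtp_thb/exchange_rate
    start_age = 3.52,         # mean age at diagnosis, years
    max_age = 100,            # model closure age
    psa_iterations = 10000,
    default_cv = 0.20         # dispersion for inputs published as +/-20%
  )
}

default_flags <- function() {
  list(
    # how the (true positive, false positive) pair among test-positives is
    # interpreted: "renormalize" rescales the pair to a branch distribution;
    # "prevalence" builds a prevalence-explicit tree (needs asd_prevalence)
    tree_interpretation = "renormalize",
    asd_prevalence = NA_real_,
    # utility credited to the non-ASD state. The default 0 makes children
    # ruled out at the diagnostic phase exit the model: lifetime costs and
    # QALYs are accrued for the diagnosed ASD cohort only, which is the
    # accounting the published per-strategy totals imply.
    u_non_asd = 0,
    fp_workup_cost = 0,          # one-time cost for a false-positive workup
    half_cycle_correction = FALSE,
    instrument_mode = "entry",   # "entry": one-time purchase; "annual"
    dirichlet_neff = "min",      # "min" or "counts" (chart-review sample sizes)
    dirichlet_counts = c(tdas = 147, clin = 148),
    rr_se_scale = "natural",     # "natural" or "log" reading of the RR SE
    amortization_diagnoses_per_provider_year = 104
  )
}

#' Path to the bundled default configuration
#'
#' The bundled YAML configuration carries every published model input
#' (means, standard errors, distribution families), the economic settings,
#' and a pointer to the bundled life table.
#'
#' @return Path to the YAML file.
#' @export
tdas_default_config <- function() {
  system.file("extdata", "default_config.yaml", package = "tdascea",
              mustWork = TRUE)
}

#' Load and validate the model parameter set
#'
#' Reads a configuration (YAML path or an equivalent nested list), checks
#' that every required input is present, attaches the life table, and
#' validates the result. Defaults are applied only to decision settings
#' (economics, structural flags), never to the published input values:
#' a configuration that omits an input block is rejected.
#'
#' @param config Path to a YAML configuration or a nested list with
#'   elements `parameters`, and optionally `economics`, `flags`,
#'   `life_table`. Defaults to the bundled configuration.
#' @param life_table Optional life table overriding the configured one:
#'   a path to a CSV with columns `age,qx`, or a data frame.
#' @return An object of class `tdas_params`.
#' @export
load_params <- function(config = tdas_default_config(), life_table = NULL) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$parameters)) {
    stop("configuration has no 'parameters' block")
  }
  tmpl <- default_param_table()
  specs <- tmpl
  for (sec in unique(tmpl$section)) {
    block <- config$parameters[[sec]]
    if (is.null(block)) {
      stop(sprintf("configuration is missing required block '%s'", sec))
    }
    for (i in which(tmpl$section == sec)) {
      nm <- tmpl$name[i]
      entry <- block[[nm]]
      if (is.null(entry)) {
        stop(sprintf("configuration is missing required key '%s' in block '%s'",
                     nm, sec))
      }
      if (is.null(entry$mean)) {
        stop(sprintf("parameter '%s' has no 'mean'", nm))
      }
      specs$mean[i] <- as.numeric(entry$mean)
      specs$se[i] <- if (is.null(entry$se)) NA_real_ else as.numeric(entry$se)
      if (!is.null(entry$family)) specs$family[i] <- entry$family
      if (!is.null(entry$cv20)) specs$cv20[i] <- isTRUE(entry$cv20)
    }
  }
  econ <- utils::modifyList(default_econ_settings(),
                            config$economics %||% list())
  flags <- utils::modifyList(default_flags(), config$flags %||% list())

  if (is.null(life_table)) {
    lt_src <- config$life_table %||% "bundled"
    life_table <- if (identical(lt_src, "bundled")) {
      default_life_table()
    } else {
      read_life_table(lt_src)
    }
  } else if (is.character(life_table)) {
    life_table <- read_life_table(life_table)
  }

  params <- structure(
    list(specs = specs, econ = econ, flags = flags, life_table = life_table),
    class = "tdas_params"
  )
  issues <- validate_params(params)
  if (length(issues)) {
    stop("invalid parameter set:\n  - ", paste(issues, collapse = "\n  - "))
  }
  params
}

#' Write a parameter set back to a YAML configuration
#'
#' The written file reproduces every mean and standard error at full
#' precision, so `load_params(write_config(p, f))` round-trips.
#'
#' @param params A `tdas_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "tdas_params"))
  specs <- params$specs
  blocks <- list()
  for (sec in unique(specs$section)) {
    rows <- specs[specs$section == sec, ]
    entries <- lapply(seq_len(nrow(rows)), function(i) {
      e <- list(mean = rows$mean[i])
      if (!is.na(rows$se[i])) e$se <- rows$se[i]
      e$family <- rows$family[i]
      if (rows$cv20[i]) e$cv20 <- TRUE
      e
    })
    names(entries) <- rows$name
    blocks[[sec]] <- entries
  }
  econ <- params$econ
  econ <- econ[!vapply(econ, is.null, logical(1))]
  flags <- params$flags
  flags$dirichlet_counts <- as.list(flags$dirichlet_counts)
  out <- list(parameters = blocks, economics = econ, flags = flags,
              life_table = "bundled")
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Validate a model parameter set
#'
#' Checks every type invariant: support of each value given its
#' distribution family, severity mixes summing to one, transition row
#' sums, life-table coverage and monotone bounds, and economic settings.
#' Violations are returned as data, not raised.
#'
#' @param params A `tdas_params` object.
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate_params <- function(params) {
  issues <- character()
  say <- function(...) issues <<- c(issues, sprintf(...))
  s <- params$specs

  for (i in seq_len(nrow(s))) {
    nm <- s$name[i]; m <- s$mean[i]; se <- s$se[i]; fam <- s$family[i]
    if (!fam %in% c("beta", "dirichlet", "gamma", "lognormal", "fixed")) {
      say("parameter '%s' has unknown family '%s'", nm, fam)
      next
    }
    if (is.na(m)) { say("parameter '%s' has no value", nm); next }
    if (fam %in% c("beta", "dirichlet") && (m < 0 || m > 1)) {
      say("parameter '%s' (%g) outside [0,1] for family %s", nm, m, fam)
    }
    if (fam %in% c("gamma", "lognormal") && m < 0) {
      say("parameter '%s' (%g) negative for family %s", nm, m, fam)
    }
    if (!is.na(se) && se < 0) say("parameter '%s' has negative SE", nm)
    if (fam == "fixed" && !is.na(se) && se > 0) {
      say("parameter '%s' is fixed but has SE %g", nm, se)
    }
    if (fam != "fixed" && !s$cv20[i] && (is.na(se) || se <= 0) &&
        !(fam == "beta" && m %in% c(0, 1))) {
      say("parameter '%s' (family %s) has no usable SE", nm, fam)
    }
  }

  for (g in c("mix_tdas", "mix_clin", "mix_clin_scenario")) {
    tot <- sum(s$mean[!is.na(s$group) & s$group == g])
    if (abs(tot - 1) > 0.005) {
      say("severity mix '%s' sums to %.4f", g, tot)
    }
  }
  adm <- sum(s$mean[s$name %in% c("p_admitted_mild", "p_admitted_moderate",
                                  "p_admitted_severe")])
  if (abs(adm - 1) > 1e-9) say("admitted severity shares sum to %.4f", adm)

  pv <- function(nm) s$mean[s$name == nm]
  for (origin in c("mild", "moderate", "severe")) {
    rows <- s$name[startsWith(s$name, paste0("tp_", origin))]
    tot <- sum(vapply(rows, pv, numeric(1)))
    if (tot > 1) say("transition probabilities out of '%s' sum to %.4f > 1",
                     origin, tot)
  }

  lt <- params$life_table
  if (is.null(lt)) {
    say("no life table configured")
  } else {
    if (!all(c("age", "qx") %in% names(lt))) {
      say("life table lacks 'age'/'qx' columns")
    } else {
      bad <- lt$age[lt$qx < 0 | lt$qx > 1]
      for (a in bad) say("life table q(%d) = %g outside [0,1]", a,
                         lt$qx[lt$age == a])
      expect_ages <- seq(0L, max(lt$age))
      if (!identical(as.integer(lt$age), expect_ages)) {
        say("life-table ages are not contiguous from 0")
      }
      if (max(lt$age) < params$econ$max_age) {
        say("life table ends at age %d, before max_age %d",
            max(lt$age), as.integer(params$econ$max_age))
      }
    }
  }

  e <- params$econ
  if (e$discount_rate < 0 || e$discount_rate >= 1) {
    say("discount rate %g outside [0,1)", e$discount_rate)
  }
  if (e$exchange_rate <= 0) say("exchange rate must be positive")
  if (e$start_age >= e$max_age) say("start_age must be below max_age")
  if (!params$flags$tree_interpretation %in% c("renormalize", "prevalence")) {
    say("unknown tree_interpretation '%s'", params$flags$tree_interpretation)
  }
  if (params$flags$tree_interpretation == "prevalence" &&
      is.na(params$flags$asd_prevalence)) {
    say("tree_interpretation 'prevalence' needs flags$asd_prevalence")
  }
  issues
}

#' One-way sensitivity bounds for a parameter
#'
#' Returns the low/high values a one-way sensitivity analysis should use:
#' the 95% confidence bounds `mean +/- 1.96 * se` when a standard error is
#' available, otherwise a 20% variation either side of the mean. Bounds are
#' clamped to the support of the distribution family.
#'
#' @param mean Point estimate.
#' @param se Standard error, or `NA` when only a +/-20% variation applies.
#' @param family Distribution family, one of `beta`, `dirichlet`, `gamma`,
#'   `lognormal`.
#' @param variation Relative variation used when `se` is missing.
#' @return Numeric vector `c(low, high)`.
#' @export
owsa_bounds <- function(mean, se = NA, family = "beta", variation = 0.20) {
  if (identical(family, "fixed")) stop("parameter is fixed")
  if (is.na(se) || se == 0) {
    lo <- mean * (1 - variation)
    hi <- mean * (1 + variation)
  } else {
    lo <- mean - 1.96 * se
    hi <- mean + 1.96 * se
  }
  support <- switch(family,
    beta = , dirichlet = c(0, 1),
    gamma = , lognormal = c(0, Inf),
    c(-Inf, Inf))
  c(low = max(lo, support[1]), high = min(hi, support[2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- structured accessors ---------------------------------------------

param_value <- function(params, name) {
  i <- match(name, params$specs$name)
  if (is.na(i)) stop(sprintf("unknown parameter '%s'", name))
  params$specs$mean[i]
}

#' Diagnostic-phase performance probabilities
#' @param params A `tdas_params` object.
#' @return Named list of the six diagnostic-phase probabilities.
#' @export
diagnostic_performance <- function(params) {
  list(
    p_test_positive  = param_value(params, "p_test_positive"),
    p_true_positive  = param_value(params, "p_true_positive"),
    p_false_positive = param_value(params, "p_false_positive"),
    p_delayed_tdas   = param_value(params, "p_delayed_tdas"),
    p_diagnosed_clin = param_value(params, "p_diagnosed_clin"),
    p_delayed_clin   = param_value(params, "p_delayed_clin")
  )
}

#' Severity mix at diagnosis for one strategy
#'
#' @param params A `tdas_params` object.
#' @param strategy `"tdas"` or `"clindx"`.
#' @param scenario Use the scenario mix for clinical diagnosis (severity
#'   shares re-estimated without the specialty hospital)?
#' @return Named probability vector over mild/moderate/severe, normalized
#'   to sum to one.
#' @export
severity_mix <- function(params, strategy = c("tdas", "clindx"),
                         scenario = FALSE) {
  strategy <- match.arg(strategy)
  nms <- if (strategy == "tdas") {
    c("p_mild_tdas", "p_moderate_tdas", "p_severe_tdas")
  } else if (scenario) {
    c("p_mild_clin_scenario", "p_moderate_clin_scenario",
      "p_severe_clin_scenario")
  } else {
    c("p_mild_clin", "p_moderate_clin", "p_severe_clin")
  }
  mix <- vapply(nms, param_value, numeric(1), params = params)
  names(mix) <- SEVERITIES
  mix / sum(mix)
}

#' Annual severity transition probabilities
#' @param params A `tdas_params` object.
#' @return Named list of the six annual transition probabilities.
#' @export
transition_rates <- function(params) {
  list(
    mild_moderate   = param_value(params, "tp_mild_moderate"),
    mild_severe     = param_value(params, "tp_mild_severe"),
    moderate_mild   = param_value(params, "tp_moderate_mild"),
    moderate_severe = param_value(params, "tp_moderate_severe"),
    severe_mild     = param_value(params, "tp_severe_mild"),
    severe_moderate = param_value(params, "tp_severe_moderate")
  )
}

#' Per-state annual utilities
#' @param params A `tdas_params` object.
#' @return Utility vector over the five model states (dead = 0).
#' @export
utility_set <- function(params) {
  c(non_asd  = params$flags$u_non_asd,
    mild     = param_value(params, "u_mild"),
    moderate = param_value(params, "u_moderate"),
    severe   = param_value(params, "u_severe"),
    dead     = 0)
}

dx_cost_inputs <- function(params) {
  list(
    tdas_training    = param_value(params, "c_tdas_training"),
    tdas_instruments = param_value(params, "c_tdas_instruments"),
    tdas_maintenance = param_value(params, "c_tdas_maintenance"),
    cloud_service    = param_value(params, "c_cloud_service"),
    labor_tdas       = param_value(params, "c_labor_tdas"),
    labor_clin       = param_value(params, "c_labor_clin"),
    diagnoses_per_week = param_value(params, "n_diagnoses_per_week"),
    amortization_diagnoses =
      params$flags$amortization_diagnoses_per_provider_year
  )
}

#' Willingness-to-pay threshold in USD/QALY
#' @param params A `tdas_params` object.
#' @return The configured THB threshold converted at the configured
#'   exchange rate, unless an explicit USD override is set.
#' @export
wtp_usd <- function(params) {
  params$econ$wtp_usd_override %||%
    (params$econ$wtp_thb / params$econ$exchange_rate)
}
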