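test_that("bundled configuration carries the published inputs verbatim", {
  p <- base_params()
  s <- p$specs
  get <- function(nm) s[match(nm, s$name), ]

  r <- get("p_test_positive")
  expect_equal(r$mean, 0.8990)
  expect_equal(r$se, 0.0339)
  expect_equal(r$family, "beta")

  r <- get("rr_death_asd")
  expect_equal(r$mean, 2.370)
  expect_equal(r$se, 0.0942)
  expect_equal(r$family, "lognormal")

  r <- get("c_tdas_training")
  expect_equal(r$mean, 151)
  expect_true(is.na(r$se))
  expect_true(r$cv20)

  expect_equal(get("tp_mild_severe")$family, "fixed")
  expect_equal(get("u_severe")$mean, 0.7930)
  expect_equal(get("c_outpatient_moderate")$mean, 133)
  expect_equal(unname(severity_mix(p, "clindx", scenario = TRUE)),
               c(0.1139, 0.4557, 0.4304), tolerance = 1e-12)
  expect_equal(length(validate_params(p)), 0)
})

test_that("every model input maps to exactly one named parameter", {
  s <- base_params()$specs
  expected <- c(
    "p_test_positive", "p_true_positive", "p_false_positive",
    "p_delayed_tdas", "p_mild_tdas", "p_moderate_tdas", "p_severe_tdas",
    "p_diagnosed_clin", "p_delayed_clin", "p_mild_clin", "p_moderate_clin",
    "p_severe_clin",
    "tp_mild_moderate", "tp_mild_severe", "tp_moderate_mild",
    "tp_moderate_severe", "tp_severe_mild", "tp_severe_moderate",
    "rr_death_asd",
    "u_mild", "u_moderate", "u_severe",
    "c_inpatient_mild", "c_inpatient_moderate", "c_inpatient_severe",
    "p_admission", "p_admitted_mild", "p_admitted_moderate",
    "p_admitted_severe",
    "c_outpatient_mild", "c_outpatient_moderate", "c_outpatient_severe",
    "c_instruments_mild", "c_instruments_moderate", "c_instruments_severe",
    "p_instruments_mild", "p_instruments_moderate", "p_instruments_severe",
    "c_activities_mild", "c_activities_moderate", "c_activities_severe",
    "p_activities_mild", "p_activities_moderate", "p_activities_severe",
    "c_travel_outpatient", "c_food_outpatient", "c_accommodation_outpatient",
    "p_accommodation_outpatient",
    "n_visits_mild", "n_visits_moderate", "n_visits_severe",
    "c_caregiver_outpatient",
    "c_travel_admission_patient", "c_food_admission_patient",
    "c_accommodation_admission_patient", "p_accommodation_admission",
    "c_travel_admission_caregiver", "c_food_admission_caregiver",
    "c_accommodation_admission_caregiver", "c_caregiver_admission",
    "n_admissions_per_year",
    "c_hired_caregiver", "p_hired_caregiver", "c_lost_income",
    "p_quit_mild", "p_quit_moderate", "p_quit_severe",
    "c_tdas_training", "c_tdas_instruments", "c_tdas_maintenance",
    "c_cloud_service", "c_labor_tdas", "c_labor_clin",
    "n_diagnoses_per_week",
    "p_mild_clin_scenario", "p_moderate_clin_scenario",
    "p_severe_clin_scenario"
  )
  expect_setequal(s$name, expected)
  expect_equal(anyDuplicated(s$name), 0)
  expect_gte(nrow(s), 60)
})

test_that("configurations missing a required block or key are rejected", {
  cfg <- yaml::read_yaml(tdas_default_config())
  broken <- cfg
  broken$parameters$utilities <- NULL
  expect_error(load_params(broken), "utilities")

  broken <- cfg
  broken$parameters$transitions$rr_death_asd <- NULL
  expect_error(load_params(broken), "rr_death_asd")
})

test_that("validation reports violations as data and names the culprit", {
  p <- base_params()
  p$specs$mean[p$specs$name %in%
                 c("p_mild_clin", "p_moderate_clin", "p_severe_clin")] <- 0.5
  issues <- validate_params(p)
  expect_true(any(grepl("mix_clin.*1\\.5", issues)))

  p <- base_params()
  p$life_table$qx[p$life_table$age == 40] <- 1.2
  issues <- validate_params(p)
  expect_true(any(grepl("q\\(40\\)", issues)))

  p <- base_params()
  p$specs$mean[p$specs$name == "tp_moderate_mild"] <- 0.99
  issues <- validate_params(p)
  expect_true(any(grepl("moderate", issues)))
})

test_that("one-way bounds are the 95% CI, or +/-20% without an SE, clamped", {
  expect_equal(unname(owsa_bounds(0.8990, 0.0339, "beta")),
               c(0.832556, 0.965444), tolerance = 1e-12)
  expect_equal(unname(owsa_bounds(151, NA, "gamma")),
               c(120.8, 181.2), tolerance = 1e-12)
  b <- owsa_bounds(0.9930, 0.02, "beta")
  expect_equal(unname(b[["high"]]), 1.0)
  expect_error(owsa_bounds(1, 0, "fixed"), "fixed")

  # symmetry about the mean before clamping
  set.seed(7)
  for (i in 1:20) {
    m <- runif(1, 0.2, 0.8); se <- runif(1, 0.001, 0.05)
    b <- owsa_bounds(m, se, "beta")
    expect_equal(unname(b[["high"]] - m), unname(m - b[["low"]]),
                 tolerance = 1e-12)
  }
})

test_that("writing and re-loading a configuration round-trips all inputs", {
  p <- base_params()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(p, f)
  p2 <- load_params(f, life_table = p$life_table)
  expect_identical(p$specs$mean, p2$specs$mean)
  expect_identical(p$specs$se, p2$specs$se)
  expect_identical(p$specs$family, p2$specs$family)
  expect_equal(p$econ, p2$econ)
})
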