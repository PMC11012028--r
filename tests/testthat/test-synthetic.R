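test_that("synthetic Gompertz life tables follow the stated hazard", {
  lt <- make_life_table(c = 1e-4, gamma = 0.09, max_age = 100)
  expect_equal(lt$qx[lt$age == 0], 1e-4)
  expect_equal(lt$qx[lt$age == 80], 0.1339430764, tolerance = 1e-9)
  expect_equal(lt$qx[lt$age == 100], 1)
  expect_true(all(diff(lt$qx) >= 0))
  expect_true(all(lt$qx >= 0 & lt$qx <= 1))

  flat <- make_life_table(c = 0.02, gamma = 0, max_age = 50)
  expect_true(all(flat$qx[-nrow(flat)] == 0.02))
  expect_error(make_life_table(c = 0), "positive")

  # the bundled table is a valid, monotone-by-old-age table covering 0..100
  blt <- default_life_table()
  expect_identical(blt$age, 0:100)
  expect_true(all(blt$qx >= 0 & blt$qx <= 1))
  expect_equal(blt$qx[101], 1)
  old <- blt$qx[blt$age >= 30]
  expect_true(all(diff(old) > 0))
})

test_that("chart-review simulation moves patients at the stated annual risks", {
  zero <- list(mild_moderate = 0, mild_severe = 0, moderate_mild = 0,
               moderate_severe = 0, severe_mild = 0, severe_moderate = 0)
  mix <- c(mild = 0.2, moderate = 0.5, severe = 0.3)
  rec <- simulate_chart_review(zero, mix, n = 50, years = 4, seed = 3)
  expect_equal(nrow(rec), 50 * 5)
  first <- rec$state[rec$year == 0]
  for (y in 1:4) expect_identical(rec$state[rec$year == y], first)

  expect_identical(simulate_chart_review(zero, mix, n = 20, years = 3,
                                         seed = 9),
                   simulate_chart_review(zero, mix, n = 20, years = 3,
                                         seed = 9))

  # empirical annual event fraction near the true rate (binomial error)
  rates <- zero
  rates$mild_moderate <- 0.062
  rec <- simulate_chart_review(rates, c(mild = 1, moderate = 0, severe = 0),
                               n = 1000, years = 5, seed = 17)
  est <- estimate_transition_rates(rec)
  row <- est[est$from == "mild" & est$to == "moderate", ]
  expect_gt(row$person_years, 3000)
  se <- sqrt(0.062 * 0.938 / row$person_years)
  expect_lt(abs(row$estimate - 0.062), 3 * se)
})

test_that("annual-risk estimation recovers rates and flags empty origins", {
  zero <- list(mild_moderate = 0, mild_severe = 0, moderate_mild = 0,
               moderate_severe = 0, severe_mild = 0, severe_moderate = 0)
  rec <- simulate_chart_review(zero, c(mild = 1, moderate = 1, severe = 1),
                               n = 30, years = 3, seed = 4)
  est <- estimate_transition_rates(rec)
  expect_true(all(est$estimate == 0))

  # one patient, one observed mild -> moderate move
  rec1 <- data.frame(patient = c(1, 1), year = c(0, 1),
                     state = c("mild", "moderate"))
  est1 <- estimate_transition_rates(rec1)
  expect_equal(est1$estimate[est1$from == "mild" & est1$to == "moderate"], 1)
  # states never at risk yield NA, flagged rather than zero
  expect_true(all(is.na(est1$estimate[est1$from == "severe"])))

  # recovery: estimates from a large synthetic review fall inside the
  # binomial 95% CI of the truth for at least 5 of the 6 rates
  p <- base_params()
  truth <- transition_rates(p)
  rec <- simulate_chart_review(truth, severity_mix(p, "tdas"),
                               n = 2000, years = 10, seed = 21)
  est <- estimate_transition_rates(rec)
  pairs <- list(c("mild", "moderate"), c("mild", "severe"),
                c("moderate", "mild"), c("moderate", "severe"),
                c("severe", "mild"), c("severe", "moderate"))
  truth_vals <- c(truth$mild_moderate, truth$mild_severe,
                  truth$moderate_mild, truth$moderate_severe,
                  truth$severe_mild, truth$severe_moderate)
  inside <- vapply(seq_along(pairs), function(i) {
    row <- est[est$from == pairs[[i]][1] & est$to == pairs[[i]][2], ]
    half <- 1.96 * sqrt(truth_vals[i] * (1 - truth_vals[i]) /
                          row$person_years)
    abs(row$estimate - truth_vals[i]) <= half + 1e-12
  }, logical(1))
  expect_gte(sum(inside), 5)
})

test_that("cost/utility survey simulation matches the published moments", {
  costs <- data.frame(name = c("outpatient_mild", "inpatient_mild"),
                      mean = c(66, 387), se = c(11, 88))
  utils_df <- data.frame(name = c("u_mild", "u_severe"),
                         mean = c(0.8659, 0.7930), se = c(0.0085, 0.0177))
  sv <- simulate_cost_survey(costs, utils_df, n = 10000, seed = 2)
  expect_equal(nrow(sv$records), 10000)
  m <- sv$moments
  expect_lt(abs(m$sample_mean[m$name == "outpatient_mild"] - 66),
            3 * 11 / sqrt(10000))
  expect_true(all(sv$records$u_mild >= 0 & sv$records$u_mild <= 1))
  expect_true(all(sv$records$outpatient_mild >= 0))

  # degenerate dispersion reproduces the mean exactly
  sv0 <- simulate_cost_survey(data.frame(name = "c", mean = 10, se = 0),
                              data.frame(name = "u", mean = 0.8, se = 0),
                              n = 5, seed = 1)
  expect_equal(sv0$records$c, rep(10, 5))
  expect_equal(sv0$records$u, rep(0.8, 5))
})

test_that("parameters re-estimated from synthetic records close the loop", {
  p <- base_params()
  truth <- transition_rates(p)
  rec <- simulate_chart_review(truth, severity_mix(p, "tdas"),
                               n = 2000, years = 10, seed = 33)
  est <- tdascea:::rates_from_estimates(estimate_transition_rates(rec))

  p_est <- p
  nm_map <- c(tp_mild_moderate = "mild_moderate",
              tp_mild_severe = "mild_severe",
              tp_moderate_mild = "moderate_mild",
              tp_moderate_severe = "moderate_severe",
              tp_severe_mild = "severe_mild",
              tp_severe_moderate = "severe_moderate")
  for (nm in names(nm_map)) {
    p_est$specs$mean[match(nm, p_est$specs$name)] <- est[[nm_map[[nm]]]]
  }
  icer_true <- run_base_case(p)$icer_disc$icer
  icer_est <- run_base_case(p_est)$icer_disc$icer
  expect_lt(abs(icer_est - icer_true) / icer_true, 0.15)
})
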