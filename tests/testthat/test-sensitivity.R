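test_that("moment fits reproduce published means and standard errors", {
  f <- fit_moment_distribution(0.8990, 0.0339, "beta")
  expect_equal(f$shape1, 70.13092578, tolerance = 1e-8)
  expect_equal(f$shape2, 7.879002785, tolerance = 1e-8)

  f <- fit_moment_distribution(66, 11, "gamma")
  expect_equal(f$shape, 36)
  expect_equal(f$scale, 121 / 66, tolerance = 1e-12)

  f <- fit_moment_distribution(2.37, 0.0942, "lognormal")
  expect_equal(f$meanlog, 0.862100673, tolerance = 1e-8)
  expect_equal(f$sdlog, 0.03973115074, tolerance = 1e-8)

  f <- fit_dirichlet(c(0.1111, 0.5069, 0.3819), c(0.0786, 0.0585, 0.0655))
  expect_equal(f$n_eff, 15.98673868, tolerance = 1e-7)
  expect_equal(unname(f$alpha), c(1.776304298, 8.104488286, 6.105946097),
               tolerance = 1e-7)

  expect_error(fit_moment_distribution(0.5, 0.6, "beta"), "infeasible")

  # every non-fixed input round-trips its first two moments
  p <- base_params()
  s <- p$specs
  for (i in seq_len(nrow(s))) {
    if (s$family[i] %in% c("fixed", "dirichlet")) next
    se <- if (is.na(s$se[i])) 0.20 * s$mean[i] else s$se[i]
    mom <- tdascea:::distribution_moments(
      fit_moment_distribution(s$mean[i], s$se[i], s$family[i]))
    expect_equal(mom$mean, s$mean[i], tolerance = 1e-6, label = s$name[i])
    expect_equal(mom$se, se, tolerance = 1e-6,
                 label = paste(s$name[i], "se"))
  }
  fits <- tdascea:::fit_all_distributions(p)
  for (g in names(fits$groups)) {
    mom <- tdascea:::distribution_moments(fits$groups[[g]])
    members <- fits$groups[[g]]$members
    target <- s$mean[match(members, s$name)]
    expect_equal(unname(mom$mean), unname(target / sum(target)),
                 tolerance = 1e-6, label = g)
  }
})

test_that("parameter sampling is seeded, joint, and degenerates when fixed", {
  p <- base_params()
  fits <- tdascea:::fit_all_distributions(p)

  set.seed(99); d1 <- sample_params(p, fits)
  set.seed(99); d2 <- sample_params(p, fits)
  expect_identical(d1$specs$mean, d2$specs$mean)

  # Dirichlet triples sum to one exactly; fixed inputs never move
  set.seed(5)
  for (i in 1:20) {
    d <- sample_params(p, fits)
    s <- d$specs
    expect_equal(sum(s$mean[s$group %in% "mix_tdas"]), 1, tolerance = 1e-12)
    expect_equal(sum(s$mean[s$group %in% "mix_clin"]), 1, tolerance = 1e-12)
    fixed <- p$specs$family == "fixed"
    expect_identical(s$mean[fixed], p$specs$mean[fixed])
  }

  expect_identical(sample_params(all_fixed_params(p))$specs$mean,
                   p$specs$mean)

  # sample means recover the input mean within Monte-Carlo error
  set.seed(12)
  n <- 2000
  draws <- vapply(seq_len(n), function(i) {
    param_value(sample_params(p, fits), "p_test_positive")
  }, numeric(1))
  expect_lt(abs(mean(draws) - 0.8990), 3 * 0.0339 / sqrt(n))
})

test_that("probabilistic analysis is reproducible and collapses when fixed", {
  p <- base_params()
  psa1 <- run_psa(p, n = 20, seed = 123)
  psa2 <- run_psa(p, n = 20, seed = 123)
  expect_identical(as.data.frame(psa1), as.data.frame(psa2))
  expect_equal(nrow(psa1), 20)

  pf <- all_fixed_params(p)
  psa <- run_psa(pf, n = 5, seed = 1)
  base <- tdascea:::model_deltas(p)
  expect_equal(psa$delta_cost, rep(base[["delta_cost"]], 5),
               tolerance = 1e-12)
  expect_equal(psa$delta_qaly, rep(base[["delta_qaly"]], 5),
               tolerance = 1e-12)

  # the fast dual-strategy runner agrees with the plain per-strategy path
  bc <- run_base_case(p)
  expect_equal(base[["delta_cost"]], bc$icer_disc$delta_cost,
               tolerance = 1e-9)
  expect_equal(base[["delta_qaly"]], bc$icer_disc$delta_qaly,
               tolerance = 1e-9)
})

test_that("quadrant shares and the CEAC classify draws consistently", {
  toy <- structure(
    data.frame(draw = 1:3, delta_cost = c(100, 100, -50),
               delta_qaly = c(1, -1, 1)),
    class = c("psa_result", "data.frame"))
  expect_equal(quadrant_shares(toy),
               c(NE = 1/3, SE = 1/3, NW = 1/3, SW = 0))

  cc <- ceac(toy, wtp_grid = c(0, 75, 1e9))
  expect_equal(cc$prob_ce[cc$wtp == 0], 1/3)        # fraction with dC < 0
  expect_equal(cc$prob_ce[cc$wtp == 75], 1/3)       # only (-50, 1) has NMB > 0
  expect_equal(cc$prob_ce[cc$wtp == 1e9], 2/3)      # fraction with dE > 0
  expect_error(ceac(toy, wtp_grid = c(5, 1)), "unsorted|strictly")

  # symmetric cloud about the origin: every quadrant near one quarter
  set.seed(8)
  n <- 4000
  cloud <- structure(
    data.frame(draw = seq_len(n), delta_cost = rnorm(n),
               delta_qaly = rnorm(n)),
    class = c("psa_result", "data.frame"))
  expect_equal(unname(quadrant_shares(cloud)), rep(0.25, 4),
               tolerance = 0.05)
  expect_equal(sum(quadrant_shares(cloud)), 1, tolerance = 1e-12)

  # CEAC at a threshold equals the positive-NMB share of the same draws
  p <- base_params()
  psa <- run_psa(p, n = 60, seed = 7)
  w <- wtp_usd(p)
  expect_equal(ceac(psa, wtp_grid = c(w))$prob_ce,
               mean(nmb(psa$delta_cost, psa$delta_qaly, w) > 0))
})

test_that("tornado entries rerun the model at the one-way bounds, sorted", {
  p <- base_params()
  tor <- owsa_tornado(p, parameters = c(
    "c_tdas_training", "u_severe", "p_mild_tdas", "tp_moderate_mild",
    "p_diagnosed_clin"))
  expect_equal(nrow(tor), 5)
  finite <- is.finite(tor$width)
  expect_true(!is.unsorted(rev(tor$width)))
  expect_true(all(tor$width >= 0))

  # additive-cost oracle: training cost enters only the intervention arm's
  # diagnostic cost, amortized over 104 diagnoses, so the ICER excursion is
  # exactly (0.4 * 151 / 104) / delta_qaly
  base <- run_base_case(p)
  row <- tor[tor$parameter == "c_tdas_training", ]
  expected <- (0.4 * 151 / 104) / base$icer_disc$delta_qaly
  expect_equal(row$icer_high - row$icer_low, expected, tolerance = 1e-9)

  # a severity-mix component is varied with complementary renormalization:
  # the other two components keep their ratio and the mix still sums to 1
  p2 <- tdascea:::set_param(p, "p_mild_tdas", 0.25)
  mix2 <- severity_mix(p2, "tdas")
  expect_equal(unname(mix2[["mild"]]), 0.25, tolerance = 1e-12)
  expect_equal(mix2[["moderate"]] / mix2[["severe"]],
               0.5069 / 0.3819, tolerance = 1e-9)
  expect_equal(sum(mix2), 1, tolerance = 1e-12)

  # fixed parameters are skipped with a log entry
  tor2 <- owsa_tornado(p, parameters = c("u_mild", "n_diagnoses_per_week"))
  expect_equal(nrow(tor2), 1)
  expect_equal(attr(tor2, "skipped"), "n_diagnoses_per_week")
})
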