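#' Fit a sampling distribution to a published mean and standard error
#'
#' Method-of-moments fits for the distribution families used in the
#' probabilistic analysis: Beta for probabilities and utilities, Gamma for
#' costs and counts, Log-normal for the relative risk (matching the
#' natural-scale mean and SE by default), and pass-through for fixed
#' inputs. Inputs published with only a +/-20% variation get a dispersion
#' of `default_cv * mean`.
#'
#' @param mean Published mean.
#' @param se Published standard error (`NA` for +/-20% inputs).
#' @param family `"beta"`, `"gamma"`, `"lognormal"` or `"fixed"`.
#' @param default_cv Coefficient of variation applied when `se` is `NA`.
#' @param rr_se_scale For the log-normal: `"natural"` interprets `se` on
#'   the natural scale (moment matching); `"log"` uses it directly as the
#'   log-scale SD.
#' @return A `fitted_distribution` list with the family and its natural
#'   parameters.
#' @export
fit_moment_distribution <- function(mean, se = NA, family,
                                    default_cv = 0.20,
                                    rr_se_scale = "natural") {
  if (family == "fixed") {
    return(structure(list(family = "fixed", value = mean),
                     class = "fitted_distribution"))
  }
  if (is.na(se)) se <- default_cv * mean
  if (se <= 0) stop("non-fixed distribution needs a positive SE")
  fit <- switch(family,
    beta = {
      if (mean <= 0 || mean >= 1) {
        stop(sprintf("beta mean %g not inside (0,1)", mean))
      }
      if (se^2 >= mean * (1 - mean)) {
        stop(sprintf("infeasible moments for beta: se^2 = %g >= mean(1-mean) = %g",
                     se^2, mean * (1 - mean)))
      }
      nu <- mean * (1 - mean) / se^2 - 1
      list(family = "beta", shape1 = mean * nu, shape2 = (1 - mean) * nu)
    },
    gamma = {
      if (mean <= 0) stop("gamma mean must be positive")
      list(family = "gamma", shape = (mean / se)^2, scale = se^2 / mean)
    },
    lognormal = {
      if (mean <= 0) stop("lognormal mean must be positive")
      sdlog <- if (identical(rr_se_scale, "log")) se
               else sqrt(log(1 + (se / mean)^2))
      list(family = "lognormal", meanlog = log(mean) - sdlog^2 / 2,
           sdlog = sdlog)
    },
    stop(sprintf("cannot fit family '%s'", family))
  )
  structure(fit, class = "fitted_distribution")
}

#' Fit a Dirichlet distribution to a severity mix
#'
#' Components share one effective sample size: by default the smallest
#' per-component `m(1-m)/se^2` (the most conservative choice, giving the
#' widest spread consistent with every published SE); alternatively an
#' explicit count (e.g. the chart-review sample size).
#'
#' @param means Component means (normalized internally).
#' @param ses Component standard errors.
#' @param method `"min"` or `"counts"`.
#' @param count Effective sample size when `method = "counts"`.
#' @return A `fitted_distribution` with the alpha vector.
#' @export
fit_dirichlet <- function(means, ses, method = c("min", "counts"),
                          count = NULL) {
  method <- match.arg(method)
  m <- means / sum(means)
  n_eff <- if (method == "counts") {
    stopifnot(!is.null(count), count > 0)
    count
  } else {
    min(m * (1 - m) / ses^2)
  }
  structure(list(family = "dirichlet", alpha = m * n_eff, n_eff = n_eff),
            class = "fitted_distribution")
}

# Implied first two moments of a fitted distribution (for round-trip checks).
distribution_moments <- function(fit) {
  switch(fit$family,
    beta = {
      a <- fit$shape1; b <- fit$shape2
      list(mean = a / (a + b),
           se = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
    },
    gamma = list(mean = fit$shape * fit$scale,
                 se = sqrt(fit$shape) * fit$scale),
    lognormal = {
      m <- exp(fit$meanlog + fit$sdlog^2 / 2)
      list(mean = m, se = m * sqrt(exp(fit$sdlog^2) - 1))
    },
    dirichlet = {
      a0 <- sum(fit$alpha)
      m <- fit$alpha / a0
      list(mean = m, se = sqrt(m * (1 - m) / (a0 + 1)))
    },
    fixed = list(mean = fit$value, se = 0)
  )
}

# Fit every non-fixed input once; returns scalar fits keyed by name and
# joint Dirichlet fits keyed by group.
fit_all_distributions <- function(params) {
  s <- params$specs
  flags <- params$flags
  scalars <- list()
  groups <- list()
  for (g in unique(stats::na.omit(s$group))) {
    rows <- s[!is.na(s$group) & s$group == g, ]
    if (any(rows$family == "dirichlet")) {
      count <- NULL
      if (identical(flags$dirichlet_neff, "counts")) {
        count <- if (g == "mix_tdas") flags$dirichlet_counts[["tdas"]]
                 else flags$dirichlet_counts[["clin"]]
      }
      fit <- fit_dirichlet(rows$mean, rows$se,
                           method = if (is.null(count)) "min" else "counts",
                           count = count)
      fit$members <- rows$name
      groups[[g]] <- fit
    }
  }
  for (i in seq_len(nrow(s))) {
    if (s$family[i] %in% c("dirichlet", "fixed")) next
    scalars[[s$name[i]]] <- fit_moment_distribution(
      s$mean[i], s$se[i], s$family[i],
      default_cv = params$econ$default_cv,
      rr_se_scale = flags$rr_se_scale
    )
  }
  list(scalars = scalars, groups = groups)
}

#' Draw one joint parameter set from the uncertainty distributions
#'
#' Every non-fixed input is replaced by a random draw from its fitted
#' distribution; Dirichlet severity mixes are drawn jointly, so sampled
#' triples sum to one exactly; fixed inputs pass through unchanged. The
#' draw consumes the current RNG state, so `set.seed()` before the call
#' makes it reproducible.
#'
#' @param params A `tdas_params` object.
#' @param fits Pre-computed fits from `fit_all_distributions` (computed on
#'   the fly when omitted).
#' @return A new `tdas_params` with sampled means.
#' @export
sample_params <- function(params, fits = NULL) {
  if (is.null(fits)) fits <- fit_all_distributions(params)
  s <- params$specs
  for (g in names(fits$groups)) {
    fit <- fits$groups[[g]]
    gam <- stats::rgamma(length(fit$alpha), shape = fit$alpha)
    draw <- gam / sum(gam)
    s$mean[match(fit$members, s$name)] <- draw
  }
  for (nm in names(fits$scalars)) {
    fit <- fits$scalars[[nm]]
    s$mean[match(nm, s$name)] <- switch(fit$family,
      beta = stats::rbeta(1, fit$shape1, fit$shape2),
      gamma = stats::rgamma(1, shape = fit$shape, scale = fit$scale),
      lognormal = stats::rlnorm(1, fit$meanlog, fit$sdlog)
    )
  }
  params$specs <- s
  params
}

# A sampled set is usable iff severity transitions out of each state
# still form a sub-probability row (betas and gammas are in-support by
# construction).
sampled_set_valid <- function(params) {
  tr <- transition_rates(params)
  tr$mild_moderate + tr$mild_severe <= 1 &&
    tr$moderate_mild + tr$moderate_severe <= 1 &&
    tr$severe_mild + tr$severe_moderate <= 1
}

# Evaluate both strategies on one parameter set sharing the per-age
# transition matrices; returns discounted/undiscounted (delta and totals).
run_both_strategies <- function(params, scenario = FALSE) {
  tdas <- run_strategy(params, "tdas", scenario = scenario)
  clin <- run_strategy(params, "clindx", scenario = scenario)
  list(tdas = tdas, clindx = clin)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: for each iteration a
#' joint parameter set is drawn from the fitted distributions and the full
#' model (decision tree, Markov cohort, accrual) is rerun for both
#' strategies; the discounted incremental cost and QALYs are recorded. A
#' draw whose severity transitions are infeasible (row sum above one) is
#' re-drawn, up to 100 attempts, with the retry count logged.
#'
#' @param params A `tdas_params` object.
#' @param n Number of iterations (the configured default is 10,000).
#' @param seed Base seed; the analysis is reproducible given `seed`.
#' @param scenario Use the scenario severity mix for clinical diagnosis?
#' @param runner Model runner mapping a sampled parameter set to
#'   `c(delta_cost, delta_qaly)`; the default reruns both strategies and
#'   differences the discounted totals.
#' @return A `psa_result` data frame with columns `draw`, `delta_cost`,
#'   `delta_qaly` and attributes `seed`, `n`, `retries`.
#' @export
run_psa <- function(params, n = params$econ$psa_iterations, seed = 1,
                    scenario = FALSE, runner = NULL) {
  stopifnot(n >= 1)
  if (is.null(runner)) {
    runner <- function(p) model_deltas(p, scenario = scenario)
  }
  fits <- fit_all_distributions(params)
  set.seed(seed)
  out <- matrix(NA_real_, n, 2)
  retries <- 0L
  for (i in seq_len(n)) {
    for (attempt in seq_len(100)) {
      drawn <- sample_params(params, fits)
      if (sampled_set_valid(drawn)) break
      retries <- retries + 1L
      if (attempt == 100) stop("draw ", i, ": 100 invalid re-draws")
    }
    out[i, ] <- runner(drawn)
  }
  res <- data.frame(draw = seq_len(n), delta_cost = out[, 1],
                    delta_qaly = out[, 2])
  structure(res, seed = seed, n = n, retries = retries,
            class = c("psa_result", "data.frame"))
}

#' Cost-effectiveness plane quadrant shares
#'
#' Fractions of probabilistic draws falling in each quadrant of the
#' cost-effectiveness plane: NE (more effective, more costly), SE (more
#' effective, cheaper — dominant), NW (less effective, more costly —
#' dominated), SW (less effective, cheaper).
#'
#' @param psa A `psa_result`.
#' @return Named probability vector `c(NE, SE, NW, SW)` summing to one.
#' @export
quadrant_shares <- function(psa) {
  de <- psa$delta_qaly; dc <- psa$delta_cost
  c(NE = mean(de > 0 & dc > 0),
    SE = mean(de > 0 & dc <= 0),
    NW = mean(de <= 0 & dc > 0),
    SW = mean(de <= 0 & dc <= 0))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of probabilistic draws
#' with positive net monetary benefit (`wtp * dQALY - dCost > 0`), i.e.
#' the probability that the intervention is cost-effective at that
#' threshold.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Increasing grid of thresholds (USD/QALY). The default
#'   spans 0 to 10,000 in steps of 100, covering both the base-case ICER
#'   and the policy threshold.
#' @return A `ceac_curve` data frame with columns `wtp`, `prob_ce`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 10000, by = 100)) {
  stopifnot(length(wtp_grid) >= 1, !is.unsorted(wtp_grid, strictly = TRUE))
  prob <- vapply(wtp_grid,
                 function(w) mean(w * psa$delta_qaly - psa$delta_cost > 0),
                 numeric(1))
  structure(data.frame(wtp = wtp_grid, prob_ce = prob),
            class = c("ceac_curve", "data.frame"))
}

# Return params with one input set to `value`; a Dirichlet severity-mix
# component is varied with complementary renormalization of the other two
# components (their ratio preserved).
set_param <- function(params, name, value) {
  s <- params$specs
  i <- match(name, s$name)
  if (is.na(i)) stop(sprintf("unknown parameter '%s'", name))
  g <- s$group[i]
  if (!is.na(g) && s$family[i] == "dirichlet") {
    members <- which(!is.na(s$group) & s$group == g)
    others <- setdiff(members, i)
    tot <- sum(s$mean[members])
    s$mean[i] <- value * tot
    rest <- s$mean[others]
    s$mean[others] <- rest / sum(rest) * (tot - s$mean[i])
    if (any(s$mean[members] < 0)) {
      stop(sprintf("varying '%s' to %g leaves no mass for its mix", name,
                   value))
    }
  } else {
    s$mean[i] <- value
  }
  params$specs <- s
  params
}

#' One-way sensitivity analysis (tornado)
#'
#' Reruns the deterministic model with each input at the low and high end
#' of its one-way range ([owsa_bounds()]: 95% CI when an SE is published,
#' +/-20% otherwise), holding everything else at base case, and records
#' the discounted ICER excursion. Severity-mix components are varied one
#' at a time with the other two renormalized. Entries are sorted by
#' decreasing excursion width; an excursion that leaves the
#' cost-effectiveness plane quadrant (so that the ICER is undefined at one
#' end) is ranked as maximally influential.
#'
#' @param params A `tdas_params` object.
#' @param parameters Input names to vary; defaults to every non-fixed
#'   input (scenario-mix entries excluded).
#' @param scenario Use the scenario severity mix for clinical diagnosis?
#' @return A `tornado_table` data frame: one row per input with the bound
#'   values, ICERs (or dominance labels) at each bound, and the width.
#' @export
owsa_tornado <- function(params, parameters = NULL, scenario = FALSE) {
  s <- params$specs
  if (is.null(parameters)) {
    parameters <- s$name[s$family != "fixed" & s$section != "scenario"]
  }
  skipped <- character()
  rows <- list()
  for (nm in parameters) {
    i <- match(nm, s$name)
    if (is.na(i)) stop(sprintf("unknown parameter '%s'", nm))
    if (s$family[i] == "fixed") {
      skipped <- c(skipped, nm)
      next
    }
    mean_i <- s$mean[i]
    if (s$family[i] == "dirichlet") {
      tot <- sum(s$mean[!is.na(s$group) & s$group == s$group[i]])
      mean_i <- mean_i / tot
    }
    b <- owsa_bounds(mean_i, s$se[i], s$family[i])
    ic <- lapply(b, function(v) {
      run_base_case(set_param(params, nm, v), scenario = scenario)$icer_disc
    })
    both_defined <- ic[[1]]$label == "ICER" && ic[[2]]$label == "ICER"
    width <- if (both_defined) abs(ic[[2]]$icer - ic[[1]]$icer) else Inf
    rows[[nm]] <- data.frame(
      parameter = nm, low = b[["low"]], high = b[["high"]],
      icer_low = ic[[1]]$icer, icer_high = ic[[2]]$icer,
      label_low = ic[[1]]$label, label_high = ic[[2]]$label,
      width = width
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$width, out$parameter), ]
  rownames(out) <- NULL
  if (length(skipped)) attr(out, "skipped") <- skipped
  class(out) <- c("tornado_table", "data.frame")
  out
}
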