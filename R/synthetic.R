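#' Synthetic Gompertz life table
#'
#' Builds a period life table with exponentially increasing mortality,
#' `q(a) = min(1, c * exp(gamma * a))`, closed at the maximum age
#' (`q(max_age) = 1`). Useful for exercising the cohort model when no
#' national table is at hand; the bundled Thai-like table
#' ([default_life_table()]) additionally carries an infant-mortality
#' component and a Makeham background term.
#'
#' @param c Mortality level at age 0 (must be positive).
#' @param gamma Exponential slope per year of age (non-negative).
#' @param max_age Last age in the table.
#' @return Data frame with columns `age`, `qx`.
#' @export
make_life_table <- function(c = 1e-4, gamma = 0.09, max_age = 100) {
  if (c <= 0) stop("mortality level 'c' must be positive")
  if (gamma < 0) stop("slope 'gamma' must be non-negative")
  age <- seq(0L, as.integer(max_age))
  qx <- pmin(1, c * exp(gamma * age))
  qx[length(qx)] <- 1
  data.frame(age = age, qx = qx)
}

#' Simulate a chart review of severity transitions
#'
#' Emulates the retrospective medical-records review behind the annual
#' severity transition probabilities: each patient starts in a severity
#' state drawn from the mix at diagnosis and moves between mild, moderate
#' and severe once per year according to the annual transition
#' probabilities. Follow-up length (the censoring year) is a parameter,
#' since the real review's follow-up structure is not published.
#'
#' @param rates Annual transition probabilities (see
#'   [transition_rates()]).
#' @param mix Severity mix at diagnosis.
#' @param n Number of patients (the study reviewed 295).
#' @param years Follow-up years per patient.
#' @param seed Random seed.
#' @return A `chart_review` data frame in long format: `patient`, `year`
#'   (0 = at diagnosis), `state`.
#' @export
simulate_chart_review <- function(rates, mix, n = 295, years = 5,
                                  seed = 1) {
  stopifnot(n >= 1, years >= 0)
  set.seed(seed)
  mix <- mix / sum(mix)
  trans <- rbind(
    mild = c(1 - rates$mild_moderate - rates$mild_severe,
             rates$mild_moderate, rates$mild_severe),
    moderate = c(rates$moderate_mild,
                 1 - rates$moderate_mild - rates$moderate_severe,
                 rates$moderate_severe),
    severe = c(rates$severe_mild, rates$severe_moderate,
               1 - rates$severe_mild - rates$severe_moderate)
  )
  colnames(trans) <- SEVERITIES
  if (any(trans < 0)) stop("transition probabilities out of a state exceed 1")

  state <- sample(SEVERITIES, n, replace = TRUE, prob = mix)
  out <- vector("list", years + 1)
  out[[1]] <- data.frame(patient = seq_len(n), year = 0L, state = state)
  if (years > 0) {
    for (y in seq_len(years)) {
      nxt <- vapply(state, function(s) {
        sample(SEVERITIES, 1, prob = trans[s, ])
      }, character(1))
      state <- unname(nxt)
      out[[y + 1]] <- data.frame(patient = seq_len(n), year = y,
                                 state = state)
    }
  }
  rec <- do.call(rbind, out)
  rec <- rec[order(rec$patient, rec$year), ]
  rownames(rec) <- NULL
  class(rec) <- c("chart_review", "data.frame")
  rec
}

#' Estimate annual transition probabilities from chart-review records
#'
#' Discrete annual-risk estimation: for each origin state, the estimated
#' probability of moving to each destination is the number of observed
#' annual moves divided by the person-years at risk in the origin state,
#' with binomial standard errors. Origin states never observed at risk
#' yield `NA` estimates, flagged in the result.
#'
#' @param records A `chart_review` data frame (long format).
#' @return Data frame with one row per ordered severity pair: `from`,
#'   `to`, `events`, `person_years`, `estimate`, `se`.
#' @export
estimate_transition_rates <- function(records) {
  records <- records[order(records$patient, records$year), ]
  by_patient <- split(records$state, records$patient)
  from <- unlist(lapply(by_patient, function(s) s[-length(s)]),
                 use.names = FALSE)
  to <- unlist(lapply(by_patient, function(s) s[-1]), use.names = FALSE)
  pairs <- expand.grid(from = SEVERITIES, to = SEVERITIES,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    at_risk <- sum(from == pairs$from[i])
    ev <- sum(from == pairs$from[i] & to == pairs$to[i])
    p <- if (at_risk > 0) ev / at_risk else NA_real_
    se <- if (at_risk > 0) sqrt(p * (1 - p) / at_risk) else NA_real_
    data.frame(from = pairs$from[i], to = pairs$to[i], events = ev,
               person_years = at_risk, estimate = p, se = se)
  }))
  rownames(out) <- NULL
  out
}

# Convert an estimate table back into the named-rate list the Markov
# module consumes (NA estimates become 0).
rates_from_estimates <- function(est) {
  get <- function(f, t) {
    v <- est$estimate[est$from == f & est$to == t]
    if (length(v) == 0 || is.na(v)) 0 else v
  }
  list(mild_moderate = get("mild", "moderate"),
       mild_severe = get("mild", "severe"),
       moderate_mild = get("moderate", "mild"),
       moderate_severe = get("moderate", "severe"),
       severe_mild = get("severe", "mild"),
       severe_moderate = get("severe", "moderate"))
}

#' Simulate a cost and utility survey
#'
#' Emulates the cross-sectional caregiver interview: per-patient itemized
#' annual costs drawn from Gamma distributions and utilities from Beta
#' distributions, each at the published mean/SE moments. Returns the
#' records together with their sample moments for parameter-recovery
#' comparisons.
#'
#' @param cost_items Data frame with columns `name`, `mean`, `se` for the
#'   Gamma-distributed cost items.
#' @param utility_items Data frame with columns `name`, `mean`, `se` for
#'   the Beta-distributed utilities.
#' @param n Number of respondents.
#' @param seed Random seed.
#' @return List with `records` (one row per respondent, one column per
#'   item) and `moments` (per-item sample mean and SE of the mean).
#' @export
simulate_cost_survey <- function(cost_items, utility_items, n = 295,
                                 seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  draw_item <- function(mean, se, family) {
    if (is.na(se) || se == 0) return(rep(mean, n))
    fit <- fit_moment_distribution(mean, se, family)
    if (family == "gamma") {
      stats::rgamma(n, shape = fit$shape, scale = fit$scale)
    } else {
      stats::rbeta(n, fit$shape1, fit$shape2)
    }
  }
  cols <- c(
    lapply(seq_len(nrow(cost_items)), function(i) {
      draw_item(cost_items$mean[i], cost_items$se[i], "gamma")
    }),
    lapply(seq_len(nrow(utility_items)), function(i) {
      draw_item(utility_items$mean[i], utility_items$se[i], "beta")
    })
  )
  names(cols) <- c(cost_items$name, utility_items$name)
  records <- data.frame(respondent = seq_len(n), cols)
  moments <- data.frame(
    name = names(cols),
    sample_mean = vapply(cols, mean, numeric(1)),
    sample_se = vapply(cols, function(x) stats::sd(x) / sqrt(n), numeric(1))
  )
  rownames(moments) <- NULL
  list(records = records, moments = moments)
}
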