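#' One-cycle transition matrix at a given age
#'
#' Composes mortality first with severity movement: from each state the
#' cohort dies with probability `min(1, q * rr_s)` (the background annual
#' death probability scaled by the state's relative risk: `rr` for the ASD
#' severity states, 1 for non-ASD), and survivors redistribute across
#' severity states according to the annual transition probabilities, with
#' the stay-probability as the complement. This composition keeps rows
#' stochastic for any `q` in `[0,1]`.
#'
#' @param rates Named list of annual severity transition probabilities,
#'   as returned by [transition_rates()].
#' @param q Annual background death probability at the current age.
#' @param rr Relative risk of death applied to the ASD severity states.
#' @return A 5x5 row-stochastic matrix over
#'   `non_asd`/`mild`/`moderate`/`severe`/`dead`.
#' @export
build_transition_matrix <- function(rates, q, rr) {
  stopifnot(q >= 0, q <= 1, rr > 0)
  sums <- c(rates$mild_moderate + rates$mild_severe,
            rates$moderate_mild + rates$moderate_severe,
            rates$severe_mild + rates$severe_moderate)
  if (any(sums > 1 + 1e-12)) {
    stop("transition probabilities out of a state sum to more than 1")
  }
  d_non <- min(1, q)
  d_asd <- min(1, q * rr)
  s <- 1 - d_asd
  m <- matrix(0, 5, 5, dimnames = list(STATES, STATES))
  m["non_asd", ] <- c(1 - d_non, 0, 0, 0, d_non)
  m["mild", ] <- c(0,
                   s * (1 - rates$mild_moderate - rates$mild_severe),
                   s * rates$mild_moderate,
                   s * rates$mild_severe,
                   d_asd)
  m["moderate", ] <- c(0,
                       s * rates$moderate_mild,
                       s * (1 - rates$moderate_mild - rates$moderate_severe),
                       s * rates$moderate_severe,
                       d_asd)
  m["severe", ] <- c(0,
                     s * rates$severe_mild,
                     s * rates$severe_moderate,
                     s * (1 - rates$severe_mild - rates$severe_moderate),
                     d_asd)
  m["dead", "dead"] <- 1
  m
}

#' Propagate the cohort through the lifetime horizon
#'
#' Runs the cohort state-transition model in one-year cycles from the
#' starting age to the closure age. Background mortality is looked up in
#' the life table at the integer part of the attained age, and the closure
#' age absorbs everyone (q = 1 at and beyond `max_age`).
#'
#' @param entry Entry distribution over the four living states (an
#'   [entry_distribution()] or a probability vector).
#' @param rates Annual severity transition probabilities.
#' @param life_table Data frame `age`/`qx`.
#' @param rr Relative risk of death in the ASD states.
#' @param start_age Age at model entry (years, may be fractional).
#' @param max_age Closure age.
#' @return A `cohort_trace`: matrix of state occupancy with one row per
#'   cycle (cycle 0 = entry) and attribute `ages` giving each cycle's
#'   attained age.
#' @export
run_cohort <- function(entry, rates, life_table, rr, start_age, max_age) {
  entry <- as.numeric(entry)
  if (length(entry) == 4) entry <- c(entry, 0)
  stopifnot(length(entry) == 5, abs(sum(entry) - 1) < 1e-9)
  n_cycles <- max_age - floor(start_age)
  if (n_cycles < 0) stop("start_age beyond max_age")
  needed <- seq(floor(start_age), max_age - 1)
  if (n_cycles > 0) {
    missing <- setdiff(needed[needed < max_age], life_table$age)
    if (length(missing)) {
      stop(sprintf("life table has no entry for age %d", min(missing)))
    }
  }
  trace <- matrix(NA_real_, n_cycles + 1, 5,
                  dimnames = list(NULL, STATES))
  ages <- start_age + seq(0, n_cycles)
  trace[1, ] <- entry
  state <- entry
  for (t in seq_len(n_cycles)) {
    q <- q_at_age(life_table, ages[t], max_age)
    m <- build_transition_matrix(rates, q, rr)
    state <- as.numeric(state %*% m)
    trace[t + 1, ] <- state
  }
  structure(trace, ages = ages, class = c("cohort_trace", class(trace)))
}

#' Accrue lifetime costs and QALYs over a cohort trace
#'
#' Rewards are accrued per model cycle from the start-of-cycle occupancy
#' (optionally the average of start and end occupancy, a half-cycle
#' correction) and discounted at `(1 + rate)^-t`, with cycle 0
#' undiscounted. The diagnostic cost and any one-time entry costs (e.g.
#' instrument acquisition) are charged at cycle 0 only.
#'
#' @param trace A `cohort_trace`.
#' @param utilities Utility per state (length 5; dead must be 0).
#' @param state_costs Annual cost per state (length 5, USD/year).
#' @param dx_cost Per-patient diagnostic cost charged at entry.
#' @param rate Annual discount rate for both costs and QALYs.
#' @param entry_costs Optional one-time per-state cost charged against
#'   the entry occupancy (length 5, USD).
#' @param half_cycle Apply a half-cycle correction to rewards?
#' @return A `strategy_outcome` list with discounted and undiscounted
#'   totals: `cost_undisc`, `cost_disc`, `qaly_undisc`, `qaly_disc`.
#' @export
accrue_outcomes <- function(trace, utilities, state_costs, dx_cost = 0,
                            rate = 0.03, entry_costs = NULL,
                            half_cycle = FALSE) {
  n_cycles <- nrow(trace) - 1
  one_time <- dx_cost +
    if (is.null(entry_costs)) 0 else sum(trace[1, ] * entry_costs)
  if (n_cycles == 0) {
    out <- list(cost_undisc = one_time, cost_disc = one_time,
                qaly_undisc = 0, qaly_disc = 0)
    class(out) <- "strategy_outcome"
    return(out)
  }
  occ <- trace[seq_len(n_cycles), , drop = FALSE]
  if (half_cycle) {
    occ <- (occ + trace[seq_len(n_cycles) + 1, , drop = FALSE]) / 2
  }
  disc <- (1 + rate)^(-(seq_len(n_cycles) - 1))
  q_per_cycle <- as.numeric(occ %*% utilities)
  c_per_cycle <- as.numeric(occ %*% state_costs)
  out <- list(
    cost_undisc = one_time + sum(c_per_cycle),
    cost_disc   = one_time + sum(c_per_cycle * disc),
    qaly_undisc = sum(q_per_cycle),
    qaly_disc   = sum(q_per_cycle * disc)
  )
  class(out) <- "strategy_outcome"
  out
}
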