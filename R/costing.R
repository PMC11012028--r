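#' Severity-specific annual admission probability
#'
#' The survey reports the overall proportion of patients admitted in a
#' year and the severity composition of the admitted, not the admission
#' probability conditional on severity. The latter follows by Bayes
#' inversion against a cohort severity mix:
#' `P(admit | s) = P(admit) * P(s | admit) / P(s)`, clamped to `[0,1]`.
#'
#' @param severity `"mild"`, `"moderate"` or `"severe"`.
#' @param p_admit_overall Overall annual admission probability.
#' @param admitted_mix Severity shares among admitted patients.
#' @param cohort_mix Severity shares in the cohort the overall admission
#'   probability refers to.
#' @return Annual admission probability for the severity level.
#' @export
severity_admission_prob <- function(severity, p_admit_overall, admitted_mix,
                                    cohort_mix) {
  severity <- match.arg(severity, SEVERITIES)
  if (cohort_mix[[severity]] <= 0) {
    stop(sprintf("cohort mix share for '%s' is zero", severity))
  }
  p <- p_admit_overall * admitted_mix[[severity]] / cohort_mix[[severity]]
  min(max(p, 0), 1)
}

#' Annual societal cost of one severity state
#'
#' Assembles the per-state annual cost from its published components:
#' outpatient and inpatient direct medical care, therapy instruments and
#' additional activities, travel/food/accommodation around outpatient
#' visits and admissions (for patient and caregiver), and caregiver costs
#' at home (hired caregiver salaries and forgone income of caregivers who
#' quit work). All amounts are USD per patient-year; components driven by
#' admissions are weighted by the severity-specific admission probability.
#'
#' @param severity `"mild"`, `"moderate"` or `"severe"`.
#' @param params A `tdas_params` object.
#' @param adm_prob Annual admission probability for this severity (see
#'   [severity_admission_prob()]).
#' @param include_instruments Count the instrument purchase in the annual
#'   total? The default model treats it as a one-time acquisition at model
#'   entry instead (see [state_cost_table()]).
#' @return A `state_cost_breakdown` list of components plus `total`.
#' @export
annual_state_cost <- function(severity, params, adm_prob,
                              include_instruments = FALSE) {
  severity <- match.arg(severity, SEVERITIES)
  pv <- function(stub) param_value(params, paste0(stub, "_", severity))
  v <- function(nm) param_value(params, nm)

  admissions <- adm_prob * v("n_admissions_per_year")
  visits <- pv("n_visits")

  outpatient_medical <- pv("c_outpatient")
  inpatient_medical <- admissions * pv("c_inpatient")
  instruments <- pv("c_instruments") * pv("p_instruments")
  activities <- pv("c_activities") * pv("p_activities")
  outpatient_nonmedical <- visits *
    (v("c_travel_outpatient") + v("c_food_outpatient") +
       v("c_accommodation_outpatient") * v("p_accommodation_outpatient") +
       v("c_caregiver_outpatient"))
  admission_nonmedical <- admissions *
    (v("c_travel_admission_patient") + v("c_food_admission_patient") +
       v("c_accommodation_admission_patient") * v("p_accommodation_admission") +
       v("c_travel_admission_caregiver") + v("c_food_admission_caregiver") +
       v("c_accommodation_admission_caregiver") * v("p_accommodation_admission") +
       v("c_caregiver_admission"))
  caregiver_home <- v("c_hired_caregiver") * v("p_hired_caregiver") +
    v("c_lost_income") * pv("p_quit")

  comp <- list(
    outpatient_medical = outpatient_medical,
    inpatient_medical = inpatient_medical,
    instruments = if (include_instruments) instruments else 0,
    activities = activities,
    outpatient_nonmedical = outpatient_nonmedical,
    admission_nonmedical = admission_nonmedical,
    caregiver_home = caregiver_home
  )
  comp$instruments_one_time <- instruments
  comp$total <- outpatient_medical + inpatient_medical + comp$instruments +
    activities + outpatient_nonmedical + admission_nonmedical + caregiver_home
  class(comp) <- "state_cost_breakdown"
  comp
}

# Cohort severity mix against which the overall admission probability is
# inverted: equal-weight average of the two chart-review mixes, unless
# overridden in flags$admission_cohort_mix.
admission_cohort_mix <- function(params) {
  override <- params$flags$admission_cohort_mix
  if (!is.null(override)) {
    mix <- as.numeric(override)
    names(mix) <- SEVERITIES
    return(mix / sum(mix))
  }
  (severity_mix(params, "tdas") + severity_mix(params, "clindx")) / 2
}

#' Per-state cost vectors for the cohort model
#'
#' @param params A `tdas_params` object.
#' @return List with `annual` (USD/year per model state), `entry`
#'   (one-time USD per state at model entry; instrument acquisition under
#'   the default `instrument_mode = "entry"`), and `breakdown` (data frame
#'   of components by severity).
#' @export
state_cost_table <- function(params) {
  admitted_mix <- c(
    mild = param_value(params, "p_admitted_mild"),
    moderate = param_value(params, "p_admitted_moderate"),
    severe = param_value(params, "p_admitted_severe")
  )
  cohort_mix <- admission_cohort_mix(params)
  p_admit <- param_value(params, "p_admission")
  annual_mode <- identical(params$flags$instrument_mode, "annual")

  per_sev <- lapply(SEVERITIES, function(s) {
    adm <- severity_admission_prob(s, p_admit, admitted_mix, cohort_mix)
    annual_state_cost(s, params, adm, include_instruments = annual_mode)
  })
  names(per_sev) <- SEVERITIES

  annual <- c(non_asd = 0,
              vapply(per_sev, function(x) x$total, numeric(1)),
              dead = 0)
  entry <- c(non_asd = 0,
             if (annual_mode) c(mild = 0, moderate = 0, severe = 0)
             else vapply(per_sev, function(x) x$instruments_one_time,
                         numeric(1)),
             dead = 0)
  names(annual) <- STATES
  names(entry) <- STATES

  breakdown <- do.call(rbind, lapply(SEVERITIES, function(s) {
    x <- per_sev[[s]]
    data.frame(severity = s,
               outpatient_medical = x$outpatient_medical,
               inpatient_medical = x$inpatient_medical,
               instruments = x$instruments_one_time,
               activities = x$activities,
               outpatient_nonmedical = x$outpatient_nonmedical,
               admission_nonmedical = x$admission_nonmedical,
               caregiver_home = x$caregiver_home,
               total_annual = x$total)
  }))
  list(annual = annual, entry = entry, breakdown = breakdown)
}
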