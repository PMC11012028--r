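#' Post-diagnosis distribution over model entry states
#'
#' Evaluates the diagnostic-phase decision tree for one strategy and
#' returns the cohort shares entering the follow-up model in each state.
#'
#' For the structured scale (TDAS): a child is test-positive with
#' probability `p_test_positive`; among positives, the published
#' (true-positive, false-positive) pair is rescaled to a branch
#' distribution (they are reported from different denominators and sum to
#' slightly more than one), true positives are split over the severity mix
#' and false positives are non-ASD; among negatives, a small fraction is
#' diagnosed late (after age five) and enters as severe ASD, the rest are
#' non-ASD. For clinical diagnosis: a child is diagnosed with probability
#' `p_diagnosed_clin`; of the diagnosed, `p_delayed_clin` are delayed
#' (entering as severe) and the rest are split over the severity mix;
#' the undiagnosed are non-ASD.
#'
#' An alternative prevalence-explicit reading of the tree (treating the
#' false-positive figure as one minus specificity) is available via
#' `interpretation = "prevalence"`.
#'
#' @param strategy `"tdas"` or `"clindx"`.
#' @param perf Named list of diagnostic-phase probabilities, as returned
#'   by [diagnostic_performance()].
#' @param mix Severity mix (mild/moderate/severe), as returned by
#'   [severity_mix()].
#' @param interpretation `"renormalize"` (default) or `"prevalence"`.
#' @param prevalence ASD prevalence among the suspected cohort; required
#'   for the prevalence-explicit interpretation.
#' @return An `entry_distribution`: named vector over
#'   `non_asd`/`mild`/`moderate`/`severe`, summing to one, with
#'   attributes `delayed` (part of the severe share due to delayed
#'   diagnosis) and `false_positive` (share of the cohort entering
#'   non-ASD after a positive test).
#' @export
entry_distribution <- function(strategy = c("tdas", "clindx"), perf, mix,
                               interpretation = c("renormalize", "prevalence"),
                               prevalence = NULL) {
  strategy <- match.arg(strategy)
  interpretation <- match.arg(interpretation)
  mix <- mix / sum(mix)

  if (strategy == "tdas") {
    pos <- perf$p_test_positive
    if (interpretation == "renormalize") {
      tot <- perf$p_true_positive + perf$p_false_positive
      if (tot <= 0) stop("degenerate tree: true + false positive shares are 0")
      t_share <- perf$p_true_positive / tot
      tp <- pos * t_share
      fp <- pos * (1 - t_share)
      neg <- 1 - pos
    } else {
      if (is.null(prevalence) || is.na(prevalence)) {
        stop("prevalence-explicit interpretation needs a prevalence")
      }
      sens <- perf$p_true_positive
      fpr <- perf$p_false_positive   # read as 1 - specificity
      tp <- prevalence * sens
      fp <- (1 - prevalence) * fpr
      neg <- 1 - tp - fp
    }
    delayed <- neg * perf$p_delayed_tdas
    shares <- c(
      non_asd  = fp + neg * (1 - perf$p_delayed_tdas),
      mild     = tp * mix[["mild"]],
      moderate = tp * mix[["moderate"]],
      severe   = tp * mix[["severe"]] + delayed
    )
    fp_share <- fp
  } else {
    dx <- perf$p_diagnosed_clin
    delayed <- dx * perf$p_delayed_clin
    confirmed <- dx - delayed
    shares <- c(
      non_asd  = 1 - dx,
      mild     = confirmed * mix[["mild"]],
      moderate = confirmed * mix[["moderate"]],
      severe   = confirmed * mix[["severe"]] + delayed
    )
    fp_share <- 0
  }
  structure(shares / sum(shares), delayed = unname(delayed),
            false_positive = unname(fp_share), class = "entry_distribution")
}

#' Per-patient diagnostic cost of a strategy
#'
#' Labor is charged per diagnosis from the monthly labor cost and the
#' weekly diagnostic throughput. The structured scale additionally carries
#' training and instrument acquisition (amortized over the diagnoses one
#' provider performs per year) and per-patient-year maintenance and cloud
#' storage charges.
#'
#' @param strategy `"tdas"` or `"clindx"`.
#' @param dc Named list of strategy cost inputs (see `dx_cost_inputs`).
#' @return Cost in USD applied once to every entrant in the arm.
#' @export
diagnostic_cost_per_patient <- function(strategy = c("tdas", "clindx"), dc) {
  strategy <- match.arg(strategy)
  if (dc$diagnoses_per_week <= 0) stop("diagnoses_per_week must be positive")
  diagnoses_per_month <- dc$diagnoses_per_week * 52 / 12
  if (strategy == "tdas") {
    dc$labor_tdas / diagnoses_per_month +
      (dc$tdas_training + dc$tdas_instruments) / dc$amortization_diagnoses +
      dc$tdas_maintenance + dc$cloud_service
  } else {
    dc$labor_clin / diagnoses_per_month
  }
}
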