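#' Incremental cost-effectiveness of one strategy against another
#'
#' Computes the cost and QALY differences and, where the comparison falls
#' in a quadrant of the cost-effectiveness plane where a ratio is
#' meaningful, the incremental cost-effectiveness ratio
#' `ICER = delta_cost / delta_qaly`. Otherwise a dominance label is
#' returned: `dominant` when the intervention gains QALYs at lower cost,
#' `dominated` when it loses QALYs at higher cost (or adds cost for no
#' gain), `equal` when both differences vanish.
#'
#' @param intervention,comparator `strategy_outcome` objects (or lists
#'   with `cost_disc`/`qaly_disc`), from the same discounting mode.
#' @param discounted Compare discounted (default) or undiscounted totals.
#' @return An `icer_result` list: `delta_cost`, `delta_qaly`, `icer`
#'   (`NA` when undefined), `label`.
#' @export
icer_result <- function(intervention, comparator, discounted = TRUE) {
  suffix <- if (discounted) "disc" else "undisc"
  dc <- intervention[[paste0("cost_", suffix)]] -
    comparator[[paste0("cost_", suffix)]]
  de <- intervention[[paste0("qaly_", suffix)]] -
    comparator[[paste0("qaly_", suffix)]]
  if (dc == 0 && de == 0) {
    label <- "equal"; icer <- NA_real_
  } else if (de > 0 && dc <= 0) {
    label <- "dominant"; icer <- NA_real_
  } else if (de <= 0 && dc >= 0) {
    label <- "dominated"; icer <- NA_real_
  } else {
    label <- "ICER"; icer <- dc / de
  }
  structure(list(delta_cost = dc, delta_qaly = de, icer = icer,
                 label = label),
            class = "icer_result")
}

#' Net monetary benefit of an incremental outcome
#'
#' `NMB = wtp * delta_qaly - delta_cost`; positive exactly when the
#' intervention is cost-effective at the willingness-to-pay threshold.
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_qaly Incremental QALYs.
#' @param wtp Willingness-to-pay threshold (USD/QALY), non-negative.
#' @return Net monetary benefit in USD.
#' @export
nmb <- function(delta_cost, delta_qaly, wtp) {
  stopifnot(wtp >= 0)
  wtp * delta_qaly - delta_cost
}
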