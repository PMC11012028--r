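#' Run the full model for one strategy
#'
#' Evaluates the diagnostic tree, propagates the entry cohort through the
#' lifetime Markov model, and accrues discounted and undiscounted costs
#' and QALYs.
#'
#' @param params A `tdas_params` object.
#' @param strategy `"tdas"` or `"clindx"`.
#' @param scenario Use the scenario severity mix for clinical diagnosis?
#' @param keep_trace Attach the cohort trace to the result?
#' @return A `strategy_outcome` with elements `cost_undisc`, `cost_disc`,
#'   `qaly_undisc`, `qaly_disc`, plus `entry`, `dx_cost` and (optionally)
#'   `trace`.
#' @export
run_strategy <- function(params, strategy = c("tdas", "clindx"),
                         scenario = FALSE, keep_trace = FALSE) {
  strategy <- match.arg(strategy)
  perf <- diagnostic_performance(params)
  mix <- severity_mix(params, strategy, scenario = scenario)
  entry <- entry_distribution(
    strategy, perf, mix,
    interpretation = params$flags$tree_interpretation,
    prevalence = params$flags$asd_prevalence
  )
  dx <- diagnostic_cost_per_patient(strategy, dx_cost_inputs(params)) +
    attr(entry, "false_positive") * params$flags$fp_workup_cost
  costs <- state_cost_table(params)
  trace <- run_cohort(entry, transition_rates(params), params$life_table,
                      param_value(params, "rr_death_asd"),
                      params$econ$start_age, params$econ$max_age)
  out <- accrue_outcomes(trace, utility_set(params), costs$annual,
                         dx_cost = dx, rate = params$econ$discount_rate,
                         entry_costs = costs$entry,
                         half_cycle = params$flags$half_cycle_correction)
  out$strategy <- strategy
  out$entry <- entry
  out$dx_cost <- dx
  if (keep_trace) out$trace <- trace
  out
}

#' Base-case (or scenario) deterministic analysis
#'
#' Runs both strategies at the point estimates and assembles the results
#' table: per-strategy undiscounted and discounted total cost and QALYs,
#' incremental cost and QALYs of the structured scale against clinical
#' diagnosis, and the ICER.
#'
#' @param params A `tdas_params` object.
#' @param scenario Swap in the scenario severity mix for clinical
#'   diagnosis (shares re-estimated without the specialty hospital)?
#' @return A `base_case_result` list: `tdas`, `clindx`
#'   (strategy outcomes), `icer_disc`, `icer_undisc` (icer_result
#'   objects), and `table` (the results data frame).
#' @export
run_base_case <- function(params, scenario = FALSE) {
  tdas <- run_strategy(params, "tdas", scenario = scenario)
  clin <- run_strategy(params, "clindx", scenario = scenario)
  ic_d <- icer_result(tdas, clin, discounted = TRUE)
  ic_u <- icer_result(tdas, clin, discounted = FALSE)
  tab <- data.frame(
    strategy = c("TDAS", "ClinDx"),
    cost_undisc = c(tdas$cost_undisc, clin$cost_undisc),
    qaly_undisc = c(tdas$qaly_undisc, clin$qaly_undisc),
    inc_cost_undisc = c(ic_u$delta_cost, NA),
    inc_qaly_undisc = c(ic_u$delta_qaly, NA),
    icer_undisc = c(ic_u$icer, NA),
    cost_disc = c(tdas$cost_disc, clin$cost_disc),
    qaly_disc = c(tdas$qaly_disc, clin$qaly_disc),
    inc_cost_disc = c(ic_d$delta_cost, NA),
    inc_qaly_disc = c(ic_d$delta_qaly, NA),
    icer_disc = c(ic_d$icer, NA)
  )
  structure(list(tdas = tdas, clindx = clin, icer_disc = ic_d,
                 icer_undisc = ic_u, table = tab, scenario = scenario),
            class = "base_case_result")
}

#' @export
print.base_case_result <- function(x, ...) {
  cat(if (x$scenario) "Scenario analysis" else "Base-case analysis", "\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, 2)
  print(tab, row.names = FALSE)
  if (x$icer_disc$label == "ICER") {
    cat(sprintf("Discounted ICER: %.0f USD/QALY\n", x$icer_disc$icer))
  } else {
    cat(sprintf("Discounted result: %s\n", x$icer_disc$label))
  }
  invisible(x)
}

#' Orchestrate a full analysis run
#'
#' Executes the requested analyses and writes machine-readable outputs
#' (CSV) plus a JSON manifest recording the configuration hash, seed,
#' structural flags in effect, and every produced file.
#'
#' @param params A `tdas_params` object.
#' @param analyses Subset of `c("base", "scenario", "owsa", "psa",
#'   "ceac")`.
#' @param out_dir Output directory (created if absent).
#' @param seed Random seed for the probabilistic analyses; drawn (and
#'   recorded) if omitted.
#' @param iterations Number of probabilistic draws; defaults to the
#'   configured `psa_iterations`.
#' @return The manifest, invisibly.
#' @export
run_full <- function(params, analyses = c("base", "scenario", "owsa",
                                          "psa", "ceac"),
                     out_dir = ".", seed = NULL, iterations = NULL) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  if (is.null(iterations)) iterations <- params$econ$psa_iterations
  files <- character()
  errors <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
  }

  psa <- NULL
  for (a in analyses) {
    res <- tryCatch({
      switch(a,
        base = emit(run_base_case(params)$table, "base_case.csv"),
        scenario = emit(run_base_case(params, scenario = TRUE)$table,
                        "scenario.csv"),
        owsa = emit(owsa_tornado(params), "tornado.csv"),
        psa = {
          psa <- run_psa(params, n = iterations, seed = seed)
          emit(as.data.frame(psa), "psa_draws.csv")
        },
        ceac = {
          if (is.null(psa)) psa <- run_psa(params, n = iterations,
                                           seed = seed)
          emit(ceac(psa), "ceac.csv")
        })
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors <- c(errors, sprintf("%s: %s", a, res))
  }

  cfg_file <- tempfile(fileext = ".yaml")
  write_config(params, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tdascea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = seed,
    iterations = iterations,
    flags = params$flags,
    analyses = analyses,
    files = files
  )
  if (length(errors)) manifest$errors <- errors
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  unlink(cfg_file)
  invisible(manifest)
}

# Fast path used by the probabilistic analysis: evaluates both strategies
# on one parameter set while building each per-age transition matrix only
# once. Must agree with run_strategy() to numerical precision (tested).
model_deltas <- function(params, scenario = FALSE, discounted = TRUE) {
  flags <- params$flags
  perf <- diagnostic_performance(params)
  entry_t <- entry_distribution("tdas", perf, severity_mix(params, "tdas"),
                                interpretation = flags$tree_interpretation,
                                prevalence = flags$asd_prevalence)
  entry_c <- entry_distribution("clindx", perf,
                                severity_mix(params, "clindx",
                                             scenario = scenario),
                                interpretation = flags$tree_interpretation,
                                prevalence = flags$asd_prevalence)
  dxc <- dx_cost_inputs(params)
  dx <- c(diagnostic_cost_per_patient("tdas", dxc) +
            attr(entry_t, "false_positive") * flags$fp_workup_cost,
          diagnostic_cost_per_patient("clindx", dxc))
  costs <- state_cost_table(params)
  u <- utility_set(params)
  rates <- transition_rates(params)
  rr <- param_value(params, "rr_death_asd")
  rate <- params$econ$discount_rate
  start_age <- params$econ$start_age
  max_age <- params$econ$max_age
  n_cycles <- max_age - floor(start_age)

  occ <- rbind(c(as.numeric(entry_t), 0), c(as.numeric(entry_c), 0))
  cost_tot <- dx + as.numeric(occ %*% costs$entry)
  qaly_tot <- c(0, 0)
  half <- isTRUE(flags$half_cycle_correction)
  d <- 1
  for (t in seq_len(n_cycles)) {
    q <- q_at_age(params$life_table, start_age + t - 1, max_age)
    m <- build_transition_matrix(rates, q, rr)
    occ_next <- occ %*% m
    basis <- if (half) (occ + occ_next) / 2 else occ
    cost_tot <- cost_tot + d * as.numeric(basis %*% costs$annual)
    qaly_tot <- qaly_tot + d * as.numeric(basis %*% u)
    occ <- occ_next
    if (discounted) d <- d / (1 + rate)
  }
  c(delta_cost = cost_tot[1] - cost_tot[2],
    delta_qaly = qaly_tot[1] - qaly_tot[2])
}
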