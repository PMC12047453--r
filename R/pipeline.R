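#' Build the baseline schedule from a parameter set
#' @param pset A `ckd_parameter_set`.
#' @param n_cycles Horizon in quarterly cycles (default 40).
#' @return A constant `ckd_schedule`.
#' @export
baseline_schedule <- function(pset, n_cycles = 40L) {
  M <- build_transition_matrix(pset$progression, pset$rr, pset$life_table,
                               adjacency = pset$adjacency)
  constant_schedule(M, n_cycles = n_cycles)
}

#' Build the four intervention specifications from a parameter set
#'
#' @param pset A `ckd_parameter_set` whose `params` element carries the
#'   intervention parameters.
#' @param baseline Baseline schedule (needed to calibrate the diagnosis
#'   intervention); defaults to [baseline_schedule()] of `pset`.
#' @return Named list of four `ckd_intervention` objects
#'   (`diagnosis`, `management`, `sglt2`, `transplant`).
#' @export
build_interventions <- function(pset, baseline = baseline_schedule(pset)) {
  p <- pset$params
  list(
    diagnosis = intervention_diagnosis(
      bame_undiagnosed_fraction = p$bame_undiagnosed_fraction,
      reduction_target = p$diagnosis_reduction,
      baseline = baseline, initial = pset$initial),
    management = intervention_management(
      treatment_gap = p$treatment_gap, progression_rr = p$progression_rr),
    sglt2 = intervention_sglt2(
      eligible_fraction = p$sglt2_eligible, cv_rr = p$cv_rr,
      renal_rr = p$renal_rr),
    transplant = intervention_transplant(
      increase = p$transplant_increase, programme_cost = p$transplant_cost)
  )
}

#' Run the full scenario grid
#'
#' Projects the baseline, each intervention individually, and the combined
#' interventions; accrues discounted costs and QALYs; and computes
#' incremental comparisons against the baseline plus the QALY interaction
#' factor. Under `scenario = "constrained"` every schedule is first passed
#' through [constrain()] with references derived from the uncapped
#' baseline.
#'
#' @param pset A `ckd_parameter_set`.
#' @param scenario `"base"` or `"constrained"`.
#' @param n_cycles Horizon (default 40).
#' @return A `ckd_scenario_grid`: list with `results` (named
#'   `ckd_scenario_result`s), `comparisons` (named `ckd_cea`s vs baseline),
#'   `interaction_factor`, `interventions`, and `scenario`.
#' @export
run_scenario_grid <- function(pset, scenario = c("base", "constrained"),
                              n_cycles = 40L) {
  scenario <- match.arg(scenario)
  base_sched <- baseline_schedule(pset, n_cycles)
  specs <- build_interventions(pset, base_sched)

  wrap <- identity
  if (scenario == "constrained") {
    cons <- derive_constraint(base_sched, pset$initial,
                              pset$params$annual_growth_cap)
    wrap <- function(s) constrain(s, cons)
  }

  schedules <- c(
    list(baseline = base_sched),
    lapply(specs, function(sp) apply_interventions(base_sched, list(sp))),
    list(combined = apply_interventions(base_sched, unname(specs)))
  )
  schedules <- lapply(schedules, wrap)

  results <- lapply(names(schedules), function(nmn) {
    sched <- schedules[[nmn]]
    active <- switch(nmn,
                     baseline = list(),
                     combined = unname(specs),
                     list(specs[[nmn]]))
    econ <- pset$econ
    econ$fixed_annual_costs <- econ$fixed_annual_costs + fixed_annual_cost(active)
    accrue(project(pset$initial, sched), econ)
  })
  names(results) <- names(schedules)

  comparisons <- lapply(results[setdiff(names(results), "baseline")],
                        function(r) compare(results$baseline, r))
  ifac <- interaction_factor(comparisons$combined,
                             comparisons[names(specs)])
  structure(list(results = results, comparisons = comparisons,
                 interaction_factor = ifac, interventions = specs,
                 scenario = scenario),
            class = "ckd_scenario_grid")
}

#' Combined-vs-baseline comparison for a parameter set
#'
#' Convenience wrapper used by the sensitivity analysis: two projections
#' (baseline and all four interventions combined) and their incremental
#' comparison.
#'
#' @inheritParams run_scenario_grid
#' @return A `ckd_cea`.
#' @export
combined_comparison <- function(pset, scenario = "base", n_cycles = 40L) {
  base_sched <- baseline_schedule(pset, n_cycles)
  specs <- build_interventions(pset, base_sched)
  comb <- apply_interventions(base_sched, unname(specs))
  if (scenario == "constrained") {
    cons <- derive_constraint(base_sched, pset$initial,
                              pset$params$annual_growth_cap)
    base_sched <- constrain(base_sched, cons)
    comb <- constrain(comb, cons)
  }
  base_econ <- pset$econ
  comb_econ <- pset$econ
  comb_econ$fixed_annual_costs <-
    comb_econ$fixed_annual_costs + fixed_annual_cost(unname(specs))
  compare(accrue(project(pset$initial, base_sched), base_econ),
          accrue(project(pset$initial, comb), comb_econ))
}
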