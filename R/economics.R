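#' Default economic inputs: per-state quarterly costs and utilities
#'
#' The default cost and utility set for the 16 states. Costs are quarterly
#' direct NHS costs in 2022 GBP; the £60/year primary-care add-on for CKD
#' stages 1-5 is already included in these figures. Undiagnosed G1/G2 cost
#' nothing (asymptomatic, untreated); undiagnosed G3/G4 carry the same
#' costs as their diagnosed counterparts. Utilities are annual EQ-5D-3L
#' weights; the at-risk group shares the stage 1-2 utility (CKD is
#' asymptomatic before stage 3), and undiagnosed states carry the same
#' utility as diagnosed ones. Transportation to dialysis is an additive
#' quarterly cost on top of the dialysis state cost.
#'
#' @param discount_rate_annual Annual discount rate applied to both costs
#'   and outcomes (default 0.035).
#' @param fixed_annual_costs Fixed programme costs in GBP/year from active
#'   interventions (default 0).
#' @return A `ckd_econ` list with elements `cost` (named quarterly GBP),
#'   `utility` (named annual weights), `transport_cost_dialysis`,
#'   `discount_rate_annual`, `fixed_annual_costs`.
#' @export
default_economic_inputs <- function(discount_rate_annual = 0.035,
                                    fixed_annual_costs = 0) {
  cost <- c(
    "No kidney disease" = 0,
    "Undiagnosed CKD G1" = 0,
    "Undiagnosed CKD G2" = 0,
    "Undiagnosed CKD G3" = 137.13,
    "Undiagnosed CKD G4" = 134.30,
    "Diagnosed CKD G1" = 16.19,
    "Diagnosed CKD G2" = 16.19,
    "Diagnosed CKD G3" = 137.13,
    "Diagnosed CKD G4" = 134.30,
    "Diagnosed CKD G5" = 173.61,
    "Transplantation (acute)" = 17512.24,
    "Transplantation (post-acute)" = 1328.05,
    "Dialysis" = 8595.16,
    "CVD (acute)" = 5153.60,
    "CVD (post-acute)" = 218.58,
    "Death" = 0
  )
  utility <- c(
    "No kidney disease" = 0.85,
    "Undiagnosed CKD G1" = 0.85,
    "Undiagnosed CKD G2" = 0.85,
    "Undiagnosed CKD G3" = 0.80,
    "Undiagnosed CKD G4" = 0.74,
    "Diagnosed CKD G1" = 0.85,
    "Diagnosed CKD G2" = 0.85,
    "Diagnosed CKD G3" = 0.80,
    "Diagnosed CKD G4" = 0.74,
    "Diagnosed CKD G5" = 0.73,
    "Transplantation (acute)" = 0.71,
    "Transplantation (post-acute)" = 0.84,
    "Dialysis" = 0.58,
    "CVD (acute)" = 0.66,
    "CVD (post-acute)" = 0.73,
    "Death" = 0
  )
  economic_inputs(cost, utility, transport_cost_dialysis = 1840.18,
                  discount_rate_annual = discount_rate_annual,
                  fixed_annual_costs = fixed_annual_costs)
}

#' Construct and validate economic inputs
#' @param cost Named quarterly cost vector (GBP, >= 0) over all 16 states.
#' @param utility Named annual utility vector in `[0, 1]`.
#' @param transport_cost_dialysis Additive quarterly transport cost for the
#'   dialysis state (GBP).
#' @param discount_rate_annual Annual discount rate.
#' @param fixed_annual_costs Fixed intervention costs, GBP/year.
#' @return A `ckd_econ` object.
#' @export
economic_inputs <- function(cost, utility, transport_cost_dialysis = 0,
                            discount_rate_annual = 0.035,
                            fixed_annual_costs = 0) {
  nm <- state_names()
  if (!all(nm %in% names(cost)) || !all(nm %in% names(utility))) {
    stop("cost and utility must cover every canonical state.", call. = FALSE)
  }
  cost <- cost[nm]; utility <- utility[nm]
  if (any(cost < 0)) stop("Costs must be >= 0.", call. = FALSE)
  if (any(utility < 0 | utility > 1)) stop("Utilities must lie in [0, 1].", call. = FALSE)
  if (cost[["Death"]] != 0 || utility[["Death"]] != 0) {
    stop("Death must have zero cost and zero utility.", call. = FALSE)
  }
  structure(list(cost = cost, utility = utility,
                 transport_cost_dialysis = transport_cost_dialysis,
                 discount_rate_annual = discount_rate_annual,
                 fixed_annual_costs = fixed_annual_costs),
            class = "ckd_econ")
}

#' Quarterly discount factor
#'
#' Discounting starts at model start: factor(t) = (1 + r)^(-t/4) for cycle
#' t, with the annual rate compounded quarterly.
#'
#' @param cycle Cycle index (>= 0).
#' @param annual_rate Annual discount rate (> -1).
#' @return Discount factor(s).
#' @export
discount_factor <- function(cycle, annual_rate = 0.035) {
  if (any(cycle < 0)) stop("cycle must be >= 0.", call. = FALSE)
  if (annual_rate <= -1) stop("annual_rate must exceed -1.", call. = FALSE)
  (1 + annual_rate)^(-cycle / 4)
}

#' Accrue discounted costs and QALYs over a trajectory
#'
#' End-of-cycle accrual with no half-cycle correction: cycle 0 accrues
#' nothing; for each cycle t in 1..T, cost(t) = occupancy * quarterly costs
#' (plus dialysis transport and a quarter of any fixed annual intervention
#' cost) and qaly(t) = occupancy * utilities * 0.25, both multiplied by the
#' discount factor. Event tallies used in the reported tables are recorded
#' alongside.
#'
#' @param traj A `ckd_trajectory`.
#' @param econ A `ckd_econ`.
#' @return A `ckd_scenario_result` with `total_discounted_cost`,
#'   `total_discounted_qalys`, per-cycle `cost` and `qaly` series, and a
#'   `tallies` list (year-10 prevalences and incidences, total deaths).
#' @export
accrue <- function(traj, econ) {
  stopifnot(inherits(traj, "ckd_trajectory"), inherits(econ, "ckd_econ"))
  n <- traj$n_cycles
  occ <- traj$occupancy[-1L, , drop = FALSE]  # cycles 1..n
  df <- discount_factor(seq_len(n), econ$discount_rate_annual)
  cost_cycle <- (occ %*% econ$cost +
                 occ[, "Dialysis"] * econ$transport_cost_dialysis +
                 econ$fixed_annual_costs / 4) * df
  qaly_cycle <- (occ %*% econ$utility) * 0.25 * df
  grp <- .state_groups()
  yr <- n %/% 4L
  tallies <- list(
    ckd12_prevalence_y10 = tally_prevalence(traj, grp$ckd12, yr),
    ckd35_prevalence_y10 = tally_prevalence(traj, grp$ckd35, yr),
    dialysis_prevalence_y10 = tally_prevalence(traj, "Dialysis", yr),
    transplant_incidence_y10 = tally_incidence(traj, "Transplantation (acute)", yr),
    cvd_incidence_y10 = tally_incidence(traj, "CVD (acute)", yr),
    deaths_total = tally_deaths(traj)
  )
  structure(list(total_discounted_cost = sum(cost_cycle),
                 total_discounted_qalys = sum(qaly_cycle),
                 cost = as.numeric(cost_cycle),
                 qaly = as.numeric(qaly_cycle),
                 tallies = tallies),
            class = "ckd_scenario_result")
}

#' Incremental cost-effectiveness comparison
#'
#' Deltas are alternative minus base. The ICER is reported signed even when
#' negative (a cost-saving, health-gaining alternative yields a negative
#' ICER and the `dominant` flag).
#'
#' @param base,alt `ckd_scenario_result` objects under the same horizon and
#'   discounting.
#' @return A `ckd_cea` with `delta_cost`, `delta_qalys`, `icer` (`NA` when
#'   `delta_qalys` is 0), and `dominance_flag` in
#'   `{"none", "dominant", "dominated"}`.
#' @export
compare <- function(base, alt) {
  stopifnot(inherits(base, "ckd_scenario_result"),
            inherits(alt, "ckd_scenario_result"))
  dc <- alt$total_discounted_cost - base$total_discounted_cost
  dq <- alt$total_discounted_qalys - base$total_discounted_qalys
  icer <- if (dq == 0) NA_real_ else dc / dq
  flag <- if (dc < 0 && dq > 0) "dominant"
          else if (dc > 0 && dq < 0) "dominated"
          else "none"
  structure(list(delta_cost = dc, delta_qalys = dq, icer = icer,
                 dominance_flag = flag),
            class = "ckd_cea")
}

#' QALY interaction factor of combined interventions
#'
#' The combined interventions' QALY gain minus the sum of the individual
#' gains, all against the same baseline. A positive value means the
#' interventions reinforce each other.
#'
#' @param combined A `ckd_cea` for the combined interventions.
#' @param individuals List of `ckd_cea` objects, one per intervention.
#' @return QALYs.
#' @export
interaction_factor <- function(combined, individuals) {
  combined$delta_qalys -
    sum(vapply(individuals, function(x) x$delta_qalys, numeric(1)))
}
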