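#' Intervention specifications
#'
#' Interventions are declarative: each names the transition cells it
#' modifies, the multiplier it applies to them, and the ramp with which the
#' effect phases in. Multipliers act on the rate scale: a multiplier m on a
#' cell with probability p yields 1 - (1 - p)^m, which is a valid
#' probability for any m >= 0 and composes multiplicatively with other
#' interventions sharing the cell.
#'
#' @name interventions
NULL

new_intervention <- function(name, targets, effect_kind, multipliers,
                             ramp = c("linear", "step"),
                             fixed_annual_cost = 0,
                             eligible_fraction = NA_real_) {
  ramp <- match.arg(ramp)
  stopifnot(is.data.frame(targets),
            all(c("from_state", "to_state") %in% names(targets)),
            length(multipliers) == nrow(targets))
  assert_states(targets$from_state)
  assert_states(targets$to_state)
  structure(list(name = name, targets = targets, effect_kind = effect_kind,
                 multipliers = multipliers, ramp = ramp,
                 fixed_annual_cost = fixed_annual_cost,
                 eligible_fraction = eligible_fraction),
            class = "ckd_intervention")
}

#' Ramp fraction for a cycle
#'
#' Linear ramps reach full effect at the final cycle (`ramp(t) = t/40`);
#' step interventions are at full effect from cycle 1.
#'
#' @param spec A `ckd_intervention`.
#' @param cycle Cycle index (0 = model start, before any effect).
#' @param n_cycles Horizon.
#' @return Fraction of full effect in `[0, 1]`.
#' @export
ramp_fraction <- function(spec, cycle, n_cycles = 40L) {
  if (spec$ramp == "step") as.numeric(cycle >= 1) else min(1, cycle / n_cycles)
}

#' Effective rate-scale multipliers at a cycle
#'
#' @param spec A `ckd_intervention`.
#' @param cycle Cycle index.
#' @param n_cycles Horizon.
#' @return Numeric vector aligned with `spec$targets` rows.
#' @export
effective_multipliers <- function(spec, cycle, n_cycles = 40L) {
  f <- ramp_fraction(spec, cycle, n_cycles)
  if (spec$effect_kind == "uptake_weighted_rr") {
    # multipliers hold the risk ratios; uptake of the eligible fraction
    # dilutes the effect across the whole state population
    1 - f * spec$eligible_fraction * (1 - spec$multipliers)
  } else {
    1 + f * (spec$multipliers - 1)
  }
}

#' Intervention 1: earlier diagnosis of CKD in underserved communities
#'
#' Outreach and selective screening in Black, Asian and minority ethnic
#' (BAME) communities, modelled as a common multiplier (> 1) on the
#' undiagnosed -> diagnosed transitions for stages 1-3. The multiplier is
#' calibrated by root-finding so that the BAME-attributable share of the
#' undiagnosed stage 1-3 population at the end of the horizon is
#' `(1 - reduction_target)` times its value under the baseline schedule.
#' Since the BAME share is tracked as a fixed fraction of the undiagnosed
#' population, the calibration is equivalent to reducing the undiagnosed
#' stage 1-3 population itself by `reduction_target`.
#'
#' @param bame_undiagnosed_fraction Fraction of the undiagnosed stage 1-3
#'   population attributable to BAME communities, in (0, 1].
#' @param reduction_target Target proportional reduction over the horizon
#'   (default 0.25).
#' @param baseline Baseline `ckd_schedule` used for calibration.
#' @param initial Initial occupancy vector.
#' @param fixed_annual_cost Programme cost in GBP/year (default 0).
#' @return A calibrated `ckd_intervention`.
#' @export
intervention_diagnosis <- function(bame_undiagnosed_fraction,
                                   reduction_target = 0.25,
                                   baseline, initial,
                                   fixed_annual_cost = 0) {
  stopifnot(bame_undiagnosed_fraction > 0, bame_undiagnosed_fraction <= 1,
            reduction_target >= 0, reduction_target < 1)
  targets <- data.frame(
    from_state = c("Undiagnosed CKD G1", "Undiagnosed CKD G2", "Undiagnosed CKD G3"),
    to_state = c("Diagnosed CKD G1", "Diagnosed CKD G2", "Diagnosed CKD G3"),
    stringsAsFactors = FALSE
  )
  undiag <- .state_groups()$undiagnosed13

  endpoint <- function(m) {
    spec <- new_intervention("diagnosis", targets, "calibrated_multiplier",
                             rep(m, 3), ramp = "linear",
                             fixed_annual_cost = fixed_annual_cost)
    traj <- project(initial, apply_interventions(baseline, list(spec)))
    bame_undiagnosed_fraction * sum(traj$occupancy[baseline$n_cycles + 1L, undiag])
  }
  base_val <- endpoint(1)
  if (reduction_target == 0 || base_val == 0) {
    return(new_intervention("diagnosis", targets, "calibrated_multiplier",
                            rep(1, 3), ramp = "linear",
                            fixed_annual_cost = fixed_annual_cost))
  }
  target_val <- (1 - reduction_target) * base_val
  f <- function(m) endpoint(m) - target_val
  hi <- 2
  while (f(hi) > 0 && hi < 1e6) hi <- hi * 4
  if (f(hi) > 0) {
    stop(sprintf(
      "Calibration failed: maximum achievable reduction is %.1f%% (target %.1f%%).",
      100 * (1 - endpoint(hi) / base_val), 100 * reduction_target), call. = FALSE)
  }
  m <- stats::uniroot(f, c(1, hi), tol = 1e-10)$root
  new_intervention("diagnosis", targets, "calibrated_multiplier",
                   rep(m, 3), ramp = "linear",
                   fixed_annual_cost = fixed_annual_cost)
}

#' Intervention 2: enhanced CKD management (ACEi/ARB treatment gap)
#'
#' Closes the treatment gap for renin-angiotensin-system blockade in
#' diagnosed CKD. A fraction `treatment_gap` of diagnosed stage 3 patients
#' who should receive ACEi/ARBs do not; closing the gap moves them onto the
#' treated progression rate. The stage 3 -> 4 cell receives the
#' population-weighted blend `(1 - gap) + gap * progression_rr`, ramped
#' linearly to full effect over the horizon.
#'
#' @param treatment_gap Proportion currently untreated (default 0.36).
#' @param progression_rr Relative progression rate under treatment, in
#'   (0, 1].
#' @param override Allow `progression_rr > 1` (default FALSE).
#' @return A `ckd_intervention`.
#' @export
intervention_management <- function(treatment_gap = 0.36, progression_rr,
                                    override = FALSE) {
  stopifnot(treatment_gap >= 0, treatment_gap <= 1, progression_rr > 0)
  if (progression_rr > 1 && !override) {
    stop("progression_rr > 1 would worsen progression; set override = TRUE ",
         "to force it.", call. = FALSE)
  }
  blend <- (1 - treatment_gap) + treatment_gap * progression_rr
  new_intervention(
    "management",
    data.frame(from_state = "Diagnosed CKD G3", to_state = "Diagnosed CKD G4",
               stringsAsFactors = FALSE),
    "multiplier", blend, ramp = "linear")
}

#' Intervention 3: SGLT-2 inhibitor uptake in stage 4 CKD
#'
#' Uptake of SGLT-2 inhibitors ramps linearly from 0% to 100% of the
#' eligible population (default 18.8% of the diagnosed stage 4 prevalent
#' population) over the horizon. The diagnosed G4 -> G5 cell is reduced by
#' the renal risk ratio and the G4 -> acute CVD cell by the cardiovascular
#' risk ratio (default 0.75), each diluted by uptake and the eligible
#' fraction: multiplier(t) = 1 - uptake(t) * eligible * (1 - rr).
#'
#' @param eligible_fraction Eligible share of diagnosed G4 (default 0.188).
#' @param cv_rr Risk ratio for cardiovascular events (default 0.75).
#' @param renal_rr Risk ratio for progression to stage 5.
#' @return A `ckd_intervention`.
#' @export
intervention_sglt2 <- function(eligible_fraction = 0.188, cv_rr = 0.75,
                               renal_rr) {
  stopifnot(eligible_fraction >= 0, eligible_fraction <= 1,
            cv_rr > 0, cv_rr <= 1, renal_rr > 0, renal_rr <= 1)
  new_intervention(
    "sglt2",
    data.frame(from_state = c("Diagnosed CKD G4", "Diagnosed CKD G4"),
               to_state = c("Diagnosed CKD G5", "CVD (acute)"),
               stringsAsFactors = FALSE),
    "uptake_weighted_rr", c(renal_rr, cv_rr), ramp = "linear",
    eligible_fraction = eligible_fraction)
}

#' Intervention 4: pre-emptive live donor transplantation outreach
#'
#' An awareness programme for patients entering end-stage kidney disease,
#' increasing pre-emptive transplantation. The diagnosed G5 ->
#' transplantation (acute) cell is scaled by `1 + increase` from cycle 1
#' (step ramp), at a fixed programme cost carried into the economics.
#'
#' @param increase Proportional increase in pre-emptive transplants
#'   (default 1.0, i.e. doubling).
#' @param programme_cost Annual outreach cost in GBP (default 149000).
#' @return A `ckd_intervention`.
#' @export
intervention_transplant <- function(increase = 1.0, programme_cost = 149000) {
  stopifnot(increase >= 0)
  new_intervention(
    "transplant",
    data.frame(from_state = "Diagnosed CKD G5",
               to_state = "Transplantation (acute)",
               stringsAsFactors = FALSE),
    "multiplier", 1 + increase, ramp = "step",
    fixed_annual_cost = programme_cost)
}

#' Apply interventions to a schedule
#'
#' Per cycle, each intervention's effective multiplier is applied to its
#' target cells on the rate scale; interventions sharing a cell compose
#' multiplicatively on rates. Rows are re-closed via the residual-mass rule
#' (self-transition, or the tunnel exit), so the result remains
#' row-stochastic with structural zeros intact.
#'
#' @param schedule A `ckd_schedule`.
#' @param specs List of `ckd_intervention` objects.
#' @param space State space.
#' @return A new `ckd_schedule`.
#' @export
apply_interventions <- function(schedule, specs, space = ckd_states()) {
  if (!length(specs)) return(schedule)
  stopifnot(all(vapply(specs, inherits, logical(1), "ckd_intervention")))
  n <- schedule$n_cycles
  base_fn <- schedule$fn
  new_schedule(function(cycle, occupancy) {
    M <- base_fn(cycle, occupancy)
    A <- attr(M, "adjacency")
    Mu <- unclass(M)
    for (spec in specs) {
      m <- effective_multipliers(spec, cycle, n)
      idx <- cbind(spec$targets$from_state, spec$targets$to_state)
      Mu[idx] <- 1 - (1 - Mu[idx])^m
    }
    Mu <- close_rows(Mu, space)
    new_transition_matrix(Mu, A)
  }, n_cycles = n)
}

#' Total fixed annual cost of a set of interventions
#' @param specs List of `ckd_intervention` objects.
#' @return GBP per year.
#' @export
fixed_annual_cost <- function(specs) {
  sum(vapply(specs, function(s) s$fixed_annual_cost, numeric(1)))
}

#' Capacity constraint specification
#'
#' Kidney replacement therapy capacity grows at the historically observed
#' compound rate rather than meeting all projected demand. Dialysis
#' occupancy and quarterly transplantation inflow are capped at
#' `reference * (1 + annual_growth_cap)^(t/4)`.
#'
#' @param annual_growth_cap Compound annual growth cap (default 0.06).
#' @param reference_dialysis Reference dialysis occupancy (persons) at model
#'   start.
#' @param reference_transplant_inflow Reference quarterly inflow into acute
#'   transplantation (persons/quarter).
#' @return A `ckd_constraint` object.
#' @export
constraint_spec <- function(annual_growth_cap = 0.06,
                            reference_dialysis,
                            reference_transplant_inflow) {
  stopifnot(annual_growth_cap >= 0, reference_dialysis >= 0,
            reference_transplant_inflow >= 0)
  structure(list(annual_growth_cap = annual_growth_cap,
                 reference_dialysis = reference_dialysis,
                 reference_transplant_inflow = reference_transplant_inflow),
            class = "ckd_constraint")
}

#' Derive a capacity constraint from a baseline run
#'
#' Reference activity is taken from the uncapped baseline: dialysis
#' occupancy at model start and the first cycle's inflow into acute
#' transplantation.
#'
#' @param schedule Baseline `ckd_schedule`.
#' @param initial Initial occupancy.
#' @param annual_growth_cap Compound annual growth cap (default 0.06).
#' @return A `ckd_constraint`.
#' @export
derive_constraint <- function(schedule, initial, annual_growth_cap = 0.06) {
  M <- matrix_for(schedule, 1, initial[state_names()])
  nm <- state_names()
  ta <- "Transplantation (acute)"
  inflow1 <- sum(initial[setdiff(nm, ta)] * unclass(M)[setdiff(nm, ta), ta])
  constraint_spec(annual_growth_cap,
                  reference_dialysis = unname(initial["Dialysis"]),
                  reference_transplant_inflow = inflow1)
}

#' Constrain a schedule to historic capacity growth
#'
#' Returns an occupancy-dependent schedule. At each cycle, if the projected
#' activity of a capped state would exceed its cap trajectory, every inbound
#' cell into that state is scaled by a common factor in `[0, 1]` chosen so
#' the cap binds exactly; the redirected mass stays in its source state
#' (an extra cycle in diagnosed G5, for instance). Dialysis is capped on
#' occupancy; transplantation on quarterly inflow.
#'
#' @param schedule A `ckd_schedule`.
#' @param constraint A `ckd_constraint` from [constraint_spec()] or
#'   [derive_constraint()].
#' @param space State space.
#' @return A new occupancy-dependent `ckd_schedule`.
#' @export
constrain <- function(schedule, constraint, space = ckd_states()) {
  stopifnot(inherits(constraint, "ckd_constraint"))
  n <- schedule$n_cycles
  base_fn <- schedule$fn
  nm <- space$name
  g <- constraint$annual_growth_cap

  cap_inbound <- function(Mu, occupancy, target, cap_value, on_occupancy) {
    src <- setdiff(nm, c(target, "Death"))
    inflow <- sum(occupancy[src] * Mu[src, target])
    stay <- if (on_occupancy) occupancy[target] * Mu[target, target] else 0
    budget <- cap_value - stay
    if (inflow <= budget || inflow <= 0) return(Mu)
    f <- max(0, min(1, budget / inflow))
    removed <- Mu[src, target] * (1 - f)
    Mu[src, target] <- Mu[src, target] * f
    # redirected mass waits in its source state (tunnel sources fall
    # through to their mandated exit instead)
    exits <- tunnel_exits(space)
    home <- ifelse(src %in% names(exits), exits[src], src)
    Mu[cbind(src, home)] <- Mu[cbind(src, home)] + removed
    Mu
  }

  new_schedule(function(cycle, occupancy) {
    if (is.null(occupancy)) {
      stop("Constrained schedules need the current occupancy.", call. = FALSE)
    }
    M <- base_fn(cycle, occupancy)
    A <- attr(M, "adjacency")
    Mu <- unclass(M)
    growth <- (1 + g)^(cycle / 4)
    Mu <- cap_inbound(Mu, occupancy, "Transplantation (acute)",
                      constraint$reference_transplant_inflow * growth,
                      on_occupancy = FALSE)
    Mu <- cap_inbound(Mu, occupancy, "Dialysis",
                      constraint$reference_dialysis * growth,
                      on_occupancy = TRUE)
    new_transition_matrix(Mu, A)
  }, n_cycles = n)
}
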