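#' Transition schedules
#'
#' A schedule supplies the transition matrix used to complete each cycle.
#' Baseline schedules ignore occupancy; the capacity-constrained schedule
#' depends on it. Schedules are deterministic: the same (cycle, occupancy)
#' pair always yields the identical matrix.
#'
#' @param fn Function `(cycle, occupancy)` returning a transition matrix.
#'   `cycle` runs 1..`n_cycles`: the matrix requested for cycle t advances
#'   occupancy from t-1 to t.
#' @param n_cycles Number of quarterly cycles (default 40 = 10 years).
#' @return A `ckd_schedule` object.
#' @export
new_schedule <- function(fn, n_cycles = 40L) {
  stopifnot(is.function(fn), n_cycles >= 1)
  structure(list(fn = fn, n_cycles = as.integer(n_cycles)),
            class = "ckd_schedule")
}

#' Constant schedule from a single matrix
#' @param M A transition matrix.
#' @inheritParams new_schedule
#' @return A `ckd_schedule` returning `M` every cycle.
#' @export
constant_schedule <- function(M, n_cycles = 40L) {
  force(M)
  new_schedule(function(cycle, occupancy) M, n_cycles = n_cycles)
}

#' Matrix for a given cycle
#' @param schedule A `ckd_schedule`.
#' @param cycle Cycle index in 1..n_cycles.
#' @param occupancy Current occupancy vector (start of the cycle); only
#'   occupancy-dependent schedules use it.
#' @return The transition matrix for that cycle.
#' @export
matrix_for <- function(schedule, cycle, occupancy = NULL) {
  stopifnot(inherits(schedule, "ckd_schedule"))
  if (cycle < 1 || cycle > schedule$n_cycles) {
    stop("cycle must lie in 1..", schedule$n_cycles, call. = FALSE)
  }
  schedule$fn(cycle, occupancy)
}

#' Project a cohort through a schedule
#'
#' Deterministic cohort projection: the occupancy row vector is multiplied
#' by each cycle's transition matrix, and the inflow into every state
#' (persons entering from a different state that cycle) is tallied.
#' The population is closed, so the total across all states (including
#' death) is conserved.
#'
#' @param initial Named numeric vector of persons per state (non-negative),
#'   names matching [state_names()].
#' @param schedule A `ckd_schedule`.
#' @param space State space.
#' @return A `ckd_trajectory`: list with `occupancy`
#'   ((n_cycles+1) x 16 matrix, row 1 = cycle 0) and `inflow`
#'   (n_cycles x 16 matrix, row t = persons entering each state during
#'   cycle t).
#' @export
project <- function(initial, schedule, space = ckd_states()) {
  nm <- space$name
  stopifnot(inherits(schedule, "ckd_schedule"))
  if (is.null(names(initial)) || !setequal(names(initial), nm)) {
    stop("initial must be named by the 16 canonical states.", call. = FALSE)
  }
  initial <- initial[nm]
  if (any(initial < 0)) stop("Initial counts must be >= 0.", call. = FALSE)

  n <- schedule$n_cycles
  occ <- matrix(0, n + 1L, length(nm), dimnames = list(0:n, nm))
  inflow <- matrix(0, n, length(nm), dimnames = list(1:n, nm))
  occ[1L, ] <- initial

  for (t in seq_len(n)) {
    M <- matrix_for(schedule, t, occ[t, ])
    prev <- occ[t, ]
    nxt <- as.numeric(prev %*% unclass(M))
    if (any(nxt < -1e-9)) {
      stop("Internal consistency error: negative occupancy at cycle ", t,
           call. = FALSE)
    }
    nxt[nxt < 0] <- 0
    occ[t + 1L, ] <- nxt
    inflow[t, ] <- nxt - prev * diag(unclass(M))
  }
  structure(list(occupancy = occ, inflow = inflow, n_cycles = n),
            class = "ckd_trajectory")
}

#' Year-end prevalence of a set of states
#'
#' Model year k covers cycles 4(k-1)+1 .. 4k; prevalence is read at the
#' final cycle of the year (cycle 4k).
#'
#' @param traj A `ckd_trajectory`.
#' @param states Character vector of state names.
#' @param year Model year, 1..horizon.
#' @return Persons occupying the named states at the end of that year.
#' @export
tally_prevalence <- function(traj, states, year) {
  assert_states(states)
  cyc <- 4L * year
  if (year < 1 || cyc > traj$n_cycles) stop("year out of range.", call. = FALSE)
  sum(traj$occupancy[cyc + 1L, states])
}

#' Incidence into a state over a model year
#' @inheritParams tally_prevalence
#' @param state A single state name.
#' @return Persons entering `state` during the 4 cycles of that year.
#' @export
tally_incidence <- function(traj, state, year) {
  assert_states(state)
  stopifnot(length(state) == 1L)
  cyc <- (4L * (year - 1L) + 1L):(4L * year)
  if (year < 1 || max(cyc) > traj$n_cycles) stop("year out of range.", call. = FALSE)
  sum(traj$inflow[cyc, state])
}

#' Total deaths over the projection
#' @param traj A `ckd_trajectory`.
#' @return Persons entering death between cycle 0 and the final cycle.
#' @export
tally_deaths <- function(traj) {
  occ <- traj$occupancy
  occ[nrow(occ), "Death"] - occ[1L, "Death"]
}
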