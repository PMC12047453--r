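# Shared fixtures, computed lazily once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fix_pset <- function() fixture("pset", function() generate_parameter_set(1))

fix_baseline <- function() fixture("baseline", function() {
  baseline_schedule(fix_pset())
})

fix_traj <- function() fixture("traj", function() {
  project(fix_pset()$initial, fix_baseline())
})

fix_grid <- function() fixture("grid", function() run_scenario_grid(fix_pset()))

fix_grid_constrained <- function() fixture("grid_constrained", function() {
  run_scenario_grid(fix_pset(), "constrained")
})

# a matrix with canonical dimnames from explicit rows; remaining mass on self
identity_matrix <- function() {
  nm <- state_names()
  diag(length(nm)) |> (\(m) { dimnames(m) <- list(nm, nm); m })()
}

all_death_matrix <- function() {
  nm <- state_names()
  M <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  M[, "Death"] <- 1
  M
}
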