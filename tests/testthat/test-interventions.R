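test_that("management intervention blends treated and untreated progression", {
  expect_equal(intervention_management(0, progression_rr = 0.5)$multipliers, 1)
  expect_equal(intervention_management(0.36, progression_rr = 0.5)$multipliers,
               0.82)  # (1 - 0.36) + 0.36 * 0.5
  expect_equal(intervention_management(1, progression_rr = 0.7)$multipliers, 0.7)
  expect_error(intervention_management(0.36, progression_rr = 1.2), "override")
  expect_equal(intervention_management(0.36, progression_rr = 1.2,
                                       override = TRUE)$multipliers,
               0.64 + 0.36 * 1.2)
})

test_that("SGLT-2 uptake dilutes the risk ratios and ramps from zero", {
  sp <- intervention_sglt2(eligible_fraction = 0.188, cv_rr = 0.75,
                           renal_rr = 0.75)
  expect_equal(effective_multipliers(sp, 0), c(1, 1))
  expect_equal(effective_multipliers(sp, 40), rep(1 - 0.188 * 0.25, 2))
  expect_equal(effective_multipliers(sp, 40)[1], 0.953)
  expect_equal(effective_multipliers(sp, 20), rep(1 - 0.5 * 0.188 * 0.25, 2))
  full <- intervention_sglt2(eligible_fraction = 1, cv_rr = 0.75, renal_rr = 0.75)
  expect_equal(effective_multipliers(full, 40), c(0.75, 0.75))
})

test_that("transplant intervention is a step doubling with a programme cost", {
  sp <- intervention_transplant(increase = 0)
  expect_equal(sp$multipliers, 1)
  expect_equal(sp$fixed_annual_cost, 149000)
  expect_equal(effective_multipliers(sp, 1), 1)

  sp2 <- intervention_transplant(increase = 1)
  expect_equal(effective_multipliers(sp2, 1), 2)   # full effect from cycle 1
  expect_equal(effective_multipliers(sp2, 40), 2)
  # rate-scale doubling of a small cell approximately doubles the probability
  expect_equal(1 - (1 - 0.01)^2, 0.02, tolerance = 1e-2)
})

test_that("applying interventions preserves row-stochasticity and structural zeros", {
  base <- fix_baseline()
  specs <- build_interventions(fix_pset(), base)
  sched <- apply_interventions(base, unname(specs))
  for (cyc in c(1, 20, 40)) {
    M <- matrix_for(sched, cyc, fix_pset()$initial)
    expect_true(all(abs(rowSums(unclass(M)) - 1) < 1e-12))
    expect_true(all(unclass(M)[!attr(M, "adjacency")] == 0))
  }
  # empty spec list leaves the schedule untouched
  expect_identical(apply_interventions(base, list()), base)
})

test_that("interventions sharing a cell compose multiplicatively on rates", {
  base <- fix_baseline()
  mk <- function(m) {
    intervention_management(1, progression_rr = m)
  }
  a <- 0.8; b <- 0.5
  both <- apply_interventions(base, list(mk(a), mk(b)))
  M0 <- unclass(matrix_for(base, 40))
  M1 <- unclass(matrix_for(both, 40))
  cell <- c("Diagnosed CKD G3", "Diagnosed CKD G4")
  p0 <- M0[cell[1], cell[2]]
  expect_equal(M1[cell[1], cell[2]], 1 - (1 - p0)^(a * b), tolerance = 1e-12)
})

test_that("diagnosis intervention calibrates to the target undiagnosed reduction", {
  pset <- fix_pset()
  base <- fix_baseline()
  sp <- build_interventions(pset, base)$diagnosis
  expect_gt(sp$multipliers[1], 1)

  undiag <- c("Undiagnosed CKD G1", "Undiagnosed CKD G2", "Undiagnosed CKD G3")
  end <- function(sched) sum(project(pset$initial, sched)$occupancy[41, undiag])
  achieved <- 1 - end(apply_interventions(base, list(sp))) / end(base)
  expect_equal(achieved, 0.25, tolerance = 1e-3)  # within 0.1%

  # zero target is a no-op; larger targets need larger multipliers
  sp0 <- intervention_diagnosis(0.15, 0, base, pset$initial)
  expect_equal(sp0$multipliers, rep(1, 3))
  sp40 <- intervention_diagnosis(0.15, 0.40, base, pset$initial)
  expect_gt(sp40$multipliers[1], sp$multipliers[1])

  # an unreachable target reports the maximum achievable reduction
  expect_error(intervention_diagnosis(0.15, 0.999, base, pset$initial),
               "maximum achievable reduction")
})

test_that("progression-slowing interventions never enlarge the severe population", {
  pset <- fix_pset()
  base <- fix_baseline()
  specs <- build_interventions(pset, base)
  sev <- c("Diagnosed CKD G5", "Dialysis")
  base_sev <- rowSums(project(pset$initial, base)$occupancy[, sev])
  for (nm in c("management", "sglt2")) {
    traj <- project(pset$initial, apply_interventions(base, list(specs[[nm]])))
    expect_true(all(rowSums(traj$occupancy[, sev]) <= base_sev + 1e-9),
                label = nm)
  }
})

test_that("the capacity constraint binds dialysis to its cap trajectory", {
  pset <- fix_pset()
  base <- fix_baseline()
  cons <- derive_constraint(base, pset$initial, annual_growth_cap = 0.06)
  traj <- project(pset$initial, constrain(base, cons))
  cap <- cons$reference_dialysis * 1.06^((0:40) / 4)
  expect_true(all(traj$occupancy[, "Dialysis"] <= cap * (1 + 1e-9)))
  # conservation still holds under redirection
  expect_true(all(abs(rowSums(traj$occupancy) - sum(pset$initial)) < 1e-6))

  # an effectively infinite cap changes nothing
  free <- constraint_spec(1e6, cons$reference_dialysis,
                          cons$reference_transplant_inflow)
  traj_free <- project(pset$initial, constrain(base, free))
  expect_equal(traj_free$occupancy, project(pset$initial, base)$occupancy)

  # a zero cap with no exits freezes dialysis occupancy
  empty <- data.frame(from_state = "Diagnosed CKD G5", to_state = "Dialysis",
                      quarterly_probability = 0.1, stringsAsFactors = FALSE)
  M <- build_transition_matrix(empty, stats::setNames(rep(0, 16), state_names()),
                               data.frame(age_band = "all", annual_q = 0,
                                          weight = 1))
  zero_cons <- constraint_spec(0, pset$initial[["Dialysis"]], 0)
  trajz <- project(pset$initial, constrain(constant_schedule(M, 8), zero_cons))
  expect_true(all(trajz$occupancy[, "Dialysis"] == pset$initial[["Dialysis"]]))
})
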