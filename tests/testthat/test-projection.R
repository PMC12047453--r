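test_that("an identity schedule leaves the cohort untouched with zero incidence", {
  init <- fix_pset()$initial
  traj <- project(init, constant_schedule(identity_matrix(), n_cycles = 8))
  expect_true(all(apply(traj$occupancy, 1, function(r) all(r == init))))
  expect_true(all(traj$inflow == 0))
  expect_equal(tally_deaths(traj), 0)
  for (y in 1:2) {
    expect_equal(tally_incidence(traj, "Dialysis", y), 0)
    expect_equal(tally_prevalence(traj, "Dialysis", y), init[["Dialysis"]])
  }
})

test_that("an all-death matrix absorbs the full population in one cycle", {
  init <- fix_pset()$initial
  traj <- project(init, constant_schedule(all_death_matrix(), n_cycles = 4))
  expect_equal(traj$occupancy[2, "Death"], sum(init))
  expect_equal(sum(traj$occupancy[2, state_names() != "Death"]), 0)
  expect_equal(tally_prevalence(traj, "Death", 1), sum(init))
  expect_equal(tally_deaths(traj), sum(init) - init[["Death"]])
})

test_that("projection conserves the closed population and death is absorbing", {
  traj <- fix_traj()
  total <- sum(fix_pset()$initial)
  expect_true(all(abs(rowSums(traj$occupancy) - total) < 1e-6))
  expect_true(all(diff(traj$occupancy[, "Death"]) >= 0))
  expect_true(all(traj$occupancy >= 0))
})

test_that("inflow tallies satisfy the conservation identity", {
  traj <- fix_traj()
  M <- unclass(matrix_for(fix_baseline(), 1))
  for (t in c(1, 20, 40)) {
    prev <- traj$occupancy[t, ]
    # occupancy(t, s) = inflow(t, s) + occupancy(t-1, s) * p_ss
    expect_equal(traj$occupancy[t + 1, ],
                 traj$inflow[t, ] + prev * diag(M),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # total deaths equal cumulative inflow into death
  expect_equal(tally_deaths(traj), sum(traj$inflow[, "Death"]),
               tolerance = 1e-6)
})

test_that("year tallies follow the cycle convention (year k = cycles 4k-3..4k)", {
  traj <- fix_traj()
  expect_equal(tally_prevalence(traj, "Dialysis", 10),
               unname(traj$occupancy[41, "Dialysis"]))
  expect_equal(tally_incidence(traj, "Transplantation (acute)", 10),
               sum(traj$inflow[37:40, "Transplantation (acute)"]))
  expect_error(tally_prevalence(traj, "Dialysis", 11), "out of range")
  expect_error(tally_prevalence(traj, "Nope", 1), "Unknown state")
})

test_that("a single-cycle mass move is counted as that year's incidence", {
  nm <- state_names()
  init <- stats::setNames(numeric(16), nm)
  init["Diagnosed CKD G5"] <- 1000
  move_cycle <- 9L  # first cycle of year 3
  sched <- new_schedule(function(cycle, occupancy) {
    M <- identity_matrix()
    if (cycle == move_cycle) {
      M["Diagnosed CKD G5", "Diagnosed CKD G5"] <- 0
      M["Diagnosed CKD G5", "Dialysis"] <- 1
    }
    M
  }, n_cycles = 12)
  traj <- project(init, sched)
  expect_equal(tally_incidence(traj, "Dialysis", 3), 1000)
  expect_equal(tally_incidence(traj, "Dialysis", 2), 0)
})
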