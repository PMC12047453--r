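held_trajectory <- function(state, persons = 1, n_cycles = 4L) {
  init <- stats::setNames(numeric(16), state_names())
  init[state] <- persons
  project(init, constant_schedule(identity_matrix(), n_cycles = n_cycles))
}

test_that("discount factors compound the annual rate quarterly from model start", {
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(4, 0.035), 1 / 1.035)
  expect_equal(discount_factor(40, 0.035), 1.035^-10)
  expect_equal(discount_factor(0:8, 0), rep(1, 9))
  expect_error(discount_factor(-1), ">= 0")
  expect_error(discount_factor(1, -1.5), "exceed -1")
})

test_that("one undiscounted person-year on dialysis costs 41741.36 GBP and yields 0.58 QALYs", {
  econ <- default_economic_inputs(discount_rate_annual = 0)
  res <- accrue(held_trajectory("Dialysis"), econ)
  expect_equal(res$total_discounted_cost, 4 * (8595.16 + 1840.18))
  expect_equal(res$total_discounted_cost, 41741.36)
  expect_equal(res$total_discounted_qalys, 0.58)
})

test_that("accrual is linear in occupancy and respects discounting bounds", {
  econ0 <- default_economic_inputs(discount_rate_annual = 0)
  econ <- default_economic_inputs()
  traj <- fix_traj()
  undisc <- accrue(traj, econ0)
  disc <- accrue(traj, econ)
  expect_lt(disc$total_discounted_cost, undisc$total_discounted_cost)
  expect_lt(disc$total_discounted_qalys, undisc$total_discounted_qalys)

  # zero inputs accrue nothing
  zero <- economic_inputs(
    stats::setNames(rep(0, 16), state_names()),
    stats::setNames(rep(0, 16), state_names()))
  expect_equal(accrue(traj, zero)$total_discounted_cost, 0)
  expect_equal(accrue(traj, zero)$total_discounted_qalys, 0)

  # closed-form limit: all utilities 1 and no deaths -> population * horizon
  u1 <- stats::setNames(rep(1, 16), state_names())
  u1["Death"] <- 0
  live <- economic_inputs(stats::setNames(rep(0, 16), state_names()), u1,
                          discount_rate_annual = 0)
  held <- held_trajectory("Diagnosed CKD G3", persons = 1000, n_cycles = 40)
  expect_equal(accrue(held, live)$total_discounted_qalys, 1000 * 10)
})

test_that("accrual over split horizons is additive with a common discount origin", {
  econ <- default_economic_inputs()
  traj <- fix_traj()
  full <- accrue(traj, econ)
  expect_equal(full$total_discounted_cost, sum(full$cost))
  expect_equal(sum(full$cost[1:20]) + sum(full$cost[21:40]),
               full$total_discounted_cost)
  expect_equal(sum(full$qaly[1:20]) + sum(full$qaly[21:40]),
               full$total_discounted_qalys)
})

test_that("fixed intervention costs are spread evenly per quarter and discounted", {
  traj <- held_trajectory("No kidney disease", n_cycles = 40)
  econ0 <- default_economic_inputs(discount_rate_annual = 0,
                                   fixed_annual_costs = 149000)
  expect_equal(accrue(traj, econ0)$total_discounted_cost, 149000 * 10)
  econ <- default_economic_inputs(fixed_annual_costs = 149000)
  expect_equal(accrue(traj, econ)$total_discounted_cost,
               sum(149000 / 4 * discount_factor(1:40, 0.035)))
})

test_that("incremental comparison yields signed ICERs and dominance flags", {
  mk <- function(cost, qalys) {
    structure(list(total_discounted_cost = cost, total_discounted_qalys = qalys,
                   cost = numeric(), qaly = numeric(), tallies = list()),
              class = "ckd_scenario_result")
  }
  base <- mk(70664656235, 71681793)

  same <- compare(base, base)
  expect_equal(same$delta_cost, 0)
  expect_true(is.na(same$icer))
  expect_equal(same$dominance_flag, "none")

  # published-scale worked example: delta cost / delta QALYs
  comb <- compare(base, mk(base$total_discounted_cost + 371335097,
                           base$total_discounted_qalys + 48381))
  expect_equal(comb$delta_cost / comb$delta_qalys, comb$icer)
  expect_equal(round(comb$icer), 7675)

  dom <- compare(base, mk(base$total_discounted_cost - 51468036,
                          base$total_discounted_qalys + 1145))
  expect_lt(dom$icer, 0)
  expect_equal(dom$dominance_flag, "dominant")

  # antisymmetry
  alt <- mk(7.1e10, 7.2e7)
  expect_equal(compare(base, alt)$delta_cost, -compare(alt, base)$delta_cost)
  expect_equal(compare(base, alt)$delta_qalys, -compare(alt, base)$delta_qalys)
})

test_that("the interaction factor is the combined gain minus the summed individual gains", {
  cea <- function(dq) structure(list(delta_cost = 0, delta_qalys = dq,
                                     icer = NA, dominance_flag = "none"),
                                class = "ckd_cea")
  inds <- lapply(c(1262, 20079, 25735, 1145), cea)
  expect_equal(interaction_factor(cea(48381), inds), 160)
  expect_equal(interaction_factor(cea(48381), rev(inds)), 160)
  expect_equal(interaction_factor(cea(sum(c(1, 2, 3))), lapply(1:3, cea)), 0)
})
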