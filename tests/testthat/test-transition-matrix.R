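zero_rr <- function() {
  stats::setNames(rep(0, 16), state_names())
}
flat_lt <- function(q = 0.01) data.frame(age_band = "all", annual_q = q, weight = 1)

empty_progression <- function() {
  data.frame(from_state = character(), to_state = character(),
             quarterly_probability = numeric(), stringsAsFactors = FALSE)
}

test_that("an empty progression table with zero mortality yields the identity matrix", {
  M <- build_transition_matrix(empty_progression(), zero_rr(), flat_lt())
  nm <- state_names()
  expected <- diag(length(nm)); dimnames(expected) <- list(nm, nm)
  # tunnel states route their whole mass to the mandated exit instead of self
  expected["Transplantation (acute)", "Transplantation (acute)"] <- 0
  expected["Transplantation (acute)", "Transplantation (post-acute)"] <- 1
  expected["CVD (acute)", "CVD (acute)"] <- 0
  expected["CVD (acute)", "CVD (post-acute)"] <- 1
  expect_equal(unclass(M)[, ], expected[, ], ignore_attr = TRUE)
  expect_equal(dimnames(M), list(nm, nm))
})

test_that("residual mass goes to the self-transition", {
  rr <- zero_rr(); rr["Diagnosed CKD G3"] <- 1
  # choose the life table so the quarterly death probability is exactly 0.1
  q_annual <- quarterly_to_annual(0.1)
  prog <- data.frame(
    from_state = c("Diagnosed CKD G3", "Diagnosed CKD G3"),
    to_state = c("Diagnosed CKD G4", "CVD (acute)"),
    quarterly_probability = c(0.2, 0.1), stringsAsFactors = FALSE)
  M <- build_transition_matrix(prog, rr, flat_lt(q_annual))
  expect_equal(M["Diagnosed CKD G3", "Death"], 0.1)
  expect_equal(M["Diagnosed CKD G3", "Diagnosed CKD G3"], 0.6)
})

test_that("the synthetic fixture matrix is row-stochastic with structural zeros", {
  M <- matrix_for(fix_baseline(), 1)
  expect_true(all(abs(rowSums(unclass(M)) - 1) < 1e-12))
  expect_true(all(unclass(M) >= 0 & unclass(M) <= 1))
  A <- attr(M, "adjacency")
  expect_true(all(unclass(M)[!A] == 0))
  expect_equal(unclass(M)["Death", ], as.numeric(state_names() == "Death"),
               ignore_attr = TRUE)
  sp <- ckd_states()
  expect_true(all(diag(unclass(M))[sp$tunnel] == 0))
})

test_that("structural violations and negative entries are rejected by name", {
  bad <- data.frame(from_state = "Dialysis", to_state = "Diagnosed CKD G1",
                    quarterly_probability = 0.1, stringsAsFactors = FALSE)
  expect_error(build_transition_matrix(bad, zero_rr(), flat_lt()),
               "Dialysis -> Diagnosed CKD G1")
  neg <- data.frame(from_state = "Diagnosed CKD G3", to_state = "Diagnosed CKD G4",
                    quarterly_probability = -0.1, stringsAsFactors = FALSE)
  expect_error(build_transition_matrix(neg, zero_rr(), flat_lt()), "Negative")
})

test_that("rows exceeding 1 trigger the competing-risk rescale", {
  rr <- zero_rr(); rr["Diagnosed CKD G5"] <- 1
  q_annual <- quarterly_to_annual(0.2)   # quarterly death 0.2
  prog <- data.frame(
    from_state = c("Diagnosed CKD G5", "Diagnosed CKD G5"),
    to_state = c("Dialysis", "Transplantation (acute)"),
    quarterly_probability = c(0.7, 0.2), stringsAsFactors = FALSE)
  expect_warning(M <- build_transition_matrix(prog, rr, flat_lt(q_annual)),
                 "rescaled")
  expect_equal(sum(M["Diagnosed CKD G5", ]), 1, tolerance = 1e-12)
  # non-death entries keep their proportions: 0.7 : 0.2 scaled into 0.8
  expect_equal(M["Diagnosed CKD G5", "Dialysis"] /
               M["Diagnosed CKD G5", "Transplantation (acute)"], 3.5)
  expect_equal(M["Diagnosed CKD G5", "Death"], 0.2)
})
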