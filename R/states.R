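#' The 16-state CKD model state space
#'
#' Returns the canonical state space of the population-level CKD model: an
#' at-risk compartment (the UK adult population without kidney disease),
#' undiagnosed CKD stages G1-G4, diagnosed CKD stages G1-G5, kidney
#' replacement therapy states (dialysis, acute and post-acute
#' transplantation), acute and post-acute cardiovascular disease states, and
#' an absorbing death state. Stage 5 CKD is always diagnosed, so no
#' undiagnosed G5 state exists. The two acute states are tunnel states:
#' occupied for exactly one quarterly cycle before a mandated exit.
#'
#' @return A data frame with one row per state and columns `name` (the
#'   canonical label, used throughout as matrix dimnames), `ckd_stage`
#'   (0 = no kidney disease, 1-5 = CKD stage, `NA` where staging does not
#'   apply), `diagnosed` (logical; `NA` where not meaningful), `tunnel`,
#'   `absorbing`, and `category`.
#' @export
#' @examples
#' ckd_states()
ckd_states <- function() {
  df <- data.frame(
    name = c(
      "No kidney disease",
      "Undiagnosed CKD G1", "Undiagnosed CKD G2",
      "Undiagnosed CKD G3", "Undiagnosed CKD G4",
      "Diagnosed CKD G1", "Diagnosed CKD G2", "Diagnosed CKD G3",
      "Diagnosed CKD G4", "Diagnosed CKD G5",
      "Transplantation (acute)", "Transplantation (post-acute)",
      "Dialysis",
      "CVD (acute)", "CVD (post-acute)",
      "Death"
    ),
    ckd_stage = c(0L, 1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L, 5L,
                  5L, 5L, 5L, NA_integer_, NA_integer_, NA_integer_),
    diagnosed = c(NA, FALSE, FALSE, FALSE, FALSE,
                  TRUE, TRUE, TRUE, TRUE, TRUE,
                  TRUE, TRUE, TRUE, NA, NA, NA),
    tunnel = c(rep(FALSE, 10), TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    absorbing = c(rep(FALSE, 15), TRUE),
    category = c("at_risk",
                 rep("ckd", 9),
                 "transplant_acute", "transplant_post", "dialysis",
                 "cvd_acute", "cvd_post", "death"),
    stringsAsFactors = FALSE
  )
  class(df) <- c("ckd_states", "data.frame")
  df
}

#' State names of the canonical space
#' @param space A state space from [ckd_states()].
#' @return Character vector of the 16 canonical state names.
#' @export
state_names <- function(space = ckd_states()) space$name

#' Mandatory exit state for each tunnel state
#'
#' Tunnel states last exactly one cycle; survivors move to the mapped
#' post-acute state.
#' @param space A state space from [ckd_states()].
#' @return Named character vector mapping tunnel state -> exit state.
#' @export
tunnel_exits <- function(space = ckd_states()) {
  c("Transplantation (acute)" = "Transplantation (post-acute)",
    "CVD (acute)" = "CVD (post-acute)")
}

# internal: names of frequently used state groups
.state_groups <- function() {
  list(
    ckd12 = c("Undiagnosed CKD G1", "Undiagnosed CKD G2",
              "Diagnosed CKD G1", "Diagnosed CKD G2"),
    ckd35 = c("Undiagnosed CKD G3", "Undiagnosed CKD G4",
              "Diagnosed CKD G3", "Diagnosed CKD G4", "Diagnosed CKD G5"),
    undiagnosed13 = c("Undiagnosed CKD G1", "Undiagnosed CKD G2",
                      "Undiagnosed CKD G3")
  )
}

#' Validate a vector of state names against the canonical space
#' @param x Character vector of state names.
#' @param space A state space.
#' @return Invisibly `x`; errors on any unknown name.
#' @export
assert_states <- function(x, space = ckd_states()) {
  bad <- setdiff(x, space$name)
  if (length(bad)) {
    stop("Unknown state name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
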