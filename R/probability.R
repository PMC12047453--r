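#' Convert an annual transition probability to a quarterly one
#'
#' Uses the constant-rate transformation: the annual probability is turned
#' into a rate r = -ln(1 - p_annual), the rate is divided by four, and the
#' quarterly probability recovered as 1 - exp(-r/4). The round trip
#' 1 - (1 - p_quarterly)^4 = p_annual holds exactly in floating point up to
#' rounding, since (1 - p_q)^4 = exp(-r).
#'
#' @param p_annual Annual probability in `[0, 1)`.
#' @return Quarterly probability.
#' @export
#' @examples
#' annual_to_quarterly(0.3)           # ~0.0853
#' 1 - (1 - annual_to_quarterly(0.3))^4  # 0.3
annual_to_quarterly <- function(p_annual) {
  if (any(!is.finite(p_annual)) || any(p_annual < 0) || any(p_annual >= 1)) {
    stop("p_annual must lie in [0, 1): the rate -ln(1 - p) is undefined at 1.",
         call. = FALSE)
  }
  r <- -log(1 - p_annual)
  1 - exp(-r / 4)
}

#' Convert a quarterly transition probability to an annual one
#'
#' Inverse of [annual_to_quarterly()]: p_annual = 1 - (1 - p_quarterly)^4.
#'
#' @param p_quarterly Quarterly probability in `[0, 1)`.
#' @return Annual probability.
#' @export
quarterly_to_annual <- function(p_quarterly) {
  if (any(!is.finite(p_quarterly)) || any(p_quarterly < 0) || any(p_quarterly >= 1)) {
    stop("p_quarterly must lie in [0, 1).", call. = FALSE)
  }
  1 - (1 - p_quarterly)^4
}

#' Quarterly death probability for a disease state
#'
#' Combines a life table with a per-state relative risk of death. The
#' age-weighted mean annual mortality q-bar = sum(w_a * q_a) is converted to
#' a rate, multiplied by the relative risk on the rate scale (so the result
#' stays a valid probability for any rr >= 0), and converted to a quarterly
#' probability.
#'
#' @param life_table Data frame with columns `age_band`, `annual_q` (annual
#'   mortality probability in `[0,1]`) and `weight` (non-negative population
#'   weights summing to 1).
#' @param rr Relative risk of death for the state (>= 0; 1 for the at-risk
#'   population).
#' @return Quarterly death probability, capped strictly below 1.
#' @export
state_death_probability <- function(life_table, rr) {
  validate_life_table(life_table)
  if (!is.finite(rr) || rr < 0) stop("rr must be a non-negative number.", call. = FALSE)
  qbar <- sum(life_table$weight * life_table$annual_q)
  rate <- -log(1 - qbar) * rr
  p <- 1 - exp(-rate / 4)
  if (p >= 1) {
    warning("Quarterly death probability reached 1; capped at 1 - 1e-9.")
    p <- 1 - 1e-9
  }
  p
}

#' Validate a life table
#' @param life_table Data frame with `age_band`, `annual_q`, `weight`.
#' @return Invisibly the life table; errors if malformed.
#' @export
validate_life_table <- function(life_table) {
  need <- c("age_band", "annual_q", "weight")
  if (!all(need %in% names(life_table))) {
    stop("Life table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(life_table$annual_q < 0 | life_table$annual_q > 1)) {
    stop("Life-table annual_q values must lie in [0, 1].", call. = FALSE)
  }
  if (any(life_table$weight < 0)) stop("Life-table weights must be >= 0.", call. = FALSE)
  if (abs(sum(life_table$weight) - 1) > 1e-8) {
    stop("Life-table weights must sum to 1.", call. = FALSE)
  }
  invisible(life_table)
}
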