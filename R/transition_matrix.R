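#' Build a quarterly transition matrix
#'
#' Assembles a row-stochastic 16 x 16 quarterly transition matrix from a
#' table of progression probabilities, a mortality model and a life table.
#' Per row: the death probability comes from [state_death_probability()]
#' (life-table mortality scaled by the state's relative risk on the rate
#' scale); the stated non-death transitions are taken as given; residual
#' mass goes to the self-transition, except in tunnel states where it goes
#' to the mandated exit state. If death plus the stated transitions exceed
#' 1, the non-death entries are rescaled proportionally (competing-risk
#' rescale) with a warning.
#'
#' @param progression Data frame with columns `from_state`, `to_state`,
#'   `quarterly_probability`; pairs must lie in the adjacency, and must not
#'   name death or a self-transition (both are derived).
#' @param rr Named numeric vector: relative risk of death per state
#'   (1 for the at-risk state; the death row ignores it).
#' @param life_table Life table, see [state_death_probability()].
#' @param space State space from [ckd_states()].
#' @param adjacency Logical adjacency matrix, see [default_adjacency()].
#' @return A `ckd_transition_matrix`: a numeric matrix with state dimnames
#'   and the adjacency kept as an attribute.
#' @export
build_transition_matrix <- function(progression, rr, life_table,
                                    space = ckd_states(),
                                    adjacency = default_adjacency(space)) {
  nm <- space$name
  if (nrow(progression)) {
    assert_states(progression$from_state, space)
    assert_states(progression$to_state, space)
    if (any(progression$quarterly_probability < 0)) {
      stop("Negative transition probabilities are not allowed.", call. = FALSE)
    }
    ok <- adjacency[cbind(progression$from_state, progression$to_state)]
    if (!all(ok)) {
      bad <- progression[!ok, , drop = FALSE]
      stop("Transition(s) outside the structural adjacency: ",
           paste(sprintf("%s -> %s", bad$from_state, bad$to_state),
                 collapse = "; "), call. = FALSE)
    }
    if (any(progression$to_state == "Death") ||
        any(progression$from_state == progression$to_state)) {
      stop("Death and self-transitions are derived; do not state them in the ",
           "progression table.", call. = FALSE)
    }
  }
  if (is.null(names(rr)) || !all(setdiff(nm, "Death") %in% names(rr))) {
    stop("rr must be a vector named by every non-death state.", call. = FALSE)
  }

  M <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  exits <- tunnel_exits(space)

  for (s in nm) {
    if (s == "Death") { M[s, s] <- 1; next }
    M[s, "Death"] <- state_death_probability(life_table, rr[[s]])
    rows <- progression[progression$from_state == s, , drop = FALSE]
    if (nrow(rows)) {
      p <- tapply(rows$quarterly_probability, rows$to_state, sum)
      M[s, names(p)] <- p
    }
    stated <- sum(M[s, ]) - M[s, "Death"]
    if (M[s, "Death"] + stated > 1) {
      warning(sprintf(
        "Row '%s': death + stated transitions sum to %.6f > 1; non-death entries rescaled.",
        s, M[s, "Death"] + stated))
      keep <- setdiff(nm, "Death")
      M[s, keep] <- M[s, keep] * (1 - M[s, "Death"]) / stated
      stated <- 1 - M[s, "Death"]
    }
    residual <- 1 - M[s, "Death"] - stated
    home <- if (s %in% names(exits)) exits[[s]] else s
    M[s, home] <- M[s, home] + residual
  }

  new_transition_matrix(M, adjacency)
}

# constructor + validator ----------------------------------------------------

new_transition_matrix <- function(M, adjacency) {
  attr(M, "adjacency") <- adjacency
  class(M) <- c("ckd_transition_matrix", class(M))
  validate_transition_matrix(M)
}

#' Validate a transition matrix
#'
#' Checks row sums (1 within 1e-12), entry range, the absorbing death row,
#' zero entries on structural zeros, and zero self-transition in tunnel
#' states.
#'
#' @param M A matrix produced by [build_transition_matrix()] (or any matrix
#'   with state dimnames and an `adjacency` attribute).
#' @param space State space.
#' @return Invisibly `M`; errors on violation.
#' @export
validate_transition_matrix <- function(M, space = ckd_states()) {
  nm <- space$name
  stopifnot(identical(rownames(M), nm), identical(colnames(M), nm))
  if (any(M < 0) || any(M > 1)) stop("Entries must lie in [0, 1].", call. = FALSE)
  if (any(abs(rowSums(M) - 1) > 1e-12)) {
    stop("Every row must sum to 1 within 1e-12.", call. = FALSE)
  }
  dd <- as.numeric(nm == "Death")
  if (any(M["Death", ] != dd)) stop("Death row must be the identity row.", call. = FALSE)
  A <- attr(M, "adjacency")
  if (!is.null(A) && any(M[!A] != 0)) {
    stop("Non-zero entry on a structurally disallowed transition.", call. = FALSE)
  }
  tun <- nm[space$tunnel]
  if (any(diag(unclass(M))[match(tun, nm)] != 0)) {
    stop("Tunnel states must have zero self-transition probability.", call. = FALSE)
  }
  invisible(M)
}

# Re-close rows after cell edits: death column is held fixed, the residual
# home cell (self, or the tunnel exit) absorbs what is left; if the edited
# exits exceed 1 - death, non-death exits are rescaled proportionally.
close_rows <- function(M, space = ckd_states()) {
  nm <- space$name
  exits <- tunnel_exits(space)
  for (s in setdiff(nm, "Death")) {
    home <- if (s %in% names(exits)) exits[[s]] else s
    other <- setdiff(nm, c("Death", home))
    stated <- sum(M[s, other])
    if (M[s, "Death"] + stated > 1) {
      M[s, other] <- M[s, other] * (1 - M[s, "Death"]) / stated
      stated <- 1 - M[s, "Death"]
    }
    M[s, home] <- 1 - M[s, "Death"] - stated
  }
  M
}
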