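#' Read and write model parameter files
#'
#' All inputs are plain CSV. File dialects:
#' \itemize{
#'   \item transition table: `from_state,to_state,quarterly_probability`;
#'   \item initial occupancy: `state,persons`;
#'   \item life table: `age_band,annual_q,weight`;
#'   \item relative risks: `state,rr`;
#'   \item economic inputs: `state,quarterly_cost_gbp,utility`, with the
#'     dialysis transport add-on keyed
#'     `Dialysis: Transportation to dialysis`;
#'   \item intervention parameters: `parameter,value`.
#' }
#' @name parameter_io
NULL

.read_csv <- function(path, need) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname parameter_io
#' @param path File path.
#' @return `read_transition_table`: the progression data frame. A warning
#'   fires if any undiagnosed stage-progression probability falls below its
#'   diagnosed counterpart (undiagnosed patients are expected to progress
#'   at least as fast).
#' @export
read_transition_table <- function(path) {
  df <- .read_csv(path, c("from_state", "to_state", "quarterly_probability"))
  assert_states(df$from_state); assert_states(df$to_state)
  if (any(df$quarterly_probability < 0 | df$quarterly_probability > 1)) {
    stop(path, ": probabilities must lie in [0, 1].", call. = FALSE)
  }
  check_undiagnosed_faster(df)
  df
}

#' Warn when undiagnosed progression is slower than diagnosed
#' @param progression Progression table.
#' @return Invisibly `TRUE` if the assumption holds, else `FALSE` (with a
#'   warning).
#' @export
check_undiagnosed_faster <- function(progression) {
  get_p <- function(from, to) {
    i <- which(progression$from_state == from & progression$to_state == to)
    if (length(i)) progression$quarterly_probability[i[1]] else NA_real_
  }
  pairs <- data.frame(
    u_from = sprintf("Undiagnosed CKD G%d", 1:4),
    u_to = c(sprintf("Undiagnosed CKD G%d", 2:4), "Diagnosed CKD G5"),
    d_from = sprintf("Diagnosed CKD G%d", 1:4),
    d_to = sprintf("Diagnosed CKD G%d", 2:5)
  )
  ok <- TRUE
  for (i in seq_len(nrow(pairs))) {
    pu <- get_p(pairs$u_from[i], pairs$u_to[i])
    pd <- get_p(pairs$d_from[i], pairs$d_to[i])
    if (!is.na(pu) && !is.na(pd) && pu < pd) {
      ok <- FALSE
      warning(sprintf(
        "Undiagnosed stage progression %s -> %s (%.5f) is below its diagnosed counterpart (%.5f).",
        pairs$u_from[i], pairs$u_to[i], pu, pd))
    }
  }
  invisible(ok)
}

#' @rdname parameter_io
#' @return `read_initial_occupancy`: named numeric vector over the 16 states.
#' @export
read_initial_occupancy <- function(path) {
  df <- .read_csv(path, c("state", "persons"))
  assert_states(df$state)
  if (any(df$persons < 0)) stop(path, ": persons must be >= 0.", call. = FALSE)
  out <- stats::setNames(numeric(16), state_names())
  out[df$state] <- df$persons
  out
}

#' @rdname parameter_io
#' @return `read_life_table`: validated life-table data frame.
#' @export
read_life_table <- function(path) {
  validate_life_table(.read_csv(path, c("age_band", "annual_q", "weight")))
}

#' @rdname parameter_io
#' @return `read_relative_risks`: named numeric vector of rr by state.
#' @export
read_relative_risks <- function(path) {
  df <- .read_csv(path, c("state", "rr"))
  assert_states(df$state)
  if (any(df$rr < 0)) stop(path, ": rr must be >= 0.", call. = FALSE)
  stats::setNames(df$rr, df$state)
}

#' @rdname parameter_io
#' @param discount_rate_annual Annual discount rate for the returned inputs.
#' @return `read_economic_inputs`: a `ckd_econ` object.
#' @export
read_economic_inputs <- function(path, discount_rate_annual = 0.035) {
  df <- .read_csv(path, c("state", "quarterly_cost_gbp", "utility"))
  transport_key <- "Dialysis: Transportation to dialysis"
  tr <- df$state == transport_key
  transport <- if (any(tr)) df$quarterly_cost_gbp[tr][1] else 0
  df <- df[!tr, , drop = FALSE]
  assert_states(df$state)
  economic_inputs(stats::setNames(df$quarterly_cost_gbp, df$state),
                  stats::setNames(df$utility, df$state),
                  transport_cost_dialysis = transport,
                  discount_rate_annual = discount_rate_annual)
}

#' @rdname parameter_io
#' @return `read_intervention_parameters`: named list of parameter values.
#' @export
read_intervention_parameters <- function(path) {
  df <- .read_csv(path, c("parameter", "value"))
  as.list(stats::setNames(df$value, df$parameter))
}

#' Write a parameter set to a directory of CSV files
#'
#' Emits the exact dialects the loaders consume: `transitions.csv`,
#' `initial_occupancy.csv`, `life_table.csv`, `relative_risks.csv`,
#' `economic_inputs.csv`, `intervention_parameters.csv`.
#'
#' @param pset A `ckd_parameter_set`.
#' @param dir Output directory (created if absent).
#' @return Invisibly the vector of written file paths.
#' @export
write_parameter_set <- function(pset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file) {
    p <- file.path(dir, file)
    utils::write.csv(df, p, row.names = FALSE, quote = TRUE)
    p
  }
  paths <- c(
    w(pset$progression, "transitions.csv"),
    w(data.frame(state = names(pset$initial), persons = unname(pset$initial)),
      "initial_occupancy.csv"),
    w(pset$life_table, "life_table.csv"),
    w(data.frame(state = names(pset$rr), rr = unname(pset$rr)),
      "relative_risks.csv"),
    w(rbind(
        data.frame(state = names(pset$econ$cost),
                   quarterly_cost_gbp = unname(pset$econ$cost),
                   utility = unname(pset$econ$utility)),
        data.frame(state = "Dialysis: Transportation to dialysis",
                   quarterly_cost_gbp = pset$econ$transport_cost_dialysis,
                   utility = NA_real_)),
      "economic_inputs.csv"),
    w(data.frame(parameter = names(pset$params),
                 value = unlist(pset$params, use.names = FALSE)),
      "intervention_parameters.csv")
  )
  invisible(paths)
}

#' Load a parameter set from a directory written by [write_parameter_set()]
#' @param dir Directory containing the six CSV files.
#' @param discount_rate_annual Annual discount rate.
#' @return A `ckd_parameter_set`.
#' @export
read_parameter_set <- function(dir, discount_rate_annual = 0.035) {
  f <- function(x) file.path(dir, x)
  structure(list(
    progression = read_transition_table(f("transitions.csv")),
    initial = read_initial_occupancy(f("initial_occupancy.csv")),
    life_table = read_life_table(f("life_table.csv")),
    rr = read_relative_risks(f("relative_risks.csv")),
    econ = read_economic_inputs(f("economic_inputs.csv"), discount_rate_annual),
    params = read_intervention_parameters(f("intervention_parameters.csv")),
    adjacency = default_adjacency()
  ), class = "ckd_parameter_set")
}
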