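#' Parameter accessors for sensitivity analysis
#'
#' Parameters are addressed by path strings into a `ckd_parameter_set`:
#' \itemize{
#'   \item `"param/<name>"` — an intervention parameter in `pset$params`;
#'   \item `"cell/<from>/<to>"` — a quarterly probability in the
#'     progression table;
#'   \item `"cost/<state>"`, `"utility/<state>"` — economic inputs.
#' }
#' @param pset A `ckd_parameter_set`.
#' @param path Accessor path string.
#' @return `pset_get` returns the current value; `pset_set` the modified
#'   parameter set. Probabilities pushed outside `[0, 1)` are clipped with
#'   a warning; negative costs are clipped to 0.
#' @export
pset_get <- function(pset, path) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  switch(parts[1],
    param = pset$params[[parts[2]]],
    cell = {
      i <- which(pset$progression$from_state == parts[2] &
                 pset$progression$to_state == parts[3])
      if (!length(i)) stop("No progression cell ", parts[2], " -> ", parts[3],
                           call. = FALSE)
      pset$progression$quarterly_probability[i]
    },
    cost = pset$econ$cost[[parts[2]]],
    utility = pset$econ$utility[[parts[2]]],
    stop("Unknown accessor path: ", path, call. = FALSE)
  )
}

#' @rdname pset_get
#' @param value New value.
#' @export
pset_set <- function(pset, path, value) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  clip_prob <- function(x) {
    if (x < 0 || x >= 1) {
      warning("Perturbed probability ", signif(x, 4), " clipped to [0, 1).")
      x <- min(max(x, 0), 1 - 1e-9)
    }
    x
  }
  switch(parts[1],
    param = { pset$params[[parts[2]]] <- value },
    cell = {
      i <- which(pset$progression$from_state == parts[2] &
                 pset$progression$to_state == parts[3])
      if (!length(i)) stop("No progression cell ", parts[2], " -> ", parts[3],
                           call. = FALSE)
      pset$progression$quarterly_probability[i] <- clip_prob(value)
    },
    cost = {
      if (value < 0) { warning("Negative cost clipped to 0."); value <- 0 }
      pset$econ$cost[[parts[2]]] <- value
    },
    utility = { pset$econ$utility[[parts[2]]] <- clip_prob(value) },
    stop("Unknown accessor path: ", path, call. = FALSE)
  )
  pset
}

#' Default one-way sensitivity parameters
#'
#' The seven variables varied in the tornado analysis: the effect of each
#' of the four interventions, the two baseline kidney-replacement-therapy
#' transition probabilities, and CKD incidence. Perturbations are relative
#' (+/-20%, except +/-7% for the transplantation intervention, whose live
#' donor pool is a small subset of overall transplant numbers).
#'
#' @return Data frame with `parameter`, `path`, `low`, `high` (relative
#'   perturbations).
#' @export
default_sensitivity_parameters <- function() {
  data.frame(
    parameter = c(
      "Diagnosis reduction target (intervention 1)",
      "ACEi/ARB progression effect (intervention 2)",
      "SGLT-2 eligible fraction (intervention 3)",
      "Pre-emptive transplant increase (intervention 4)",
      "Baseline G5 to dialysis probability",
      "Baseline G5 to transplantation probability",
      "CKD incidence"
    ),
    path = c(
      "param/diagnosis_reduction",
      "param/progression_rr",
      "param/sglt2_eligible",
      "param/transplant_increase",
      "cell/Diagnosed CKD G5/Dialysis",
      "cell/Diagnosed CKD G5/Transplantation (acute)",
      "cell/No kidney disease/Undiagnosed CKD G1"
    ),
    low = c(-0.20, -0.20, -0.20, -0.07, -0.20, -0.20, -0.20),
    high = c(0.20, 0.20, 0.20, 0.07, 0.20, 0.20, 0.20),
    stringsAsFactors = FALSE
  )
}

#' One-way (tornado) sensitivity analysis
#'
#' For each parameter the model is re-run twice — once at
#' `value * (1 + low)` and once at `value * (1 + high)` — and the ICER of
#' the combined interventions versus baseline recomputed from scratch.
#' Entries are sorted by descending bar width. The analysis is
#' deterministic and re-entrant: runs share no state, so parameter order
#' cannot affect the result.
#'
#' @param pset A `ckd_parameter_set` at base-case values.
#' @param params Data frame as from [default_sensitivity_parameters()].
#' @param scenario `"base"` or `"constrained"`.
#' @return A `ckd_tornado` data frame with `parameter`, `icer_low`,
#'   `icer_high`, `width`, plus attribute `base_icer`.
#' @export
one_way <- function(pset, params = default_sensitivity_parameters(),
                    scenario = "base") {
  stopifnot(nrow(params) >= 1)
  base_icer <- combined_comparison(pset, scenario)$icer

  run_at <- function(path, rel) {
    v <- pset_get(pset, path)
    combined_comparison(pset_set(pset, path, v * (1 + rel)), scenario)$icer
  }
  icer_low <- mapply(run_at, params$path, params$low)
  icer_high <- mapply(run_at, params$path, params$high)

  out <- data.frame(parameter = params$parameter,
                    icer_low = as.numeric(icer_low),
                    icer_high = as.numeric(icer_high),
                    stringsAsFactors = FALSE)
  out$width <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$width), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  class(out) <- c("ckd_tornado", "data.frame")
  out
}
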