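#' Patient-count table for a scenario grid
#'
#' One row per scenario (baseline, each intervention, combined, and the
#' baseline-vs-combined difference): year-10 prevalence of CKD stages 1-2,
#' stages 3-5 and dialysis; year-10 incidence of transplantation and acute
#' cardiovascular events; and total deaths over years 1-10.
#'
#' @param grid A `ckd_scenario_grid` from [run_scenario_grid()].
#' @return Data frame of raw (unrounded) person counts.
#' @export
patient_count_table <- function(grid) {
  row_of <- function(r) {
    t <- r$tallies
    data.frame(ckd12_prevalence_y10 = t$ckd12_prevalence_y10,
               ckd35_prevalence_y10 = t$ckd35_prevalence_y10,
               dialysis_prevalence_y10 = t$dialysis_prevalence_y10,
               transplant_incidence_y10 = t$transplant_incidence_y10,
               cvd_incidence_y10 = t$cvd_incidence_y10,
               deaths_total = t$deaths_total)
  }
  tab <- do.call(rbind, lapply(grid$results, row_of))
  diff <- tab["combined", ] - tab["baseline", ]
  tab <- rbind(tab, difference = diff)
  cbind(scenario = rownames(tab), tab, row.names = NULL)
}

#' Economics table for a scenario grid
#'
#' Baseline absolute discounted direct costs and QALYs, then incremental
#' costs, QALYs and the signed ICER for each intervention and the combined
#' set, versus the baseline.
#'
#' @param grid A `ckd_scenario_grid`.
#' @return Data frame with raw values and display columns rounded the way
#'   results are conventionally printed (nearest GBP, whole QALYs).
#' @export
economics_table <- function(grid) {
  base <- grid$results$baseline
  rows <- lapply(names(grid$comparisons), function(nmn) {
    cc <- grid$comparisons[[nmn]]
    data.frame(scenario = nmn, delta_cost = cc$delta_cost,
               delta_qalys = cc$delta_qalys, icer = cc$icer,
               dominance = cc$dominance_flag)
  })
  tab <- rbind(
    data.frame(scenario = "baseline",
               delta_cost = base$total_discounted_cost,
               delta_qalys = base$total_discounted_qalys,
               icer = NA_real_, dominance = "none"),
    do.call(rbind, rows)
  )
  tab$display_cost <- round(tab$delta_cost)
  tab$display_qalys <- round(tab$delta_qalys)
  tab$display_icer <- round(tab$icer)
  tab
}

#' Run a configured analysis and write reports
#'
#' The reporting entry point: loads (or takes) a parameter set, runs the
#' scenario grid, and writes `patient_counts.csv`, `economics.csv` and a
#' `manifest.json` recording input file hashes, the scenario, horizon,
#' discount rate, interaction factor and package version, so any emitted
#' number can be traced to its inputs and reproduced. Deterministic: the
#' same configuration always produces identical report files.
#'
#' @param pset A `ckd_parameter_set`, or a directory path readable by
#'   [read_parameter_set()].
#' @param out_dir Output directory.
#' @param scenario `"base"` or `"constrained"`.
#' @param n_cycles Horizon (default 40).
#' @return Invisibly the `ckd_scenario_grid`.
#' @export
run_analysis <- function(pset, out_dir, scenario = "base", n_cycles = 40L) {
  input_dir <- NULL
  if (is.character(pset)) {
    input_dir <- pset
    pset <- read_parameter_set(pset)
  }
  grid <- run_scenario_grid(pset, scenario = scenario, n_cycles = n_cycles)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  utils::write.csv(patient_count_table(grid),
                   file.path(out_dir, "patient_counts.csv"), row.names = FALSE)
  utils::write.csv(economics_table(grid),
                   file.path(out_dir, "economics.csv"), row.names = FALSE)

  if (is.null(input_dir)) {
    # hash the in-memory inputs by serializing them to the loaders' dialect
    tmp <- tempfile("ckdmarkov-manifest-")
    write_parameter_set(pset, tmp)
    input_dir <- tmp
    on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  }
  files <- sort(list.files(input_dir, pattern = "\\.csv$", full.names = TRUE))
  manifest <- list(
    scenario = scenario,
    n_cycles = n_cycles,
    discount_rate_annual = pset$econ$discount_rate_annual,
    interaction_factor_qalys = grid$interaction_factor,
    input_hashes = as.list(stats::setNames(unname(tools::md5sum(files)),
                                           basename(files))),
    package_version = as.character(utils::packageVersion("ckdmarkov"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(grid)
}

#' Write a tornado analysis to CSV
#' @param tornado A `ckd_tornado` from [one_way()].
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_tornado <- function(tornado, path) {
  utils::write.csv(as.data.frame(tornado)[, c("parameter", "icer_low", "icer_high")],
                   path, row.names = FALSE)
  invisible(path)
}
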