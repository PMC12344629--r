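#' Water-filled pore space
#'
#' WFPS (%) = 100 * theta / porosity with porosity = 1 - bulk_density /
#' particle_density. WFPS above 100% (supersaturation, e.g. ponding or a
#' sensor artefact) raises a warning, not an error.
#'
#' @param theta volumetric water content, m3 m-3, in \[0, 1\].
#' @param bulk_density g cm-3, must be below `particle_density`.
#' @param particle_density g cm-3; the mineral-soil default is 2.65.
#' @return WFPS in percent (vectorised over `theta` and `bulk_density`).
#' @examples
#' wfps(0.30, 1.20) # 54.83 %
#' @export
wfps <- function(theta, bulk_density, particle_density = 2.65) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 1))
    abort_input("'theta' must be within [0, 1]")
  if (any(!is.finite(bulk_density)) || any(bulk_density <= 0))
    abort_input("'bulk_density' must be > 0")
  porosity <- 1 - bulk_density / particle_density
  if (any(porosity <= 0))
    abort_input("porosity <= 0: bulk_density must be below particle_density")
  out <- 100 * theta / porosity
  if (any(out > 100))
    warning("WFPS exceeds 100% (supersaturation)")
  out
}

#' Yield-scaled N2O emission
#'
#' Cumulative seasonal N2O emission divided by the dried crop (maize ear)
#' yield: an emission-intensity metric in kg N2O Mg-1 yield.
#'
#' @param cumulative_n2o_kg_ha cumulative emission, kg ha-1 (>= 0).
#' @param yield_Mg_ha dried yield, Mg ha-1 (> 0).
#' @return YSNE in kg Mg-1 (vectorised).
#' @examples
#' yield_scaled_emission(5.52, 6.81) # 0.81 kg Mg-1
#' @export
yield_scaled_emission <- function(cumulative_n2o_kg_ha, yield_Mg_ha) {
  if (any(!is.finite(cumulative_n2o_kg_ha)) || any(cumulative_n2o_kg_ha < 0))
    abort_input("'cumulative_n2o_kg_ha' must be finite and >= 0")
  if (any(!is.finite(yield_Mg_ha)) || any(yield_Mg_ha <= 0))
    abort_input("'yield_Mg_ha' must be > 0")
  cumulative_n2o_kg_ha / yield_Mg_ha
}

#' Percent reduction relative to a control
#'
#' 100 * (control - treatment) / control. Negative when the treatment exceeds
#' the control.
#'
#' @param control control value (> 0).
#' @param treatment treatment value.
#' @return percent reduction (vectorised).
#' @examples
#' percent_reduction(5.52, 4.18) # 24.3 %
#' @export
percent_reduction <- function(control, treatment) {
  if (any(!is.finite(control)) || any(control <= 0))
    abort_input("'control' must be > 0")
  if (any(!is.finite(treatment)))
    abort_input("'treatment' must be finite")
  100 * (control - treatment) / control
}

#' Net ion consumption between two incubation time points
#'
#' Concentration difference early minus late: positive values are net
#' consumption of the analyte (e.g. NO3-, SO42- drawn down as electron
#' acceptors), negative values net production.
#'
#' @param conc_early concentration at the early time point, mg kg-1 (>= 0).
#' @param conc_late concentration at the late time point, mg kg-1 (>= 0).
#' @return net consumption, mg kg-1 (vectorised).
#' @export
net_consumption <- function(conc_early, conc_late) {
  if (any(!is.finite(conc_early)) || any(conc_early < 0) ||
      any(!is.finite(conc_late)) || any(conc_late < 0))
    abort_input("concentrations must be finite and >= 0")
  conc_early - conc_late
}

#' Treatment-by-year summary of cumulative emissions, yield and YSNE
#'
#' Reconstructs the standard field-trial summary table: per (treatment, year)
#' cell means, per-treatment across-year means, and per-year across-treatment
#' means for cumulative N2O emission, yield, and yield-scaled emission.
#'
#' YSNE is aggregated ratio-then-mean: each record's ratio is formed first and
#' means are taken over ratios, so a treatment's across-year YSNE mean is the
#' mean of its yearly YSNE values, not the ratio of mean emission to mean
#' yield (the two differ whenever yield varies).
#'
#' @param records data frame with columns `treatment`, `year`,
#'   `cumulative_kg_ha`, `yield_Mg_ha` (one or more records per cell).
#' @param digits optional named vector of decimal places for half-up rounding
#'   in the report, e.g. `c(cumulative = 2, yield = 2, ysne = 2)`; `NULL`
#'   (default) keeps full precision.
#' @return An object of class `season_summary`: data frames `cells` (per
#'   treatment x year), `treatment_means` (across years), `year_means`
#'   (across treatments).
#' @export
treatment_year_summary <- function(records, digits = NULL) {
  req <- c("treatment", "year", "cumulative_kg_ha", "yield_Mg_ha")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    abort_input(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(records) == 0L) abort_input("empty records table")
  records$ysne <- yield_scaled_emission(records$cumulative_kg_ha, records$yield_Mg_ha)

  agg <- function(df, by) stats::aggregate(df[c("cumulative", "yield", "ysne")],
                                           by = df[by], FUN = mean)
  records$cumulative <- records$cumulative_kg_ha
  records$yield <- records$yield_Mg_ha
  cells <- agg(records, c("treatment", "year"))
  # treatment means average the yearly cell means (not pooled plots), so that
  # unbalanced replicate counts across years do not weight one year more
  treatment_means <- agg(cells, "treatment")
  year_means <- agg(cells, "year")

  if (!is.null(digits)) {
    rnd <- function(df) {
      for (v in intersect(c("cumulative", "yield", "ysne"), names(digits)))
        df[[v]] <- round_half_up(df[[v]], digits[[v]])
      df
    }
    cells <- rnd(cells); treatment_means <- rnd(treatment_means)
    year_means <- rnd(year_means)
  }
  structure(list(cells = cells, treatment_means = treatment_means,
                 year_means = year_means),
            class = "season_summary")
}

#' @export
print.season_summary <- function(x, ...) {
  cat("<season_summary>\nPer-cell means:\n")
  print(x$cells, row.names = FALSE)
  cat("Treatment means (across years):\n")
  print(x$treatment_means, row.names = FALSE)
  cat("Year means (across treatments):\n")
  print(x$year_means, row.names = FALSE)
  invisible(x)
}

#' Printed two-year field summary cells
#'
#' The per-treatment, per-year cumulative N2O emissions (kg ha-1) and maize
#' ear yields (Mg ha-1) of the two-year metal-sulfate field trial, at their
#' published precision. Useful as a worked input for
#' [treatment_year_summary()], [percent_reduction()] and the lettering
#' pipeline.
#'
#' @return data frame with columns `treatment`, `year`, `cumulative_kg_ha`,
#'   `yield_Mg_ha`; treatments control, FeSO4, MnSO4, ZnSO4 by years Y1/Y2.
#' @export
field_summary_cells <- function() {
  data.frame(
    treatment = rep(c("control", "FeSO4", "MnSO4", "ZnSO4"), each = 2),
    year = rep(c("Y1", "Y2"), times = 4),
    cumulative_kg_ha = c(5.52, 4.12, 4.55, 3.55, 4.99, 3.75, 4.18, 3.60),
    yield_Mg_ha = c(6.81, 5.32, 6.74, 5.53, 7.28, 4.93, 7.19, 5.53),
    stringsAsFactors = FALSE
  )
}
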