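#' N2O density at standard conditions
#'
#' Mass density of pure N2O at 273.15 K and 0.101 MPa from the ideal gas law,
#' d = M / Vm with M = 44.013 g mol-1 and Vm = 22414 cm3 mol-1. Used to convert
#' a dry-air mole fraction into a mass concentration in the chamber flux
#' equation.
#'
#' @format A single number, g m-3 (about 1963.6).
#' @export
N2O_DENSITY_STP <- 44.013 / 22414 * 1e6

#' Molar masses used for N2O / N2O-N basis conversion (g mol-1)
#' @rdname N2O_DENSITY_STP
#' @export
N2O_MOLAR_MASS <- 44.013

#' @rdname N2O_DENSITY_STP
#' @export
N2O_N_MOLAR_MASS <- 28.014

#' Timed headspace N2O series for one chamber closure
#'
#' Container for the concentration-versus-time record of a single static
#' chamber (or microcosm jar) closure: N2O dry-air mole fractions (ppb)
#' sampled at known minutes since lid placement.
#'
#' @param chamber_id identifier for the chamber/jar.
#' @param minutes numeric vector of sampling times in minutes since closure,
#'   strictly increasing, non-negative. The first sample need not be at 0.
#' @param n2o_ppb numeric vector of N2O mixing ratios (ppb), finite and >= 0.
#' @param closure_date optional `Date` (or string coercible to one); field
#'   closures carry a date, microcosm closures may omit it.
#' @return An object of class `gas_sample_series`.
#' @export
gas_sample_series <- function(chamber_id, minutes, n2o_ppb, closure_date = NULL) {
  minutes <- as.numeric(minutes)
  n2o_ppb <- as.numeric(n2o_ppb)
  if (length(minutes) < 2L)
    abort_input("a gas sample series needs at least 2 samples")
  if (length(minutes) != length(n2o_ppb))
    abort_input("'minutes' and 'n2o_ppb' must have equal length")
  if (anyNA(minutes) || any(!is.finite(minutes)) || any(minutes < 0))
    abort_input("'minutes' must be finite and non-negative")
  if (any(diff(minutes) <= 0))
    abort_input("'minutes' must be strictly increasing (duplicated or unordered timestamps)")
  if (anyNA(n2o_ppb) || any(!is.finite(n2o_ppb)) || any(n2o_ppb < 0))
    abort_input("'n2o_ppb' must be finite and non-negative")
  if (!is.null(closure_date)) closure_date <- as.Date(closure_date)
  structure(list(chamber_id = as.character(chamber_id),
                 minutes = minutes, n2o_ppb = n2o_ppb,
                 closure_date = closure_date),
            class = "gas_sample_series")
}

#' @export
print.gas_sample_series <- function(x, ...) {
  cat(sprintf("<gas_sample_series> chamber %s, %d samples over %g min%s\n",
              x$chamber_id, length(x$minutes), diff(range(x$minutes)),
              if (is.null(x$closure_date)) "" else paste0(", ", format(x$closure_date))))
  print(data.frame(minutes = x$minutes, n2o_ppb = x$n2o_ppb), row.names = FALSE)
  invisible(x)
}

#' Chamber or microcosm geometry and environment
#'
#' Everything the flux equation needs besides the fitted concentration slope:
#' headspace volume, the normalisation basis (soil mass for jar microcosms,
#' footprint area for field chambers), the closure temperature and the gas
#' density at standard conditions.
#'
#' @param headspace_volume_cm3 headspace volume in cm3 (> 0).
#' @param basis `"per_soil_mass"` (microcosm; flux in ng N2O g-1 h-1) or
#'   `"per_area"` (field chamber; flux in ug N2O m-2 h-1).
#' @param soil_mass_g dry soil mass in g; required iff basis is per_soil_mass.
#' @param footprint_area_m2 chamber footprint in m2; required iff basis is
#'   per_area.
#' @param temperature_K closure temperature in K. A sanity range of 250-330 K
#'   is enforced unless `check_temperature = FALSE`.
#' @param standard_temperature_K reference temperature for the gas density
#'   (default 273.15 K).
#' @param gas_density_g_m3 N2O density at standard conditions, g m-3
#'   (default [N2O_DENSITY_STP]).
#' @param check_temperature logical; disable the 250-330 K sanity bound.
#' @return An object of class `chamber_geometry`.
#' @export
chamber_geometry <- function(headspace_volume_cm3,
                             basis = c("per_soil_mass", "per_area"),
                             soil_mass_g = NULL,
                             footprint_area_m2 = NULL,
                             temperature_K = 298.15,
                             standard_temperature_K = 273.15,
                             gas_density_g_m3 = N2O_DENSITY_STP,
                             check_temperature = TRUE) {
  basis <- match.arg(basis)
  stopifnot_scalar_number(headspace_volume_cm3, "headspace_volume_cm3", positive = TRUE)
  stopifnot_scalar_number(temperature_K, "temperature_K", positive = TRUE)
  stopifnot_scalar_number(standard_temperature_K, "standard_temperature_K", positive = TRUE)
  stopifnot_scalar_number(gas_density_g_m3, "gas_density_g_m3", positive = TRUE)
  if (check_temperature && (temperature_K < 250 || temperature_K > 330))
    abort_input("temperature_K outside sanity range 250-330 K (set check_temperature = FALSE to override)")
  if (basis == "per_soil_mass") {
    if (is.null(soil_mass_g) || !is.null(footprint_area_m2))
      abort_config("basis 'per_soil_mass' requires soil_mass_g and no footprint_area_m2")
    stopifnot_scalar_number(soil_mass_g, "soil_mass_g", positive = TRUE)
  } else {
    if (is.null(footprint_area_m2) || !is.null(soil_mass_g))
      abort_config("basis 'per_area' requires footprint_area_m2 and no soil_mass_g")
    stopifnot_scalar_number(footprint_area_m2, "footprint_area_m2", positive = TRUE)
  }
  structure(list(headspace_volume_cm3 = headspace_volume_cm3,
                 basis = basis,
                 soil_mass_g = soil_mass_g,
                 footprint_area_m2 = footprint_area_m2,
                 temperature_K = temperature_K,
                 standard_temperature_K = standard_temperature_K,
                 gas_density_g_m3 = gas_density_g_m3),
            class = "chamber_geometry")
}

#' @export
print.chamber_geometry <- function(x, ...) {
  norm <- if (x$basis == "per_soil_mass")
    sprintf("%g g soil", x$soil_mass_g) else sprintf("%g m2", x$footprint_area_m2)
  cat(sprintf("<chamber_geometry> V = %g cm3, %s, T = %g K (T0 = %g K, d = %.1f g m-3)\n",
              x$headspace_volume_cm3, norm, x$temperature_K,
              x$standard_temperature_K, x$gas_density_g_m3))
  invisible(x)
}

#' Fit the headspace accumulation slope
#'
#' Ordinary least-squares line of N2O mixing ratio against minutes since
#' closure over all samples of one closure. No r-squared cut-off is applied;
#' the coefficient of determination is reported so users can impose their own
#' QA filter.
#'
#' @param series a [gas_sample_series()].
#' @return An object of class `slope_fit` with elements `slope` (ppb min-1),
#'   `intercept` (ppb), `r_squared`, `n_points`, `chamber_id`.
#' @examples
#' s <- gas_sample_series("jar1", c(0, 10, 20), c(330, 342, 348))
#' fit_headspace_slope(s) # slope 0.9 ppb/min
#' @export
fit_headspace_slope <- function(series) {
  if (!inherits(series, "gas_sample_series"))
    series <- do.call(gas_sample_series, series)
  fit <- stats::lm(n2o_ppb ~ minutes,
                   data = data.frame(minutes = series$minutes, n2o_ppb = series$n2o_ppb))
  co <- stats::coef(fit)
  ss_tot <- sum((series$n2o_ppb - mean(series$n2o_ppb))^2)
  # constant series: define r2 = 1 (the zero-slope line fits perfectly);
  # a 2-point fit is exact by construction as well
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = unname(co[["minutes"]]),
                 intercept = unname(co[["(Intercept)"]]),
                 r_squared = min(max(r2, 0), 1),
                 n_points = length(series$minutes),
                 chamber_id = series$chamber_id),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> %s: %0.4g ppb/min (intercept %0.5g ppb, r2 = %0.4f, n = %d)\n",
              x$chamber_id, x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Chamber N2O flux from a fitted slope
#'
#' Converts a fitted headspace accumulation slope (ppb min-1) into an N2O
#' flux. The mole-fraction slope is converted to a mass-concentration rate
#' with the N2O density at standard conditions and the ideal-gas temperature
#' correction T0/T, multiplied by the headspace volume, and normalised by soil
#' mass (microcosm, ng N2O g-1 h-1) or by footprint area (field chamber,
#' ug N2O m-2 h-1):
#'
#' per soil mass: flux = slope*60 * d * (T0/T) * V / W,
#' with slope in ppb min-1, d in g m-3, V in m3, W in g (the ppb 1e-9 and the
#' g-to-ng 1e9 cancel).
#'
#' @param fit a [fit_headspace_slope()] result (or any list with a `slope`
#'   in ppb min-1).
#' @param geometry a [chamber_geometry()].
#' @param as_n2o_n report on the N2O-N mass basis (multiplies by 28.014/44.013).
#' @return An object of class `flux_estimate` with elements `value`, `unit`,
#'   `basis`, `fit`, `chamber_id`, `closure_date`.
#' @examples
#' g <- chamber_geometry(460, "per_soil_mass", soil_mass_g = 400,
#'                       temperature_K = 298.15)
#' chamber_flux(list(slope = 1000 / 60), g) # ~2.07 ng N2O g-1 h-1
#' @export
chamber_flux <- function(fit, geometry, as_n2o_n = FALSE) {
  if (!inherits(geometry, "chamber_geometry"))
    abort_config("'geometry' must be a chamber_geometry object")
  slope <- fit$slope
  stopifnot_scalar_number(slope, "fit$slope")
  v_m3 <- geometry$headspace_volume_cm3 * 1e-6
  t_corr <- geometry$standard_temperature_K / geometry$temperature_K
  # mass accumulation rate in the headspace: (g N2O per 1e9 g-basis) h-1
  mass_rate <- slope * 60 * geometry$gas_density_g_m3 * t_corr * v_m3
  if (geometry$basis == "per_soil_mass") {
    value <- mass_rate / geometry$soil_mass_g          # ng g-1 h-1
    unit <- "ng N2O g-1 h-1"
  } else {
    value <- mass_rate / geometry$footprint_area_m2 * 1e-3  # ug m-2 h-1
    unit <- "ug N2O m-2 h-1"
  }
  if (as_n2o_n) {
    value <- value * (N2O_N_MOLAR_MASS / N2O_MOLAR_MASS)
    unit <- sub("N2O", "N2O-N", unit)
  }
  structure(list(value = value, unit = unit, basis = geometry$basis,
                 fit = if (inherits(fit, "slope_fit")) fit else NULL,
                 chamber_id = if (!is.null(fit$chamber_id)) fit$chamber_id else NA_character_,
                 closure_date = NULL),
            class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf("<flux_estimate> %s: %0.5g %s\n", x$chamber_id, x$value, x$unit))
  invisible(x)
}

#' Flux series over a season or incubation
#'
#' @param days numeric vector of time points in days, strictly increasing.
#' @param fluxes numeric vector of flux values on a common basis and unit
#'   (one per time point).
#' @param unit free-text unit label carried through to the cumulative report.
#' @return An object of class `flux_series`.
#' @export
flux_series <- function(days, fluxes, unit = "per day") {
  days <- as.numeric(days); fluxes <- as.numeric(fluxes)
  if (length(days) < 2L) abort_input("a flux series needs at least 2 time points")
  if (length(days) != length(fluxes)) abort_input("'days' and 'fluxes' lengths differ")
  if (any(!is.finite(days)) || any(diff(days) <= 0))
    abort_input("'days' must be finite and strictly increasing")
  if (any(!is.finite(fluxes))) abort_input("'fluxes' must be finite")
  structure(list(days = days, fluxes = fluxes, unit = unit), class = "flux_series")
}

#' Cumulative emission by interval integration
#'
#' Integrates a daily flux series into a cumulative emission by summing, over
#' consecutive sampling dates, the interval mean flux R_i times the interval
#' duration D_i. With `method = "trapezoid"` (default) R_i is the mean of the
#' two bounding fluxes — linear interpolation between sampling dates. The
#' rectangle rule (left endpoint) is available as an explicit alternative.
#'
#' Unit hooks: `hourly_to_daily = TRUE` multiplies fluxes by 24 before
#' integration (for hourly chamber fluxes); `area_to_kg_ha = TRUE` converts a
#' ug m-2 day-1 series so the total is in kg ha-1 (factor 1e-5).
#'
#' @param series a [flux_series()], or a numeric vector of fluxes with `days`
#'   supplied separately.
#' @param days time points in days (ignored when `series` is a flux_series).
#' @param method `"trapezoid"` or `"rectangle"`.
#' @param hourly_to_daily multiply fluxes by 24 before integrating.
#' @param area_to_kg_ha convert ug m-2 totals to kg ha-1.
#' @return An object of class `cumulative_result`: `total`, and `per_interval`
#'   data frame with columns `t_start`, `t_end`, `duration_days`, `mean_flux`,
#'   `contribution`.
#' @examples
#' cumulative_emission(flux_series(c(0, 1, 2), c(1, 3, 5)))$total # 6
#' @export
cumulative_emission <- function(series, days = NULL,
                                method = c("trapezoid", "rectangle"),
                                hourly_to_daily = FALSE,
                                area_to_kg_ha = FALSE) {
  method <- match.arg(method)
  if (!inherits(series, "flux_series")) {
    if (is.null(days)) abort_input("supply a flux_series or both 'series' (fluxes) and 'days'")
    series <- flux_series(days, series)
  }
  f <- series$fluxes
  if (hourly_to_daily) f <- f * 24
  if (area_to_kg_ha) f <- f * 1e-5
  t <- series$days
  n <- length(t)
  d_i <- diff(t)
  r_i <- if (method == "trapezoid") (f[-n] + f[-1]) / 2 else f[-n]
  per <- data.frame(t_start = t[-n], t_end = t[-1], duration_days = d_i,
                    mean_flux = r_i, contribution = r_i * d_i)
  structure(list(total = sum(per$contribution), per_interval = per,
                 method = method, unit = series$unit),
            class = "cumulative_result")
}

#' @export
print.cumulative_result <- function(x, ...) {
  cat(sprintf("<cumulative_result> total %0.6g (%s, %d intervals, %s rule)\n",
              x$total, x$unit, nrow(x$per_interval), x$method))
  invisible(x)
}
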