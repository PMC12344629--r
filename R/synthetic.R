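# Seedable generators emulating every input the analysis chain consumes.
# Each generator is a deterministic function of (configuration, seed) and is,
# at zero noise, the exact inverse of its analysis stage.

#' Simulate a chamber headspace accumulation series
#'
#' Inverts the chamber flux equation: the ppb min-1 slope that would produce
#' `true_flux` under `geometry` is computed, and mixing ratios
#' baseline + slope * t + N(0, noise_sd) are emitted at the requested sample
#' times. With zero noise, [fit_headspace_slope()] + [chamber_flux()] recover
#' `true_flux` exactly.
#'
#' @param true_flux target flux on the geometry's basis (ng N2O g-1 h-1 for
#'   per_soil_mass, ug N2O m-2 h-1 for per_area).
#' @param geometry a [chamber_geometry()].
#' @param sample_times minutes since closure (default the microcosm design
#'   0, 10, 20).
#' @param baseline_ppb mixing ratio at closure (default 330 ppb, near
#'   tropospheric background).
#' @param noise_sd Gaussian instrument noise on each sample, ppb (>= 0).
#' @param seed integer seed.
#' @param chamber_id identifier for the emitted series.
#' @return A [gas_sample_series()].
#' @export
simulate_chamber_series <- function(true_flux, geometry,
                                    sample_times = c(0, 10, 20),
                                    baseline_ppb = 330, noise_sd = 0, seed,
                                    chamber_id = "sim") {
  if (missing(seed)) abort_input("'seed' must be supplied")
  if (!inherits(geometry, "chamber_geometry"))
    abort_config("'geometry' must be a chamber_geometry object")
  if (!is.numeric(noise_sd) || noise_sd < 0) abort_input("'noise_sd' must be >= 0")
  slope <- slope_for_flux(true_flux, geometry)
  noise <- withr::with_seed(as.integer(seed),
                            stats::rnorm(length(sample_times), 0, noise_sd))
  ppb <- baseline_ppb + slope * sample_times + noise
  gas_sample_series(chamber_id, sample_times, pmax(ppb, 0))
}

# Internal inverse of chamber_flux: ppb min-1 slope giving `flux` under `geometry`
slope_for_flux <- function(flux, geometry) {
  v_m3 <- geometry$headspace_volume_cm3 * 1e-6
  t_corr <- geometry$standard_temperature_K / geometry$temperature_K
  denom <- 60 * geometry$gas_density_g_m3 * t_corr * v_m3
  if (geometry$basis == "per_soil_mass")
    flux * geometry$soil_mass_g / denom
  else
    flux * geometry$footprint_area_m2 * 1e3 / denom
}

#' Simulate a field season of daily fluxes with treatment effects
#'
#' Emulates a replicated field trial: a common baseline daily flux curve with
#' two fertilization-event peaks, multiplied per treatment by its effect
#' factor and per plot by lognormal noise with coefficient of variation
#' `flux_noise_cv`. Returns per-plot flux series (via [flux_series()]), the
#' per-plot integrated cumulative emissions, and the noise-free analytic
#' cumulative per treatment (trapezoid over the same grid), so flux
#' integration, summary tables, ANOVA and lettering can be exercised
#' end-to-end.
#'
#' The default design follows a typical split-fertilization maize season:
#' 120 days, peaks centred at days 20 and 60, four plots per treatment.
#'
#' @param treatment_effects named numeric vector of multiplicative effects on
#'   the baseline curve (e.g. `c(control = 1, amended = 0.8)`), all > 0.
#' @param n_days season length in days.
#' @param n_plots_per_treatment replicate plots per treatment (>= 2).
#' @param flux_noise_cv lognormal coefficient of variation of plot-level
#'   noise (>= 0; 0 gives the exact baseline curve).
#' @param baseline_peak peak daily flux of the baseline curve, kg ha-1 day-1
#'   scale units.
#' @param seed integer seed.
#' @return list with `plots` (data frame: treatment, plot, cumulative),
#'   `series` (named list of [flux_series()]), `expected` (named numeric,
#'   noise-free cumulative per treatment), `days`.
#' @export
simulate_field_season <- function(treatment_effects = c(control = 1, amended = 0.8),
                                  n_days = 120, n_plots_per_treatment = 4,
                                  flux_noise_cv = 0.2, baseline_peak = 0.08,
                                  seed) {
  if (missing(seed)) abort_input("'seed' must be supplied")
  if (any(!is.finite(treatment_effects)) || any(treatment_effects <= 0))
    abort_config("'treatment_effects' must be > 0")
  if (n_plots_per_treatment < 2) abort_config("need >= 2 plots per treatment")
  if (flux_noise_cv < 0) abort_config("'flux_noise_cv' must be >= 0")
  days <- 0:n_days
  # double-peak baseline keyed to split fertilization events
  peak_at <- function(centre, width) exp(-((days - centre) / width)^2 / 2)
  baseline <- baseline_peak * (peak_at(0.17 * n_days, 0.05 * n_days) +
                                 0.8 * peak_at(0.5 * n_days, 0.06 * n_days)) +
    0.1 * baseline_peak
  sdlog <- sqrt(log(1 + flux_noise_cv^2))
  trts <- names(treatment_effects)
  if (is.null(trts)) trts <- paste0("T", seq_along(treatment_effects))

  out <- withr::with_seed(as.integer(seed), {
    plots <- list(); series <- list()
    for (i in seq_along(treatment_effects)) {
      for (p in seq_len(n_plots_per_treatment)) {
        mult <- if (flux_noise_cv > 0)
          stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
        f <- baseline * treatment_effects[i] * mult
        id <- sprintf("%s_plot%d", trts[i], p)
        fs <- flux_series(days, f, unit = "kg ha-1 day-1")
        series[[id]] <- fs
        plots[[id]] <- data.frame(treatment = trts[i], plot = id,
                                  cumulative = cumulative_emission(fs)$total,
                                  stringsAsFactors = FALSE)
      }
    }
    list(plots = do.call(rbind, plots), series = series)
  })
  expected <- vapply(seq_along(treatment_effects), function(i)
    cumulative_emission(flux_series(days, baseline * treatment_effects[i]))$total,
    numeric(1))
  names(expected) <- trts
  rownames(out$plots) <- NULL
  list(plots = out$plots, series = out$series, expected = expected, days = days)
}

#' Simulate an ambient-diluted isotope mixture
#'
#' Forward model of the two-pool mass balance: a true soil-emitted signature
#' at `soil_concentration_ppb` is mixed with the ambient reference, then
#' instrument noise at the stated precisions is added to the observed alpha,
#' beta and delta18O. With zero precisions, [ambient_correction()] recovers
#' the true source exactly on all three delta axes.
#'
#' @param true_source list (or `source_signature`) with `d15n_bulk`, `sp`,
#'   `d18o` of the soil-emitted N2O.
#' @param ambient an [ambient_reference()].
#' @param soil_concentration_ppb soil-emitted N2O added to ambient (> 0).
#' @param precision an [instrument_precision()] (sigmas may be 0).
#' @param seed integer seed.
#' @param sample_id identifier for the emitted measurement.
#' @return An [isotopomer_measurement()] of the mixture.
#' @export
simulate_isotope_mixture <- function(true_source, ambient,
                                     soil_concentration_ppb,
                                     precision = instrument_precision(),
                                     seed, sample_id = "sim") {
  if (missing(seed)) abort_input("'seed' must be supplied")
  stopifnot_scalar_number(soil_concentration_ppb, "soil_concentration_ppb",
                          positive = TRUE)
  if (!inherits(ambient, "ambient_reference"))
    abort_input("'ambient' must be an ambient_reference")
  src_a <- true_source$d15n_bulk + true_source$sp / 2
  src_b <- true_source$d15n_bulk - true_source$sp / 2
  c_amb <- ambient$concentration_ppb
  c_obs <- c_amb + soil_concentration_ppb
  mix <- function(d_src, d_amb) (d_src * soil_concentration_ppb + d_amb * c_amb) / c_obs
  noise <- withr::with_seed(as.integer(seed), stats::rnorm(3))
  isotopomer_measurement(
    d15n_alpha = mix(src_a, ambient$d15n_alpha) + noise[1] * precision$sigma_alpha,
    d15n_beta = mix(src_b, ambient$d15n_beta) + noise[2] * precision$sigma_beta,
    d18o = mix(true_source$d18o, ambient$d18o) + noise[3] * precision$sigma_d18o,
    concentration_ppb = c_obs,
    sample_id = sample_id)
}

#' Simulate a population of meta-analysis records
#'
#' Draws response ratios from Normal(`true_mean_rr`, `sd_rr`^2) and converts
#' each to a treatment/control pair with the control fixed at 100 units, so
#' [response_ratio()] recovers the drawn effect exactly.
#'
#' @param true_mean_rr population mean response ratio, percent.
#' @param sd_rr population SD, percent (>= 0).
#' @param n number of records (>= 2).
#' @param seed integer seed.
#' @return data frame with columns `study_id`, `treatment_n2o`, `control_n2o`.
#' @export
simulate_meta <- function(true_mean_rr, sd_rr, n, seed) {
  if (missing(seed)) abort_input("'seed' must be supplied")
  if (!is.numeric(sd_rr) || sd_rr < 0) abort_input("'sd_rr' must be >= 0")
  if (!is.numeric(n) || n < 2) abort_input("'n' must be >= 2")
  rr <- withr::with_seed(as.integer(seed), stats::rnorm(n, true_mean_rr, sd_rr))
  data.frame(study_id = sprintf("sim%03d", seq_len(n)),
             treatment_n2o = 100 * (1 + rr / 100),
             control_n2o = rep(100, n),
             stringsAsFactors = FALSE)
}
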