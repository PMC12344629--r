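# CSV readers/writers for the pipeline's exchange schemas. Dialect is fixed:
# comma separator, '.' decimal, UTF-8, ISO-8601 dates, header row required.

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss))
    abort_input(sprintf("%s: missing required column(s): %s",
                        path, paste(miss, collapse = ", ")))
  df
}

#' Read timed headspace gas samples
#'
#' Reads `gas_samples.csv` (columns `chamber_id`, `minutes`, `n2o_ppb`,
#' optional `date`) and partitions the rows into one [gas_sample_series()]
#' per chamber closure (chamber_id, or chamber_id x date when dates are
#' present). Rows within a closure are sorted by time; non-monotone duplicate
#' times raise a validation error naming the closure.
#'
#' @param path CSV file path.
#' @return named list of `gas_sample_series`.
#' @export
read_gas_samples <- function(path) {
  df <- read_csv_checked(path, c("chamber_id", "minutes", "n2o_ppb"))
  has_date <- "date" %in% names(df)
  key <- if (has_date) paste(df$chamber_id, df$date, sep = "@") else as.character(df$chamber_id)
  out <- lapply(split(seq_len(nrow(df)), key), function(rows) {
    sub <- df[rows, ]
    sub <- sub[order(sub$minutes), ]
    tryCatch(
      gas_sample_series(sub$chamber_id[1], sub$minutes, sub$n2o_ppb,
                        closure_date = if (has_date) sub$date[1] else NULL),
      error = function(e) abort_input(sprintf("closure '%s': %s",
                                              key[rows[1]], conditionMessage(e))))
  })
  out[unique(key)]
}

#' Write per-closure flux estimates to CSV
#'
#' @param fluxes list of [chamber_flux()] results.
#' @param path output CSV path.
#' @return the written data frame, invisibly.
#' @export
write_flux_csv <- function(fluxes, path) {
  df <- do.call(rbind, lapply(fluxes, function(f)
    data.frame(chamber_id = f$chamber_id, flux = f$value, unit = f$unit,
               slope_ppb_min = if (!is.null(f$fit)) f$fit$slope else NA_real_,
               r_squared = if (!is.null(f$fit)) f$fit$r_squared else NA_real_,
               n_points = if (!is.null(f$fit)) f$fit$n_points else NA_integer_,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(df)
}

#' Read a season summary table
#'
#' Reads `season_summary.csv` with columns `treatment`, `year`,
#' `cumulative_kg_ha`, `yield_Mg_ha`.
#'
#' @param path CSV file path.
#' @return data frame suitable for [treatment_year_summary()].
#' @export
read_season_summary <- function(path) {
  read_csv_checked(path, c("treatment", "year", "cumulative_kg_ha", "yield_Mg_ha"))
}

#' Read isotopomer measurements
#'
#' Reads `isotopes.csv` with columns `sample_id`, `d18o`, `n2o_ppb` and
#' either (`d15n_alpha`, `d15n_beta`) or (`d15n_bulk`, `sp`).
#'
#' @param path CSV file path.
#' @return named list of [isotopomer_measurement()].
#' @export
read_isotopes <- function(path) {
  df <- read_csv_checked(path, c("sample_id", "d18o", "n2o_ppb"))
  has_ab <- all(c("d15n_alpha", "d15n_beta") %in% names(df))
  has_bs <- all(c("d15n_bulk", "sp") %in% names(df))
  if (!has_ab && !has_bs)
    abort_input(sprintf("%s: need columns d15n_alpha+d15n_beta or d15n_bulk+sp", path))
  out <- lapply(seq_len(nrow(df)), function(i) {
    if (has_ab)
      isotopomer_measurement(d15n_alpha = df$d15n_alpha[i], d15n_beta = df$d15n_beta[i],
                             d18o = df$d18o[i], concentration_ppb = df$n2o_ppb[i],
                             sample_id = df$sample_id[i])
    else
      isotopomer_measurement(d15n_bulk = df$d15n_bulk[i], sp = df$sp[i],
                             d18o = df$d18o[i], concentration_ppb = df$n2o_ppb[i],
                             sample_id = df$sample_id[i])
  })
  names(out) <- df$sample_id
  out
}

#' Read meta-analysis records
#'
#' Reads `meta_records.csv` with columns `study_id`, `treatment_n2o`,
#' `control_n2o` (optional `sulfate_form`, `rate_kg_ha`, `crop`).
#'
#' @param path CSV file path.
#' @return data frame suitable for [summarize_effects()].
#' @export
read_meta_records <- function(path) {
  read_csv_checked(path, c("study_id", "treatment_n2o", "control_n2o"))
}

#' Read and validate a run configuration
#'
#' Parses a YAML run configuration with sections `geometry` (the
#' [chamber_geometry()] fields), optional `ambient` ([ambient_reference()]
#' fields), optional `domains` (list of [endmember_domain()] specs) and
#' optional `analysis` (`alpha`, `confidence`). Section contents are
#' validated by the corresponding constructors; errors name the offending
#' section.
#'
#' @param path YAML file path.
#' @return list with validated `geometry`, `ambient`, `domains`, `analysis`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  out <- list(geometry = NULL, ambient = NULL, domains = NULL,
              analysis = list(alpha = 0.05, confidence = 0.95))
  wrap <- function(section, expr) {
    tryCatch(expr, error = function(e)
      abort_config(sprintf("config section '%s': %s", section, conditionMessage(e))))
  }
  if (!is.null(cfg$geometry)) {
    g <- cfg$geometry
    out$geometry <- wrap("geometry", chamber_geometry(
      headspace_volume_cm3 = g$headspace_volume_cm3,
      basis = g$basis,
      soil_mass_g = g$soil_mass_g,
      footprint_area_m2 = g$footprint_area_m2,
      temperature_K = if (is.null(g$temperature_K)) 298.15 else g$temperature_K,
      standard_temperature_K = if (is.null(g$standard_temperature_K)) 273.15
                               else g$standard_temperature_K,
      gas_density_g_m3 = if (is.null(g$gas_density_g_m3)) N2O_DENSITY_STP
                         else g$gas_density_g_m3))
  }
  if (!is.null(cfg$ambient)) {
    a <- cfg$ambient
    out$ambient <- wrap("ambient", ambient_reference(
      d15n_bulk = a$d15n_bulk, sp = a$sp, d18o = a$d18o,
      concentration_ppb = a$concentration_ppb))
  }
  if (!is.null(cfg$domains)) {
    out$domains <- wrap("domains", lapply(cfg$domains, function(d)
      endmember_domain(name = d$name, sp_range = unlist(d$sp_range),
                       d15n_bulk_range = if (is.null(d$d15n_bulk_range)) NULL
                                         else unlist(d$d15n_bulk_range),
                       d18o_range = if (is.null(d$d18o_range)) NULL
                                    else unlist(d$d18o_range))))
  }
  if (!is.null(cfg$analysis)) {
    out$analysis <- utils::modifyList(out$analysis, cfg$analysis)
  }
  out
}
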