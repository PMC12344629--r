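#' Run one pipeline stage end-to-end
#'
#' Programmatic core of the command-line interface: reads the declared
#' inputs, runs one analysis stage and writes the declared outputs.
#' Commands:
#'
#' * `flux`: gas-sample CSV + geometry config -> per-closure flux CSV.
#' * `cumulative`: flux-series CSV (`days`, `flux`) -> JSON cumulative report.
#' * `ysne`: season summary CSV -> summary CSV of all cells/means.
#' * `isotope-correct`: isotope CSV + ambient config -> corrected JSON.
#' * `isotope-classify`: isotope CSV + ambient + domains -> classification JSON.
#' * `anova` / `letters`: long CSV (`group`, `value`) -> ANOVA/letters JSON.
#' * `meta`: meta-records CSV -> meta-summary JSON.
#' * `simulate-chamber`, `simulate-meta`: write synthetic inputs.
#'
#' @param command one of the commands above.
#' @param input input CSV path (stage-dependent).
#' @param output output file path (`.csv` or `.json` depending on stage).
#' @param config parsed [read_run_config()] list (or a path to a YAML file).
#' @param seed integer seed for the `simulate-*` commands.
#' @param ... stage-specific options (e.g. `true_flux`, `n`, `true_mean_rr`,
#'   `sd_rr`, `noise_sd`).
#' @return the stage result, invisibly.
#' @export
run_pipeline <- function(command, input = NULL, output = NULL, config = NULL,
                         seed = NULL, ...) {
  if (is.character(config)) config <- read_run_config(config)
  opts <- list(...)
  result <- switch(
    command,
    "flux" = {
      if (is.null(config$geometry)) abort_config("'flux' needs a geometry section")
      series <- read_gas_samples(input)
      fluxes <- lapply(series, function(s)
        chamber_flux(fit_headspace_slope(s), config$geometry))
      if (!is.null(output)) write_flux_csv(fluxes, output)
      fluxes
    },
    "cumulative" = {
      df <- read_csv_checked(input, c("days", "flux"))
      res <- cumulative_emission(flux_series(df$days, df$flux), ...)
      if (!is.null(output))
        jsonlite::write_json(list(total = res$total, method = res$method,
                                  per_interval = res$per_interval),
                             output, auto_unbox = TRUE, digits = NA)
      res
    },
    "ysne" = {
      df <- read_season_summary(input)
      res <- treatment_year_summary(df, digits = opts$digits)
      if (!is.null(output)) {
        cells <- res$cells
        cells$level <- "cell"
        tm <- res$treatment_means; tm$year <- NA; tm$level <- "treatment_mean"
        ym <- res$year_means; ym$treatment <- NA; ym$level <- "year_mean"
        utils::write.csv(rbind(cells, tm[names(cells)], ym[names(cells)]),
                         output, row.names = FALSE)
      }
      res
    },
    "isotope-correct" = {
      if (is.null(config$ambient)) abort_config("'isotope-correct' needs an ambient section")
      obs <- read_isotopes(input)
      res <- lapply(obs, ambient_correction, ambient = config$ambient)
      if (!is.null(output))
        jsonlite::write_json(lapply(res, unclass), output, auto_unbox = TRUE, digits = NA)
      res
    },
    "isotope-classify" = {
      if (is.null(config$ambient) || is.null(config$domains))
        abort_config("'isotope-classify' needs ambient and domains sections")
      obs <- read_isotopes(input)
      res <- lapply(obs, function(o) {
        sig <- ambient_correction(o, config$ambient)
        cl <- classify_source(sig, config$domains)
        list(signature = unclass(sig), membership = cl$membership,
             nearest = cl$nearest, distances = as.list(cl$distances))
      })
      if (!is.null(output))
        jsonlite::write_json(res, output, auto_unbox = TRUE, digits = NA)
      res
    },
    "anova" = ,
    "letters" = {
      df <- read_csv_checked(input, c("group", "value"))
      res <- letter_groups(df$value, df$group,
                           alpha = config$analysis$alpha %||% 0.05)
      if (!is.null(output))
        jsonlite::write_json(
          list(f_statistic = res$anova$f_statistic, p_value = res$anova$p_value,
               df = c(res$anova$df_between, res$anova$df_within),
               gate_passed = res$lsd$gate_passed,
               letters = as.list(res$letters$letters)),
          output, auto_unbox = TRUE, digits = NA)
      res
    },
    "meta" = {
      df <- read_meta_records(input)
      res <- summarize_effects(df, confidence = config$analysis$confidence %||% 0.95)
      if (!is.null(output))
        jsonlite::write_json(unclass(res)[c("n", "mean_rr", "sd_rr", "ci_low",
                                            "ci_high", "p_value", "prop_negative")],
                             output, auto_unbox = TRUE, digits = NA)
      res
    },
    "simulate-chamber" = {
      if (is.null(config$geometry)) abort_config("'simulate-chamber' needs a geometry section")
      if (is.null(seed)) abort_input("simulate-* commands need --seed")
      s <- simulate_chamber_series(true_flux = opts$true_flux %||% 2,
                                   geometry = config$geometry,
                                   noise_sd = opts$noise_sd %||% 0,
                                   seed = seed)
      df <- data.frame(chamber_id = s$chamber_id, minutes = s$minutes,
                       n2o_ppb = s$n2o_ppb)
      if (!is.null(output)) utils::write.csv(df, output, row.names = FALSE)
      s
    },
    "simulate-meta" = {
      if (is.null(seed)) abort_input("simulate-* commands need --seed")
      df <- simulate_meta(true_mean_rr = opts$true_mean_rr %||% -9,
                          sd_rr = opts$sd_rr %||% 28.4,
                          n = opts$n %||% 76, seed = seed)
      if (!is.null(output)) utils::write.csv(df, output, row.names = FALSE)
      df
    },
    abort_config(sprintf("unknown command '%s'", command))
  )
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
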