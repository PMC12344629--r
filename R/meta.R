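#' Response ratio of a treatment/control pair
#'
#' Effect size for one study record: the relative change in cumulative N2O
#' emission of the treated soil against its control, as a percentage,
#' RR% = 100 * (treatment - control) / control. Negative values are
#' mitigation. The natural-log response ratio 100 * ln(treatment/control) is
#' available via `type = "log"` for cross-study comparability, but percent
#' change is the default reporting scale.
#'
#' @param treatment,control cumulative emissions in the same units
#'   (control > 0; treatment > 0 required for the log type).
#' @param type `"percent"` (default) or `"log"`.
#' @return response ratio in percent (vectorised).
#' @examples
#' response_ratio(3.89, 4.82) # -19.3 %
#' @export
response_ratio <- function(treatment, control, type = c("percent", "log")) {
  type <- match.arg(type)
  if (any(!is.finite(control)) || any(control <= 0))
    abort_input("'control' must be > 0")
  if (any(!is.finite(treatment)))
    abort_input("'treatment' must be finite")
  if (type == "percent") {
    100 * (treatment - control) / control
  } else {
    if (any(treatment <= 0)) abort_input("'treatment' must be > 0 for the log response ratio")
    100 * log(treatment / control)
  }
}

#' Unweighted one-sample t summary of response ratios
#'
#' Meta-analytic summary of a set of per-record response ratios: mean, sample
#' SD, the t-based confidence interval mean +/- t(1-(1-conf)/2, n-1)*SD/sqrt(n),
#' the two-sided p-value of the one-sample t test of mean = 0, and the
#' proportion of records with negative (mitigating) effects. Records are
#' unweighted, as appropriate when per-record variances are unavailable.
#'
#' @param records data frame with columns `treatment_n2o` and `control_n2o`
#'   (optionally `study_id`), or a numeric vector of precomputed response
#'   ratios in percent.
#' @param confidence confidence level in (0, 1), default 0.95.
#' @param type response-ratio type passed to [response_ratio()].
#' @return An object of class `meta_summary`: `n`, `mean_rr`, `sd_rr`,
#'   `ci_low`, `ci_high`, `p_value`, `prop_negative`, `confidence`,
#'   `degenerate` (TRUE when the SD is zero and p is not defined), and the
#'   per-record `rr` vector.
#' @examples
#' summarize_effects(c(-10, 0, 10)) # mean 0, p = 1
#' @export
summarize_effects <- function(records, confidence = 0.95,
                              type = c("percent", "log")) {
  type <- match.arg(type)
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence <= 0 || confidence >= 1)
    abort_config("'confidence' must be inside (0, 1)")
  if (is.data.frame(records)) {
    req <- c("treatment_n2o", "control_n2o")
    if (!all(req %in% names(records)))
      abort_input("records need columns treatment_n2o and control_n2o")
    rr <- response_ratio(records$treatment_n2o, records$control_n2o, type = type)
  } else {
    rr <- as.numeric(records)
    if (any(!is.finite(rr))) abort_input("response ratios must be finite")
  }
  n <- length(rr)
  if (n < 2L) abort_input("need at least 2 records")
  m <- mean(rr)
  s <- stats::sd(rr)
  se <- s / sqrt(n)
  t_crit <- stats::qt(1 - (1 - confidence) / 2, df = n - 1)
  degenerate <- s == 0
  p <- if (degenerate) {
    if (m == 0) 1 else 0  # all records identical: p collapses
  } else {
    2 * stats::pt(abs(m / se), df = n - 1, lower.tail = FALSE)
  }
  structure(list(n = n, mean_rr = m, sd_rr = s,
                 ci_low = m - t_crit * se, ci_high = m + t_crit * se,
                 p_value = p, prop_negative = mean(rr < 0),
                 confidence = confidence, type = type,
                 degenerate = degenerate, rr = rr),
            class = "meta_summary")
}

#' @export
print.meta_summary <- function(x, ...) {
  cat(sprintf(paste0("<meta_summary> n = %d: mean RR %0.2f%% (SD %0.2f), ",
                     "%g%% CI [%0.2f, %0.2f], p = %0.4g, %0.1f%% negative%s\n"),
              x$n, x$mean_rr, x$sd_rr, 100 * x$confidence, x$ci_low, x$ci_high,
              x$p_value, 100 * x$prop_negative,
              if (x$degenerate) " [degenerate: zero SD]" else ""))
  invisible(x)
}
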