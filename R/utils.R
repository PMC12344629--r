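#' Round half away from zero at a fixed number of decimals
#'
#' Base R's `round()` rounds half to even (IEC 60559). Printed field tables in
#' agronomy are conventionally rounded half-up; this helper reproduces that
#' convention so reported cells can be matched at their printed precision.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.685, 2) # 0.69, where round(0.685, 2) gives 0.68
#' @export
round_half_up <- function(x, digits = 0) {
  # the sqrt(eps) nudge keeps exact decimal halves (e.g. 3.755) that sit just
  # below .5 after binary representation from rounding down
  scale <- 10^digits
  sign(x) * trunc(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Internal: stop with a consistent classed condition so callers can
# distinguish validation problems from I/O problems.
abort_input <- function(msg, class = "n2okit_input_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_config <- function(msg) abort_input(msg, class = "n2okit_config_error")

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_input(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    abort_input(sprintf("'%s' must be > 0", name))
  invisible(x)
}
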