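#' N2O isotopomer measurement
#'
#' Holds the intramolecular nitrogen isotope deltas of N2O — delta15N-alpha
#' (central N) and delta15N-beta (terminal N), per mil vs AIR-N2 — the oxygen
#' delta18O (per mil vs VSMOW), and the N2O mixing ratio. The bulk nitrogen
#' delta and the site preference are derived:
#'
#' delta15N_bulk = (alpha + beta) / 2,  SP = alpha - beta.
#'
#' A measurement can be built either from (alpha, beta) or from (bulk, sp);
#' the two parameterisations are mutually inverse:
#' alpha = bulk + sp/2, beta = bulk - sp/2.
#'
#' @param d15n_alpha,d15n_beta per-mil deltas of the central/terminal N.
#' @param d15n_bulk,sp alternative parameterisation (supply either pair).
#' @param d18o per-mil delta18O.
#' @param concentration_ppb N2O mixing ratio, ppb (> 0).
#' @param sample_id optional identifier.
#' @return An object of class `isotopomer_measurement` with fields
#'   `d15n_alpha`, `d15n_beta`, `d15n_bulk`, `sp`, `d18o`, `concentration_ppb`.
#' @examples
#' m <- isotopomer_measurement(d15n_alpha = 30, d15n_beta = 10,
#'                             d18o = 44, concentration_ppb = 500)
#' m$d15n_bulk # 20
#' m$sp        # 20
#' @export
isotopomer_measurement <- function(d15n_alpha = NULL, d15n_beta = NULL,
                                   d15n_bulk = NULL, sp = NULL,
                                   d18o, concentration_ppb,
                                   sample_id = NA_character_) {
  from_ab <- !is.null(d15n_alpha) && !is.null(d15n_beta)
  from_bs <- !is.null(d15n_bulk) && !is.null(sp)
  if (from_ab == from_bs)
    abort_input("supply exactly one of (d15n_alpha, d15n_beta) or (d15n_bulk, sp)")
  if (from_bs) {
    d15n_alpha <- d15n_bulk + sp / 2
    d15n_beta <- d15n_bulk - sp / 2
  }
  stopifnot_scalar_number(d15n_alpha, "d15n_alpha")
  stopifnot_scalar_number(d15n_beta, "d15n_beta")
  stopifnot_scalar_number(d18o, "d18o")
  stopifnot_scalar_number(concentration_ppb, "concentration_ppb", positive = TRUE)
  structure(list(sample_id = as.character(sample_id),
                 d15n_alpha = d15n_alpha, d15n_beta = d15n_beta,
                 d15n_bulk = (d15n_alpha + d15n_beta) / 2,
                 sp = d15n_alpha - d15n_beta,
                 d18o = d18o,
                 concentration_ppb = concentration_ppb),
            class = "isotopomer_measurement")
}

#' @export
print.isotopomer_measurement <- function(x, ...) {
  cat(sprintf(paste0("<isotopomer_measurement> %s: d15Na %0.2f, d15Nb %0.2f ",
                     "(bulk %0.2f, SP %0.2f), d18O %0.2f permil; %0.1f ppb\n"),
              x$sample_id, x$d15n_alpha, x$d15n_beta, x$d15n_bulk, x$sp,
              x$d18o, x$concentration_ppb))
  invisible(x)
}

#' Ambient (background) air isotopic reference
#'
#' Tropospheric N2O background used in the two-endmember mass-balance
#' correction. No default values ship with the package: the reference (e.g. a
#' Northern-Hemisphere mean for the sampling year) must come from the user's
#' calibration source.
#'
#' @param d15n_bulk,sp,d18o per-mil deltas of ambient N2O.
#' @param concentration_ppb ambient N2O mixing ratio, ppb (>= 0; 0 means no
#'   background, in which case corrections are the identity).
#' @return An object of class `ambient_reference`.
#' @export
ambient_reference <- function(d15n_bulk, sp, d18o, concentration_ppb) {
  stopifnot_scalar_number(d15n_bulk, "d15n_bulk")
  stopifnot_scalar_number(sp, "sp")
  stopifnot_scalar_number(d18o, "d18o")
  stopifnot_scalar_number(concentration_ppb, "concentration_ppb")
  if (concentration_ppb < 0) abort_input("'concentration_ppb' must be >= 0")
  structure(list(d15n_bulk = d15n_bulk, sp = sp, d18o = d18o,
                 d15n_alpha = d15n_bulk + sp / 2,
                 d15n_beta = d15n_bulk - sp / 2,
                 concentration_ppb = concentration_ppb),
            class = "ambient_reference")
}

# Internal: one-axis two-pool mass balance
# delta_soil = (delta_obs * C_obs - delta_amb * C_amb) / (C_obs - C_amb)
mass_balance_correct <- function(delta_obs, c_obs, delta_amb, c_amb) {
  (delta_obs * c_obs - delta_amb * c_amb) / (c_obs - c_amb)
}

#' Ambient-air mass-balance correction of headspace isotope data
#'
#' The chamber headspace holds a mixture of background air and soil-emitted
#' N2O; for every delta axis the observed signature obeys
#' `delta_obs * C_obs = delta_amb * C_amb + delta_soil * C_soil` with
#' `C_soil = C_obs - C_amb`. Solving for delta_soil isolates the isotopic
#' signature of the soil-emitted N2O.
#'
#' The mass balance is linear in delta, so correcting alpha and beta and then
#' recomputing SP is algebraically identical to correcting SP directly; both
#' routes are available via `route` and agree to machine precision.
#'
#' @param obs an [isotopomer_measurement()].
#' @param ambient an [ambient_reference()]; observed concentration must
#'   exceed the ambient concentration.
#' @param route `"alpha_beta"` (default) corrects the two isotopomer deltas
#'   and derives bulk/SP; `"bulk_sp"` corrects bulk and SP directly.
#' @return An object of class `source_signature`: `d15n_bulk`, `sp`, `d18o`,
#'   `d15n_alpha`, `d15n_beta`, `soil_concentration_ppb`, plus optional
#'   `*_sd` uncertainty fields (filled by [propagate_uncertainty()]).
#' @examples
#' amb <- ambient_reference(0, 0, 0, 330)
#' obs <- isotopomer_measurement(d15n_bulk = 6.7, sp = 6.7, d18o = 6.7,
#'                               concentration_ppb = 1000)
#' ambient_correction(obs, amb)$d15n_bulk # 10: the undiluted soil signature
#' @export
ambient_correction <- function(obs, ambient, route = c("alpha_beta", "bulk_sp")) {
  route <- match.arg(route)
  if (!inherits(obs, "isotopomer_measurement"))
    abort_input("'obs' must be an isotopomer_measurement")
  if (!inherits(ambient, "ambient_reference"))
    abort_input("'ambient' must be an ambient_reference")
  c_obs <- obs$concentration_ppb
  c_amb <- ambient$concentration_ppb
  if (c_obs <= c_amb)
    abort_input("no detectable soil contribution: observed concentration <= ambient")
  d18o <- mass_balance_correct(obs$d18o, c_obs, ambient$d18o, c_amb)
  if (route == "alpha_beta") {
    a <- mass_balance_correct(obs$d15n_alpha, c_obs, ambient$d15n_alpha, c_amb)
    b <- mass_balance_correct(obs$d15n_beta, c_obs, ambient$d15n_beta, c_amb)
    bulk <- (a + b) / 2
    sp <- a - b
  } else {
    bulk <- mass_balance_correct(obs$d15n_bulk, c_obs, ambient$d15n_bulk, c_amb)
    sp <- mass_balance_correct(obs$sp, c_obs, ambient$sp, c_amb)
    a <- bulk + sp / 2
    b <- bulk - sp / 2
  }
  structure(list(sample_id = obs$sample_id,
                 d15n_bulk = bulk, sp = sp, d18o = d18o,
                 d15n_alpha = a, d15n_beta = b,
                 soil_concentration_ppb = c_obs - c_amb,
                 route = route),
            class = "source_signature")
}

#' @export
print.source_signature <- function(x, ...) {
  cat(sprintf(paste0("<source_signature> %s: d15N_bulk %0.2f, SP %0.2f, ",
                     "d18O %0.2f permil (soil N2O %0.1f ppb)\n"),
              x$sample_id, x$d15n_bulk, x$sp, x$d18o, x$soil_concentration_ppb))
  if (!is.null(x$d15n_bulk_sd))
    cat(sprintf("  MC sd: bulk %0.3f, SP %0.3f, d18O %0.3f permil (%d draws kept)\n",
                x$d15n_bulk_sd, x$sp_sd, x$d18o_sd, x$n_kept))
  invisible(x)
}

#' End-member domain in N2O isotope space
#'
#' Axis-aligned box delimiting the isotopic signature of one production
#' pathway — nitrification (Ni), bacterial denitrification (bD), nitrifier
#' denitrification (nD) or fungal denitrification (fD). End-member ranges are
#' user-supplied from a published compilation; the package ships no values.
#'
#' @param name label, e.g. `"bD"`.
#' @param sp_range length-2 numeric, SP min/max, per mil (required axis).
#' @param d15n_bulk_range,d18o_range optional length-2 numeric ranges; at
#'   least one of them must be supplied in addition to SP.
#' @return An object of class `endmember_domain`.
#' @export
endmember_domain <- function(name, sp_range, d15n_bulk_range = NULL,
                             d18o_range = NULL) {
  chk <- function(r, nm) {
    if (is.null(r)) return(NULL)
    r <- as.numeric(r)
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      abort_input(sprintf("'%s' must be a finite [min, max] pair", nm))
    r
  }
  sp_range <- chk(sp_range, "sp_range")
  if (is.null(sp_range)) abort_input("'sp_range' is required")
  d15n_bulk_range <- chk(d15n_bulk_range, "d15n_bulk_range")
  d18o_range <- chk(d18o_range, "d18o_range")
  if (is.null(d15n_bulk_range) && is.null(d18o_range))
    abort_input("supply at least one of d15n_bulk_range / d18o_range besides SP")
  structure(list(name = as.character(name), sp_range = sp_range,
                 d15n_bulk_range = d15n_bulk_range, d18o_range = d18o_range),
            class = "endmember_domain")
}

# Internal: per-axis outside distance of value v from range r (0 if inside)
axis_outside_distance <- function(v, r) max(0, r[1] - v, v - r[2])

#' Classify a source signature against end-member domains
#'
#' Reports every domain whose box contains the corrected soil signature on
#' all of its supplied axes. When no box contains it, the nearest domain by
#' Euclidean box-edge distance over the supplied axes is reported; distances
#' can be scaled per axis (`scales`) to weight per-mil units differently —
#' default unit scaling. Distance is 0 exactly when the point is inside.
#'
#' @param sig a [ambient_correction()] result (or any list with `sp`,
#'   `d15n_bulk`, `d18o`).
#' @param domains list of [endmember_domain()] objects; may overlap.
#' @param scales named numeric, per-axis division factors for the distance,
#'   e.g. `c(sp = 1, d15n_bulk = 1, d18o = 1)`.
#' @return An object of class `source_classification`: `membership`
#'   (character vector of containing domain names, possibly empty), `nearest`
#'   (name of the closest domain), and `distances` (named numeric, box-edge
#'   distance to every domain).
#' @export
classify_source <- function(sig, domains,
                            scales = c(sp = 1, d15n_bulk = 1, d18o = 1)) {
  if (inherits(domains, "endmember_domain")) domains <- list(domains)
  if (length(domains) == 0L) abort_config("no end-member domains supplied")
  point <- c(sp = sig$sp, d15n_bulk = sig$d15n_bulk, d18o = sig$d18o)
  dist_one <- function(dom) {
    d2 <- (axis_outside_distance(point[["sp"]], dom$sp_range) / scales[["sp"]])^2
    if (!is.null(dom$d15n_bulk_range))
      d2 <- d2 + (axis_outside_distance(point[["d15n_bulk"]], dom$d15n_bulk_range) /
                    scales[["d15n_bulk"]])^2
    if (!is.null(dom$d18o_range))
      d2 <- d2 + (axis_outside_distance(point[["d18o"]], dom$d18o_range) /
                    scales[["d18o"]])^2
    sqrt(d2)
  }
  distances <- vapply(domains, dist_one, numeric(1))
  names(distances) <- vapply(domains, `[[`, character(1), "name")
  membership <- names(distances)[distances == 0]
  structure(list(membership = membership,
                 nearest = names(distances)[which.min(distances)],
                 distances = distances),
            class = "source_classification")
}

#' @export
print.source_classification <- function(x, ...) {
  if (length(x$membership))
    cat("<source_classification> inside:", paste(x$membership, collapse = ", "), "\n")
  else
    cat(sprintf("<source_classification> outside all domains; nearest %s (distance %0.3g)\n",
                x$nearest, min(x$distances)))
  invisible(x)
}

#' Two-endmember mixing fraction
#'
#' Linear position of `value` between two end-member values:
#' f = (value - end_a) / (end_b - end_a). Fractions outside \[0, 1\] are
#' returned unclamped with `out_of_range = TRUE` so callers can decide how to
#' treat signatures beyond the end-member span.
#'
#' @param value observed delta, per mil.
#' @param end_a,end_b end-member deltas (must differ).
#' @return list with `fraction` and `out_of_range`.
#' @examples
#' mixing_fraction(20.3, 0, 30)$fraction # 0.677
#' @export
mixing_fraction <- function(value, end_a, end_b) {
  stopifnot_scalar_number(value, "value")
  stopifnot_scalar_number(end_a, "end_a")
  stopifnot_scalar_number(end_b, "end_b")
  if (end_a == end_b) abort_input("degenerate end-members: end_a equals end_b")
  f <- (value - end_a) / (end_b - end_a)
  list(fraction = f, out_of_range = f < 0 || f > 1)
}

#' Instrument precisions for N2O isotopomer measurements
#'
#' One-sigma measurement precisions of the isotope-ratio mass spectrometry,
#' per mil. Defaults follow typical continuous-flow IRMS performance for N2O
#' isotopomers: 0.2 for delta15N-bulk, 0.3 for delta18O and 0.5 for each of
#' delta15N-alpha/beta.
#'
#' @param sigma_bulk,sigma_d18o,sigma_alpha,sigma_beta per-mil 1-sigma
#'   precisions (> 0).
#' @return An object of class `instrument_precision`.
#' @export
instrument_precision <- function(sigma_bulk = 0.2, sigma_d18o = 0.3,
                                 sigma_alpha = 0.5, sigma_beta = 0.5) {
  # zero is admitted as the degenerate (noise-free) limit used in round-trip
  # checks; negative sigmas are invalid
  for (nm in c("sigma_bulk", "sigma_d18o", "sigma_alpha", "sigma_beta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      abort_input(sprintf("'%s' must be >= 0", nm))
  }
  structure(list(sigma_bulk = sigma_bulk, sigma_d18o = sigma_d18o,
                 sigma_alpha = sigma_alpha, sigma_beta = sigma_beta),
            class = "instrument_precision")
}

#' Monte-Carlo propagation of instrument noise through the ambient correction
#'
#' Perturbs the observed delta15N-alpha, delta15N-beta and delta18O with
#' independent Gaussian noise at the stated instrument precisions, re-runs
#' the mass-balance correction for each draw, and reports per-axis means and
#' standard deviations of the corrected soil signature. Concentrations are
#' not perturbed; draws where the observed concentration would not exceed
#' ambient are rejected and counted, and more than 50% rejections is an
#' error.
#'
#' @param obs an [isotopomer_measurement()].
#' @param ambient an [ambient_reference()].
#' @param precision an [instrument_precision()].
#' @param n_draws number of Monte-Carlo draws (>= 100).
#' @param seed integer seed; identical seeds give identical output.
#' @return A `source_signature` whose deltas are the MC means, with `*_sd`
#'   fields (`d15n_bulk_sd`, `sp_sd`, `d18o_sd`, `d15n_alpha_sd`,
#'   `d15n_beta_sd`), `n_kept` and `n_rejected`.
#' @export
propagate_uncertainty <- function(obs, ambient, precision = instrument_precision(),
                                  n_draws = 10000, seed) {
  if (missing(seed)) abort_input("'seed' must be supplied for reproducibility")
  if (!is.numeric(n_draws) || n_draws < 100)
    abort_input("'n_draws' must be >= 100")
  if (!inherits(precision, "instrument_precision"))
    abort_input("'precision' must be an instrument_precision")
  n_draws <- as.integer(n_draws)
  noise <- withr::with_seed(as.integer(seed), list(
    a = stats::rnorm(n_draws, 0, precision$sigma_alpha),
    b = stats::rnorm(n_draws, 0, precision$sigma_beta),
    o = stats::rnorm(n_draws, 0, precision$sigma_d18o)
  ))
  a <- obs$d15n_alpha + noise$a
  b <- obs$d15n_beta + noise$b
  o <- obs$d18o + noise$o
  c_obs <- obs$concentration_ppb
  c_amb <- ambient$concentration_ppb
  keep <- rep(c_obs > c_amb, n_draws)
  n_rejected <- sum(!keep)
  if (n_rejected > n_draws / 2)
    abort_input("more than 50% of Monte-Carlo draws rejected (no soil contribution)")
  a_s <- mass_balance_correct(a[keep], c_obs, ambient$d15n_alpha, c_amb)
  b_s <- mass_balance_correct(b[keep], c_obs, ambient$d15n_beta, c_amb)
  o_s <- mass_balance_correct(o[keep], c_obs, ambient$d18o, c_amb)
  bulk_s <- (a_s + b_s) / 2
  sp_s <- a_s - b_s
  structure(list(sample_id = obs$sample_id,
                 d15n_bulk = mean(bulk_s), sp = mean(sp_s), d18o = mean(o_s),
                 d15n_alpha = mean(a_s), d15n_beta = mean(b_s),
                 soil_concentration_ppb = c_obs - c_amb,
                 d15n_bulk_sd = stats::sd(bulk_s), sp_sd = stats::sd(sp_s),
                 d18o_sd = stats::sd(o_s),
                 d15n_alpha_sd = stats::sd(a_s), d15n_beta_sd = stats::sd(b_s),
                 n_kept = sum(keep), n_rejected = n_rejected,
                 route = "alpha_beta"),
            class = "source_signature")
}
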