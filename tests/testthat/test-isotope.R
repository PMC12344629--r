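test_that("bulk/SP and alpha/beta parameterisations are mutual inverses", {
  m <- isotopomer_measurement(d15n_alpha = 30, d15n_beta = 10,
                              d18o = 44, concentration_ppb = 500)
  expect_equal(m$d15n_bulk, 20)
  expect_equal(m$sp, 20)

  # alpha = beta: symmetric molecule signal
  m2 <- isotopomer_measurement(d15n_alpha = 5, d15n_beta = 5,
                               d18o = 44, concentration_ppb = 500)
  expect_equal(m2$sp, 0)

  # inversion of the defining equations for the measured bulk/SP pair
  m3 <- isotopomer_measurement(d15n_bulk = 3.8, sp = 12.8,
                               d18o = 43.8, concentration_ppb = 800)
  expect_equal(m3$d15n_alpha, 10.2)
  expect_equal(m3$d15n_beta, -2.6)

  # round trip on arbitrary values to machine precision
  for (ab in list(c(7.3, -2.1), c(-15, 42), c(0, 0))) {
    m4 <- isotopomer_measurement(d15n_alpha = ab[1], d15n_beta = ab[2],
                                 d18o = 40, concentration_ppb = 400)
    m5 <- isotopomer_measurement(d15n_bulk = m4$d15n_bulk, sp = m4$sp,
                                 d18o = 40, concentration_ppb = 400)
    expect_equal(m5$d15n_alpha, ab[1])
    expect_equal(m5$d15n_beta, ab[2])
  }

  expect_error(isotopomer_measurement(d15n_alpha = 1, d15n_beta = 1, d18o = 0,
                                      concentration_ppb = 0), "> 0")
  expect_error(isotopomer_measurement(d15n_alpha = 1, d18o = 0,
                                      concentration_ppb = 10), "exactly one")
})

test_that("ambient correction inverts the two-pool mass balance", {
  amb <- ambient_reference(0, 0, 0, 330)
  # delta_amb 0 at 330 ppb + delta_soil 10 at 670 ppb -> delta_obs 6.7 at 1000 ppb
  obs <- isotopomer_measurement(d15n_bulk = 6.7, sp = 6.7, d18o = 6.7,
                                concentration_ppb = 1000)
  sig <- ambient_correction(obs, amb)
  expect_equal(sig$d15n_bulk, 10)
  expect_equal(sig$sp, 10)
  expect_equal(sig$d18o, 10)
  expect_equal(sig$soil_concentration_ppb, 670)

  # fixed point: observed equals ambient signature
  amb2 <- test_ambient()
  obs2 <- isotopomer_measurement(d15n_bulk = amb2$d15n_bulk, sp = amb2$sp,
                                 d18o = amb2$d18o, concentration_ppb = 700)
  sig2 <- ambient_correction(obs2, amb2)
  expect_equal(sig2$d15n_bulk, amb2$d15n_bulk)
  expect_equal(sig2$sp, amb2$sp)
  expect_equal(sig2$d18o, amb2$d18o)

  # zero background: correction is the identity
  amb0 <- ambient_reference(5, 5, 5, 0)
  obs0 <- isotopomer_measurement(d15n_bulk = -3, sp = 21, d18o = 42,
                                 concentration_ppb = 500)
  sig0 <- ambient_correction(obs0, amb0)
  expect_equal(sig0$d15n_bulk, -3)
  expect_equal(sig0$sp, 21)

  expect_error(ambient_correction(
    isotopomer_measurement(d15n_bulk = 0, sp = 0, d18o = 0, concentration_ppb = 300),
    test_ambient(330)), "no detectable soil contribution")
})

test_that("alpha/beta and bulk/SP correction routes agree", {
  amb <- test_ambient()
  for (seed in 1:20) {
    mix <- simulate_isotope_mixture(
      list(d15n_bulk = -2.7 + seed, sp = 20.3 - seed / 2, d18o = 42.8),
      amb, soil_concentration_ppb = 50 + 20 * seed,
      precision = instrument_precision(0.2, 0.3, 0.5, 0.5), seed = seed)
    r1 <- ambient_correction(mix, amb, route = "alpha_beta")
    r2 <- ambient_correction(mix, amb, route = "bulk_sp")
    expect_equal(r1$sp, r2$sp)
    expect_equal(r1$d15n_bulk, r2$d15n_bulk)
    expect_equal(r1$d15n_alpha, r2$d15n_alpha)
  }
})

test_that("synthetic mixtures are corrected exactly on all axes at zero noise", {
  amb <- test_ambient()
  p0 <- instrument_precision(0, 0, 0, 0)
  for (seed in 1:10) {
    src <- list(d15n_bulk = stats::runif(1, -30, 10), sp = stats::runif(1, -10, 35),
                d18o = stats::runif(1, 20, 60))
    mix <- simulate_isotope_mixture(src, amb, soil_concentration_ppb = 420,
                                    precision = p0, seed = seed)
    sig <- ambient_correction(mix, amb)
    expect_equal(sig$d15n_bulk, src$d15n_bulk, tolerance = 1e-12)
    expect_equal(sig$sp, src$sp, tolerance = 1e-12)
    expect_equal(sig$d18o, src$d18o, tolerance = 1e-12)
  }
})

test_that("corrected values converge to observed as ambient concentration vanishes", {
  obs <- isotopomer_measurement(d15n_bulk = -2.7, sp = 20.3, d18o = 42.8,
                                concentration_ppb = 900)
  amb <- ambient_reference(6.2, 18.7, 44.3, 1e-6 * 900)
  sig <- ambient_correction(obs, amb)
  expect_equal(sig$d15n_bulk, obs$d15n_bulk, tolerance = 1e-4)
  expect_equal(sig$sp, obs$sp, tolerance = 1e-4)
  expect_equal(sig$d18o, obs$d18o, tolerance = 1e-4)
})

test_that("correction moves deltas away from the ambient endmember", {
  # soil-dominant mixture: observed sits between soil and ambient, so the
  # corrected value lies on the far side of the observation from ambient
  amb <- test_ambient()
  src <- list(d15n_bulk = -5, sp = 14, d18o = 41)
  mix <- simulate_isotope_mixture(src, amb, soil_concentration_ppb = 1200,
                                  precision = instrument_precision(0, 0, 0, 0),
                                  seed = 1)
  sig <- ambient_correction(mix, amb)
  for (ax in c("d15n_bulk", "sp", "d18o")) {
    expect_gt(abs(sig[[ax]] - amb[[ax]]), abs(mix[[ax]] - amb[[ax]]))
  }
  # and specifically bulk decreases when ambient is enriched relative to soil
  expect_lt(sig$d15n_bulk, mix$d15n_bulk)
})

test_that("domain classification reports containment, overlap and nearest box", {
  doms <- test_domains()
  inside_bd <- list(sp = -3, d15n_bulk = -20, d18o = 45)
  cl <- classify_source(inside_bd, doms)
  expect_setequal(cl$membership, c("bD", "nD"))  # overlapping boxes both reported
  expect_equal(min(cl$distances), 0)

  only_ni <- list(sp = 28, d15n_bulk = -20, d18o = 45)
  cl2 <- classify_source(only_ni, doms)
  expect_equal(cl2$membership, "Ni")
  expect_equal(unname(cl2$distances[["Ni"]]), 0)

  # point one SP unit above the bD box whose bulk axis contains it
  outside <- list(sp = 6, d15n_bulk = -5, d18o = 45)
  cl3 <- classify_source(outside, doms)
  expect_length(cl3$membership, 0)
  expect_equal(cl3$nearest, "bD")
  expect_equal(unname(cl3$distances[["bD"]]), 1)

  expect_error(classify_source(inside_bd, list()), class = "n2okit_config_error")
})

test_that("classification distance is zero iff membership is non-empty", {
  doms <- test_domains()
  set.seed(7)
  for (i in 1:50) {
    pt <- list(sp = stats::runif(1, -30, 60), d15n_bulk = stats::runif(1, -80, 30),
               d18o = stats::runif(1, 0, 80))
    cl <- classify_source(pt, doms)
    expect_identical(length(cl$membership) > 0, min(cl$distances) == 0)
  }
})

test_that("mixing fraction is the linear position between endmembers", {
  expect_equal(mixing_fraction(15, 10, 20)$fraction, 0.5)
  expect_equal(mixing_fraction(10, 10, 20)$fraction, 0)
  expect_equal(mixing_fraction(20, 10, 20)$fraction, 1)
  mf <- mixing_fraction(20.3, 0, 30)
  expect_equal(mf$fraction, 0.677, tolerance = 1e-3)
  expect_false(mf$out_of_range)
  expect_true(mixing_fraction(35, 0, 30)$out_of_range)
  expect_error(mixing_fraction(1, 5, 5), "degenerate")
})

test_that("Monte-Carlo propagation is seeded, unbiased and matches closed form", {
  obs <- isotopomer_measurement(d15n_bulk = 5, sp = 15, d18o = 40,
                                concentration_ppb = 1000)
  amb0 <- ambient_reference(0, 0, 0, 1e-9)

  # degenerate noise: sd 0, mean equals the deterministic correction
  p0 <- instrument_precision(0, 0, 0, 0)
  r0 <- propagate_uncertainty(obs, amb0, p0, n_draws = 200, seed = 11)
  expect_equal(r0$sp_sd, 0)
  det <- ambient_correction(obs, amb0)
  expect_equal(r0$sp, det$sp)
  expect_equal(r0$d15n_bulk, det$d15n_bulk)

  # determinism: same seed, identical summaries
  p <- instrument_precision()
  r1 <- propagate_uncertainty(obs, amb0, p, n_draws = 500, seed = 99)
  r2 <- propagate_uncertainty(obs, amb0, p, n_draws = 500, seed = 99)
  expect_identical(r1, r2)

  # closed form: SP sd = sqrt(sigma_a^2 + sigma_b^2) with no ambient dilution
  r3 <- propagate_uncertainty(obs, amb0, p, n_draws = 1e5, seed = 5)
  expect_equal(r3$sp_sd, sqrt(0.5^2 + 0.5^2), tolerance = 0.02)
})

test_that("propagation rejects draws with no soil contribution", {
  obs <- isotopomer_measurement(d15n_bulk = 5, sp = 15, d18o = 40,
                                concentration_ppb = 300)
  expect_error(propagate_uncertainty(obs, test_ambient(330),
                                     instrument_precision(), n_draws = 200,
                                     seed = 1),
               "rejected")
})
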