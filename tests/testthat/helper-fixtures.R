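# Shared fixtures: the standard microcosm jar geometry (400 g soil, 460 cm3
# headspace, 25 C) and a field chamber, plus a generic ambient reference.

jar_geometry <- function(...) {
  chamber_geometry(headspace_volume_cm3 = 460, basis = "per_soil_mass",
                   soil_mass_g = 400, temperature_K = 298.15, ...)
}

field_geometry <- function(...) {
  chamber_geometry(headspace_volume_cm3 = 1500, basis = "per_area",
                   footprint_area_m2 = 0.032, temperature_K = 298.15, ...)
}

test_ambient <- function(conc = 330) {
  ambient_reference(d15n_bulk = 6.2, sp = 18.7, d18o = 44.3,
                    concentration_ppb = conc)
}

# Four-pathway endmember box set with made-up but plausibly shaped ranges
test_domains <- function() {
  list(
    endmember_domain("Ni", sp_range = c(25, 35), d15n_bulk_range = c(-60, 0)),
    endmember_domain("bD", sp_range = c(-10, 5), d15n_bulk_range = c(-50, 10)),
    endmember_domain("nD", sp_range = c(-13, 0), d15n_bulk_range = c(-60, -10)),
    endmember_domain("fD", sp_range = c(30, 40), d15n_bulk_range = c(-50, 10))
  )
}
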