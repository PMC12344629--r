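# n2okit run configuration template.
# End-member domain ranges and the ambient reference below are SYNTHETIC
# placeholders: fill them from your calibration source and a published
# end-member compilation before use.

geometry:
  headspace_volume_cm3: 460
  basis: per_soil_mass        # or per_area (then footprint_area_m2 instead)
  soil_mass_g: 400
  temperature_K: 298.15
  standard_temperature_K: 273.15
  # gas_density_g_m3: 1963.6  # override N2O density at standard conditions

ambient:                      # background tropospheric N2O (synthetic values)
  d15n_bulk: 6.0
  sp: 18.0
  d18o: 44.0
  concentration_ppb: 330

domains:                      # axis-aligned boxes in (SP, d15N_bulk, d18O)
  - name: Ni                  # nitrification (synthetic ranges)
    sp_range: [25, 35]
    d15n_bulk_range: [-60, 0]
  - name: bD                  # bacterial denitrification (synthetic ranges)
    sp_range: [-10, 5]
    d15n_bulk_range: [-50, 10]
  - name: nD                  # nitrifier denitrification (synthetic ranges)
    sp_range: [-13, 0]
    d15n_bulk_range: [-60, -10]
  - name: fD                  # fungal denitrification (synthetic ranges)
    sp_range: [30, 40]
    d15n_bulk_range: [-50, 10]

analysis:
  alpha: 0.05
  confidence: 0.95
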