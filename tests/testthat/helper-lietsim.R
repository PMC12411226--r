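# Shared fixtures. Unit tests run the periodic solver at reduced settings
# (N = 11-21 harmonics, coarse grids); the acceptance tests use the
# spec-level settings.

fix_char <- default_device("characterization")
fix_sens <- default_device("sensing")
fix_bands <- electronic_bands()

# one cached curly-G evaluation used by several photonic tests
gap_intensity <- function(device, lambda_nm, theta_rad, N = 21,
                          n_dip = 11, from = "superstrate") {
  angle_resolved_photonic(device, lambda_nm, theta_rad,
                          x_nm = dipole_positions(device, n_dip),
                          N = N, from = from)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
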