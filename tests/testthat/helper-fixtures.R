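# Shared study conditions: a POPC-like stack (d = 53 A, eta = 0.1,
# xi = 60 A -> kappa ~ 20 kBT at 298 K) with the domain sizes used
# throughout the package checks. Correlation tables are fetched through
# the package's session cache so the quadrature cost is paid once per
# test run.

test_p <- function() caille_parameters(eta = 0.1, xi = 60, d = 53)

test_m <- function() {
  finite_size_model(Lr_mean = 3000, Lr_sigma = 1000,
                    Lz_mean = 530, Lz_sigma = 106, d = 53)
}

test_geometry <- function() {
  detector_geometry(distance_mm = 200, pixel_mm = 0.1,
                    beam_center = c(195, 115), wavelength = 1.5418)
}

# main shared table: 1500 radius nodes, n up to the axial support
test_unit_table <- function() {
  unit_correlation_table(r_grid = default_r_grid(n_nodes = 1500),
                         n_max = 30L)
}

test_corr <- function(p = test_p()) rescale_correlation(test_unit_table(), p)

test_fit_config <- function(eta_init = 0.15, xi_init = 40, ...) {
  fit_config(eta_init = eta_init, xi_init = xi_init,
             size_model = test_m(), beam = beam_model(0.001), d = 53,
             control = sf_control(dr = 2), corr_table = test_unit_table(),
             ...)
}

test_fixture_spec <- function(..., diffuse_scale = 1e-9) {
  fixture_spec(test_p(), test_m(), beam = beam_model(0.001),
               diffuse_scale = diffuse_scale, control = sf_control(dr = 2),
               table_r_nodes = 1500L, table_n_max = 30L, ...)
}

# a qpar grid whose negative half is the exact negation of the positive
# half (seq() alone leaves last-ulp asymmetries)
sym_qpar <- function(step, qmax) {
  pos <- seq(step, qmax, by = step)
  c(-rev(pos), 0, pos)
}

new_intensity_map_for_test <- function(mat) {
  membranexds:::new_intensity_map(mat)
}

make_test_cut <- function(qpar, intensity, sigma = rep(1, length(qpar)),
                          qz = 0.35) {
  membranexds:::new_line_cut(qpar = qpar, intensity = intensity,
                             sigma = sigma, qz_center = qz)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * abs(expected)),
              label = sprintf("max rel dev %.3g vs tol %.3g",
                              max(abs(actual - expected) / abs(expected)),
                              tol))
}
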