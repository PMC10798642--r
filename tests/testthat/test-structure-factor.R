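test_that("Lambda kernel limits: qz = 0, Bragg maximum, decorrelation", {
  p <- test_p()
  m <- test_m()
  corr <- test_corr()
  r <- c(10, 100, 1000)
  # qz = 0: cos = 1, G = 1 -> Lambda = Hz(0) + 2 sum Hz(nd), r-independent
  lam0 <- lambda_kernel(r, qz = 0, corr = corr, m = m)
  n_all <- 1:corr$n_max
  expected <- size_weight_axial(0, m) + 2 * sum(size_weight_axial(n_all, m))
  expect_equal(lam0, rep(expected, 3), tolerance = 1e-9)
  # at qz = q1 all cosines are +1: Lambda maximal among qz in [q1/2, 3q1/2]
  qz_grid <- seq(0.5, 1.5, length.out = 21) * p$q1
  lams <- vapply(qz_grid, function(qq)
    lambda_kernel(100, qz = qq, corr = corr, m = m), numeric(1))
  expect_equal(which.max(lams), which.min(abs(qz_grid - p$q1)))
  # huge delta_u kills every n >= 1 term through G -> 0
  corr_huge <- corr
  corr_huge$values <- corr$values + 1e6
  lam_huge <- lambda_kernel(100, qz = p$q1, corr = corr_huge, m = m)
  g0 <- exp(-p$q1^2 * (corr$values[1, which.min(abs(corr$r_grid - 100))] + 1e6) / 2)
  expect_lt(abs(lam_huge), size_weight_axial(0, m) * 1e-3)
  # unit-scale table is rejected
  expect_error(lambda_kernel(100, qz = p$q1, corr = test_unit_table(), m = m),
               "unit scale")
})

test_that("structure factor is even in qpar and decays in the tail", {
  p <- test_p()
  m <- test_m()
  corr <- test_corr()
  qpar <- c(-0.1, -0.05, -0.01, 0.01, 0.05, 0.1)
  prof <- structure_factor_profile(3 * p$q1, qpar, p, m, corr,
                                   control = sf_control(dr = 2))
  expect_identical(prof$intensity[1:3], rev(prof$intensity[4:6]))
  expect_true(all(prof$intensity >= 0))
  # monotone tail beyond the domain-size scale
  v <- structure_factor_profile(3 * p$q1, c(0.05, 0.2), p, m, corr,
                                control = sf_control(dr = 2))$intensity
  expect_gt(v[1], v[2])
})

test_that("beam convolution: identity, conservation, semigroup", {
  grid <- seq(-0.2, 0.2, by = 0.002)
  x <- exp(-grid^2 / (2 * 0.03^2))
  expect_identical(convolve_beam(x, grid, beam_model(0)), x)
  # delta spike spreads into a discretized Gaussian of equal area
  spike <- numeric(length(grid)); spike[101] <- 7
  out <- convolve_beam(spike, grid, beam_model(0.004))
  expect_equal(sum(out), sum(spike), tolerance = 1e-3)
  expect_equal(out[101], 7 * dnorm(0, sd = 0.004) /
                 sum(dnorm(seq(-10, 10) * 0.002, sd = 0.004)),
               tolerance = 1e-6)
  # double convolution with sigma equals single with sigma*sqrt(2)
  d1 <- convolve_beam(convolve_beam(x, grid, beam_model(0.004)),
                      grid, beam_model(0.004))
  d2 <- convolve_beam(x, grid, beam_model(0.004 * sqrt(2)))
  expect_equal(d1, d2, tolerance = 1e-4)
  expect_error(beam_model(-1), "sigma_q")
  expect_error(convolve_beam(x, grid^2, beam_model(0.004)), "uniform")
})

test_that("map rows equal individual profiles and peak at lamellar orders", {
  p <- test_p()
  m <- test_m()
  corr <- test_corr()
  qpar <- sym_qpar(0.005, 0.1)
  qz_axis <- seq(2.5, 3.5, by = 0.05) * p$q1
  map <- structure_factor_map(qz_axis, qpar, p, m, corr,
                              beam = beam_model(0.001),
                              control = sf_control(dr = 2))
  # row consistency
  one <- structure_factor_profile(qz_axis[3], qpar, p, m, corr,
                                  control = sf_control(dr = 2))$intensity
  one <- convolve_beam(one, qpar, beam_model(0.001))
  row3 <- map$intensity[map$qz == qz_axis[3]]
  expect_identical(row3, one)
  # evenness of every row
  for (qq in qz_axis[c(1, 11, 21)]) {
    rowv <- map$intensity[map$qz == qq]
    expect_identical(rowv, rev(rowv))
  }
  # diffuse lobe centered at qz = 3 q1: that row has the largest intensity
  # at qpar = 0.02 among the scanned rows
  at_q <- map$intensity[abs(map$qpar - 0.02) < 1e-9]
  expect_equal(which.max(at_q), which.min(abs(qz_axis - 3 * p$q1)))
})
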