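test_that("chi-square definition and spreadsheet cross-check", {
  # single point: Y = 2, y = 1, sigma = 1, s = 1 -> 1
  mcut <- list(make_test_cut(0.01, 2))
  dcut <- list(make_test_cut(0.01, 1))
  expect_equal(chi_squared(mcut, dcut, 1), 1)
  # model = data, s = 1 -> 0
  same <- list(make_test_cut(seq(0.01, 0.05, by = 0.01), 1:5))
  expect_identical(chi_squared(same, same, 1), 0)
  # independent recomputation on a 2-cut, 5-point fixture
  set.seed(21)
  q <- seq(0.01, 0.05, by = 0.01)
  Y1 <- c(5, 4, 3, 2, 1); y1 <- c(5.5, 3.6, 3.1, 2.2, 0.8); s1 <- c(1, 2, 1, 2, 1)
  Y2 <- c(9, 7, 5, 3, 1); y2 <- c(8.2, 7.4, 4.9, 3.3, 1.1); s2 <- rep(0.5, 5)
  by_hand <- sum((2 * Y1 - y1)^2 / s1^2) + sum((0.5 * Y2 - y2)^2 / s2^2)
  got <- chi_squared(list(make_test_cut(q, Y1, s1), make_test_cut(q, Y2, s2)),
                     list(make_test_cut(q, y1, s1), make_test_cut(q, y2, s2)),
                     scales = c(2, 0.5))
  expect_equal(got, by_hand, tolerance = 1e-12)
  # sigma = 0 is rejected
  expect_error(chi_squared(mcut, list(make_test_cut(0.01, 1, sigma = 0)), 1),
               "sigma")
  # first-power weighting option
  got_p <- chi_squared(list(make_test_cut(q, Y1, s1)),
                       list(make_test_cut(q, y1, s1)), 1,
                       weighting = "sigma")
  expect_equal(got_p, sum((Y1 - y1)^2 / s1), tolerance = 1e-12)
})

test_that("optimal scales solve the weighted least-squares problem", {
  q <- seq(0.01, 0.1, by = 0.01)
  Y <- exp(-q * 20)
  # data = 3 * model -> s = 3 exactly
  s <- optimal_scales(list(make_test_cut(q, Y)),
                      list(make_test_cut(q, 3 * Y)))
  expect_equal(s, 3, tolerance = 1e-14)
  # uniform sigma: ratio of dot products
  set.seed(5)
  y <- 3 * Y + rnorm(10, sd = 0.01)
  s2 <- optimal_scales(list(make_test_cut(q, Y)), list(make_test_cut(q, y)))
  expect_equal(s2, sum(Y * y) / sum(Y^2), tolerance = 1e-14)
  # optimality: chi2 at s* beats 100 random perturbations
  chi_at <- function(sc) chi_squared(list(make_test_cut(q, Y)),
                                     list(make_test_cut(q, y)), sc)
  base <- chi_at(s2)
  for (pert in 1 + rnorm(100, sd = 0.1)) {
    expect_lte(base, chi_at(s2 * pert))
  }
  expect_error(optimal_scales(list(make_test_cut(q, rep(0, 10))),
                              list(make_test_cut(q, y))), "zero")
})

test_that("fit is invariant to cut order and to per-cut scaling of the data", {
  p <- test_p()
  spec <- test_fixture_spec(noise = "none")
  qpar <- seq(-0.15, 0.15, by = 0.003)
  ds <- make_line_cut_dataset(spec, qz_list = c(3, 3.5) * p$q1,
                              qpar_axis = qpar)
  cfg <- test_fit_config(max_iter = 60)
  fit_ab <- fit_structure_factor(ds$cuts, cfg)
  fit_ba <- fit_structure_factor(rev(ds$cuts), cfg)
  expect_equal(fit_ba$chisq, fit_ab$chisq, tolerance = 1e-9)
  expect_equal(fit_ba$eta, fit_ab$eta, tolerance = 1e-9)
  expect_equal(fit_ba$xi, fit_ab$xi, tolerance = 1e-9)
  # multiplying one data cut by a constant moves only its scale factor
  cuts_scaled <- ds$cuts
  cuts_scaled[[2]]$intensity <- 10 * cuts_scaled[[2]]$intensity
  cuts_scaled[[2]]$sigma <- 10 * cuts_scaled[[2]]$sigma
  fit_s <- fit_structure_factor(cuts_scaled, cfg)
  expect_equal(fit_s$eta, fit_ab$eta, tolerance = 1e-7)
  expect_equal(fit_s$xi, fit_ab$xi, tolerance = 1e-6)
  expect_equal(fit_s$scales[2] / fit_ab$scales[2], 10, tolerance = 1e-6)
  expect_equal(fit_s$scales[1], fit_ab$scales[1], tolerance = 1e-6)
})

test_that("accepted-step trace is nonincreasing and identifiability holds", {
  p <- test_p()
  spec <- test_fixture_spec(noise = "gaussian", noise_level = 0.01, seed = 3)
  qpar <- seq(-0.15, 0.15, by = 0.003)
  ds <- make_line_cut_dataset(spec, qz_list = c(3, 3.5) * p$q1,
                              qpar_axis = qpar)
  fit <- fit_structure_factor(ds$cuts, test_fit_config())
  expect_true(all(diff(fit$trace$chisq) <= 0))
  expect_true(fit$converged)
  # chi2 rises when either parameter is perturbed 20% off the optimum
  ev <- membranexds:::.make_fit_evaluator(ds$cuts, c(3, 3.5) * p$q1,
                                          test_fit_config())
  chi_opt <- sum(ev$residuals(fit$eta, fit$xi)^2)
  expect_gt(sum(ev$residuals(fit$eta * 1.2, fit$xi)^2), chi_opt)
  expect_gt(sum(ev$residuals(fit$eta, fit$xi * 1.2)^2), chi_opt)
  # moduli round trip consistency on the result
  p_back <- caille_from_moduli(fit$moduli, d = 53)
  expect_equal(p_back$eta, fit$eta, tolerance = 1e-12)
  expect_equal(p_back$xi, fit$xi, tolerance = 1e-12)
})

test_that("fit requires two cuts at distinct qz and honors the simplex option", {
  p <- test_p()
  spec <- test_fixture_spec(noise = "none")
  qpar <- seq(-0.1, 0.1, by = 0.004)
  ds <- make_line_cut_dataset(spec, qz_list = c(3, 3.5) * p$q1,
                              qpar_axis = qpar)
  expect_error(fit_structure_factor(ds$cuts[1], test_fit_config()),
               "at least two")
  same_q <- list(ds$cuts[[1]], ds$cuts[[1]])
  expect_error(fit_structure_factor(same_q, test_fit_config()), "distinct")
  # simplex fallback converges to the same optimum on clean data
  fit_s <- fit_structure_factor(ds$cuts,
                                test_fit_config(optimizer = "simplex",
                                                max_iter = 60))
  expect_rel_equal(fit_s$eta, 0.1, 0.02)
  expect_rel_equal(fit_s$xi, 60, 0.02)
})

test_that("tidiers and glance expose the fit in broom shape", {
  p <- test_p()
  spec <- test_fixture_spec(noise = "none")
  qpar <- seq(-0.1, 0.1, by = 0.004)
  ds <- make_line_cut_dataset(spec, qz_list = c(3, 3.5) * p$q1,
                              qpar_axis = qpar)
  fit <- fit_structure_factor(ds$cuts, test_fit_config())
  td <- tidy(fit)
  expect_true(all(c("eta", "xi", "kappa_kbt", "scale_1", "scale_2") %in%
                    td$term))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
  ag <- augment(fit)
  expect_setequal(unique(ag$kind), c("data", "fit"))
  pl <- autoplot(fit)
  expect_s3_class(pl, "ggplot")
})
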