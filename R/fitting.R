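#' Configuration for the structure-factor fit
#'
#' Bundles the start values and bounds of the two nonlinear parameters
#' (`eta`, `xi`), the fixed instrument and sample parameters, and the
#' optimizer controls. Per-cut multiplicative scale factors (absorbing the
#' `q_z` dependence of the form factor) are not part of the nonlinear
#' search: they are profiled out analytically at each step.
#'
#' @param eta_init,xi_init Start values for the Caille parameters.
#' @param eta_bounds,xi_bounds Box constraints (defaults `(1e-6, 2]` and
#'   `[1, 1e5]` Angstrom).
#' @param size_model A [finite_size_model()] (held fixed).
#' @param beam A [beam_model()] (held fixed).
#' @param d Lamellar repeat spacing in Angstrom.
#' @param temperature Temperature in Kelvin for the derived moduli.
#' @param weighting `"variance"` for the standard chi-square
#'   `sum((s*Y - y)^2 / sigma^2)`; `"sigma"` weights by the first power
#'   of sigma instead.
#' @param optimizer `"lm"` (trust-region least squares with numerically
#'   differenced Jacobian; default) or `"simplex"` (Nelder-Mead
#'   fallback).
#' @param max_iter Maximum optimizer iterations.
#' @param ftol Relative chi-square convergence tolerance.
#' @param control An [sf_control()] for the radial integration.
#' @param table_r_nodes,table_n_max Resolution of the unit correlation
#'   table built (and cached) for the fit.
#' @param corr_table Optionally, a prebuilt unit-scale table.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(eta_init, xi_init, size_model, beam, d,
                       temperature = 298,
                       eta_bounds = c(1e-6, 2), xi_bounds = c(1, 1e5),
                       weighting = c("variance", "sigma"),
                       optimizer = c("lm", "simplex"),
                       max_iter = 100L, ftol = 1e-10,
                       control = sf_control(),
                       table_r_nodes = 2000L, table_n_max = NULL,
                       corr_table = NULL) {
  weighting <- arg_match(weighting)
  optimizer <- arg_match(optimizer)
  stopifnot(inherits(size_model, "finite_size_model"),
            inherits(beam, "beam_model"), d > 0, temperature > 0)
  if (eta_init <= eta_bounds[1] || eta_init > eta_bounds[2]) {
    abort("`eta_init` outside bounds")
  }
  if (xi_init < xi_bounds[1] || xi_init > xi_bounds[2]) {
    abort("`xi_init` outside bounds")
  }
  if (is.null(table_n_max)) {
    table_n_max <- min(
      999L,
      max(30L, ceiling((size_model$Lz_mean + 10 * size_model$Lz_sigma) /
                         size_model$d)))
  }
  structure(list(eta_init = eta_init, xi_init = xi_init,
                 eta_bounds = eta_bounds, xi_bounds = xi_bounds,
                 size_model = size_model, beam = beam, d = d,
                 temperature = temperature, weighting = weighting,
                 optimizer = optimizer, max_iter = as.integer(max_iter),
                 ftol = ftol, control = control,
                 table_r_nodes = as.integer(table_r_nodes),
                 table_n_max = as.integer(table_n_max),
                 corr_table = corr_table),
            class = "fit_config")
}

#' Chi-square of scaled model cuts against data cuts
#'
#' `chi2 = sum_l sum_k (s_l * Y_l[k] - y_l[k])^2 / sigma_l[k]^2` with
#' variance weighting (the default); `weighting = "sigma"` divides by the
#' first power of sigma instead. Model and data cuts must share their
#' `q_par` abscissae (interpolate the model beforehand).
#'
#' @param model_cuts,data_cuts Lists of cuts (tibbles with `qpar`,
#'   `intensity`; data cuts also `sigma`), matched by position.
#' @param scales Per-cut multiplicative factors.
#' @param weighting `"variance"` (default) or `"sigma"`.
#' @return The chi-square value.
#' @export
chi_squared <- function(model_cuts, data_cuts, scales,
                        weighting = c("variance", "sigma")) {
  weighting <- arg_match(weighting)
  stopifnot(length(model_cuts) == length(data_cuts),
            length(scales) == length(data_cuts))
  tot <- 0
  for (l in seq_along(data_cuts)) {
    y <- data_cuts[[l]]$intensity
    s <- data_cuts[[l]]$sigma
    Y <- model_cuts[[l]]$intensity
    if (length(Y) != length(y)) abort("model and data cuts differ in length")
    if (any(s <= 0)) abort("zero or negative sigma in data cut")
    resid2 <- (scales[l] * Y - y)^2
    tot <- tot + sum(resid2 / if (weighting == "variance") s^2 else s)
  }
  tot
}

#' Optimal per-cut scale factors
#'
#' Weighted-least-squares solution of the per-cut multiplicative factor:
#' `s_l = sum_k(Y y / sigma^2) / sum_k(Y^2 / sigma^2)` (the closed-form
#' minimizer of the chi-square in `s_l`). With these profiled out, the
#' nonlinear search runs over `(eta, xi)` only.
#'
#' @inheritParams chi_squared
#' @return Numeric vector of scales, one per cut; an error if a cut's
#'   optimum is nonpositive or its model is identically zero.
#' @export
optimal_scales <- function(model_cuts, data_cuts,
                           weighting = c("variance", "sigma")) {
  weighting <- arg_match(weighting)
  stopifnot(length(model_cuts) == length(data_cuts))
  vapply(seq_along(data_cuts), function(l) {
    y <- data_cuts[[l]]$intensity
    s <- data_cuts[[l]]$sigma
    Y <- model_cuts[[l]]$intensity
    if (any(s <= 0)) abort("zero or negative sigma in data cut")
    w <- if (weighting == "variance") 1 / s^2 else 1 / s
    denom <- sum(w * Y^2)
    if (denom <= 0) abort(sprintf("model cut %d is identically zero", l))
    sc <- sum(w * Y * y) / denom
    if (sc <= 0) abort(sprintf("optimal scale for cut %d is nonpositive (%g)", l, sc))
    sc
  }, numeric(1))
}

#' Fit the Caille structure factor to line cuts
#'
#' Simultaneously fits two or more in-plane line cuts at distinct `q_z`
#' with the finite-stack smectic structure factor. The nonlinear
#' parameters are `(eta, xi)`; per-cut multiplicative scales are profiled
#' out analytically at every step ([optimal_scales()]). Each evaluation
#' rescales the cached unit correlation table (cheap), recomputes the
#' structure-factor profile per cut on a uniform grid, convolves it with
#' the beam kernel, and interpolates it to the data abscissae (cubic).
#' The default optimizer is a trust-region least-squares method with
#' numerically differenced Jacobian; a Nelder-Mead simplex is available
#' as a fallback. On convergence `(eta, xi)` are converted to
#' `(kappa, B)` at the stated temperature.
#'
#' @param data_cuts List of at least two `line_cut` tibbles (columns
#'   `qpar`, `intensity`, `sigma`) at distinct `q_z`; each must carry a
#'   `qz_center` attribute or be accompanied by `qz_list`.
#' @param config A [fit_config()].
#' @param qz_list Optional explicit cut positions overriding the
#'   attributes.
#' @return An object of class `caille_fit`. Use [tidy()] / [glance()] /
#'   [autoplot()] to inspect it.
#' @export
fit_structure_factor <- function(data_cuts, config, qz_list = NULL) {
  stopifnot(inherits(config, "fit_config"))
  if (length(data_cuts) < 2L) {
    abort("at least two line cuts at distinct qz are required to determine both moduli")
  }
  if (is.null(qz_list)) {
    qz_list <- vapply(data_cuts, function(cc) {
      qq <- attr(cc, "qz_center")
      if (is.null(qq)) NA_real_ else qq
    }, numeric(1))
  }
  if (any(is.na(qz_list))) abort("cut positions unknown: supply `qz_list`")
  if (length(unique(round(qz_list, 10))) < 2L) {
    abort("line cuts must be at distinct qz values")
  }
  eval_env <- .make_fit_evaluator(data_cuts, qz_list, config)
  trace_env <- new.env(parent = emptyenv())
  trace_env$rows <- list()
  objective <- function(par) {
    res <- eval_env$residuals(par[1], par[2])
    chi2 <- sum(res^2)
    trace_env$rows[[length(trace_env$rows) + 1L]] <-
      c(eta = par[1], xi = par[2], chisq = chi2)
    res
  }
  p0 <- c(config$eta_init, config$xi_init)
  lower <- c(config$eta_bounds[1], config$xi_bounds[1])
  upper <- c(config$eta_bounds[2], config$xi_bounds[2])
  if (config$optimizer == "lm") {
    fitted <- minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper, fn = objective,
      control = minpack.lm::nls.lm.control(
        maxiter = config$max_iter, ftol = config$ftol, ptol = 1e-10))
    par_hat <- fitted$par
    converged <- fitted$info %in% 1:4
    message_opt <- fitted$message
    n_iter <- fitted$niter
  } else {
    # simplex fallback in log space: (eta, xi) differ by orders of
    # magnitude, so Nelder-Mead is run on log parameters with a penalty
    # outside the box
    opt <- optim(log(p0), fn = function(lpar) {
      par <- exp(lpar)
      if (any(par < lower) || any(par > upper)) return(1e300)
      sum(objective(par)^2)
    }, method = "Nelder-Mead",
    control = list(maxit = config$max_iter * 10L,
                   reltol = config$ftol))
    par_hat <- exp(opt$par)
    converged <- opt$convergence == 0L
    message_opt <- sprintf("Nelder-Mead convergence code %d", opt$convergence)
    n_iter <- opt$counts[["function"]]
  }
  at_bounds <- any(abs(par_hat - lower) < 1e-12 * pmax(abs(lower), 1)) ||
    any(abs(par_hat - upper) < 1e-12 * abs(upper))

  # best-fit state
  final <- eval_env$state(par_hat[1], par_hat[2])
  p_hat <- caille_parameters(eta = par_hat[1], xi = par_hat[2], d = config$d)
  moduli <- moduli_from_caille(p_hat, temperature = config$temperature)

  # approximate standard errors from the quadratic expansion at the optimum
  se <- .fit_standard_errors(eval_env, par_hat, final$chisq,
                             n_obs = sum(vapply(data_cuts, nrow, 0L)))

  # accepted-step trace: chi-square improvements in evaluation order
  all_rows <- do.call(rbind, trace_env$rows)
  acc <- which(cummin(all_rows[, "chisq"]) == all_rows[, "chisq"] &
                 !duplicated(cummin(all_rows[, "chisq"])))
  trace <- as_tibble(all_rows[acc, , drop = FALSE])
  trace$step <- seq_len(nrow(trace))

  structure(list(
    eta = par_hat[1], xi = par_hat[2],
    eta_se = se[1], xi_se = se[2],
    scales = final$scales,
    parameters = p_hat, moduli = moduli,
    kappa = moduli$kappa, kappa_kbt = kappa_kbt(moduli),
    B = moduli$B, temperature = config$temperature,
    chisq = final$chisq, chisq_per_cut = final$chisq_per_cut,
    n_obs = sum(vapply(data_cuts, nrow, 0L)),
    dof = sum(vapply(data_cuts, nrow, 0L)) - 2L - length(data_cuts),
    trace = trace, n_eval = length(trace_env$rows), n_iter = n_iter,
    converged = converged, at_bounds = at_bounds,
    optimizer_message = message_opt,
    qz_list = qz_list, data_cuts = data_cuts,
    model_cuts = final$model_cuts, config = config),
    class = "caille_fit")
}

# builds the per-fit evaluator with everything qz-independent precomputed:
# the radial integration grid, H_r on it, the trapezoid/Bessel weight
# matrix per cut, and the uniform model grids
.make_fit_evaluator <- function(data_cuts, qz_list, config) {
  m <- config$size_model
  ctrl <- config$control
  unit_tab <- config$corr_table %||% unit_correlation_table(
    r_grid = default_r_grid(n_nodes = config$table_r_nodes),
    n_max = config$table_n_max)
  r_int <- .sf_integration_grid(m, ctrl)
  hr <- size_weight_radial(r_int, m)
  base_w <- .trapz_weights(r_int) * r_int * hr

  cuts_pre <- lapply(data_cuts, function(cut) {
    qp <- cut$qpar
    dq <- diff(sort(unique(qp)))
    h_data <- max(min(dq[dq > 1e-12]), 1e-5)
    # the model grid must resolve the finite-size central peak
    # (width ~ 2*pi/Lr) and the beam kernel, not just the data spacing
    h_feat <- (2 * pi / m$Lr_mean) / 4
    if (config$beam$sigma_q > 0) h_feat <- min(h_feat, config$beam$sigma_q / 2)
    h <- min(h_data, h_feat)
    gmax <- max(abs(qp)) + 6 * config$beam$sigma_q + h
    pos <- seq(0, gmax + h, by = h)
    grid <- c(-rev(pos[-1]), pos)        # symmetric, contains 0 exactly
    # weight matrix: column j = J0(grid_j * r) * base_w  (eta/xi independent)
    M <- besselJ(abs(outer(r_int, grid)), 0) * base_w
    list(qpar = qp, y = cut$intensity, sigma = cut$sigma,
         grid = grid, M = M)
  })

  evaluate <- function(eta, xi) {
    p <- caille_parameters(eta = eta, xi = xi, d = config$d)
    corr <- rescale_correlation(unit_tab, p)
    model_on_data <- vector("list", length(cuts_pre))
    for (l in seq_along(cuts_pre)) {
      cp <- cuts_pre[[l]]
      lam <- lambda_kernel(r_int, qz = qz_list[l], corr = corr, m = m)
      prof <- pmax(drop(crossprod(cp$M, lam)), 0)
      prof <- convolve_beam(prof, cp$grid, config$beam)
      interp <- splinefun(cp$grid, prof, method = "natural")
      model_on_data[[l]] <- tibble(qpar = cp$qpar,
                                   intensity = pmax(interp(cp$qpar), 0))
    }
    model_on_data
  }

  env <- new.env(parent = emptyenv())
  env$residuals <- function(eta, xi) {
    model <- evaluate(eta, xi)
    dat <- lapply(cuts_pre, function(cp) {
      tibble(qpar = cp$qpar, intensity = cp$y, sigma = cp$sigma)
    })
    scales <- optimal_scales(model, dat, weighting = config$weighting)
    unlist(lapply(seq_along(model), function(l) {
      denom <- if (config$weighting == "variance") cuts_pre[[l]]$sigma
               else sqrt(cuts_pre[[l]]$sigma)
      (scales[l] * model[[l]]$intensity - cuts_pre[[l]]$y) / denom
    }))
  }
  env$state <- function(eta, xi) {
    model <- evaluate(eta, xi)
    dat <- lapply(cuts_pre, function(cp) {
      tibble(qpar = cp$qpar, intensity = cp$y, sigma = cp$sigma)
    })
    scales <- optimal_scales(model, dat, weighting = config$weighting)
    per_cut <- vapply(seq_along(model), function(l) {
      chi_squared(model[l], dat[l], scales[l], weighting = config$weighting)
    }, numeric(1))
    model_cuts <- lapply(seq_along(model), function(l) {
      out <- model[[l]]
      out$intensity <- out$intensity * scales[l]
      attr(out, "qz_center") <- qz_list[l]
      class(out) <- c("line_cut", class(out))
      out
    })
    list(scales = scales, chisq = sum(per_cut), chisq_per_cut = per_cut,
         model_cuts = model_cuts)
  }
  env
}

.fit_standard_errors <- function(eval_env, par, chisq, n_obs) {
  res0 <- eval_env$residuals(par[1], par[2])
  J <- matrix(0, nrow = length(res0), ncol = 2L)
  for (j in 1:2) {
    dp <- par
    h <- 1e-4 * max(abs(par[j]), 1e-6)
    dp[j] <- par[j] + h
    J[, j] <- (eval_env$residuals(dp[1], dp[2]) - res0) / h
  }
  jtj <- crossprod(J)
  dof <- max(n_obs - 2L, 1L)
  cov <- tryCatch(solve(jtj) * chisq / dof,
                  error = function(e) matrix(NA_real_, 2, 2))
  sqrt(pmax(diag(cov), 0))
}

#' @export
print.caille_fit <- function(x, ...) {
  cat("<caille_fit>\n")
  cat(sprintf("  eta = %.5g +/- %.2g, xi = %.5g +/- %.2g A\n",
              x$eta, x$eta_se, x$xi, x$xi_se))
  cat(sprintf("  kappa = %.4g J = %.3f kBT at %g K, B = %.4g J/A^4\n",
              x$kappa, x$kappa_kbt, x$temperature, x$B))
  cat(sprintf("  chi-square = %.6g over %d cuts (%d points), %s\n",
              x$chisq, length(x$data_cuts), x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  if (x$at_bounds) cat("  note: solution at a parameter bound\n")
  invisible(x)
}
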