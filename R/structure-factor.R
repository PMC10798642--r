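#' Gaussian beam profile
#'
#' Width of the (circular, Gaussian) beam footprint expressed in
#' reciprocal space; the computed structure-factor profile is convolved
#' with this kernel before comparison to data.
#'
#' @param sigma_q Standard deviation in 1/Angstrom, `>= 0`
#'   (`0` disables the convolution).
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(sigma_q = 0) {
  stopifnot(is.numeric(sigma_q), length(sigma_q) == 1L)
  if (sigma_q < 0) abort("`sigma_q` must be >= 0")
  structure(list(sigma_q = sigma_q), class = "beam_model")
}

#' Numerical controls for the structure-factor radial integration
#'
#' The structure factor is a zeroth-order Hankel transform evaluated by
#' the trapezoidal rule on a uniform radius grid. The grid runs from
#' `r_min` to `min(r_max, Lr_mean + 6*Lr_sigma)` (beyond which the radial
#' size weight is numerically zero) in steps of `dr`.
#'
#' @param r_min,r_max Integration limits in Angstrom (defaults 1 and 1e6).
#' @param dr Step in Angstrom (default 1).
#' @return A list of class `sf_control`.
#' @export
sf_control <- function(r_min = 1, r_max = 1e6, dr = 1) {
  stopifnot(r_min > 0, r_max > r_min, dr > 0)
  structure(list(r_min = r_min, r_max = r_max, dr = dr),
            class = "sf_control")
}

# effective n range: where the axial weight is non-negligible, capped by
# the table and the conventional |n| < 1000 window
.n_effective <- function(corr, m, n_cap = 999L) {
  n_max <- min(corr$n_max, n_cap)
  hz <- size_weight_axial(0:n_max, m)
  keep <- which(hz > 1e-16 * hz[1])
  if (!length(keep)) return(0L)
  min(n_max, max(keep) - 1L)
}

#' Axial kernel Lambda(r) of the structure factor
#'
#' The part of the structure-factor double sum/integral that depends only
#' on `q_z`:
#' `Lambda(r) = sum_n H_z(|n|d) * cos(q_z n d) * G(r, n, q_z)` with
#' `G = exp(-q_z^2 * delta_u_|n|(r) / 2)` (the Gaussian/cumulant form of
#' the correlation exponent, which keeps the structure factor real and
#' positive). Evenness in `n` is exploited:
#' `Lambda = H_z(0) G(r, 0) + 2 * sum_{n>=1} H_z(nd) cos(q_z n d) G(r, n)`.
#' Layer separations whose axial weight is numerically zero are skipped;
#' the sum is capped at `|n| < 1000`.
#'
#' @param r Radii in Angstrom (vector). Defaults to the table's own nodes;
#'   other radii are evaluated by cubic interpolation of `delta_u` in
#'   `log(r)`.
#' @param qz Out-of-plane scattering vector in 1/Angstrom (scalar).
#' @param corr A rescaled [rescale_correlation()] table.
#' @param m A [finite_size_model()].
#' @param n_range Optional cap on `|n|` (default 999).
#' @return `Lambda(r)`, same length as `r`.
#' @export
lambda_kernel <- function(r = NULL, qz, corr, m, n_range = 999L) {
  stopifnot(inherits(corr, "correlation_table"),
            inherits(m, "finite_size_model"), length(qz) == 1L)
  if (identical(corr$scale_state, "unit")) {
    abort("`corr` is at unit scale; rescale_correlation() it to the target (xi, eta) first")
  }
  n_eff <- .n_effective(corr, m, n_cap = as.integer(n_range))
  node_vals <- .lambda_nodes(qz, corr, m, n_eff)
  if (is.null(r)) return(node_vals)
  sf <- splinefun(log(corr$r_grid), node_vals, method = "natural")
  rng <- range(corr$r_grid)
  if (any(r < rng[1] | r > rng[2])) {
    abort(sprintf("radius outside correlation grid [%g, %g] A", rng[1], rng[2]))
  }
  sf(log(r))
}

# Lambda at the table's radius nodes (no interpolation)
.lambda_nodes <- function(qz, corr, m, n_eff) {
  du <- corr$values[seq_len(n_eff + 1L), , drop = FALSE]
  if (any(!is.finite(du))) abort("non-finite delta_u in correlation table")
  g <- exp(-qz^2 * du / 2)
  hz <- size_weight_axial(0:n_eff, m)
  cosw <- cos(qz * (0:n_eff) * m$d)
  w <- hz * cosw * c(1, rep(2, n_eff))
  drop(crossprod(g, w))
}

#' Diffuse-scattering structure factor along q-parallel
#'
#' Computes `S(q_z, q_par) = integral_0^Inf r dr H_r(r) J0(q_par r)
#' Lambda(r)` by the trapezoidal rule on a uniform radius grid (see
#' [sf_control()]), with `Lambda` evaluated by cubic interpolation of its
#' values at the correlation-table nodes and `H_r` evaluated directly on
#' the integration grid. Even in `q_par` by construction (`J0` is even);
#' tiny negative values from integration noise are clipped to zero with a
#' warning.
#'
#' @param qz Out-of-plane scattering vector, 1/Angstrom (scalar).
#' @param qpar_axis In-plane scattering vectors, 1/Angstrom.
#' @param p A [caille_parameters()] object (must match the rescaled
#'   table).
#' @param m A [finite_size_model()].
#' @param corr A rescaled correlation table.
#' @param control An [sf_control()] list.
#' @return A tibble with columns `qpar` and `intensity` (arbitrary
#'   units); attribute `qz` records the cut position.
#' @export
structure_factor_profile <- function(qz, qpar_axis, p, m, corr,
                                     control = sf_control()) {
  vals <- .sf_profile_values(qz, qpar_axis, p, m, corr, control)
  out <- tibble(qpar = qpar_axis, intensity = vals)
  attr(out, "qz") <- qz
  class(out) <- c("sf_profile", class(out))
  out
}

.sf_integration_grid <- function(m, control) {
  r_hi <- min(control$r_max, m$Lr_mean + 6 * m$Lr_sigma)
  seq(control$r_min, r_hi, by = control$dr)
}

.sf_profile_values <- function(qz, qpar_axis, p, m, corr, control) {
  stopifnot(all(is.finite(qpar_axis)))
  r_int <- .sf_integration_grid(m, control)
  lam <- lambda_kernel(r_int, qz = qz, corr = corr, m = m)
  if (any(is.na(lam))) abort("NaN in Lambda kernel")
  hr <- size_weight_radial(r_int, m)
  w <- .trapz_weights(r_int) * r_int * hr * lam
  # J0 is even: evaluate at |qpar|
  vals <- vapply(qpar_axis, function(q) {
    sum(besselJ(abs(q) * r_int, 0) * w)
  }, numeric(1))
  neg <- vals < 0
  if (any(neg)) {
    if (min(vals) < -1e-6 * max(abs(vals))) {
      warn(sprintf("clipping %d negative structure-factor values (min %g) to 0",
                   sum(neg), min(vals)))
    }
    vals[neg] <- 0
  }
  vals
}

# forward model sampled at arbitrary abscissae: computed on an internal
# uniform grid fine enough to resolve the finite-size central peak
# (~2*pi/Lr) and the beam kernel, beam-convolved there, then interpolated
.sf_profile_convolved <- function(qz, qpar, p, m, corr, beam,
                                  control = sf_control()) {
  h_feat <- (2 * pi / m$Lr_mean) / 4
  if (beam$sigma_q > 0) h_feat <- min(h_feat, beam$sigma_q / 2)
  dq <- diff(sort(unique(qpar)))
  h_data <- if (length(dq)) max(min(dq[dq > 1e-12]), 1e-5) else h_feat
  h <- min(h_data, h_feat)
  gmax <- max(abs(qpar)) + 6 * beam$sigma_q + h
  pos <- seq(0, gmax + h, by = h)
  grid <- c(-rev(pos[-1]), pos)
  v <- .sf_profile_values(qz, grid, p, m, corr, control)
  v <- convolve_beam(v, grid, beam)
  pmax(splinefun(grid, v, method = "natural")(qpar), 0)
}

.trapz_weights <- function(x) {
  n <- length(x)
  w <- c(diff(x), 0) + c(0, diff(x))
  w / 2
}

#' Convolve a profile with the Gaussian beam kernel
#'
#' Discrete convolution of intensities on a uniform `q_par` grid with a
#' unit-area Gaussian of standard deviation `sigma_q`, truncated at
#' `+/- 5 sigma_q`. Near the profile edges the kernel is renormalized
#' over its in-range support (no zero-padding artifacts); away from the
#' edges the integral of the profile is conserved. `sigma_q = 0` is the
#' identity.
#'
#' @param intensity Intensities on a uniform grid.
#' @param qpar_axis The uniform grid, 1/Angstrom.
#' @param beam A [beam_model()].
#' @return Convolved intensities, same length.
#' @export
convolve_beam <- function(intensity, qpar_axis, beam) {
  stopifnot(inherits(beam, "beam_model"),
            length(intensity) == length(qpar_axis))
  if (beam$sigma_q == 0) return(intensity)
  dq <- diff(qpar_axis)
  if (length(dq) == 0L) return(intensity)
  if (max(abs(dq - dq[1])) > 1e-8 * abs(dq[1])) {
    abort("`qpar_axis` must be uniformly spaced for beam convolution")
  }
  .convolve_gauss(intensity, abs(dq[1]), beam$sigma_q)
}

# discrete Gaussian smoothing, kernel truncated at +/- 5 sigma and
# renormalized over the in-range support at the edges
.convolve_gauss <- function(intensity, h, sigma) {
  half <- ceiling(5 * sigma / h)
  k <- dnorm(seq(-half, half) * h, sd = sigma)
  n <- length(intensity)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1L & j <= n
    kk <- k[ok]
    out[i] <- sum(kk * intensity[j[ok]]) / sum(kk)
  }
  out
}

#' Two-dimensional structure-factor map
#'
#' Row-wise application of [structure_factor_profile()] (plus optional
#' beam convolution) over a grid of `q_z` values. Rows are computed
#' independently of each other, so the result does not depend on
#' evaluation order.
#'
#' @inheritParams structure_factor_profile
#' @param qz_axis Out-of-plane grid, 1/Angstrom.
#' @param beam Optional [beam_model()]; `NULL` skips convolution.
#' @return A tibble of class `sf_map` in long format: columns `qz`,
#'   `qpar`, `intensity`.
#' @export
structure_factor_map <- function(qz_axis, qpar_axis, p, m, corr,
                                 beam = NULL, control = sf_control()) {
  rows <- lapply(qz_axis, function(qz) {
    v <- .sf_profile_values(qz, qpar_axis, p, m, corr, control)
    if (!is.null(beam)) v <- convolve_beam(v, qpar_axis, beam)
    tibble(qz = qz, qpar = qpar_axis, intensity = v)
  })
  out <- bind_rows(rows)
  class(out) <- c("sf_map", class(out))
  out
}
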