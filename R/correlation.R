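#' Height-height correlation by adaptive quadrature
#'
#' Mean-square relative height displacement `delta_u_n(r)` between points
#' on membranes `n` layers apart at lateral separation `r`, for a stack of
#' fluctuating bilayers in the harmonic (discrete smectic) approximation:
#'
#' `delta_u_n(r) = (2*eta/q1^2) * integral_0^Inf dx
#'    (1 - J0((r/xi)*sqrt(2x)) * (sqrt(1+x^2) - x)^(2n)) / (x*sqrt(1+x^2))`
#'
#' The integrand is finite at `x -> 0` (the apparent singularity cancels:
#' its limit is `2n + (r/xi)^2/2`) but is oscillatory at large `r/xi`, so
#' the integral is evaluated by adaptive quadrature on the semi-infinite
#' interval with the endpoint limit substituted analytically. If the
#' requested tolerance cannot be met the tolerance is relaxed stepwise; if
#' all rungs fail an error reports `n`, `r` and the tolerances tried.
#'
#' This direct evaluation is intended for `n < 30` and `r/xi < 1000`;
#' outside that regime use [delta_u_asymptotic()], which is numerically
#' indistinguishable there and far cheaper.
#'
#' @param n Layer separation, integer `>= 0`.
#' @param r Lateral separation in Angstrom, `>= 0`.
#' @param p A [caille_parameters()] object.
#' @param rel_tol Relative tolerance rungs tried in order.
#' @param abs_tol Absolute tolerance.
#' @return `delta_u` in Angstrom^2, `>= 0`. Vectorized over `r`.
#' @seealso [delta_u_asymptotic()], [build_unit_correlation_table()]
#' @export
delta_u_exact <- function(n, r, p,
                          rel_tol = c(1e-8, 1e-6, 1e-4),
                          abs_tol = 1e-10) {
  stopifnot(inherits(p, "caille_parameters"),
            length(n) == 1L, n >= 0, n == round(n), all(r >= 0))
  vapply(r, function(ri) {
    2 * p$eta / p$q1^2 * .du_integral(n, ri / p$xi, rel_tol, abs_tol)
  }, numeric(1))
}

# dimensionless core integral I(n, a); delta_u = (2 eta / q1^2) * I(n, r/xi)
.du_integral <- function(n, a, rel_tol, abs_tol) {
  if (a == 0 && n == 0) return(0)
  f <- function(x) {
    damp <- (sqrt(1 + x^2) - x)^(2 * n)
    out <- (1 - besselJ(a * sqrt(2 * x), 0) * damp) / (x * sqrt(1 + x^2))
    at0 <- x < 1e-14
    if (any(at0)) out[at0] <- 2 * n + a^2 / 2
    out
  }
  for (rt in rel_tol) {
    v <- tryCatch(
      suppressWarnings(integrate(f, 0, Inf, rel.tol = rt, abs.tol = abs_tol,
                                 subdivisions = 4000L)$value),
      error = function(e) NA_real_)
    if (!is.na(v)) return(v)
  }
  abort(sprintf(
    "correlation quadrature did not converge at n = %d, r/xi = %g (tolerances tried: %s)",
    n, a, paste(format(rel_tol), collapse = ", ")))
}

#' Height-height correlation, large-separation asymptote
#'
#' Asymptotic form of [delta_u_exact()] valid for large layer separation
#' or large radius (`n >= 30` or `r/xi >= 1000`):
#'
#' `delta_u_n(r) = (4*eta/q1^2) * (gamma + log(r/xi) + 0.5*E1(r^2/(4*n*xi^2)))`
#'
#' with `gamma` the Euler-Mascheroni constant and `E1` the exponential
#' integral. The additive `gamma + log` form is fixed numerically by
#' continuity against the exact quadrature across the regime seam (the two
#' branches agree to well below 0.1% there; see the package vignette).
#'
#' @inheritParams delta_u_exact
#' @return `delta_u` in Angstrom^2. Vectorized over `r`.
#' @export
delta_u_asymptotic <- function(n, r, p) {
  stopifnot(inherits(p, "caille_parameters"),
            length(n) == 1L, n == round(n), all(r > 0))
  if (n == 0) {
    abort("`n = 0` has no asymptotic branch (E1 argument infinite); use delta_u_exact()")
  }
  a <- r / p$xi
  gam <- -digamma(1)
  4 * p$eta / p$q1^2 *
    (gam + log(a) + 0.5 * pracma::expint_E1(a^2 / (4 * n)))
}

# asymptotic plateau for n = 0 at large r (E1 term -> 0); used only for
# table rows where the exact branch is out of regime
.du_plateau <- function(r_over_xi) {
  4 * (-digamma(1) + log(r_over_xi))
}

#' Default logarithmic radius grid
#'
#' 10,000 logarithmically spaced radii between 1e-4 and 1e6 Angstrom, the
#' grid on which the unit-scale correlation table is precomputed.
#'
#' @param n_nodes Number of nodes.
#' @param r_min,r_max Grid limits in Angstrom.
#' @return Numeric vector of radii.
#' @export
default_r_grid <- function(n_nodes = 10000L, r_min = 1e-4, r_max = 1e6) {
  10^seq(log10(r_min), log10(r_max), length.out = n_nodes)
}

#' Precompute the unit-scale correlation table
#'
#' Builds the matrix `delta_u_n(r)` at unit scale (`xi = 1`, `eta = 1`,
#' `q1 = 1`) on a logarithmic radius grid for layer separations
#' `n = 0 ... n_max`. Any other `(xi, eta, q1)` is obtained from this table
#' by [rescale_correlation()] without re-quadrature.
#'
#' The exact quadrature branch is used for `n < 30` and radii below 1000
#' Angstrom (applied on the unit-scale grid); the asymptotic branch
#' elsewhere. The n = 0 row beyond 1000 Angstrom uses the `n -> 0` limit of
#' the asymptote, where the exponential-integral term vanishes.
#'
#' Building the full default grid (10,000 x 1001) takes appreciable time;
#' fits and simulations are typically run with a few thousand radius nodes
#' and `n_max` slightly beyond the axial domain support, which leaves the
#' interpolated structure factor unchanged (see the vignette).
#'
#' @param r_grid Logarithmically spaced radii in Angstrom
#'   (default [default_r_grid()]).
#' @param n_max Largest layer separation tabulated (default 1000).
#' @param rel_tol,abs_tol Quadrature tolerances, passed to
#'   [delta_u_exact()].
#' @param exact_n_below,exact_r_below Regime seam: the exact branch is
#'   used where `n` is below `exact_n_below` and `r` below
#'   `exact_r_below`.
#' @return An object of class `correlation_table`: list with `r_grid`,
#'   `n_max`, `values` (matrix, rows `n = 0 ... n_max`), and `scale_state`
#'   (`"unit"` here).
#' @export
build_unit_correlation_table <- function(r_grid = default_r_grid(),
                                         n_max = 1000L,
                                         rel_tol = c(1e-8, 1e-6, 1e-4),
                                         abs_tol = 1e-10,
                                         exact_n_below = 30L,
                                         exact_r_below = 1000) {
  stopifnot(n_max >= 1, all(diff(r_grid) > 0), all(r_grid > 0))
  p_unit <- caille_parameters(eta = 1, xi = 1, q1 = 1)
  nr <- length(r_grid)
  vals <- matrix(0, nrow = n_max + 1L, ncol = nr)
  near <- r_grid < exact_r_below
  gam <- -digamma(1)
  for (n in 0:n_max) {
    row <- numeric(nr)
    if (n < exact_n_below) {
      row[near] <- delta_u_exact(n, r_grid[near], p_unit,
                                 rel_tol = rel_tol, abs_tol = abs_tol)
      if (any(!near)) {
        row[!near] <- if (n == 0) .du_plateau(r_grid[!near])
                      else delta_u_asymptotic(n, r_grid[!near], p_unit)
      }
    } else {
      row <- delta_u_asymptotic(n, r_grid, p_unit)
    }
    vals[n + 1L, ] <- row
  }
  structure(list(r_grid = r_grid, n_max = as.integer(n_max), values = vals,
                 scale_state = "unit"),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, ...) {
  st <- if (identical(x$scale_state, "unit")) "unit scale" else
    sprintf("xi = %g A, eta = %g, q1 = %g 1/A",
            x$scale_state$xi, x$scale_state$eta, x$scale_state$q1)
  cat(sprintf(
    "<correlation_table> %d radii in [%g, %g] A x n = 0..%d (%s)\n",
    length(x$r_grid), min(x$r_grid), max(x$r_grid), x$n_max, st))
  invisible(x)
}

#' Rescale a unit correlation table to target parameters
#'
#' Applies the scaling identity
#' `delta_u_n(r; xi, eta, q1) = (eta/q1^2) * delta_u_n^unit(r/xi)`:
#' the radius axis is relabeled (`r_grid * xi`) and the values multiplied
#' by `eta/q1^2`; no quadrature is repeated. Exactly linear in `eta`.
#'
#' @param table A unit-scale `correlation_table` from
#'   [build_unit_correlation_table()].
#' @param p A [caille_parameters()] object.
#' @return A `correlation_table` with `scale_state = list(xi, eta, q1)`.
#' @export
rescale_correlation <- function(table, p) {
  stopifnot(inherits(table, "correlation_table"),
            inherits(p, "caille_parameters"))
  if (!identical(table$scale_state, "unit")) {
    abort("table is already rescaled; rescale_correlation() requires a unit-scale table")
  }
  structure(list(r_grid = table$r_grid * p$xi,
                 n_max = table$n_max,
                 values = table$values * (p$eta / p$q1^2),
                 scale_state = list(xi = p$xi, eta = p$eta, q1 = p$q1)),
            class = "correlation_table")
}

# cubic interpolation of one table row in log(r); error outside the grid
.corr_row_fun <- function(table, n) {
  stopifnot(n >= 0, n <= table$n_max)
  sf <- splinefun(log(table$r_grid), table$values[n + 1L, ],
                  method = "natural")
  rng <- range(table$r_grid)
  function(r) {
    if (any(r < rng[1] | r > rng[2])) {
      abort(sprintf("radius outside correlation grid [%g, %g] A; extrapolation is not allowed",
                    rng[1], rng[2]))
    }
    sf(log(r))
  }
}

# unit-table session cache: building the table is the expensive step, and
# it depends only on the grid, so reuse within a session
#' Fetch (and cache) a unit correlation table
#'
#' Convenience wrapper around [build_unit_correlation_table()] that caches
#' the result for the session, keyed by the grid signature, so repeated
#' fits do not rebuild it.
#'
#' @inheritParams build_unit_correlation_table
#' @return A unit-scale `correlation_table`.
#' @export
unit_correlation_table <- function(r_grid = default_r_grid(),
                                   n_max = 1000L, ...) {
  key <- paste0("t", length(r_grid), "_", n_max, "_",
                format(min(r_grid), digits = 12), "_",
                format(max(r_grid), digits = 12))
  if (!is.null(.table_cache[[key]])) return(.table_cache[[key]])
  tab <- build_unit_correlation_table(r_grid = r_grid, n_max = n_max, ...)
  .table_cache[[key]] <- tab
  tab
}
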