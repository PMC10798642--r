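#' Reference structure factor by direct double integration
#'
#' Validation-grade evaluation of `S(q_z, q_par)` that bypasses the
#' precomputed correlation table and all interpolation: `delta_u_n(r)` is
#' evaluated directly (exact quadrature for `n < 30` and radii below 1000
#' Angstrom at unit scale, asymptotic form elsewhere) at every node of a
#' dense uniform radius grid, and the Hankel integral is carried out by
#' the trapezoidal rule on that grid. Orders of magnitude slower than the
#' table-driven pipeline; intended as an independent cross-check of it.
#'
#' @inheritParams structure_factor_profile
#' @param control An [sf_control()]; `dr` sets the dense-grid step.
#' @param rel_tol Quadrature tolerance rungs for the per-node
#'   correlation integrals (looser than the table default is fine here:
#'   quadrature error is orders of magnitude below the approximations
#'   this reference is used to measure).
#' @return Numeric intensities, one per `qpar_axis` entry.
#' @export
structure_factor_bruteforce <- function(qz, qpar_axis, p, m,
                                        control = sf_control(),
                                        rel_tol = c(1e-6, 1e-4)) {
  r_int <- .sf_integration_grid(m, control)
  n_max <- min(999L, ceiling((m$Lz_mean + 10 * m$Lz_sigma) / m$d))
  hz <- size_weight_axial(0:n_max, m)
  keep_n <- hz > 1e-16 * hz[1]
  n_eff <- max(which(keep_n)) - 1L
  # direct delta_u on the dense grid, no table, no interpolation
  near <- (r_int / p$xi) < 1000
  lam <- numeric(length(r_int))
  for (n in 0:n_eff) {
    du <- numeric(length(r_int))
    if (n < 30) {
      du[near] <- delta_u_exact(n, r_int[near], p, rel_tol = rel_tol)
      if (any(!near)) {
        du[!near] <- if (n == 0) {
          2 * p$eta / p$q1^2 * .du_plateau(r_int[!near] / p$xi)
        } else {
          delta_u_asymptotic(n, r_int[!near], p)
        }
      }
    } else {
      du <- delta_u_asymptotic(n, r_int, p)
    }
    g <- exp(-qz^2 * du / 2)
    w_n <- if (n == 0) 1 else 2
    lam <- lam + w_n * hz[n + 1L] * cos(qz * n * m$d) * g
  }
  hr <- size_weight_radial(r_int, m)
  w <- .trapz_weights(r_int) * r_int * hr * lam
  vals <- vapply(qpar_axis, function(q) sum(besselJ(abs(q) * r_int, 0) * w),
                 numeric(1))
  pmax(vals, 0)
}
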