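#' Finite-size model of coherently scattering membrane domains
#'
#' Real samples scatter coherently only over finite patches: the stack
#' height is limited by how many bilayers can be deposited with good
#' order, and the in-plane extent by beam coherence and sample mosaicity.
#' Both dimensions are modeled as Gaussian distributed: the in-plane
#' domain diameter `L_r ~ N(Lr_mean, Lr_sigma^2)` and the stack height
#' `L_z ~ N(Lz_mean, Lz_sigma^2)`.
#'
#' @param Lr_mean Mean in-plane domain diameter in Angstrom.
#' @param Lr_sigma Spread of the diameter distribution in Angstrom
#'   (`>= 0`; `0` selects the delta-distributed closed forms).
#' @param Lz_mean Mean stack height in Angstrom (at least one repeat `d`).
#' @param Lz_sigma Spread of the stack-height distribution in Angstrom.
#' @param d Lamellar repeat spacing in Angstrom.
#' @return An object of class `finite_size_model`.
#' @export
finite_size_model <- function(Lr_mean, Lr_sigma, Lz_mean, Lz_sigma, d) {
  stopifnot(Lr_mean > 0, Lr_sigma >= 0, Lz_mean > 0, Lz_sigma >= 0, d > 0)
  if (Lz_mean / d < 1) abort("`Lz_mean` must be at least one repeat spacing `d`")
  structure(list(Lr_mean = Lr_mean, Lr_sigma = Lr_sigma,
                 Lz_mean = Lz_mean, Lz_sigma = Lz_sigma, d = d),
            class = "finite_size_model")
}

#' @export
print.finite_size_model <- function(x, ...) {
  cat(sprintf(
    "<finite_size_model> Lr = %g +/- %g A, Lz = %g +/- %g A (%.1f bilayers), d = %g A\n",
    x$Lr_mean, x$Lr_sigma, x$Lz_mean, x$Lz_sigma, x$Lz_mean / x$d, x$d))
  invisible(x)
}

#' Axial finite-size weight H_z
#'
#' Weight of the layer-pair separation `z = |n|*d` in the structure-factor
#' sum, for a Gaussian-distributed stack height:
#' `H_z(z) = integral_z^Inf dLz N(Lz; Lz_mean, Lz_sigma) * (Lz - z) / d`
#' with `N` a fully normalized Gaussian density. Evaluated in closed form
#' through the Gaussian cdf/pdf:
#' `H_z(z) = ((Lz_mean - z) * Phibar(u) + Lz_sigma * phi(u)) / d`,
#' `u = (z - Lz_mean)/Lz_sigma`. For `Lz_sigma = 0` this reduces to the
#' delta-distribution limit `max(Lz_mean - z, 0)/d`.
#'
#' @param n Integer layer separation (any sign; `|n|*d` is used).
#' @param m A [finite_size_model()].
#' @return Dimensionless weight(s), vectorized over `n`.
#' @export
size_weight_axial <- function(n, m) {
  stopifnot(inherits(m, "finite_size_model"))
  z <- abs(n) * m$d
  if (m$Lz_sigma == 0) {
    return(pmax(m$Lz_mean - z, 0) / m$d)
  }
  u <- (z - m$Lz_mean) / m$Lz_sigma
  ((m$Lz_mean - z) * pnorm(u, lower.tail = FALSE) +
     m$Lz_sigma * dnorm(u)) / m$d
}

#' Radial finite-size weight H_r
#'
#' Weight of the in-plane pair separation `r` for cylindrical domains with
#' Gaussian-distributed diameter. The geometric factor is the (unnormalized)
#' overlap area of two disks of diameter `L_r` at center distance `r`:
#' `H_r(r) = integral_r^Inf dLr N(Lr; Lr_mean, Lr_sigma) * Lr^2 *
#'   (acos(r/Lr) - (r/Lr) * sqrt(1 - (r/Lr)^2))`,
#' zero where the separation exceeds the domain diameter. The Gaussian
#' uses the radial spread `Lr_sigma` and is
#' fully normalized. Evaluated by fixed-order Gauss-Legendre quadrature
#' over the (truncated) Gaussian support; for `Lr_sigma = 0` the
#' delta-distribution closed form is returned.
#'
#' @param r Radius (Angstrom), vectorized, nonnegative.
#' @param m A [finite_size_model()].
#' @param n_nodes Number of quadrature nodes (default 200).
#' @return Weight(s) in Angstrom^2, nonincreasing in `r`.
#' @export
size_weight_radial <- function(r, m, n_nodes = 200L) {
  stopifnot(inherits(m, "finite_size_model"), all(r >= 0))
  geom <- function(rho) {
    # overlap kernel for rho = r/L in [0, 1]; 0 beyond
    out <- numeric(length(rho))
    ok <- rho <= 1
    out[ok] <- acos(rho[ok]) - rho[ok] * sqrt(pmax(1 - rho[ok]^2, 0))
    out
  }
  if (m$Lr_sigma == 0) {
    rho <- r / m$Lr_mean
    return(m$Lr_mean^2 * geom(rho))
  }
  lo_gauss <- max(m$Lr_mean - 10 * m$Lr_sigma, 0)
  hi <- m$Lr_mean + 10 * m$Lr_sigma
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  out <- numeric(length(r))
  live <- which(r < hi)
  if (length(live)) {
    lo <- pmax(r[live], lo_gauss)
    span <- hi - lo
    # one row of quadrature nodes per radius: L in [max(r, support), hi]
    Lmat <- outer(lo, rep(1, n_nodes)) + outer(span, gl$x)
    integ <- dnorm(Lmat, mean = m$Lr_mean, sd = m$Lr_sigma) * Lmat^2 *
      matrix(geom(r[live] / Lmat), nrow = length(live))
    out[live] <- span * drop(integ %*% gl$w)
  }
  out
}
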