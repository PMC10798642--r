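#' Caille parameters of a fluctuating membrane stack
#'
#' The smectic structure factor of a stack of thermally fluctuating bilayers
#' is parameterized by the dimensionless fluctuation amplitude `eta`, the
#' in-plane correlation length `xi` (in Angstrom) and the position of the
#' first lamellar Bragg peak `q1 = 2*pi/d`. Together with the repeat spacing
#' `d` these are the quantities the diffuse-scattering fit estimates; they
#' map onto the bending modulus `kappa` and the inter-membrane compression
#' modulus `B` (see [moduli_from_caille()]).
#'
#' @param eta Dimensionless Caille parameter, `eta >= 0`.
#' @param xi In-plane correlation length in Angstrom, `xi > 0`.
#' @param d Lamellar repeat spacing in Angstrom. Exactly one of `d`, `q1`
#'   must be supplied.
#' @param q1 First-order lamellar peak position in inverse Angstrom.
#'
#' @return An object of class `caille_parameters`: a list with fields
#'   `eta`, `xi`, `d` and `q1` satisfying `q1 * d == 2*pi`.
#'
#' @examples
#' p <- caille_parameters(eta = 0.1, xi = 60, d = 53)
#' p$q1 * p$d / (2 * pi)   # 1 by construction
#' @export
caille_parameters <- function(eta, xi, d = NULL, q1 = NULL) {
  if (is.null(d) == is.null(q1)) {
    abort("supply exactly one of `d` or `q1`")
  }
  if (is.null(d)) d <- 2 * pi / q1 else q1 <- 2 * pi / d
  stopifnot(is.numeric(eta), length(eta) == 1L, eta >= 0,
            is.numeric(xi), length(xi) == 1L, xi > 0,
            d > 0)
  if (abs(q1 * d - 2 * pi) > 1e-9 * 2 * pi) {
    abort("`q1 * d` must equal 2*pi")
  }
  structure(list(eta = eta, xi = xi, d = d, q1 = q1),
            class = "caille_parameters")
}

#' @export
print.caille_parameters <- function(x, ...) {
  cat(sprintf(
    "<caille_parameters> eta = %g, xi = %g A, d = %g A (q1 = %g 1/A)\n",
    x$eta, x$xi, x$d, x$q1))
  invisible(x)
}

#' Elastic moduli of a membrane stack
#'
#' Stores the bending modulus `kappa` (Joule), the inter-membrane
#' compression modulus `B` (Joule per Angstrom^4, in the discrete-smectic
#' convention where `xi^4 = kappa/B` with `xi` in Angstrom) and the
#' absolute temperature.
#'
#' @param kappa Bending modulus in Joule, `> 0`.
#' @param B Compression modulus in J/A^4, `> 0`.
#' @param temperature Absolute temperature in Kelvin, `> 0`.
#' @return An object of class `elastic_moduli`.
#' @seealso [kappa_kbt()], [moduli_from_caille()], [caille_from_moduli()]
#' @export
elastic_moduli <- function(kappa, B, temperature) {
  stopifnot(kappa > 0, B > 0, temperature > 0)
  structure(list(kappa = kappa, B = B, temperature = temperature),
            class = "elastic_moduli")
}

#' @export
print.elastic_moduli <- function(x, ...) {
  cat(sprintf(
    "<elastic_moduli> kappa = %.4g J (%.3g kBT), B = %.4g J/A^4 (%.3g erg/cm^4), T = %g K\n",
    x$kappa, kappa_kbt(x), x$B, b_erg_cm4(x), x$temperature))
  invisible(x)
}

#' Bending modulus in thermal units
#'
#' @param moduli An [elastic_moduli()] object.
#' @return `kappa / (kB * T)`, dimensionless.
#' @export
kappa_kbt <- function(moduli) {
  moduli$kappa / (.kB * moduli$temperature)
}

#' Compression modulus in erg/cm^4
#'
#' Converts `B` from J/A^4 to the erg/cm^4 units conventional in the
#' lamellar-phase literature (1 J/A^4 = 1e39 erg/cm^4).
#'
#' @inheritParams kappa_kbt
#' @return `B` in erg/cm^4.
#' @export
b_erg_cm4 <- function(moduli) {
  moduli$B * 1e39
}

#' Convert Caille parameters to elastic moduli
#'
#' Inverts the defining relations
#' `eta = kB*T*q1^2 / (8*pi*sqrt(B*kappa))` and `xi^4 = kappa/B`
#' to `kappa = kB*T*q1^2*xi^2 / (8*pi*eta)` and `B = kappa/xi^4`.
#'
#' @param p A [caille_parameters()] object with `eta > 0`.
#' @param temperature Absolute temperature in Kelvin.
#' @return An [elastic_moduli()] object.
#' @examples
#' p <- caille_parameters(eta = 0.1, xi = 60, d = 53)
#' m <- moduli_from_caille(p, temperature = 298)
#' kappa_kbt(m)   # about 20 kBT, typical for a fluid phospholipid bilayer
#' @export
moduli_from_caille <- function(p, temperature) {
  stopifnot(inherits(p, "caille_parameters"), temperature > 0)
  if (p$eta <= 0) abort("`eta` must be > 0 to derive kappa (kappa ~ 1/eta)")
  kappa <- .kB * temperature * p$q1^2 * p$xi^2 / (8 * pi * p$eta)
  elastic_moduli(kappa = kappa, B = kappa / p$xi^4, temperature = temperature)
}

#' Convert elastic moduli to Caille parameters
#'
#' Direct evaluation of `eta = kB*T*q1^2 / (8*pi*sqrt(B*kappa))` and
#' `xi = (kappa/B)^(1/4)`.
#'
#' @param moduli An [elastic_moduli()] object.
#' @param d Lamellar repeat spacing in Angstrom (or supply `q1`).
#' @param q1 First-order peak position in 1/Angstrom.
#' @return A [caille_parameters()] object.
#' @export
caille_from_moduli <- function(moduli, d = NULL, q1 = NULL) {
  stopifnot(inherits(moduli, "elastic_moduli"))
  if (is.null(d) == is.null(q1)) abort("supply exactly one of `d` or `q1`")
  if (is.null(q1)) q1 <- 2 * pi / d
  eta <- .kB * moduli$temperature * q1^2 /
    (8 * pi * sqrt(moduli$B * moduli$kappa))
  xi <- (moduli$kappa / moduli$B)^(1 / 4)
  caille_parameters(eta = eta, xi = xi, q1 = q1)
}
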