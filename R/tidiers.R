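#' Tidy a Caille structure-factor fit
#'
#' One row per estimated quantity: the Caille parameters with their
#' approximate standard errors, the derived moduli, and the per-cut scale
#' factors.
#'
#' @param x A `caille_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`, `unit`.
#' @export
tidy.caille_fit <- function(x, ...) {
  bind_rows(
    tibble(term = "eta", estimate = x$eta, std.error = x$eta_se,
           unit = "1"),
    tibble(term = "xi", estimate = x$xi, std.error = x$xi_se,
           unit = "Angstrom"),
    tibble(term = "kappa", estimate = x$kappa, std.error = NA_real_,
           unit = "J"),
    tibble(term = "kappa_kbt", estimate = x$kappa_kbt,
           std.error = NA_real_, unit = "kBT"),
    tibble(term = "B", estimate = x$B, std.error = NA_real_,
           unit = "J/A^4"),
    tibble(term = paste0("scale_", seq_along(x$scales)),
           estimate = x$scales, std.error = NA_real_, unit = "1"))
}

#' Glance at a Caille structure-factor fit
#'
#' @param x A `caille_fit`.
#' @param ... Unused.
#' @return A one-row tibble of fit-level summaries.
#' @export
glance.caille_fit <- function(x, ...) {
  tibble(eta = x$eta, xi = x$xi, kappa_kbt = x$kappa_kbt, B = x$B,
         chisq = x$chisq, dof = x$dof, n_cuts = length(x$data_cuts),
         n_obs = x$n_obs, n_eval = x$n_eval,
         converged = x$converged, at_bounds = x$at_bounds)
}

#' Best-fit curves alongside the data
#'
#' @param x A `caille_fit`.
#' @param ... Unused.
#' @return A long tibble: `qz`, `qpar`, `intensity`, `sigma`, `kind`
#'   (`"data"` or `"fit"`).
#' @export
augment.caille_fit <- function(x, ...) {
  rows <- list()
  for (l in seq_along(x$data_cuts)) {
    d <- x$data_cuts[[l]]
    m <- x$model_cuts[[l]]
    rows[[2 * l - 1]] <- tibble(qz = x$qz_list[l], qpar = d$qpar,
                                intensity = d$intensity, sigma = d$sigma,
                                kind = "data")
    rows[[2 * l]] <- tibble(qz = x$qz_list[l], qpar = m$qpar,
                            intensity = m$intensity, sigma = NA_real_,
                            kind = "fit")
  }
  bind_rows(rows)
}
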