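#' Specification of a synthetic diffuse-scattering dataset
#'
#' Bundles everything the forward generator needs: the fluctuation
#' parameters, finite-size model, detector geometry, beam width, the
#' painted specular peaks, a smooth stand-in for the form-factor envelope,
#' background and noise model. The seed fixes all stochastic output
#' bitwise.
#'
#' The form factor only ever enters the analysis through per-cut scale
#' factors, so any smooth positive envelope is admissible for testing;
#' `"constant"` and a damped cosine of configurable period are provided.
#'
#' @param p A [caille_parameters()] object (ground truth).
#' @param size_model A [finite_size_model()].
#' @param geometry A [detector_geometry()] (for image synthesis).
#' @param beam A [beam_model()].
#' @param envelope `"constant"` or `"damped_cosine"`.
#' @param envelope_period Period (in `q_z`, 1/Angstrom) of the damped
#'   cosine envelope.
#' @param specular_amplitudes Peak amplitudes (counts) of the painted
#'   specular Gaussians at `q_z = n * q1`, `n = 1, 2, ...`.
#' @param specular_sigma_qz,specular_sigma_qpar Gaussian widths of the
#'   specular peaks in 1/Angstrom.
#' @param diffuse_scale Counts scale multiplying the (arbitrary-unit)
#'   structure factor.
#' @param background Constant background level in counts.
#' @param noise `"none"`, `"poisson"`, or `"gaussian"`.
#' @param noise_level Relative level for Gaussian noise (e.g. 0.01 for
#'   1%).
#' @param seed Integer random seed.
#' @param control An [sf_control()] for the forward model.
#' @param table_r_nodes,table_n_max Unit-table resolution for the forward
#'   model.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(p, size_model, geometry = NULL,
                         beam = beam_model(0),
                         envelope = c("constant", "damped_cosine"),
                         envelope_period = 0.2,
                         specular_amplitudes = c(2e4, 8e3, 3e3, 1e3, 400),
                         specular_sigma_qz = 0.004,
                         specular_sigma_qpar = 0.003,
                         diffuse_scale = 1,
                         background = 0,
                         noise = c("none", "poisson", "gaussian"),
                         noise_level = 0.01,
                         seed = 1L,
                         control = sf_control(dr = 2),
                         table_r_nodes = 1500L, table_n_max = NULL) {
  envelope <- arg_match(envelope)
  noise <- arg_match(noise)
  stopifnot(inherits(p, "caille_parameters"),
            inherits(size_model, "finite_size_model"),
            inherits(beam, "beam_model"),
            background >= 0, diffuse_scale > 0)
  if (is.null(table_n_max)) {
    table_n_max <- min(
      999L,
      max(30L, ceiling((size_model$Lz_mean + 10 * size_model$Lz_sigma) /
                         size_model$d)))
  }
  structure(list(p = p, size_model = size_model, geometry = geometry,
                 beam = beam, envelope = envelope,
                 envelope_period = envelope_period,
                 specular_amplitudes = specular_amplitudes,
                 specular_sigma_qz = specular_sigma_qz,
                 specular_sigma_qpar = specular_sigma_qpar,
                 diffuse_scale = diffuse_scale, background = background,
                 noise = noise, noise_level = noise_level,
                 seed = as.integer(seed), control = control,
                 table_r_nodes = as.integer(table_r_nodes),
                 table_n_max = as.integer(table_n_max)),
            class = "fixture_spec")
}

.envelope_at <- function(spec, qz) {
  switch(spec$envelope,
         constant = rep(1, length(qz)),
         damped_cosine = {
           # smooth, strictly positive, slowly varying in qz
           (0.6 + 0.4 * cos(2 * pi * qz / spec$envelope_period)^2) *
             exp(-qz / 2)
         })
}

.fixture_unit_table <- function(spec) {
  unit_correlation_table(
    r_grid = default_r_grid(n_nodes = spec$table_r_nodes),
    n_max = spec$table_n_max)
}

#' Generate line cuts with known ground truth
#'
#' Runs the forward model (structure-factor profile, beam convolution,
#' form-factor envelope, noise) at each requested `q_z` and returns the
#' cuts together with a truth record of every generating parameter.
#'
#' @param spec A [fixture_spec()].
#' @param qz_list Cut positions in 1/Angstrom.
#' @param qpar_axis In-plane axis (uniform, 1/Angstrom).
#' @return A list with `cuts` (list of `line_cut` tibbles) and `truth`
#'   (the generating parameters, including the per-cut noiseless
#'   profiles).
#' @export
make_line_cut_dataset <- function(spec, qz_list, qpar_axis) {
  stopifnot(inherits(spec, "fixture_spec"))
  unit_tab <- .fixture_unit_table(spec)
  corr <- rescale_correlation(unit_tab, spec$p)
  env <- .envelope_at(spec, qz_list)
  set.seed(spec$seed)
  cuts <- vector("list", length(qz_list))
  clean <- vector("list", length(qz_list))
  for (l in seq_along(qz_list)) {
    v <- .sf_profile_convolved(qz_list[l], qpar_axis, spec$p,
                               spec$size_model, corr, spec$beam,
                               spec$control)
    v <- v * env[l] * spec$diffuse_scale + spec$background
    clean[[l]] <- v
    noisy <- switch(spec$noise,
                    none = v,
                    poisson = rpois(length(v), lambda = v),
                    gaussian = v * (1 + spec$noise_level *
                                      rnorm(length(v))))
    sig <- switch(spec$noise,
                  none = rep(1, length(v)),
                  poisson = sqrt(pmax(v, 1)),
                  gaussian = spec$noise_level * pmax(v, 1e-12))
    cuts[[l]] <- new_line_cut(qpar = qpar_axis, intensity = as.numeric(noisy),
                              sigma = sig, qz_center = qz_list[l],
                              qz_requested = qz_list[l])
  }
  list(cuts = cuts,
       truth = list(spec = spec, qz_list = qz_list,
                    clean_profiles = clean))
}

#' Synthesize a detector image with known ground truth
#'
#' Paints, per pixel, the diffuse intensity of the forward structure
#' factor (using the independent fixture geometry formulas, not the
#' reduction module's code), adds Gaussian specular peaks at
#' `q_z = n * q1` on the meridian, a constant background, and noise, then
#' writes a 16-bit grayscale TIFF. Counts are clipped to the 16-bit range.
#'
#' @param spec A [fixture_spec()] whose `geometry` is set.
#' @param path Output TIFF path.
#' @param n_rows,n_cols Detector size in pixels.
#' @return Invisibly, a list with the noiseless `image` matrix, the
#'   written `path`, and the `truth` record.
#' @export
synthesize_detector_image <- function(spec, path, n_rows, n_cols) {
  stopifnot(inherits(spec, "fixture_spec"),
            inherits(spec$geometry, "detector_geometry"))
  g <- spec$geometry
  rows <- seq_len(n_rows); cols <- seq_len(n_cols)
  q_rows <- .fixture_pixel_q(rows, rep(g$beam_center[2], n_rows),
                             g$distance_mm, g$pixel_mm,
                             g$beam_center[1], g$beam_center[2],
                             g$wavelength, g$distort_qz, g$distort_qpar)
  q_cols <- .fixture_pixel_q(rep(g$beam_center[1], n_cols), cols,
                             g$distance_mm, g$pixel_mm,
                             g$beam_center[1], g$beam_center[2],
                             g$wavelength, g$distort_qz, g$distort_qpar)
  qz_axis <- q_rows$qz          # one qz per row
  qpar_axis <- q_cols$qpar      # one qpar per column
  n_orders <- length(spec$specular_amplitudes)
  max_q1 <- n_orders * spec$p$q1
  if (max(qz_axis) < max_q1) {
    warn(sprintf("detector covers qz up to %.3g but specular orders extend to %.3g 1/A",
                 max(qz_axis), max_q1))
  }
  unit_tab <- .fixture_unit_table(spec)
  corr <- rescale_correlation(unit_tab, spec$p)
  m <- spec$size_model
  r_int <- .sf_integration_grid(m, spec$control)
  hr <- size_weight_radial(r_int, m)
  base_w <- .trapz_weights(r_int) * r_int * hr
  # shared fine qpar grid: resolves the finite-size central peak and the
  # beam kernel, and sidesteps the (slightly) nonuniform pixel q spacing
  h_feat <- (2 * pi / m$Lr_mean) / 4
  if (spec$beam$sigma_q > 0) h_feat <- min(h_feat, spec$beam$sigma_q / 2)
  h <- min(min(abs(diff(qpar_axis))), h_feat)
  gmax <- max(abs(qpar_axis)) + 6 * spec$beam$sigma_q + h
  pos <- seq(0, gmax + h, by = h)
  fine <- c(-rev(pos[-1]), pos)
  # J0 weight matrix shared by all rows (columns fixed across rows)
  M <- besselJ(abs(outer(r_int, fine)), 0) * base_w
  env <- .envelope_at(spec, qz_axis)
  img <- matrix(0, n_rows, n_cols)
  for (i in rows) {
    if (qz_axis[i] <= 0) next   # painter covers the upper half plane
    lam <- lambda_kernel(r_int, qz = qz_axis[i], corr = corr, m = m)
    v <- pmax(drop(crossprod(M, lam)), 0)
    v <- convolve_beam(v, fine, spec$beam)
    v <- pmax(splinefun(fine, v, method = "natural")(qpar_axis), 0)
    img[i, ] <- v * env[i] * spec$diffuse_scale
  }
  # specular Gaussians on the meridian
  for (n in seq_len(n_orders)) {
    qc <- n * spec$p$q1
    amp <- spec$specular_amplitudes[n]
    gz <- exp(-(qz_axis - qc)^2 / (2 * spec$specular_sigma_qz^2))
    gp <- exp(-qpar_axis^2 / (2 * spec$specular_sigma_qpar^2))
    img <- img + amp * outer(gz, gp)
  }
  img <- img + spec$background
  set.seed(spec$seed)
  noisy <- switch(spec$noise,
                  none = img,
                  poisson = matrix(rpois(length(img), lambda = img),
                                   n_rows, n_cols),
                  gaussian = img * (1 + spec$noise_level *
                                      matrix(rnorm(length(img)),
                                             n_rows, n_cols)))
  counts <- pmin(pmax(round(noisy), 0), 65535)
  tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16L)
  truth <- list(spec = spec, qz_axis = qz_axis, qpar_axis = qpar_axis)
  invisible(list(image = img, counts = counts, path = path, truth = truth))
}

#' Write a truth record as flat key-value text
#'
#' @param truth A truth record from the generators.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_truth_record <- function(truth, path) {
  spec <- truth$spec
  kv <- c(
    eta = spec$p$eta, xi = spec$p$xi, d = spec$p$d, q1 = spec$p$q1,
    Lr_mean = spec$size_model$Lr_mean, Lr_sigma = spec$size_model$Lr_sigma,
    Lz_mean = spec$size_model$Lz_mean, Lz_sigma = spec$size_model$Lz_sigma,
    sigma_q = spec$beam$sigma_q, background = spec$background,
    diffuse_scale = spec$diffuse_scale, seed = spec$seed)
  lines <- c(sprintf("%s = %.12g", names(kv), kv),
             sprintf("envelope = %s", spec$envelope),
             sprintf("noise = %s", spec$noise))
  writeLines(lines, path)
  invisible(path)
}
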