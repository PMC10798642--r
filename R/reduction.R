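#' Detector geometry of the diffraction experiment
#'
#' Everything needed to map detector pixels to reciprocal space: the
#' sample-to-detector distance, the pixel pitch, the position of the
#' direct beam on the detector and the wavelength. Rows are counted from
#' the top of the image (row 1 = top), `q_z` increases upward from the
#' beam center and `q_par` to the right.
#'
#' A flat detector subtends the spherical coordinate system of reciprocal
#' space, so equal pixel steps are not equal angle steps. The
#' `distort_qz` / `distort_qpar` flags enable the arctangent correction of
#' this flat-detector distortion per axis (on by default); disabling them
#' selects the small-angle linear mapping.
#'
#' @param distance_mm Sample-to-detector distance in mm.
#' @param pixel_mm Pixel edge length in mm.
#' @param beam_center `(row, col)` pixel of the direct beam; fractional
#'   values allowed.
#' @param wavelength X-ray wavelength in Angstrom (0.1 to 10).
#' @param distort_qz,distort_qpar Apply the arctangent distortion
#'   correction along the respective axis.
#' @return An object of class `detector_geometry`.
#' @export
detector_geometry <- function(distance_mm, pixel_mm, beam_center,
                              wavelength, distort_qz = TRUE,
                              distort_qpar = TRUE) {
  stopifnot(distance_mm > 0, pixel_mm > 0, length(beam_center) == 2L,
            wavelength >= 0.1, wavelength <= 10)
  structure(list(distance_mm = distance_mm, pixel_mm = pixel_mm,
                 beam_center = as.numeric(beam_center),
                 wavelength = wavelength,
                 distort_qz = isTRUE(distort_qz),
                 distort_qpar = isTRUE(distort_qpar)),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "<detector_geometry> L = %g mm, pixel = %g mm, beam at (%g, %g), lambda = %g A\n",
    x$distance_mm, x$pixel_mm, x$beam_center[1], x$beam_center[2],
    x$wavelength))
  invisible(x)
}

#' Load a detector image from TIFF
#'
#' Reads a single-channel grayscale TIFF (8/16/32-bit integer or float).
#' Integer samples are returned unscaled. If the data were stored on a
#' logarithmic scale, they are linearized as `I = base^stored` (base 10 by
#' default; detector vendors differ, so the base is configurable).
#' Negative intensities after linearization are an error. A Poisson
#' variance estimate `var = max(I, 1)` is attached per pixel.
#'
#' @param path Path to the TIFF file.
#' @param log_scale Stored values are `log_base(I)` rather than `I`.
#' @param log_base Base of the logarithmic storage (default 10).
#' @return An object of class `intensity_map`: list with `data` (matrix,
#'   row 1 = top of image), `variance`, `log_scale`, `path`.
#' @export
load_intensity_map <- function(path, log_scale = FALSE, log_base = 10) {
  if (!file.exists(path)) abort(sprintf("TIFF file not found: %s", path))
  raw <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(raw)) == 3L && dim(raw)[3] > 1L) {
    abort(sprintf(
      "multi-channel (RGB) TIFF with %d channels: a single-channel grayscale detector image is required",
      dim(raw)[3]))
  }
  m <- if (length(dim(raw)) == 3L) raw[, , 1L] else raw
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) abort("non-finite pixel values in TIFF")
  if (log_scale) m <- log_base^m
  if (any(m < 0)) {
    abort(sprintf("%d negative intensities after linearization", sum(m < 0)))
  }
  new_intensity_map(m, log_scale = log_scale, path = path)
}

new_intensity_map <- function(data, log_scale = FALSE, path = NA_character_) {
  structure(list(data = data, variance = pmax(data, 1),
                 log_scale = log_scale, path = path),
            class = "intensity_map")
}

#' @export
print.intensity_map <- function(x, ...) {
  cat(sprintf("<intensity_map> %d x %d pixels, range [%g, %g]\n",
              nrow(x$data), ncol(x$data), min(x$data), max(x$data)))
  invisible(x)
}

#' Pixel offsets to scattering angles
#'
#' Maps a detector pixel to the meridional angle `theta` (vertical axis)
#' and azimuthal angle `Xi` (horizontal axis), in degrees. With `k` the
#' signed pixel offset from the beam center (upward positive for `theta`,
#' rightward positive for `Xi`), the linear mode gives
#' `angle = (pixel_mm * k / distance_mm) * 180/pi` and the corrected mode
#' `angle = atan(pixel_mm * k / distance_mm) * 180/pi`. The corrected
#' (arctangent) branch is the geometric truth for a flat detector; the
#' mode per axis follows the geometry's `distort_qz` / `distort_qpar`
#' flags.
#'
#' @param row,col Pixel indices (row 1 = top; fractional allowed),
#'   vectorized.
#' @param g A [detector_geometry()].
#' @return A list with `theta` and `xi` in degrees.
#' @export
pixel_to_angles <- function(row, col, g) {
  stopifnot(inherits(g, "detector_geometry"))
  k_theta <- g$beam_center[1] - row     # rows count downward; qz is up
  k_xi <- col - g$beam_center[2]
  ratio_t <- g$pixel_mm * k_theta / g$distance_mm
  ratio_x <- g$pixel_mm * k_xi / g$distance_mm
  theta <- if (g$distort_qz) atan(ratio_t) else ratio_t
  xi <- if (g$distort_qpar) atan(ratio_x) else ratio_x
  list(theta = theta * 180 / pi, xi = xi * 180 / pi)
}

#' Scattering angles to reciprocal-space coordinates
#'
#' `q_z = 4*pi*sin(theta)/lambda` and `q_par = 4*pi*sin(Xi/2)/lambda`,
#' with angles in degrees converted internally to radians. Note the
#' asymmetric convention (`theta` vs `Xi/2`) between the two axes.
#'
#' @param theta,xi Angles in degrees (vectorized).
#' @param wavelength Wavelength in Angstrom.
#' @return A list with `qz` and `qpar` in 1/Angstrom.
#' @export
angles_to_q <- function(theta, xi, wavelength) {
  stopifnot(wavelength > 0)
  list(qz = 4 * pi * sin(theta * pi / 180) / wavelength,
       qpar = 4 * pi * sin(xi * pi / 360) / wavelength)
}

#' Map a detector image to reciprocal space
#'
#' Labels every pixel with its `(q_z, q_par)` coordinate via
#' [pixel_to_angles()] and [angles_to_q()]. Intensities are left untouched
#' (no regridding): line cuts are taken on pixel rows/columns and carry
#' their q labels. Since `theta` depends only on the row and `Xi` only on
#' the column, the coordinates separate into a per-row `q_z` axis and a
#' per-column `q_par` axis.
#'
#' @param img An [load_intensity_map()] result.
#' @param g A [detector_geometry()].
#' @return An object of class `q_map`: list with `qz_axis` (per row),
#'   `qpar_axis` (per column), `intensity`, `variance`, `geometry`.
#' @export
map_to_qspace <- function(img, g) {
  stopifnot(inherits(img, "intensity_map"), inherits(g, "detector_geometry"))
  nr <- nrow(img$data); nc <- ncol(img$data)
  ang_r <- pixel_to_angles(seq_len(nr), rep(g$beam_center[2], nr), g)
  ang_c <- pixel_to_angles(rep(g$beam_center[1], nc), seq_len(nc), g)
  q_r <- angles_to_q(ang_r$theta, ang_r$xi, g$wavelength)
  q_c <- angles_to_q(ang_c$theta, ang_c$xi, g$wavelength)
  structure(list(qz_axis = q_r$qz, qpar_axis = q_c$qpar,
                 intensity = img$data, variance = img$variance,
                 geometry = g),
            class = "q_map")
}

#' @export
print.q_map <- function(x, ...) {
  cat(sprintf(
    "<q_map> %d x %d pixels; qz in [%.4g, %.4g], qpar in [%.4g, %.4g] 1/A\n",
    nrow(x$intensity), ncol(x$intensity),
    min(x$qz_axis), max(x$qz_axis), min(x$qpar_axis), max(x$qpar_axis)))
  invisible(x)
}

#' Meridional (specular) reflectivity profile
#'
#' Averages the intensity over a box of columns centered at `q_par = 0`
#' (default 12 pixels wide) to produce the out-of-plane intensity scan
#' from which the lamellar repeat spacing is read off. Uncertainties are
#' propagated from the per-pixel Poisson variances (`variance / m^2`
#' summed over the `m` averaged pixels).
#'
#' @param qmap A [map_to_qspace()] result covering `q_par = 0`.
#' @param box_pixels Box width in pixels (default 12).
#' @return A tibble of class `reflectivity_profile` with columns `qz`,
#'   `intensity`, `sigma`, sorted by increasing `qz`.
#' @export
meridional_profile <- function(qmap, box_pixels = 12L) {
  stopifnot(inherits(qmap, "q_map"), box_pixels >= 1)
  nc <- ncol(qmap$intensity)
  c0 <- which.min(abs(qmap$qpar_axis))
  if (min(qmap$qpar_axis) > 0 || max(qmap$qpar_axis) < 0) {
    abort("image does not span qpar = 0; cannot form a meridional profile")
  }
  half <- (box_pixels - 1) / 2
  cols <- seq(ceiling(c0 - half), floor(c0 + half))
  if (any(cols < 1L | cols > nc)) {
    warn("meridional box clipped at the detector edge")
    cols <- cols[cols >= 1L & cols <= nc]
  }
  m <- length(cols)
  inten <- rowMeans(qmap$intensity[, cols, drop = FALSE])
  sig <- sqrt(rowSums(qmap$variance[, cols, drop = FALSE])) / m
  out <- tibble(qz = qmap$qz_axis, intensity = inten, sigma = sig)
  out <- out[order(out$qz), ]
  class(out) <- c("reflectivity_profile", class(out))
  out
}

#' Estimate the lamellar repeat spacing from a reflectivity profile
#'
#' Detects local maxima above a prominence threshold, refines each peak
#' position by a three-point parabolic fit, assigns integer diffraction
#' orders (`q_n = n * q1`) starting from the lowest-q peak, and estimates
#' `q1` by a least-squares fit through the origin over the detected
#' orders; `d = 2*pi/q1`.
#'
#' @param profile A [meridional_profile()] result.
#' @param peak_orders Optional integer orders to assign to the detected
#'   peaks (in increasing-q order); by default orders are inferred from
#'   the peak-position ratios.
#' @param min_prominence Minimum peak height above its surrounding
#'   baseline, as a fraction of the profile maximum (default 0.05).
#' @param qz_min Ignore peaks below this `q_z` (default 0.02 1/A),
#'   excluding the direct beam and substrate reflectivity.
#' @return A list with `d` (Angstrom), `q1`, and a tibble `peaks`
#'   (`qz`, `order`).
#' @export
estimate_d_spacing <- function(profile, peak_orders = NULL,
                               min_prominence = 0.05, qz_min = 0.02) {
  stopifnot(inherits(profile, "reflectivity_profile"))
  qz <- profile$qz; y <- profile$intensity
  usable <- qz > qz_min
  if (!any(usable)) abort("no usable qz range above `qz_min`")
  thr <- min_prominence * max(y[usable])
  idx <- which(usable)
  peaks_q <- c()
  for (i in idx) {
    if (i <= 1L || i >= length(y)) next
    if (y[i] > y[i - 1L] && y[i] >= y[i + 1L] && y[i] > thr) {
      # local baseline: lower of the two flanking minima within 5 pixels
      lo <- max(1L, i - 5L); hi <- min(length(y), i + 5L)
      base <- min(min(y[lo:i]), min(y[i:hi]))
      if (y[i] - base < thr) next
      # parabolic sub-pixel refinement on (qz, y)
      d1 <- y[i] - y[i - 1L]; d2 <- y[i] - y[i + 1L]
      denom <- d1 + d2
      shift <- if (denom > 0) 0.5 * (d1 - d2) / denom else 0
      dq <- (qz[i + 1L] - qz[i - 1L]) / 2
      peaks_q <- c(peaks_q, qz[i] + shift * dq)
    }
  }
  if (!length(peaks_q)) {
    abort("no lamellar peaks found; supply the d-spacing manually")
  }
  peaks_q <- sort(peaks_q)
  if (!is.null(peak_orders)) {
    if (length(peak_orders) != length(peaks_q)) {
      abort(sprintf("%d peaks detected but %d orders supplied",
                    length(peaks_q), length(peak_orders)))
    }
    orders <- as.numeric(peak_orders)
    keep <- rep(TRUE, length(peaks_q))
  } else {
    # consensus order assignment: spurious local maxima (noise, diffuse
    # ridge shoulders) must not anchor the ladder, so try each peak (and
    # small divisors of it) as a q1 candidate and keep the candidate that
    # makes the most peaks land on integer multiples
    best <- NULL
    for (i in seq_along(peaks_q)) {
      for (k in 1:3) {
        q1c <- peaks_q[i] / k
        ratio <- peaks_q / q1c
        ok <- abs(ratio - round(ratio)) < 0.12 & round(ratio) >= 1
        score <- sum(ok)
        resid <- sum(abs(ratio[ok] - round(ratio[ok])))
        if (is.null(best) || score > best$score ||
            (score == best$score && resid < best$resid)) {
          best <- list(score = score, resid = resid, ok = ok,
                       orders = round(ratio))
        }
      }
    }
    keep <- best$ok
    orders <- best$orders
  }
  q1 <- sum(orders[keep] * peaks_q[keep]) / sum(orders[keep]^2)
  list(d = 2 * pi / q1, q1 = q1,
       peaks = tibble(qz = peaks_q[keep], order = orders[keep]))
}

#' Extract in-plane line cuts at chosen q_z positions
#'
#' For each requested `q_z`, crops a rectangular box of detector rows
#' (width `box_pixels`, centered on the nearest row) and either averages
#' along `q_z` within the box (`mode = "average"`, the default: one cut
#' per requested `q_z`) or emits one cut per pixel row in the box
#' (`mode = "per_row"`). Uncertainties are propagated from the per-pixel
#' variances. At least two cuts at distinct `q_z` are needed downstream to
#' determine both moduli.
#'
#' @param qmap A [map_to_qspace()] result.
#' @param qz_list Requested `q_z` positions in 1/Angstrom.
#' @param box_pixels Rows to average per cut (default 1).
#' @param mode `"average"` or `"per_row"`.
#' @return A list of line cuts: tibbles of class `line_cut` with columns
#'   `qpar`, `intensity`, `sigma`; attributes `qz_center` (intensity-box
#'   mean `q_z`), `qz_requested`, `rows`.
#' @export
extract_line_cuts <- function(qmap, qz_list, box_pixels = 1L,
                              mode = c("average", "per_row")) {
  stopifnot(inherits(qmap, "q_map"), box_pixels >= 1)
  mode <- arg_match(mode)
  rng <- range(qmap$qz_axis)
  bad <- qz_list < rng[1] | qz_list > rng[2]
  if (any(bad)) {
    abort(sprintf("requested qz outside the image range [%.4g, %.4g] 1/A: %s",
                  rng[1], rng[2],
                  paste(format(qz_list[bad]), collapse = ", ")))
  }
  cuts <- list()
  for (qz in qz_list) {
    r0 <- which.min(abs(qmap$qz_axis - qz))
    half <- (box_pixels - 1) / 2
    rows <- seq(ceiling(r0 - half), floor(r0 + half))
    rows <- rows[rows >= 1L & rows <= nrow(qmap$intensity)]
    if (mode == "average") {
      m <- length(rows)
      inten <- colMeans(qmap$intensity[rows, , drop = FALSE])
      sig <- sqrt(colSums(qmap$variance[rows, , drop = FALSE])) / m
      cuts[[length(cuts) + 1L]] <- new_line_cut(
        qpar = qmap$qpar_axis, intensity = inten, sigma = sig,
        qz_center = mean(qmap$qz_axis[rows]), qz_requested = qz,
        rows = rows)
    } else {
      for (rr in rows) {
        cuts[[length(cuts) + 1L]] <- new_line_cut(
          qpar = qmap$qpar_axis, intensity = qmap$intensity[rr, ],
          sigma = sqrt(qmap$variance[rr, ]),
          qz_center = qmap$qz_axis[rr], qz_requested = qz, rows = rr)
      }
    }
  }
  cuts
}

new_line_cut <- function(qpar, intensity, sigma, qz_center,
                         qz_requested = NA_real_, rows = integer(),
                         background_subtracted = FALSE) {
  out <- tibble(qpar = qpar, intensity = intensity, sigma = sigma)
  attr(out, "qz_center") <- qz_center
  attr(out, "qz_requested") <- qz_requested
  attr(out, "rows") <- rows
  attr(out, "background_subtracted") <- background_subtracted
  class(out) <- c("line_cut", class(out))
  out
}

#' Cut position of a line cut
#'
#' @param cut A `line_cut`.
#' @return The `q_z` of the cut in 1/Angstrom.
#' @export
qz_center <- function(cut) attr(cut, "qz_center")

#' Rudimentary constant-background subtraction
#'
#' Estimates a constant baseline as the median intensity over the outer
#' flanks of the cut (the outer `flank_fraction` of points on each side,
#' pooled) and subtracts it. This presumes the cut extends far enough in
#' `|q_par|` that the diffuse signal has decayed at the flanks; if the
#' estimated baseline exceeds half the peak intensity a warning is
#' issued. Negative intensities after subtraction are floored at zero and
#' their count recorded in the `n_floored` attribute.
#'
#' @param cut A `line_cut`.
#' @param flank_fraction Fraction of points per side treated as baseline
#'   (default 0.1).
#' @return The background-subtracted `line_cut`; attributes `baseline`
#'   and `n_floored` record what was done.
#' @export
subtract_background <- function(cut, flank_fraction = 0.1) {
  stopifnot(inherits(cut, "line_cut"), flank_fraction > 0,
            flank_fraction < 0.5)
  n <- nrow(cut)
  k <- max(1L, ceiling(flank_fraction * n))
  flank <- c(cut$intensity[seq_len(k)],
             cut$intensity[seq(n - k + 1L, n)])
  baseline <- median(flank)
  if (baseline > 0.5 * max(cut$intensity)) {
    warn("estimated baseline exceeds 50% of the peak; flanks may overlap the signal region")
  }
  new_val <- cut$intensity - baseline
  n_floored <- sum(new_val < 0)
  out <- cut
  out$intensity <- pmax(new_val, 0)
  attr(out, "baseline") <- baseline
  attr(out, "n_floored") <- n_floored
  attr(out, "background_subtracted") <- TRUE
  class(out) <- class(cut)
  out
}
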