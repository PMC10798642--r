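# Reciprocal-space coordinates for the synthetic-image painter.
#
# Deliberately independent of the reduction module: the fixture generator
# must not share geometry code with the code under test, so that the
# pixel -> q round trip through the reduction chain is a genuine check.
# Formulas are written out directly from the flat-detector geometry here.

# per-pixel q coordinates for the painter; row 1 = top, qz increases upward
.fixture_pixel_q <- function(rows, cols, distance_mm, pixel_mm,
                             beam_row, beam_col, wavelength,
                             distort_qz = TRUE, distort_qpar = TRUE) {
  up <- (beam_row - rows) * pixel_mm / distance_mm
  right <- (cols - beam_col) * pixel_mm / distance_mm
  th <- if (distort_qz) atan(up) else up
  xi <- if (distort_qpar) atan(right) else right
  list(qz = (4 * pi / wavelength) * sin(th),
       qpar = (4 * pi / wavelength) * sin(xi / 2))
}
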