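---
title: "Methods: the Caillé structure factor and the diffuse-scattering analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Caillé structure factor and the diffuse-scattering analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the model it
computes, the assumptions behind it, the numerical choices made where
the mathematics leaves room, and what the shipped checks do and do not
demonstrate.

## The physical model

A stack of `N` fluid bilayers on a solid support is described by the
discrete smectic free energy: each membrane `n` carries a Helfrich
bending energy `(κ/2)(∇²uₙ)²` and couples harmonically to its neighbors
through `(B/2d)(uₙ₊₁ − uₙ)²`, with `d` the repeat spacing. Decomposing
the displacement field into Fourier modes and applying equipartition
gives the height–height correlation function

$$\delta u_n(r) = \frac{2\eta}{q_1^2}\int_0^\infty
\frac{1 - J_0\!\big(\tfrac{r}{\xi}\sqrt{2x}\big)\,
\big(\sqrt{1+x^2}-x\big)^{2n}}{x\sqrt{1+x^2}}\,dx,$$

with `q₁ = 2π/d` and the two Caillé parameters

$$\eta = \frac{k_B T\, q_1^2}{8\pi\sqrt{B\kappa}},\qquad
\xi = \left(\frac{\kappa}{B}\right)^{1/4}.$$

`η` is the dimensionless fluctuation amplitude; `ξ` (Å) is the in-plane
length over which a membrane responds to a perturbation of its
neighbor. Fitting the diffuse intensity yields `(η, ξ)`, which invert
uniquely to `(κ, B)` at a stated temperature — `moduli_from_caille()` /
`caille_from_moduli()` are exact algebraic inverses of the pair above.

The measurable structure factor of a *finite* stack is

$$S(q_z, q_\parallel) = \int_0^\infty r\,dr\,H_r(r)\,
J_0(q_\parallel r)\,\Lambda(r),\qquad
\Lambda(r) = \sum_{n} H_z(|n|d)\cos(q_z n d)\,
e^{-q_z^2\,\delta u_{|n|}(r)/2},$$

where `H_z` and `H_r` weight layer-pair separations and in-plane pair
distances by the probability that both points fall inside one
coherently scattering domain. Domains are cylindrical with Gaussian
distributed height (`Lz_mean`, `Lz_sigma`) and diameter (`Lr_mean`,
`Lr_sigma`); both weights have closed or quadrature forms implemented
in `size_weight_axial()` / `size_weight_radial()`.

### The correlation exponent

The structure-factor literature this model comes from writes the
correlation term loosely as a phase factor in `δuₙ(r)`, which is
dimensionally inconsistent (`δu` is a squared length). The package uses
the standard Gaussian-cumulant form `exp(−q_z² δuₙ(r)/2)`, which is what
the underlying harmonic theory gives for Gaussian-distributed relative
displacements and what makes `S` real, positive and dimensionally
coherent. This is a deliberate interpretation, stated here prominently.

### Exact and asymptotic branches

The defining integral for `δuₙ(r)` is evaluated two ways:

- **exact** (`delta_u_exact()`): adaptive quadrature on the semi-infinite
  interval. The integrand is finite at `x → 0` (limit `2n + (r/ξ)²/2`),
  which the implementation substitutes analytically; naive panel rules
  fail there. For large `r/ξ` the integrand oscillates and the QUADPACK
  integrator can report roundoff failure at tight tolerances, so a
  tolerance ladder `1e-8 → 1e-6 → 1e-4` (relative; absolute `1e-10`) is
  tried in order, and an error with `(n, r, tolerances)` is raised if
  all rungs fail. The looser rungs were verified to agree with the
  asymptote to ~1e-6 relative where they engage.
- **asymptotic** (`delta_u_asymptotic()`), for `n ≥ 30` or `r/ξ ≥ 1000`:

  $$\delta u_n(r) = \frac{4\eta}{q_1^2}\left[\gamma + \ln\frac{r}{\xi}
  + \tfrac12 E_1\!\left(\frac{r^2}{4 n \xi^2}\right)\right].$$

  The printed sources are typographically ambiguous about whether the
  Euler–Mascheroni constant multiplies or adds to the logarithm. This
  was settled **numerically**: the additive form matches the exact
  quadrature to about `1e-6` relative throughout the seam band
  (`n = 25…35`, `r = 800…1200` Å at unit scale) and far beyond, while
  the product form is off by ~47%. The branch-continuity check is part
  of the test suite. Likewise the ambiguous grouping
  `(√(1+x²) − x)^{2n}` was adopted over `(1 + x² − x)^{2n}`: it is
  bounded in (0, 1], yields convergent integrals and monotone-in-`n`
  decorrelation, and is continuous with the asymptote; the alternative
  diverges.
- `n = 0` has no asymptote (the `E₁` argument is infinite), so
  `delta_u_asymptotic(0, …)` raises an error by contract. Table rows for
  `n = 0` beyond the exact regime use the `E₁ → 0` plateau
  `(4η/q₁²)(γ + ln(r/ξ))`, which the exact integral approaches to ~1e-6
  by `r/ξ ≈ 1000`.

### The rescalable unit table

`δuₙ(r)` does not depend on `q_z`, and scales as
`δuₙ(r; ξ, η, q₁) = (η/q₁²) · δuₙ^{unit}(r/ξ)` where the unit table is
computed once at `ξ = 1, η = 1, q₁ = 1`
(`build_unit_correlation_table()`). A fit therefore pays the quadrature
cost once; every optimizer step just relabels the radius axis and
multiplies (`rescale_correlation()`, exactly linear in `η`). Storing the
table `q₁`-free (unit `q₁`, applied at rescale time) keeps one cached
table valid across d-spacings; this is the same scaling identity with
the constant prefactor factored out. The table defaults mirror the
method's standard grid — 10,000 log-spaced radii in `1e-4…1e6` Å and
`n = 0…1000` — but the resolution is an accuracy/time dial, not part of
the physics: the shipped checks build 1,500-node tables with `n ≤ 30`
(the axial weight support for the check geometry), which reproduces a
dense no-table calculation to ~4e-6 relative (see "Validation" below).
Interpolation between nodes is a natural cubic spline in `log r`;
extrapolation outside the grid is an error, never silent.

## From table to intensity

`Λ(r)` is summed over the layers whose axial weight is non-negligible
(`H_z` is Gaussian-tailed, so the sum truncates itself; a cap of
`|n| < 1000` applies) exploiting evenness in `n`. The radial integral
is the field-standard trapezoidal rule on a uniform grid, default
`dr = 1` Å from 1 Å, truncated at `Lr_mean + 6·Lr_sigma` where `H_r` is
numerically zero (identical result, large constant-factor savings); the
step is configurable via `sf_control()`. Tiny negative values from
trapezoid cancellation noise in the far tail are clipped to zero with a
warning. `S` is even in `q_parallel` by construction (`J₀` is even in
its argument).

The instrument's Gaussian beam footprint enters as a 1-D convolution of
the computed profile with a unit-area Gaussian of standard deviation
`sigma_q` (Å⁻¹), truncated at ±5σ; at the profile edges the kernel is
renormalized over its in-range support, so no zero-padding artifacts
(`convolve_beam()`; `sigma_q = 0` is the identity).

One numerical subtlety matters in practice: the diffuse profile has a
finite-size central peak of width ~`2π/Lr_mean` (≈ 0.002 Å⁻¹ for the
3000 Å domains used here). Model evaluation therefore always happens on
an internal uniform grid fine enough to resolve both that width and the
beam kernel — `min(data spacing, (2π/Lr)/4, σ_q/2)` — and is then
interpolated to the data abscissae. Tying the model grid to the data
spacing alone silently undersamples the central peak and badly skews
the profiled scale factors.

## Reduction of detector images

The reduction chain maps TIFF detector images to reciprocal space with
the flat-detector geometry: with `k` the signed pixel offset from the
direct beam, the meridional and azimuthal angles are
`atan(pixel·k/L)` (distortion-corrected mode, geometric truth for a
planar detector) or the linear small-angle form (both modes are
offered per axis; the historical "distorted/non-distorted" naming is
preserved on the command line), and

$$q_z = \frac{4\pi\sin\theta}{\lambda},\qquad
q_\parallel = \frac{4\pi\sin(\Xi/2)}{\lambda}.$$

The asymmetric convention (`θ` vs `Ξ/2`) follows the source geometry
exactly. Intensities are never regridded: cuts live on pixel
rows/columns and carry q labels, so reduction is exactly linear and
mirror-symmetric. Uncertainties are Poisson, `var = max(counts, 1)`,
averaged as variance/m².

Specifics worth knowing:

- **Log-scale input**: linearized as `I = 10^stored`; the base is
  configurable since vendor conventions differ.
- **d-spacing** (`estimate_d_spacing()`): local maxima above a
  prominence threshold, three-point parabolic sub-pixel refinement,
  then a *consensus* order assignment — every detected peak (and its
  small divisors) is tried as a `q₁` candidate and the candidate that
  makes the most peaks land on integer multiples wins, with `q₁` from a
  least-squares fit through the origin over the consistent peaks. This
  keeps spurious maxima (noise, diffuse shoulders) from anchoring the
  ladder.
- **Background** (`subtract_background()`): the source material names
  only a "rudimentary" routine, so the declared choice here is a
  constant baseline equal to the median of the outer 10% of points on
  each side (pooled), subtracted, with negatives floored at zero and
  counted. It presumes the cut extends past the diffuse decay; a
  warning fires if the baseline exceeds half the peak.

## Fitting

`fit_structure_factor()` minimizes

$$\chi^2 = \sum_l \sum_k \frac{(s_l Y_l[k] - y_l[k])^2}{\sigma_l[k]^2}$$

over `(η, ξ)`, with the per-cut scales `s_l` — which absorb the form
factor `|F(q_z)|²` — profiled out in closed form at every step
(`optimal_scales()`; convex in `s_l`, so the optimum is identical to
treating them as free parameters while shrinking the nonlinear search
to two dimensions). Weighting is by `σ²`, the standard chi-square; the
first-power-of-σ variant that sometimes appears in print is available
as `weighting = "sigma"` for comparison, but makes χ² carry units. The
default optimizer is `minpack.lm`'s trust-region least squares
(Levenberg–Marquardt family) with numerically differenced Jacobian and
box constraints (`η ∈ (0, 2]`, `ξ ∈ [1, 1e5]` Å); a Nelder–Mead simplex
on log-parameters is the fallback (`optimizer = "simplex"`) since
derivative-free minimizers also have a history in this analysis.
Standard errors come from the local quadratic expansion at the optimum
(`(JᵀJ)⁻¹·χ²/dof`) and are labeled approximate. The reported iteration
trace contains the accepted (χ²-improving) steps, so it is nonincreasing
by construction. The domain sizes, beam width, d-spacing and temperature
are fixed inputs, not fitted — at these noise levels they are not
identifiable together with `(η, ξ)` from two cuts.

At least two cuts at distinct `q_z` are required: a single cut cannot
separate `η` from `ξ` (amplitude vs shape trade against the free scale).

## The synthetic generator

`fixture_spec()` + `make_line_cut_dataset()` /
`synthesize_detector_image()` emulate the experiment forward: diffuse
intensity from the same structure-factor pipeline, a smooth positive
form-factor stand-in (constant or damped cosine — the analysis only
ever sees the form factor through per-cut scales, so any smooth
envelope is equally informative for testing), Gaussian specular peaks
painted at `q_z = n·q₁` on the meridian, a constant background, and
Poisson or relative-Gaussian noise under a bitwise-reproducible seed.
The image painter computes pixel coordinates from its own geometry
formulas, deliberately sharing no code with the reduction module, so
the pixel → q round trip through the reduction chain is a genuine
test. Images are written as 16-bit unsigned integer TIFFs (counts
clipped at 65535).

What the generator does *not* emulate: physical reflectivity and
substrate scattering (specular lines are plain Gaussians), absolute
intensities, mosaic spread, window-material rings, flat-field and
geometric detector distortions beyond the ideal flat-detector mapping,
and the smooth `q_z`-dependence of a real form factor. Passing tests
therefore demonstrate the correctness and stability of the *analysis
chain* under its own model assumptions — not that the model captures
every systematic in real data.

## Standard check conditions

The shipped tests and `scripts/acceptance.R` run under one fixed set of
study conditions, chosen once as representative of a well-measured
fluid-phase sample: `η = 0.1`, `ξ = 60` Å, `d = 53` Å (κ ≈ 20 k_BT at
298 K — a POPC-like stack), domains `Lr = 3000 ± 1000` Å and
`Lz = 10d ± 2d`, beam σ_q = 0.001 Å⁻¹, Cu-Kα wavelength 1.5418 Å,
detector 200 × 229 pixels of 0.1 mm at 200 mm with the beam at
(195, 115), diffuse exposure ~2×10³ counts at the third-order lobe over
a 20-count background, cuts at `q_z = 3q₁` and `3.5q₁`. Model
evaluations in the checks use `dr = 2` Å and 1,500-node tables; the
pipeline-vs-brute-force comparison uses the same trapezoid step on both
sides so that it isolates the table-and-interpolation approximation it
is meant to bound.

## Known limitations

- The radial trapezoid rule loses the profile tail (≳ 4–5 decades below
  the central peak) to cancellation noise; affected values are clipped
  to zero with a warning. Halving `dr` pushes the floor down.
- `extract_line_cuts()` does not mask the specular region around
  `q_parallel = 0`; cuts taken exactly at integer lamellar orders
  include the painted (or real) specular peak, which the diffuse model
  does not describe. Choosing cut positions off the integer orders, or
  at them accepting a small bias, is the user's call.
- Standard errors are curvature-based approximations; no profile
  likelihood or resampling is offered.
- The rocking-scan convolution used by fixed-detector synchrotron
  setups is out of scope; data from such setups need that extra
  convolution before these fits are quantitative.
- Absolute intensities are arbitrary throughout; only ratios within and
  between cuts matter, by design.
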