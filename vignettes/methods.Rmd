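---
title: "Models and methods in mierecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mierecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mierecon)
```

# The physical model

`mierecon` treats a strongly scattering sample — a polymer microsphere, or
an idealized single cell — as a homogeneous or two-layer dielectric sphere
in air.  Space is discretized into `J` voxels of constant complex
refractive index: one voxel for a homogeneous sphere, two concentric voxels
(core and shell) for a stratified one.  Within voxel `j` the imaginary
index is a sum of `M` anti-symmetrized Lorentzian absorption bands with
centre `ν̃_m` (cm⁻¹), height `h_m` (imaginary-index units) and half-width
`Γ_m` (cm⁻¹).  Subtracting each band's mirror image at `−ν̃_m` makes
`k(ν̃)` an odd function of wavenumber, which is what causality demands of
the imaginary index; for this basis the Kramers–Kronig transform of every
band is available in closed form, so the real part
`n(ν̃) = n_∞ + (closed-form band sum)` is obtained without any numerical
Hilbert transform.  That matters in the mid infrared because measured
spectra cover only ≈500–4000 cm⁻¹, far too little support for an accurate
principal-value integral.  The free parameter `n_∞ ≥ 1` absorbs the real
index contributed by all resonances outside the fitted window (chiefly
electronic transitions in the UV/visible).

The forward map from a candidate model to data is the Lorenz–Mie partial
wave series: homogeneous coefficients from the internal logarithmic
derivative (downward recurrence seeded above `max(N, |m x|)`), stratified
coefficients by a ratio-stabilized elimination of the interior fields
derived from the two-interface boundary conditions, both truncated at the
Wiscombe order `N = ⌈x + 4x^{1/3} + 2⌉` and implemented in C++.  The
package verifies the homogeneous series against an independently coded
evaluation (function values by normalized downward recurrence, textbook
coefficient formulas) and the coated series against a direct 4×4 linear
solve of the boundary conditions per order; degenerate-limit identities
(identical layers, vanishing core, vanishing shell) are asserted in the
test suite.  A core whose size parameter stays below 0.1 is treated as
absent — its neglected contribution scales with the cube of its size
parameter, below the accuracy of everything downstream.

Measured data may arrive as apparent absorbance instead of extinction
efficiency.  The two are related pointwise through
`Q_ext = (G/g)(1 − 10^{-A})`, with `G/g` the detector-to-sample area
ratio.  Experimental artefacts are modelled on the absorbance side as
`A_obs = s·A + c₀ + c₁u + c₂u²` in the centred, range-normalized coordinate
`u ∈ [−½, ½]`: constant = baseline shift, linear = tilt, quadratic =
curvature, `s` = scaling.  The normalization keeps all four parameters O(1)
and weakly correlated.  When `G/g` is unknown it is not jointly
identifiable with `s`; the package then fixes `G/g = 100` and lets the
fitted scale absorb the mismatch, which is documented behaviour rather than
an estimate of the true ratio.

# The inverse fit

The fit minimizes the sum of squared differences between model and given
spectra over all band parameters, `n_∞` per voxel, optional distortion
parameters and optional radii.  The solver is bounded Levenberg–Marquardt
on the residual vector (`minpack.lm::nls.lm`, finite-difference Jacobian),
with step and residual tolerances `1e-10` and at most 400 iterations per
run.  Box constraints keep the parameters physical: heights in `[0, 1]`
(non-negative — passive media absorb; a switch permits gain bands for
non-standard uses), widths in `[2, 400]` cm⁻¹, `n_∞` in `[1, 2]`, centres
inside the data range widened by one initialization bin but floored at half
the lowest data wavenumber.  That floor exists because a band whose centre
reaches zero cancels exactly against its mirror term and becomes an
invisible "ghost" parameter; keeping centres away from zero removes a flat
direction of the objective.

Band centres start equi-spaced at mid-bin positions
`ν̃_min + (m − ½)Δν̃/M`, so some initial band is always near every true
absorption feature; heights start uniform in `[0.001, 0.1]` and widths in
`[5, 50]` cm⁻¹ from the configured seed, `n_∞` at 1.5, the distortion at
identity.  The fit repeats from `n_starts` (default 3) such
initializations under distinct, prefix-stable sub-seeds and keeps the
best-objective result, ties to the earliest start; a start whose objective
falls below `perfect_floor` (default `1e-10` of the data's sum of squares)
ends the search, since later starts cannot improve on a perfect fit.
Identical data, configuration and seed give bit-identical results.

Plain multi-start LM is not enough for this landscape, so three
deterministic continuation devices wrap it; all were chosen during
development on synthetic instances and are part of the algorithm, not
per-dataset tuning:

* **Stage-then-refine.**  Each start first fits a 5-point moving average of
  the data (narrower than the narrowest resolvable band), then the raw
  data.  The smoothed stage finds the right basin under noise; the raw
  stage removes the smoothing bias, which matters because a smoothed
  spectrum is not the extinction spectrum of any dispersion model.
* **Band repair.**  After convergence, the band with the smallest peak
  contribution to the imaginary index inside the window is relocated to the
  wavenumber of the largest smoothed absolute residual, and — for layered
  spheres — each band is alternatively offered to the other voxel in
  exchange for that voxel's weakest band.  Candidate moves are ranked by
  short fits on 3×-subsampled data, the two best are refit in full, and a
  move is kept only when the objective improves (up to `n_reseeds` rounds,
  default 4).  This rescues the two characteristic failure modes: a dead
  band far from any feature, and a band attributed to the wrong layer.
* **Radius continuation.**  The objective is oscillatory in the radii
  (interference fringes of period well below a micrometre), so a free
  radius cannot be found by gradient descent from a distant start.  Every
  start therefore scans 21 candidate radii across the bounds, running its
  staged band fit at each frozen radius on subsampled data, and releases
  the radius only after the bands have locked onto the winning branch.
  Release is reliable from within roughly ±0.25 µm of the optimum at the
  default geometry, which sets the candidate spacing.
* **Layered cascade.**  A two-voxel fit is initialized from a homogeneous
  pre-fit carrying the combined band count: absorption features appear in
  `Q_ext` wherever they reside, so the pre-fit localizes all centres, and
  the layered problem reduces largely to assigning bands to layers.  All
  `C(M₁+M₂, M₁)` assignments (when at most 300) are ranked by short
  subsampled fits; the best assignments seed the starts, with a core-radius
  cross-scan when that radius is free.  For larger band counts the cascade
  is skipped and the fit falls back to equi-spaced initialization.

Noisy spectra get one further protection.  Exact least squares on raw noisy
points is statistically treacherous here: spurious narrow bands and
band-weight shifts between overlapping bands change the recovered index
substantially while changing `Q_ext` by less than the noise floor, so the
global minimum of the raw objective need not lie in the basin of the
generating model.  When the data look noisy — the spectral flatness of
their double-differenced values over the upper frequency band, whitened by
the differencing response, exceeds 0.4 (white noise sits near 0.56, while
deterministic fine structure, including the narrowband interference ripple
of coated spheres that defeats purely local statistics, stays below about
0.3), on a grid sampled at 5 cm⁻¹ or finer so that the filter window is
narrow on the band scale — the optimizer targets a Savitzky–Golay filtered
copy of the
spectrum (order 3, 21 points), which suppresses the noise variance while
preserving band shapes.  The reported objective is always the raw Eq.-style
sum of squares, and the behaviour can be forced either way with the
`denoise` configuration switch.  On clean data the filter never engages, so
noiseless recovery remains exact.

The identifiability guard requires at least ten data points per free
parameter (an error by default, demotable to a warning).  When the given
spectrum is an absorbance spectrum the comparison is made in absorbance
space by default — the distortion acts there — and the model's distortion
is applied to the model's absorbance, which is equivalent to unfolding the
data and leaves the recovered distortion directly comparable to the one
that produced the observation.

# Scoring

Reconstructions are scored against a reference index separately for the
real and imaginary parts: `R² = 1 − S_res/S_tot`, with `S_tot` taken about
the scalar mean of the reference part over the scoring grid.  The
reconstruction side is always evaluated analytically at the reference
wavenumbers (the dispersion model is continuous), so no interpolation error
enters; the reference is never interpolated either when it is itself a
model, and linearly when it is a table queried off its own grid.  `R²` can
be negative for reconstructions worse than the reference mean and is
reported unclamped.  Note one consequence of near-degeneracy in the layered
problem: two fits of visually similar `S` can differ greatly in `R²`, which
is why the layered cascade aims for the exact basin (`S` at the numerical
floor) rather than merely a small objective.

# The synthetic-data generator

All tests and the acceptance script run on synthetic data generated inside
the package.  `random_dispersion()` draws band centres uniformly (rejection
sampling keeps every pair at least 1.5× the mean width apart, so bands stay
resolvable), heights and widths uniformly within configured ranges.  The
default study conditions are: spectra on 500–4000 cm⁻¹, sphere radius
10 µm, optional 8 µm core; six bands for homogeneous experiments and 4+4
for layered ones, centres in 600–3600 cm⁻¹, heights 0.02–0.3, widths
10–60 cm⁻¹, `n_∞ = 1.5` — magnitudes representative of strong polymer
vibrational bands.  Tests use a 4 cm⁻¹ grid spacing (876 points) and the
bundled default is 2 cm⁻¹.  Noise is bounded uniform multiplicative:
each point is multiplied by `1 + ε`, `ε ~ U(−f, f)`, which makes a stated
level of "up to 10%" literal.  Distorted observations are produced by
converting the clean extinction spectrum to absorbance at a known `G/g`
and applying a known distortion.

What the generator does not emulate: instrument line-shape convolution,
detector nonlinearity and wavelength-dependent source coherence;
non-spherical and more-than-two-layer geometries; dispersions outside the
Lorentzian family (real materials contain non-Lorentzian structure that a
finite band sum only approximates).  Passing the synthetic recovery suite
therefore demonstrates that the inverse machinery finds the generating
model under the stated noise, not that any real cell is a two-layer
Lorentzian sphere.

# Numerical choices and limitations

Degenerate inputs are handled explicitly: empty band sets are permitted
only internally (the public constructor requires `M ≥ 1`); bands are kept
in canonical order (ascending centre, ties by descending height) so
recovered band sets are comparable; a coated sphere collapses to the
homogeneous solver when the core is negligible or the shell thinner than
`1e-12` relative.  The numerical Kramers–Kronig transform shipped as the
analytic pair's oracle integrates the singularity-subtracted integrand by
trapezoid over an anti-symmetrically extended grid and refuses evaluation
points beyond half the grid top, where truncation error dominates.

Known limitations: band count `M` is user-set, with no automatic model
selection; uncertainty quantification is out of scope; the layered cascade
enumerates assignments and is therefore limited to modest band counts;
fitting a free radius together with heavy noise multiplies the scan cost,
as no floor break occurs.  Runtimes at the default test scale (876 points,
one CPU): a homogeneous 6-band fit converges in seconds; layered 4+4 fits
and free-radius fits in minutes, dominated by the assignment ranking and
radius scans.
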