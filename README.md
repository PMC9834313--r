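# mierecon

Reference-free reconstruction of the complex refractive index of
homogeneous and two-layer dielectric spheres from infrared extinction
spectra.

## The problem

Single-cell infrared microspectroscopy measures an apparent absorbance
`A(ν̃) = -log10(I/I0)` in the forward direction.  For samples whose size is
comparable to the wavelength — single cells, polymer microspheres — this
signal mixes true vibrational absorption with strong Mie scattering, plus
instrumental baseline shift, tilt, curvature and scaling errors.  The
chemistry lives in the complex refractive index
`η(ν̃) = n(ν̃) + i k(ν̃)`, and recovering both of its parts from the single
real curve `Q_ext(ν̃)` (the extinction efficiency,
`Q_ext = (G/g)(1 - 10^(-A))` for a detector of reception area `G` and
sample cross section `g`) is an inverse scattering problem.

`mierecon` solves it without a reference spectrum and without a numerical
Kramers–Kronig transform.  The imaginary index of each voxel (the whole
sphere, or the core and shell of a layered sphere) is modelled as a sum of
`M` anti-symmetrized Lorentzian absorption bands

    k(ν̃) = Σ_m  h_m / (1 + ((ν̃ − ν̃_m)/Γ_m)²)  −  h_m / (1 + ((ν̃ + ν̃_m)/Γ_m)²)

whose Kramers–Kronig partner is known in closed form,

    n(ν̃) = n_∞ − Σ_m  h_m u_m⁻/(1+u_m⁻²) − h_m u_m⁺/(1+u_m⁺²),
    u_m∓ = (ν̃ ∓ ν̃_m)/Γ_m,

so every candidate model is causal by construction.  A Lorenz–Mie forward
model (homogeneous or stratified sphere, compiled C++ core) maps band
parameters to `Q_ext^(model)`, and a bounded multi-start Levenberg–Marquardt
fit minimizes

    S = Σ_l [ Q_ext^(model)(ν̃_l) − Q_ext^(given)(ν̃_l) ]².

Alongside the band parameters the fit can estimate `n_∞` per voxel, the
sphere and core radii, and the four distortion parameters of a raw
absorbance spectrum (scale, shift, tilt, curvature), which corrects the
measurement while reconstructing the index.  Reconstructions are scored
against reference optical constants with per-part coefficients of
determination `R² = 1 − S_res/S_tot`.

## Worked example

```r
library(mierecon)

# ground truth: a 6-band dispersion on a 10 um sphere
truth  <- random_dispersion(6, seed = 101)
geom   <- sphere_geometry(10)                    # radius in micrometres
nu     <- seq(500, 4000, by = 4)                 # wavenumbers, cm^-1
bundle <- make_observation(truth, geom, nu = nu, seed = 101)

# invert the extinction spectrum with matched band count, 3 starts
cfg <- fit_config(bands_per_voxel = 6, seed = 202, n_starts = 3)
fit <- fit_dispersion(bundle$observed, geom, cfg, reference = truth)
fit
```

```
<fit_result> S = 3.27032e-28, converged = TRUE, best start 1 of 3
-- voxel 1 --
<voxel_dispersion> 6 band(s), n_inf = 1.5
    center    height    width
  731.4744 0.1837627 46.59863
 1349.5672 0.1133708 56.58172
 1500.1645 0.1941633 32.75603
 1716.5951 0.1728320 39.51599
 2573.0712 0.2663428 51.02180
 2729.0521 0.2179249 21.20592
<sphere_geometry> homogeneous, outer radius 10 um
voxel 1: R2 real 1.0000, R2 imag 1.0000
```

The recovered bands match the generating truth to machine precision: the
objective `S ≈ 3e-28` is the numerical floor, and both parts of the
refractive index score `R² = 1`.  With 10% multiplicative noise on the same
spectrum the fit still recovers the index with `R² ≈ 0.8–0.9`; with the
radius left free (started at 7 um) it returns the generating 10 um.

For a core–shell sphere, pass two dispersions and a two-radius geometry and
fit with `fit_layered()`; setting `fit_core_radius = TRUE` in the
configuration additionally estimates the core radius from the spectrum
alone.

A command-line interface wrapping the same functions is installed at
`inst/cli/mierecon` (`simulate`, `reconstruct`, `score` subcommands).

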