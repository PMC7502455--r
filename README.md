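# laosfit

Nonlinear fractional viscoelastic characterisation of soft tissue from
rotational-rheometer torque data acquired under combined compressive
preload and large-amplitude oscillatory shear (LAOS).

## The problem

Liver and similar soft tissues are quasi-linear at small strains but
strongly nonlinear, hysteretic and rate dependent at the deformations that
matter for surgery simulation, elastography and impact biomechanics.  A
standard probe is a cylindrical sample compressed between rheometer plates
(preloads of 1–20%) and sheared sinusoidally about its axis (amplitudes
1–50%, frequencies 0.5–2 Hz) while the plate torque is recorded.  `laosfit`
provides the full modelling pipeline for such experiments:

- exact compression–torsion kinematics of the cylindrical sample
  (isochoric deformation gradient, strain invariants, spectral measures);
- three constitutive models whose second Piola–Kirchhoff stress combines
  elastic, fractional viscoelastic and hydrostatic parts,
  `S = S_e + D_t^α S_v + S_p`, with the Caputo derivative
  `D_t^α f(t) = 1/Γ(1−α) ∫₀ᵗ (t−z)^(−α) f′(z) dz` supplying the
  `G* ∝ ω^α` frequency behaviour observed in tissue:
  - **vMR** (modified Mooney–Rivlin): `S = C·S_e² + δ·D_t^α(S_e¹) + S_p`,
  - **vOG** (Ogden-type): `S = δ·D_t^α(Σᵢ λᵢ^(b−1) vᵢ⊗vᵢ) + S_p`,
  - **vEXP** (Fung exponential): `S = δ·Dev[D_t^α(e^(b(II_C−3)) C)] + S_p`;
- a forward simulator of the plate torque
  `τ₃ = ∫ r₁σ₂₃ − r₂σ₁₃ dΓ` over burn-in plus recorded cycles (L1 scheme
  for the Caputo operator, radial Gauss–Legendre quadrature or a
  765-element triangulated disc for the surface integral);
- a synthetic-data generator emulating the 18-test protocol (compression ×
  shear × frequency) with per-test strain-softening amplitude factors and
  measurement noise, with ground truth recorded in a manifest;
- a fitting engine that sweeps the nonlinear parameters (α, b), solves the
  linear ones (C, δ ≥ 0) by nonnegative least squares, and scores with
  three norms — plain **L2**, **point-wise** (every sample weighted by its
  own data magnitude) and **parameter scaling** (shared nonlinear
  parameters, per-test amplitude scalings βᵢ that absorb strain softening
  and sample variability; absolute per-test parameters xᵢ = x*/βᵢ).

All norms are calibrated so a perfect fit scores 0% and zeroed linear
parameters score exactly 100%.

## Worked example

Simulate one test of the protocol and fit the whole synthetic study:

```r
library(laosfit)

pars <- material_parameters("vexp", delta = 300, alpha = 0.2, b = 1.3)
cond <- test_condition(sample_geometry(3e-3, 10e-3, 0.1), shear = 0.5, freq = 1)
tr <- simulate_test(pars, cond)
max(tr$tau)
#> [1] 0.001265132
```

The simulated plate torque peaks at about 1.27 mN·m for a 10% compressed,
50% sheared sample at 1 Hz — `tau_e`/`tau_v` in the trace are the
unit-parameter (per-Pa) elastic and viscoelastic components, and
`autoplot(tr)` draws the Lissajous curve (torque against plate angle).

```r
ds  <- generate_dataset(pars, softening = "linear", noise_sd = 0.01, seed = 1)
fit <- sweep_fit(ds, "vexp", "scaling")
fit
#> <laos_fit> model vexp, scaling norm: error 1.539% at alpha = 0.2, b = 1.3
#>   shared x* = (233.6) Pa; per-test beta in [0.778, 1.56]
```

The sweep (240 grid nodes × 18 tests, a few seconds on one core) recovers
the generating fractional order α = 0.2 and nonlinear power b = 1.3
exactly at the grid resolution, with a 1.5% residual matching the 1%
injected noise.  The per-test absolute parameters δᵢ = δ*/βᵢ reproduce the
softening schedule; `tidy(fit)`, `glance(fit)`, `augment(fit)` and
`autoplot(fit)` expose the result in the usual tidyverse shapes, and
`write_fit_report()` serialises it as JSON.

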