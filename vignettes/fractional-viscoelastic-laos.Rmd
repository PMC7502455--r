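---
title: "Fractional viscoelastic models for tissue under compression and oscillatory shear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional viscoelastic models for tissue under compression and oscillatory shear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(laosfit)
library(ggplot2)
```

## The problem

A soft-tissue sample — the motivating case is liver — is mounted as a short
cylinder between the serrated plates of a rotational rheometer, compressed
axially to a preload of 1–20%, and then sheared sinusoidally about its axis
at amplitudes of 1–50% and frequencies of 0.5–2 Hz.  At small shear the
torque response is a phase-delayed sinusoid; at large shear it becomes
visibly non-sinusoidal, hysteretic, and rate dependent.  `laosfit`
implements the full characterisation pipeline for such data: an exact
kinematic description of the combined compression–torsion deformation,
three fractional viscoelastic constitutive models, a forward torque
simulator, and a sweep-based fitting engine with three objective norms.
Because the motivating experimental data are not publicly deposited, the
package also ships a synthetic-data generator that emulates the study's
18-test protocol with known ground truth; the test suite and the acceptance
script exercise the pipeline end-to-end on those synthetic data.

## Kinematics

The sample has undeformed height $H$ and radius $R$.  Ideal (homogeneous,
isochoric) compression at strain $\mathrm{CS}$ gives the axial stretch
$\lambda = 1-\mathrm{CS}$, deformed height $h=\lambda H$ and radius
$r=R/\sqrt{\lambda}$.  The imposed plate rotation at shear amplitude
$\gamma$ and frequency $f$ is

$$\psi(t) = \sin(2\pi f t)\, h\gamma/r,$$

and the torsion angle varies linearly along the axis,
$\Psi(t,X_3)=\psi(t)X_3/H$.  The deformation gradient of this motion is
known in closed form; its determinant is identically one, which the test
suite verifies to $10^{-12}$ together with agreement to a central
finite-difference Jacobian of the motion map ($10^{-6}$ relative).  A point
worth recording: the printed closed form of the gradient mixes the
top-plate angle $\psi$ (in the third column, through $\partial\Psi/\partial
X_3 = \psi/H$) with the position-dependent angle $\theta(t)$ elsewhere.  We
confirmed analytically, and by the finite-difference oracle, that this *is*
the exact Jacobian at every interior point — the two forms are consistent,
not an approximation that holds only at the top surface.

## Constitutive models

All three models decompose the second Piola–Kirchhoff stress into elastic,
fractional viscoelastic and hydrostatic parts,
$S = S_e + D_t^\alpha S_v + S_p$, with $S_p = JPC^{-1}$ and the Caputo
derivative

$$D_t^\alpha S_v(t) = \frac{1}{\Gamma(1-\alpha)}\int_0^t
  (t-z)^{-\alpha}\,\partial_t S_v(z)\,\mathrm{d}z .$$

* **vMR** (modified Mooney–Rivlin): $S = C S_e^2 + \delta D_t^\alpha(S_e^1)
  + S_p$ with the neo-Hookean kernel $S_e^1 = J^{-2/3}(I - \tfrac{I_C}{3}
  C^{-1})$ and the quadratic kernel $S_e^2 = J^{-4/3}(II_{\hat C}-3)(C -
  \tfrac{II_C}{3}C^{-1})$.
* **vOG** (Ogden-type): $S = \delta D_t^\alpha(S_e^b) + S_p$ with $S_e^b =
  \sum_i \lambda_i^{b-1} v_i \otimes v_i$, the $\lambda_i, v_i$ being the
  principal stretches and eigenvectors of $C$.
* **vEXP** (Fung exponential): $S = \delta\,\mathrm{Dev}[D_t^\alpha(S_e^b)]
  + S_p$ with $S_e^b = e^{b(II_C-3)}C$ and $\mathrm{Dev}[A] = A -
  \tfrac{A:C}{3}C^{-1}$ evaluated with the *current-time* $C$, applied
  after the fractional derivative so that the deviatoric and hydrostatic
  parts remain separated.

$C_{\mathrm{lin}}$ and $\delta$ (Pa) are linear scales constrained to be
nonnegative; $\alpha \in [0,1]$ interpolates from hyperelastic to viscous
response and $b$ controls the strength of the nonlinearity ($b$ small:
near-sinusoidal torque; larger $b$: triangle-like waveforms and growing
harmonic distortion).

Two deliberate design points:

* The Ogden kernel is implemented **exactly as the printed stress**
  ($\lambda_i^{b-1}$ weights, i.e. the spectral function $C^{(b-1)/2}$),
  although the strict derivative of the one-term Ogden energy
  $W=(\sum_i\lambda_i^b-3)/(2b)$ would carry $\lambda_i^{b-2}$ weights.
  Fidelity to the published stress takes precedence; consequently the
  energy-consistency test (finite differences of $W$) covers the
  Mooney–Rivlin and exponential kernels only.
* The principal stretches entering the Ogden kernel are the full ones; the
  loading protocol is isochoric ($J=1$), so the isochoric stretches
  coincide with them anyway.

The hydrostatic pressure never enters the torque (a pressure stress has no
$13/23$ moment), but it is recoverable from the traction-free lateral wall
and `recover_wall_pressure()` exposes that balance.

## Fractional derivative: numerical choices

The Caputo integral is discretised with the **L1 scheme**: the history is
interpolated piecewise linearly inside the memory integral, giving
convolution weights $w_\ell \propto (\ell+1)^{1-\alpha} - \ell^{1-\alpha}$.
The scheme is exact for linear histories, $O(\Delta t^{2-\alpha})$ for
smooth ones, and reduces to the backward difference at $\alpha=1$.  The
convolution is evaluated by FFT, and the *full* history is kept — at the
problem sizes of this protocol (a few thousand samples) a short-memory
truncation would buy nothing and cost exactness with respect to the
scheme.

Two boundary decisions are not dictated by the integral definition:

* **History origin.**  The memory starts at $t=0$, defined as the instant
  the compressed preload state is reached.  The compression ramp is not
  simulated (the experimental protocol records long after it), so the
  kernel history begins at its static preloaded value, and constants
  differentiate to zero.
* **$\alpha = 0$.**  The literal Caputo limit would give $f(t)-f(0)$; the
  package instead returns the identity map on the history, matching the
  interpretation of $\alpha=0$ as a purely hyperelastic contribution.  This
  divergence is documented on `caputo_derivative()`.

The operator's oracles — closed forms for $f(t)=t$ and $t^2$, the
steady-state sinusoid response $\omega^\alpha\sin(\omega t + \alpha\pi/2)$,
and the $t^{-\alpha}$ step-relaxation slope — are all pinned in the test
suite.  The same power law explains why a single fractional term suffices
for this data: with $\alpha = 0.2$ the stress after a step takes
$0.01^{-1/0.2} = 10^{10}$ s (about 317 years) to decay to 1% of its peak,
so no separate equilibrium-elastic term is identifiable on experimental
time scales:

```{r}
power_law_decay_time(alpha = 0.2, fraction = 0.01)
```

## Forward torque model

The measured signal is the axial torque on the top plate,
$\tau_3 = \int_{\Gamma_t} r_1\sigma_{23} - r_2\sigma_{13}\,\mathrm{d}\Gamma$,
with $\sigma = \frac1J F S F^T$.  Two integration modes are provided:

* **Radial Gauss–Legendre quadrature** (order 16, the default).  The stress
  field is axisymmetric, so $\tau_3 = 2\pi\int_0^r \rho^2
  \sigma_{\theta z}(\rho)\,\mathrm{d}\rho$; doubling the order changes the
  result by less than $10^{-6}$ relative.
* A **765-element triangulated disc** (45 sectors × 9 rings, centroid
  evaluation), provided for fidelity to the original study's mesh and used
  as a cross-check.  Its node radii are inflated by
  $\sqrt{2\pi/(s\sin(2\pi/s))}$ so the flat-triangle areas sum to the disc
  area exactly; on the analytic torsion field it reproduces
  $\tau_3 = \pi r^4 c/2$ to 0.25%.

Internally the simulator exploits a reduction that makes sweeps cheap: on
the top surface $C(t)$ at radius $\rho$ has only two nontrivial independent
entries driven by $g(t) = \psi(t)\rho/H$, every isotropic kernel inherits
that structure, and the torque density needs only the kernel components
$A_{23}$ and $A_{33}$.  Because the Caputo operator is linear in time, it
commutes with the radially weighted sums, so each test requires just two
scalar fractional convolutions per $(\alpha, b)$ node.  A slow reference
route — full $3\times3$ tensors through `deformation_gradient()`,
`viscoelastic_kernel()`, `caputo_derivative()` and `cauchy_from_pk2()` — is
kept in the test suite and agrees with the fast path to $10^{-15}$ for all
three models.  (The vEXP deviatoric projection drops out of the torque
entirely: its correction term pushes forward to a hydrostatic Cauchy
stress.)

Default sampling mirrors the experimental protocol: $T = 200$ points per
period ($\mathrm{d}t = 1/(fT)$), 8 preconditioning cycles simulated and
discarded, 3 recorded cycles (601 recorded samples including the cycle
boundary).  The fractional derivative always acts on the full burn-in plus
recorded history, so memory crosses the recording boundary.  After 8
burn-in cycles the last two recorded cycles differ by under 0.5% RMS, which
is the same steadiness criterion the experimental preconditioning aims at.

```{r lissajous, fig.width = 6, fig.height = 4}
pars <- material_parameters("vexp", delta = 300, alpha = 0.2, b = 1.3)
cond <- test_condition(sample_geometry(3e-3, 10e-3, 0.1), shear = 0.5, freq = 1)
autoplot(simulate_test(pars, cond))
```

## Synthetic data: what it emulates, and what it does not

`generate_dataset()` reproduces the statistical structure of the study:

* the 18-test protocol (`default_protocol()`): compression 1/10/20% ×
  shear 1/10/25/50% at 1 Hz, plus the 10%-compression column at shear
  1/10/25% at 0.5 and 2 Hz;
* nominal geometry $H = 3$ mm, $R = 10$ mm;
* fractional phase delay and shear-strain nonlinearity through the forward
  model itself;
* **strain softening** as a per-test amplitude factor $\beta_i$ applied to
  the linear parameters ($x_i = x^*/\beta_i$), shape-preserving by
  construction — exactly the modelling assumption behind the
  parameter-scaling norm.  The default schedule is linear in the shear
  amplitude with a 2-fold decrease of the absolute parameters from 1% to
  50% shear.  Real tissue shows a stronger and noisier spread (standard
  deviations up to 90% of the mean); the default is deliberately milder,
  and `softening_schedule(kind = "custom")` accepts any positive map.
* additive Gaussian measurement noise, standard deviation 1% of each
  test's torque amplitude by default (no noise model is published; this is
  a package choice).

Default fixture parameters are vEXP with $\alpha = 0.2$ (the value
repeatedly identified for liver in shear rheometry), $b = 1.3$ and $\delta
= 300$ Pa; the latter two are plausible round numbers recorded in the
dataset manifest, not measured values.  What passing the recovery tests
shows is therefore *identifiability of the method under its own model
class with realistic noise and softening* — not that real liver data would
be fit this well.  Real data add barrelled (non-ideal) compression,
inter-sample biological variability beyond an amplitude factor, drift, and
model misfit; none of these are emulated.

## Fitting engine

For each candidate $(\alpha, b)$ the linear parameters are the solution of
a nonnegative least-squares problem built from unit-parameter torque
columns $[\tau^{m,e}\;\tau^{m,v}]$ stacked across tests; the nonlinear
parameters are found by sweeping a grid: $\alpha$ from 0.05 to 1 in steps
of 0.05, refined to 0.01 on $[0.15, 0.4]$; $b$ on $[1, 14]$ step 0.5 (vOG)
or $[1, 1.5]$ step 0.1 (vEXP) by default, with the wider exploratory
ranges available by argument.  Grid ties resolve deterministically to the
smallest $\alpha$, then smallest $b$.

Three norms are available, all calibrated so that a perfect fit scores 0%
and zeroed linear parameters score exactly 100%:

* **L2**: $\|Ax-b\|_2/\|b\|_2$ — simple, but dominated by the
  highest-amplitude tests (the data span two orders of magnitude).
* **Point-wise**: every residual is scaled by its own data magnitude,
  guarded by a tolerance below which points are not upweighted.  The guard
  is unspecified in the source description; the package default is
  $10^{-3}\max|b_i|$ per test, configurable, chosen to keep zero-crossing
  samples from dominating while preserving the equal-weight intent.
* **Parameter scaling**: nonlinear parameters shared across all 18 tests,
  per-test amplitudes $\beta_i$ floating, alternating between a stacked
  NNLS for $x^*$ and the closed-form per-test $\beta_i$ update, iterated
  until the error changes by less than $10^{-10}$ relative (or 200
  alternations).  The reported gauge fixes $\mathrm{mean}(\beta)=1$; the
  per-test absolute parameters are gauge-invariant.

One subtlety is worth stating plainly.  The printed $\beta_i$ update
minimises $\|A_i^*x^* - \beta_i b_i^*\|$, which is the scaling-norm
residual *weighted by* $\beta_i$, not the norm itself; on noisy data the
first alternation can therefore raise the error by a term of order
(residual fraction)$^2$ before the iteration settles — about $10^{-4}$
relative at 1% noise, and zero on exact data, where the update's fixed
point coincides with the plain per-test NNLS solution.  The package
implements the update as printed; the monotone-descent property test
allows a $10^{-8}$ relative slack for this reason.

At vanishing shear amplitude the response is linear and $b$ becomes
unidentifiable — the error surface is flat in $b$, which the suite checks
explicitly.  Identification of $b$ therefore rests on the large-strain
tests, and identification of $\alpha$ on the phase delay and the
cross-frequency amplitude ratio $(\omega_2/\omega_1)^\alpha$.

```{r fit, fig.width = 6, fig.height = 4}
ds <- generate_dataset(pars, default_protocol(points_per_period = 100),
                       softening = "linear", noise_sd = 0.01, seed = 1)
fit <- sweep_fit(ds, "vexp", "scaling",
                 alpha_grid = seq(0.15, 0.25, by = 0.01),
                 b_grid = seq(1.1, 1.5, by = 0.1))
glance(fit)
autoplot(fit)
```

```{r recovery}
# per-test absolute parameters against the generator's ground truth
dplyr::tibble(truth = 300 / ds$beta, estimate = fit$x_tests["delta", ])
```

## Problem sizes and runtime

The package's standard problem sizes are those of the emulated protocol:
18 tests, $T=200$ points per period, $8+3$ cycles (2201 simulated / 601
recorded samples per test).  With the separable torque reduction a full
default sweep (240 grid nodes × 18 tests) takes seconds on one core; the
examples in this vignette use $T = 100$ or a protocol slice purely to keep
document build time short, and the tolerances quoted above were all
measured at the full sizes in the test suite.

## Known limitations

* Ideal compression only: barrelled samples are out of scope, and the
  torque of a barrelled sample differs by a multiplicative factor that
  grows with preload, so absolute linear parameters fitted under the ideal
  assumption are upper-bound estimates at high compression.
* Normal force is not a validated output (ideal and non-ideal compression
  differ qualitatively there).
* No inertia, no sample inhomogeneity, no poroelastic effects.
* Fractional orders above 1, non-uniform time grids, and multi-term
  (extended) model variants are deliberately unsupported; the extended
  variants were found not to improve fits while breaking identifiability.
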