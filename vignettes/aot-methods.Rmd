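---
title: "Modeling and calibrating an angular optical trap"
author: "aotrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and calibrating an angular optical trap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The instrument and the model

An angular optical trap (AOT) focuses a linearly polarized 1064-nm beam
through a high-NA oil-immersion objective into an aqueous sample chamber and
traps a nanofabricated quartz cylinder whose extraordinary (optic) axis lies
perpendicular to the cylinder axis. The cylinder's orientation follows the
beam polarization; a misalignment angle α produces a restoring optical
torque, which is how torque on a DNA tether is applied and measured. Because
the immersion oil and coverslip (n = 1.518) do not match the aqueous medium
(n = 1.326 at 1064 nm), the converging wavefront acquires spherical
aberration that grows with the depth of the focus below the coverslip. The
package models the consequences of that aberration for trapping forces,
torques, and calibrations.

The simulation pipeline has three layers.

## Vector focusing through the stratified medium

The focused field is the Debye–Wolf angular spectrum of an aplanatic lens:
each pupil ray at polar angle θ₁ carries the apodization
√cosθ₁ · exp[−(sinθ₁/(f₀ sinθ_max))²], where θ_max = arcsin(NA/n_glass) and
the filling factor f₀ is the ratio of the input Gaussian waist to the
aperture radius (the standard convention for an apertured Gaussian; the
default 0.98 matches the modeled instrument). Crossing the glass–water
interface at depth d below the nominal focus, each plane-wave component is
split into s and p parts with Fresnel transmission and acquires the
stratified-medium phase k₀d(n₂cosθ₂ − n₁cosθ₁); components beyond the
critical angle (none at NA 1.3 into water) would carry a decaying axial
wavenumber. The azimuthal integrals are analytic (Bessel functions J₀, J₁,
J₂ for both E and H), leaving one-dimensional θ integrals evaluated by
Gauss–Legendre quadrature — order 120 by default; doubling the order moves
the peak field by well under 0.5%.

Normalization: the amplitude is fixed so that the power crossing a
transverse plane equals the requested specimen-plane power. The objective's
power transmission (0.42) is applied only when converting a pre-objective
power reading (`power_at_specimen()`); all forces and torques are otherwise
strictly linear in power.

Conventions worth stating once: +z is the propagation direction with the
origin at the nominal (aberration-free) focus; the coverslip plane sits at
z = −d and water occupies z > −d; the stage coordinate `zsurf` equals d, so
moving the surface away from the objective deepens the focus. The trap
height `htrap` is the distance from the cylinder's *bottom* face to the
coverslip. Lengths are nm, forces pN, torques pN·nm, powers mW.

## Coupled-dipole scattering

The cylinder (truncated cone, 473/589 nm diameters, 1016 nm height) is
discretized on a cubic lattice (50 nm by default, safely below λ₀/(10n))
clipped to the cone hull. Each dipole carries the anisotropic
Clausius–Mossotti polarizability relative to water, diagonal along the
crystal axes — diag(n_e², n_o², n_o²) — with the radiative-reaction
correction, rotated into the lab frame. Dipoles couple through the
free-space dyadic Green's function of the aqueous medium; the linear system
is solved densely. Reflections of the *scattered* field at the coverslip are
neglected (the 1.326→1.518 index step reflects well under 1% in intensity);
the cylinder–coverslip Fabry–Pérot interference that matters for calibration
is treated separately by the plane-wave fringe model, mirroring how the
measurement itself is analyzed.

Two exact structural facts make the pipeline fast. The interaction matrix
depends only on the lattice and the medium — not on the cylinder pose, the
interface depth, or the polarization — so its inverse is computed once per
setup (about 1800 dipoles at default spacing) and every pose costs only an
incident-field evaluation and matrix–vector products. And because the cone
is rotationally symmetric about z, rotating the cylinder by α is equivalent
to rotating the beam polarization by −α; the solver keeps the crystal frame
fixed and rotates the polarization, which is exact up to
lattice-discretization error (verified directly against an explicitly
rotated crystal tensor in the tests).

## Force, torque, and trap observables

Force and torque are closed-surface integrals of the time-averaged Maxwell
stress tensor of the total (incident + scattered) field over a cuboid
enclosing the cylinder, 200 nm beyond its hull, with per-face
Gauss–Legendre quadrature (20×20 by default). On the surface the medium is
water, so the tensor takes its isotropic form; the anisotropic form with
the permittivity tensor is available for evaluation inside the particle.
The surface co-moves with the cylinder, so the dipole-to-surface Green maps
are also precomputed. Growing the cuboid changes the force by <1%; an
independent dipole-summation force (½ Re Σ p*·∇E) agrees with the surface
integral to a few percent and serves as the cross-check, and as the force
path when the cylinder sits so close to the coverslip that the cuboid
cannot fit (the surface-attached scan).

From pose-wise forces the package derives: axial force profiles Fz(z); the
equilibrium (stable zero crossing, bracketing plus Brent refinement to
1 nm, warm-started across surface positions); the focal shift ratio of the
trap as the least-squares slope of htrap versus zsurf; axial stiffness
−dFz/dz at equilibrium (10-nm central difference); torque–angle curves
fitted as τ_z = −(κ_θ/2) sin 2α (a sinusoid fit is robust to the α grid,
unlike a two-point slope); and angular stiffness versus trap height or
cylinder displacement zcyl (negative zcyl = toward the coverslip, the
direction a taut DNA tether pulls; magnitudes are what the instrument
reports).

# Calibration estimators

**DNA ruler.** Near 20 pN dsDNA is stretched to ≈98% of its contour length
(0.338 nm/bp) and its extension is insensitive to the elasticity
parameters, so the *difference* between the stage positions at which two
molecules of different lengths (6546 and 11516 bp) reach 20 pN, compared
with the worm-like-chain prediction of the extension difference, yields the
focal shift ratio f_s = Δz_without/Δz_with. The 20-pN crossing is read by
local linear interpolation over samples within ±0.5 pN; the uncertainty is
first-order propagation of the two crossing fits. Using two lengths cancels
the session-systematic surface-zero and anchor offsets (tens of nm) that
bias any single-length estimate — both estimators are provided, and the
synthetic-data tests demonstrate the cancellation. The WLC parameter
defaults (L_p = 43 nm, K₀ = 1200 pN, kT at 23 °C) are configuration values;
the 20-pN ruler is insensitive to them by design.

**Fabry–Pérot fringes.** Interference between reflections off the cylinder
bottom and the coverslip modulates the detected intensity as the stage
moves; under the plane-wave assumption the round-trip phase advances by
4π n_w f_s/λ₀ per unit stage motion. The fringe frequency is initialized
from the periodogram peak and refined by Levenberg–Marquardt; f_s follows
from the fitted spatial frequency (period λ₀/(2 n_w) ≈ 401 nm at f_s = 1).

**Iterative loop.** Force and displacement calibrations themselves assume a
focal shift ratio, so raw traces recorded under an assumed ratio are
rescaled by the ratio of the current estimate to the instrument's assumed
value and re-analyzed until the estimate moves by <10⁻³. The fixed point is
the ground truth regardless of the starting value because the 20-pN
crossing is only weakly sensitive to the force scale near full extension.

**Angular PSD.** The angular fluctuations of a trapped cylinder are an
Ornstein–Uhlenbeck process; the Welch-averaged spectrum is fit with the
Lorentzian S(f) = D/(π²(f² + f_c²)) and κ_θ = 2π f_c γ_θ. The fit band is
restricted to f < 3 f_c (seeded from the equipartition estimate): the tail
of a *sampled* process is aliased and non-Lorentzian, and fitting it biases
the corner upward by several percent. The rotational drag γ_θ is an input;
`cylinder_rotational_drag()` provides an order-of-magnitude lateral-surface
estimate clearly labeled approximate. Equipartition kT/⟨α²⟩ is reported as
a cross-check.

**Twist analysis.** Under constant force, torque rises linearly with added
turns until the DNA buckles to extrude a plectoneme; past buckling torque
plateaus and extension falls linearly. Torque-versus-turns is fit as a line
continuous with a flat plateau, extension as a constant followed by a
linear decrease, sharing one breakpoint found by grid search at 0.25-turn
resolution. The segment fits and the buckled/not-buckled decision use the
raw samples — residuals of the 2-s-smoothed channels are strongly
autocorrelated and can fake a breakpoint on an unbuckled trace — while the
reported plateau torque is the mean of the smoothed post-buckling torque,
matching the instrument's 2-s display convention. Traces recorded with the
mirrored turn convention are detected (plateau at the wrong end) and
mirrored internally.

# The synthetic-data generators

The generators emulate the acquisition conditions of the modeled
experiments: 400-Hz stretching with a 2-step protocol (free until the
cylinder excursion reaches 300 nm, then constant-excursion feedback to
beyond 20 pN), stage-coordinate geometry x = f_s(z − z₀) − z_cyl(F) +
offset; fringe sweeps over 3 µm at SNR 10; 10-kHz, 60-s angular records
generated with the *exact* Ornstein–Uhlenbeck conditional update so that
equipartition holds at any sampling step; and 2-turn/s twist traces at a
3-pN clamp. Ground-truth defaults are the modeled study's conditions: focal
shift 0.829, ±20-nm-class session offsets, 0.3-pN force noise, torsional
slope 0.87 pN·nm/turn with buckling at 30 turns (plateau ≈ 26 pN·nm at
3 pN) and −45 nm/turn of plectoneme growth — values a torsional
single-molecule lab would call typical for ~6.5-kb DNA at 3 pN. All
randomness comes from one seeded stream per trace and the caller's RNG
state is restored.

What the generators deliberately do not emulate: detector filtering and
sensitivity physics, drift, instrument feedback latency, and Brownian
dynamics of the tethered cylinder in the computed optical field (trap
stiffnesses enter the generators as parameters; the physics path is
validated separately in the trap-characterization module). Passing
estimator tests therefore demonstrate correctness of the analysis given the
assumed statistical structure, not robustness to every instrumental
artifact.

# Numerical choices and problem sizes

* θ-quadrature order 120 (tests use 96); peak-field convergence is asserted
  at <0.5% on order doubling.
* Dipole spacing 50 nm (≈1800 dipoles) for reported numbers; the test suite
  runs a 65-nm lattice, and the trap focal shift moves by only ~0.002
  between the two. A true spacing-halving convergence test runs on a
  half-scale cylinder where it is tractable.
* Stress-tensor cuboid: 200-nm margin, 20×20 Gauss–Legendre per face
  (16×16 in tests); surface independence holds at 1%.
* Equilibria: bracket on a 100-nm scan, `uniroot` to 0.5 nm; stiffness by
  ±10-nm central difference.
* The trap focal-shift fit uses five surface positions over 2 µm
  (zsurf 1.0–3.0 µm), matching the modeled protocol; the stiffness trend
  uses trap heights 0.5–3.0 µm in 0.5-µm steps.
* Breakpoint grid 0.25 turn; PSD Welch segments of 2¹⁵ samples with Hann
  window and 50% overlap.

# Design decisions on open points

* The focal shift is defined, and fit, in the stage frame: f_s =
  d(htrap)/d(zsurf) with zsurf the interface depth; only differences enter
  any estimator, so zero offsets cancel.
* htrap follows the cylinder-bottom-to-surface convention; a trap-center
  convention differs by a constant that cancels in all slopes.
* n_water = 1.326 and n_glass = 1.518 at 1064 nm are adopted as defaults;
  they reproduce the paraxial ratio n_w/n_g = 0.87 quoted for the modeled
  instrument.
* Field grids export as TSV slices with a JSON metadata sidecar.
* The interface appears only in the *incident* field; scattered-field
  image terms are neglected (weak reflection, above).

# Known limitations

The idealized stratified-medium model treats the objective as a perfect
aplanatic lens plus a bare index step. That reproduces the focal-shift
observables well — the beam focus ratio (0.748), its paraxial limit
(0.871 at NA 0.3), and the trap ratio (0.790 at 50-nm spacing) — but it
*overstates* how fast the trap weakens with depth: the simulated axial
stiffness at equilibrium declines by roughly 19% per micron of trap height,
an order more than the few-percent decline measured on the physical
instrument this models. Two observations from the simulation itself bound
the discrepancy. First, the peak focal intensity falls only ~1.5%/µm; the
stiffness decline is dominated by axial spot elongation and by the
equilibrium drifting downstream into the weaker-gradient tail. Second, the
decline is strongly operating-point dependent: with the cylinder pulled
300 nm below the trap center — the condition under which unzipping-based
stiffness calibrations actually operate — the simulated decline flattens to
≈10%/µm, and the angular stiffness (an overlap-averaged quantity) varies by
only ~5% over 1–3 µm of trap height. Physical objectives also partially
compensate design aberrations, which the ideal model does not. Conclusions
that rest on focal-shift ratios, torque–angle shapes, or relative angular
stiffness are robust; absolute axial-stiffness-versus-depth trends from
this model should be treated as upper bounds on the degradation.

Other limitations: no multilayer (Sommerfeld) Green's functions, no
reflected field back into the glass, no thermal dynamics inside the solver,
no absorption (quartz is lossless at 1064 nm), no transverse stiffness
maps, and no ssDNA-elasticity (unzipping) calibration path.
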