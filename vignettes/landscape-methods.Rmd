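---
title: "Modeling strenuous self-righting on a potential energy landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling strenuous self-righting on a potential energy landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfright)
```

## The model

An overturned, self-deforming body — an insect opening its wings against the
ground, or a robot built the same way — is described by its gravitational
potential energy

$$E(\beta, \gamma;\ \theta_\mathrm{wing}) = m\, g\, z_\mathrm{CoM},$$

where $\beta$ and $\gamma$ are body pitch and roll (intrinsic Z-Y'-X'
Tait-Bryan angles; yaw does not change the height of the center of mass and
is ignored), and $z_\mathrm{CoM}$ is the height of the center of mass when
the body is translated vertically until its lowest surface point touches the
ground. This is a quasistatic model: the body never lifts off, contact is a
single support point, and no friction, compliance or dynamics enter. Over
the $[-180°, 180°]^2$ pitch-roll chart the landscape has an
upside-down/metastable basin near the origin, a pitch-upright basin at
$(\pm180°, 0)$, two roll-upright basins at $(0, \pm180°)$, and (for
composites whose center of mass sits off the geometric center) a shallow
backward-pitch basin below $-162°$ pitch. Self-righting is the escape from
the first basin into an upright one, and the cost of escape along the
straight path at polar angle $\psi$ from the positive-pitch axis is the
maximal rise of $E$ along that path. The pitch barrier is the barrier at
$\psi = 0$; the roll barrier is the minimum over
$\psi \in \pm[45°, 135°]$ (closed intervals — whether the published window
includes its endpoints is unstated, and the minimum is interior in
practice).

Two self-deformation degrees of freedom are modelled. Wing opening
$\theta_\mathrm{wing}$ rotates each wing about a hinge on the transverse cut
line, by the same angle in roll and pitch: the left wing by
$R_y(-\theta)R_x(+\theta)$ and the right wing by its sagittal mirror image,
so the posterior wing tips push dorsally (into the ground when overturned)
while the lateral edges lift ventrally. The composition order and signs are
not published for the original robot; of the physically plausible variants
this is the one that reproduces the qualitative landscape structure reported
for both animal and robot — the metastable minimum's pitch rises
monotonically with wing opening, both barriers decrease monotonically, and
the roll barrier stays below the pitch barrier — whereas wings whose lateral
edges roll toward the ground obstruct the roll path and produce a
non-monotone roll barrier. Leg position $\theta_\mathrm{leg}$ swings a
ventral pendulum leg in the coronal plane; the landscape is computed with
the leg held in the middle, and moving it across $\pm45°$ changes the roll
barrier only by a few percent (bounded below 20% in the tests).

## Ground contact without discretization error

The landscape is only as accurate as the support height. For every part
that is an ellipsoid or an ellipsoidal-shell slice, the lowest point is
found **analytically**: mapping the surface to the unit sphere
($x = \mathrm{diag}(a,b,c)\,q$, $|q| = 1$) turns the support height into the
minimum of a linear functional $e \cdot q$ over the sphere intersected with
at most three axis-aligned half-spaces (the slice cuts). Enumerating active
constraint sets gives a closed-form candidate for each subset, and the
feasible minimum is exact to machine precision. Cuboids contribute their
corners and rods their endpoints exactly; only uneven-ground contact falls
back to sampled surface points. Consequently the wings-closed animal
landscape matches the closed-form ellipsoid support height
$\sqrt{a^2 w_1^2 + b^2 w_2^2 + c^2 w_3^2}$ to rounding error, and the
headline barriers are limited only by the 1° grid and the 0.25° ray
sampling, not by mesh resolution.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| pitch/roll grid increment | 1 (headline), 2–5 (tests) | deg | 1° matches the published grids; barriers change < 2% on refinement |
| wing-angle range | [-10, 90] | deg | resting wing angle is slightly negative; 90° is the largest opening modelled |
| ray sampling along $\psi$ | 0.25 | deg | sub-grid accuracy via bilinear interpolation without re-solving contact |
| $\psi$ increment | 1 | deg | the roll window minimum is flat on this scale |
| Butterworth filter | order 6, 25 Hz | — | standard low-pass for 2000 frames/s marker tracks |
| body split | 38% of length from anterior | — | two-part ellipsoid body with uniform density |
| leg rod masses | 0.07 / 0.01 | g | coxa-femur and tibia-tarsus segment masses |
| tip sphere | 0.14 | g | added mass for the modified-leg condition |
| gravity | 9.81 | m s⁻² | SI; energies reported in mJ with mm/g interfaces |

The animal landscape mass is an explicit argument: the published barrier
values are consistent with the mean intact body mass (2.6 g), while the
similarity analysis uses the modified-leg mass (2.84 g). Both are supported
(`animal_spec(mass = )`); neither is silently substituted for the other.

The robot composite (260 g total across head, wings, leg rod, added mass and
five motors) requires internal part placement that the original hardware
does not publish. The defaults place the wing pitch motors on the
transverse hinge line, the wing roll motors along the sagittal hinge line,
all motors against the dorsal shell interior (center depth −6 mm), a 100 mm
ventral leg rod, and the added-mass carriage at mid-rod (45 mm). These are
physical-reasoning choices made once and exposed as the `placement`
argument. With them, the wings-closed pitch and roll barriers land within
about 2% and 11% of the published robot values — adequate for the
property-level claims (ordering, monotonicity) the package makes about the
composite. Placing the mass carriage at the rod tip (which the published
Froude number hints at) would pull the center of mass further ventral and
the roll barrier ~18% below the published value; the tension is inherent in
reconstructing an unpublished CAD model and is documented rather than
hidden.

## Kinetic energy decomposition

Pitch and roll kinetic energy of each rigid segment are
$\tfrac12 I_{yy}\omega_y^2 + \tfrac12 m v_x^2$ and
$\tfrac12 I_{xx}\omega_x^2 + \tfrac12 m v_y^2$, with inertias and velocity
components about/along the body fore-aft and lateral principal axes; point
masses contribute only translational terms, and point-cloud parts contribute
as collections of point masses. Vertical translation and yaw are excluded
by definition — they do not drive pitching or rolling — so the segment sum
equals the closed-form rigid-body energy only for motions without vertical
part velocities (the tests use rolling about the fore-aft axis, where the
identity is exact). Body axes are estimated per frame from the head-tip,
midpoint and abdomen-tip markers by Gram-Schmidt orthogonalization (the
midpoint marker must sit slightly off the fore-aft axis to span the sagittal
plane; the published frame-estimation procedure is unstated). Velocities
use central differences on zero-phase-filtered tracks, one-sided at the
ends; angular velocity of the body triad is
$\tfrac12\sum_i e_i \times \dot e_i$, and rod angular velocity is
$\hat d \times \dot{\hat d}$ (axial spin is irrelevant for a thin rod).
The averaging window for "wings fully open" is wing angle within 1% of its
plateau, exposed as `open_frac`; the leg-tip speed entering the Froude
number is the RMS lateral body-frame speed — both conventions are
package choices where the source leaves them open.

## What the synthetic generator does and does not emulate

`gen_marker_tracks()` produces the seven-landmark track of a stationary
upside-down two-part body with both hind legs (two rigid rods each, optional
tip spheres) flailing sinusoidally in the coronal plane at 10 Hz — the
~100 ms flailing period — sampled at 2000 frames/s with additive Gaussian
marker noise (0.1 mm default), and returns the pitch/roll kinetic energy of
the generating motion evaluated analytically (exact angles and rates through
the same decomposition formulas), independent of the marker-estimation path.
`gen_orientation_trace()` produces smooth open-hold-close wing cycles at
2 Hz with pitch tracking the metastable state and, for successful outcomes,
a roll (or pitch) excursion to ±180° in the final attempt.
`simulate_attempts()` draws attempt-level roll kinetic energy from a
zero-truncated Gaussian with mean $\propto \theta_\mathrm{leg}^2$ and a free
coefficient of variation (0.3 default; the attempt-level energy variance is
not quantified anywhere, so this is a modelling choice, not an inference),
succeeding when the draw reaches the roll barrier at full wing opening.

Passing tests on these inputs show that the estimation pipeline recovers
known energetics from clean-ish data and that ensemble trends
(probability non-decreasing, attempts-to-success non-increasing in both
amplitudes) follow from the barrier structure. They do not show robustness
to real tracking pathologies — marker occlusion and mislabeling, abdomen
flexion, wing deformation under load, leg scraping — none of which the
generator emulates, and trial-to-trial carryover is deliberately absent
(attempts are independent draws).

## Numerical choices and degenerate inputs

* Minima are strict 8-neighbour minima on the toroidally wrapped grid
  (tolerance $10^{-12}$ mJ); a constant landscape returns a single plateau
  representative (region centroid) flagged `plateau = TRUE`, which
  downstream code treats as a valid flat origin (a sphere has zero barriers
  rather than an error).
* The Euler chart is redundant — $(\beta, \gamma)$ and
  $(180°-\beta, \gamma+180°)$ are the same orientation up to yaw — so the
  upside-down minimum reappears near the chart corners; minima with both
  coordinates beyond 135° are dropped as duplicates, pitch-edge minima are
  reported at +180°, and roll-edge minima at both ±180°.
* The metastable minimum is continued across wing angles by nearest
  neighbour in pitch-roll space (ties broken by first index); the sequence
  truncates with a warning only if no minimum exists at all.
* Barrier rays run from the origin to the chart boundary; the relevant
  maxima lie well inside. Bilinear interpolation is used along rays and for
  trajectory projection, with angles wrapped (and a warning) outside
  ±180°.
* Point clouds come from deterministic Halton sequences; solid-ellipsoid
  and cuboid clouds are antithetically symmetrized so their centroids are
  exact. Shell-slice point masses are weighted by the ellipsoid area
  element (uniform surface density).
* Zero-phase filtering demeans each coordinate before `filtfilt` (exact DC
  passthrough and better conditioning at a 25/1000 relative cutoff) and
  pads by reflection against edge transients.
* Attempt simulation uses inverse-CDF sampling of the truncated Gaussian,
  so ensembles are bit-reproducible under a seed.

## Known limitations

* Quasistatic only: no contact friction, impacts, lift-off or multi-body
  dynamics; trajectories are projected onto the landscape for
  interpretation, and only their end points carry instantaneous energy.
* The robot composite is a desk-scale reconstruction: its absolute barriers
  are within ~15% of the published hardware values, not exact, and the
  upright-to-upside-down basin energy ratio (~3 with the default ventral
  leg) exceeds the published ~1.5 because the hardware's upright leg
  geometry is unknown. The ratio is computed and asserted only to exceed 1.
* Above roughly 72° wing opening the composite's metastable minimum splits
  into a symmetric pair a few degrees off zero roll (the triangular support
  narrows as the wings approach vertical); tracking reports one of the pair.
  Pitch and barrier monotonicity are unaffected.
* Published Froude numbers for the animal and robot require unpublished
  tracked velocities; `froude()` is validated on synthetic kinematics
  (scale invariance under dynamic-similarity scaling), not against those
  values.
* Problem sizes: headline barriers use the 1° grid (a landscape in well
  under a second); property tests use 2–5° grids and short (0.1–0.5 s)
  synthetic tracks, which refinement checks show to be adequate for the
  asserted tolerances.
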