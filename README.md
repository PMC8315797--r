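# selfright

Potential energy landscapes and energetics of strenuous ground self-righting.

## The problem

An overturned insect (or a biomimetic robot) must return itself upright, and
for many body plans this is a strenuous, stochastic maneuver: the animal
pushes its wings against the ground, pitches up into a metastable posture
supported by the head and the two opened wing edges, usually falls back, and
after repeated attempts finally escapes by rolling sideways while flailing
its legs. `selfright` models this maneuver as a **barrier-crossing transition
on a potential energy landscape**: the gravitational potential energy

> E(β, γ; θ_wing) = m · g · z_CoM(β, γ; θ_wing)

of the self-deforming body over body pitch β and roll γ, with the lowest
body point constrained to touch the ground, at each wing-opening angle
θ_wing. Escape from the upside-down/metastable minimum is quantified by
directional barriers: along the straight path at polar angle ψ from the
positive-pitch axis, the barrier is the maximal rise of E along the path.
The **pitch barrier** is the barrier at ψ = 0 (toward a head-over
somersault); the **roll barrier** is the lowest barrier within
ψ ∈ ±[45°, 135°] (toward the roll-upright basins). Wing opening lowers the
roll barrier to the scale of the small, perturbing kinetic energy supplied by
leg flailing — which is why propelling (wings) and perturbing (legs)
appendages together make self-righting probable.

The package is aimed at biomechanists and robot designers who want to
compute such landscapes and barriers for parametric bodies, measure
segment-wise pitch/roll kinetic energy from 3D marker tracks, check
geometric/dynamic similarity between an animal and a scaled physical model,
and simulate attempt ensembles.

## What is in the package

* **Body models** — solid ellipsoids, zero-thickness ellipsoidal shell
  slices, cuboids, rods and point masses, assembled into articulated bodies
  with symmetric wing-opening and pendulum-leg joint rules
  (`build_animal_model()`, `build_robot_model()`, `part_shape()`).
  Ground-contact support heights of ellipsoid surfaces are computed
  analytically (constrained minimization on the sphere preimage), so a
  1° × 1° landscape takes well under a second.
* **Landscapes and barriers** — `compute_landscape()`, `find_minima()`,
  `track_metastable()`, `barrier_profile()`, `pitch_roll_barriers()`,
  `barriers_vs_wing_opening()`, `project_trajectory()`, uneven ground via
  `ground_heightfield()`.
* **Energetics** — `filter_track()` (zero-phase Butterworth),
  `animal_segment_states()`, `ke_pitch_roll()`, `average_ke()`,
  `ke_minus_barrier()`.
* **Similarity and coordination** — `scale_factors()`, `froude()`,
  `xcorr_normalized()`.
* **Synthetic data and simulation** — `gen_marker_tracks()` (with analytic
  ground-truth energetics), `gen_orientation_trace()`, `simulate_attempts()`.
* **Pipeline** — `run_command()` runs a named stage from a config list or
  YAML body file and writes CSV artifacts plus a JSON run manifest.

Results are tibbles (or carry `tidy()`/`glance()` methods) and have
`autoplot()` methods, so they compose with dplyr and ggplot2.

## Worked example

```r
library(selfright)

# rigid-ellipsoid animal model: 53 x 23 x 8 mm, mean intact mass 2.6 g
body <- build_animal_model(animal_spec(mass = 2.6))
grid <- compute_landscape(body, theta_wing = 0, pitch_step = 1)
find_minima(grid)
#>   pitch  roll energy basin                  plateau
#> 1     0  -180  0.102 roll-upright-left      FALSE
#> 2   180     0  0.102 pitch-upright          FALSE
#> 3     0     0  0.102 upside-down/metastable FALSE
#> 4     0   180  0.102 roll-upright-right     FALSE

round(pitch_roll_barriers(barrier_profile(grid)), 3)
#> pitch  roll
#> 0.574 0.191
```

The four minima are the upside-down state (E = m·g·c = 0.102 mJ) and the
three upright states reachable by pitching over the head or rolling to
either side. With wings closed the pitch barrier is m·g·(a−c) ≈ 0.574 mJ
and the roll barrier m·g·(b−c) ≈ 0.191 mJ — the published values are 0.58
and 0.19 mJ.

For the 260 g robot-like composite, barriers fall monotonically as the
wings open, with rolling always cheaper than pitching:

```r
robot <- build_robot_model()
curves <- barriers_vs_wing_opening(robot, seq(0, 90, by = 15),
                                   pitch_step = 2, psi_step = 3)
curves
#> theta_wing_deg pitch_barrier_mJ roll_barrier_mJ
#>              0            277.9           218.2
#>             15            246.1           181.4
#>             30            201.9           120.2
#>             45            157.6            54.6
#>             60            116.9            39.5
#>             75             79.9            27.0
#>             90             45.1            15.2

simulate_attempts(curves, theta_wing = 72, theta_leg = 30, n = 1000, seed = 1)
#> <attempt_ensemble> theta_wing = 72 deg, theta_leg = 30 deg
#>   roll barrier: 29.49 mJ; attempts: 35608
#>   self-righting probability: 0.0142 ; mean attempts-to-success: 35.6
```

At this wing opening the roll barrier (29.5 mJ) still slightly exceeds the
mean roll kinetic energy from 30° leg flailing, so attempts succeed only on
favourable energy draws; at θ_leg = 45° the mean energy clears the barrier
and self-righting becomes near-certain.

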