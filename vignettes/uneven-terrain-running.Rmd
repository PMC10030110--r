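---
title: "Models and methods: footstep regulation and collision impulses on uneven terrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: footstep regulation and collision impulses on uneven terrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runeven)
```

## The scientific question

Runners on undulating, trail-like terrain face two candidate stabilization
strategies: *aim the feet* at more level patches of ground, or *soften the
landing* so that whatever patch is hit transfers little destabilizing
fore-aft impulse. `runeven` implements the computational machinery needed
to weigh these strategies against each other: terrain roughness statistics,
stochastic foot-placement models, gait-event detection and per-step
kinematics, ground-reaction-force impulse analysis, a planar four-link
collision model of heel strike, and net metabolic rate — all exercised on
synthetic data with known ground truth, because the raw laboratory trials
behind the original study are not publicly deposited.

## Terrain representation and roughness

Terrain is a node-registered height grid (`terrain_field`), rows along the
track (`y`), columns across (`x`), metres throughout. Two statistics drive
everything downstream:

* **Patch unevenness** `h_IQR`: the interquartile range of heights inside a
  rear-foot-sized patch, 95 mm x 95 mm by default (half a 190 mm foot).
  Quantiles use linear interpolation between order statistics (R's type 7)
  everywhere in the package; the source study does not state its quantile
  rule, so one convention is declared and used consistently.
* **Amplitude and wavelength**: along each longitudinal transect the
  heights are smoothed with a 20 mm moving average, alternating local
  maxima/minima are located (same-type neighbours collapse to the more
  extreme one), amplitudes are |peak - valley| of consecutive extrema and
  wavelengths are peak-to-peak separations. Whether the original analysis
  used 1D transects or 2D neighbourhoods is unstated; the transect
  convention is adopted because the printed wavelengths are explicitly
  "along the length of the track".

Patches overhanging the track edge are clipped rather than rejected, and
flagged. A boundary point belongs to exactly one cell (half-open
`[start, end)` cells).

## Synthetic terrain generator

`generate_terrain()` filters a white-noise field through an annular
Gaussian band in radial spatial frequency, then calibrates itself against
`measure_amplitude_wavelength()` — the same instrument used on the output —
iterating the band centre until the measured wavelength is within 10 mm of
target and rescaling heights so the measured amplitude matches within 2 mm.
Gaussian tails are soft-clipped (`a * tanh(h/a)` with `a` = 0.75 of the
target amplitude) because a physically built surface has a bounded height
distribution; without this, rare tall peaks defeat the 15 mm stance-height
criterion far more often than on the real track. The generator is a pure
function of its spec and seed.

Class defaults are the study conditions: uneven I with amplitude
18 +/- 6 mm and wavelength 102 +/- 45 mm, uneven II with 28 +/- 11 mm and
108 +/- 52 mm, on a 21.6 m x 0.6 m straight section at 5 mm resolution.
The relative bandwidth of the annulus is set from the target wavelength
spread; the achieved wavelength SD is somewhat narrower than the printed
one (the means, which the acceptance checks compare, calibrate exactly).

## Synthetic running trials

`generate_trial()` renders a back-and-forth shuttle run as the signals a
laboratory would record: two instrumented feet (heel, toe, ankle markers at
300 Hz), four hip markers whose mean is the CoM, and a 600 Hz force trace.
Design choices that matter:

* Footsteps advance by the configured step length (mean 128 %LL, SD 6 %LL)
  with alternating lateral offsets of half the step width; at the track
  ends the direction reverses and the runner plants for a 0.5 s turnaround.
* During stance the heel is planted on the terrain; each foot swings to its
  next stance (one stride later) along a C2-smooth quintic with a 120 ms
  constant-velocity terminal approach. The approach is longer than the
  100 ms landing-fit window, so cubic-fit landing velocities are exact on
  noise-free data and robust to one-frame timing error.
* The CoM advances linearly between touchdown anchors placed one virtual
  leg lead behind each footstep, with a sinusoidal vertical bounce whose
  downward velocity at touchdown equals the configured 0.7 m/s. That value
  is nominal (the study does not print it) and is a configuration knob.
* The vertical GRF is an impact bump plus an active peak, rising from zero
  exactly at touchdown and vanishing at liftoff, scaled so the stance
  impulse supports body weight over one step period. The fore-aft GRF is a
  braking lobe whose trapezoid-exact impulse is `braking_fraction` (6 % by
  default) of the step's aerial forward momentum, followed by an equal
  propulsive lobe. Marker and force noise SDs are configurable; defaults
  are noise-free markers and a 0.5 N force baseline, and the original
  marker/baseline noise levels are unstated, so recovery tests quote the
  noise they assume.

What the generator does **not** emulate: soft-tissue and shoe compliance,
double support transients, force cross-talk, swing-leg dynamics beyond the
smooth transport curve, speed fluctuations within a traversal, and
marker occlusion. Passing recovery tests therefore demonstrate the
*pipeline's* correctness, not robustness to every artefact of real data.

## Gait events and per-step measures

Stance detection implements the heel criterion: heel forward speed at a
minimum while the heel is within 15 mm of its standing height. Numerics the
criterion leaves open are declared here: the speed is low-pass filtered at
10 Hz (zero phase) and gated at 0.5 m/s; the height test is one-sided
(at most 15 mm *above* standing — a heel in a valley is still on the
ground), which is what lets stances on local peaks up to the threshold be
found; interval edges are refined on unfiltered one-sided differences and
the touchdown is interpolated sub-frame by extrapolating the terminal
approach velocity. Stances shorter than 50 ms are discarded and touchdowns
of one foot must be 0.3 s apart. On the roughest terrain, steps landing on
peaks above 15 mm go undetected — a faithful property of the criterion, not
a pipeline defect.

Step length and duration come from CoM travel between consecutive
touchdowns (both feet merged); step width is twice the nearest approach of
the stance heel to the total-least-squares line of the stance-phase CoM
path; leg angle and virtual leg length come from the heel-to-CoM vector at
touchdown; landing velocities are cubic fits over the 100 ms before
touchdown; the retraction rate is the component of heel velocity relative
to the CoM perpendicular to the virtual leg, divided by its length. All
fore-aft quantities are expressed in the direction-of-travel frame so that
back-and-forth traversals pool. Steps adjacent to a turnaround are flagged
and excluded from summaries and meanders.

## Kinetics

Forces are filtered with a 4th-order Butterworth applied forward and
backward: the effective magnitude response is 8th order with gain 0.5 at
the 270 Hz cutoff. The alternative reading (8th-order design run twice,
16th-order net) was rejected as inconsistent with common force-plate
practice. Touchdown on the plate is the vertical force crossing the
unloaded-baseline mean plus four baseline SDs, sustained for 5 ms.

The fore-aft collision impulse integrates the fore-aft force cumulatively
from touchdown (trapezoidal quadrature at native sampling) and takes the
largest magnitude of the *braking* excursion; for the canonical
braking-then-propulsion stance this coincides with the largest magnitude of
the running integral, and it is identically zero when no deceleration phase
exists. It is normalized by the aerial-phase forward momentum `m * v_y`;
when no flight phase is available the touchdown CoM speed is used and the
record flagged.

## Foot-placement models

The **blind** scheme samples rear-foot patches uniformly over the analysed
region. The **directed** scheme is a Markov chain whose every step is an
open-loop target (mean step length forward, mean step width to the
alternating side), a minimization that scans a rear-foot window over the
search rectangle (half-extents one SD of step length/width, sub-steps a
tenth of each SD, endpoints included: 21 x 21 candidates) for the lowest
patch `h_IQR`, and additive noise drawn from a zero-centred von Mises
distribution with concentration 1, mapped linearly so the support width
equals the respective SD (hence bounded by half an SD either side). At the
track ends the lateral position resets to the track centre and the
direction flag toggles before the minimization. Ties in the minimization go
to the candidate nearest the open-loop target, then to the smallest (y, x)
— the centre-first rule is what makes a featureless field reproduce the
open-loop gait exactly. Patch queries snap to the nearest 5 mm grid node of
a precomputed sliding-window table, which makes 100,000-step walks cheap;
the sub-steps (2.5-5.3 mm for the default gait) are at the grid scale, so
snapping costs at most half a node.

Model step length is |dy| between consecutive steps and model step width is
the lateral displacement signed by the alternation; the signed form is used
because the lateral search extent is comparable to the width itself and
|dx| would carry a folding bias of about one percent. Steps across a reset
are excluded from both.

The **foot placement index** divides the track into cells one foot length
long and half a foot length wide, counts heel landings per cell, and
normalizes by the average footstep count of all step-length-long, full-width
windows containing the cell's row. Perfectly periodic stepping yields 1 on
stepped cells and 0 elsewhere; uniform stepping yields approximately the
reciprocal of the number of cells in a step-length-sized box. Rows not
covered by any fully contained window are flagged undefined, as are cells
whose normalizer is zero.

## The four-link collision model

Heel strike is an instantaneous, inelastic, point-contact collision of a
planar chain — foot, shank, thigh, torso — moving with CoM velocity
`v_G = (v_y, v_z)` and a single shared angular velocity `Omega` (the leg
retraction rate, derived from the forward heel speed via
`v_heel,y = v_y + Omega * G_z`). The contact point O sits a fraction
`s = 0.15` of the foot length ahead of the heel (heel-strike foot-strike
index) and is brought exactly to rest.

* **Rigid joints**: one unknown post-collision angular velocity from
  angular momentum balance about O; the impulse is
  `J = Mb (vG+ - vG-)`, its fore-aft magnitude `|Jy*|` normalized by
  `Jb = Mb * v_y`.
* **Compliant joints**: each segment keeps its own post-collision angular
  velocity; the four balances (whole body about O, shank+thigh+torso about
  the ankle, thigh+torso about the knee, torso about the hip), with segment
  velocities chained from the arrested contact point, form a 4 x 4 linear
  system solved by QR with an explicit rank check.

Anthropometry is an editable table; the default treats every link as a
uniform slender rod (CoM at midlength, radius of gyration `1/sqrt(12)` of
its length) with standard mass fractions — foot 0.0145, shank 0.0465,
thigh 0.100, torso the remainder (which lumps head, arms, trunk, and the
swing leg). Segment lengths put the hip one leg length up the chain
(ankle at 0.074, shank 0.464, thigh 0.462) and the torso link is half a
leg length. The source study delegates these values to a scaling reference
without printing them, so the minimal rod convention was chosen a priori
and shipped as configuration.

The touchdown posture solves a two-parameter Newton iteration (chain
inclination and a uniform leg-extension factor) so that the *composed* CoM
sits exactly on the measured virtual leg: 1.20 leg lengths from the heel at
the touchdown angle. This matches how touchdown geometry is defined from
motion capture; using the chain angle directly (available via
`solve_posture = FALSE`) would misplace the CoM by a few centimetres. The
torso stays vertical and the foot sole is inclined 20 degrees, both
configuration knobs, as the original joint configuration is unstated.

For impulse-speed relationships the ambiguity of whether the published
"mean model" lines fix the geometry at subject means or rebuild it per
step is resolved by providing both modes; the fixed-mean-geometry mode is
treated as the headline reading, and the per-step mode (leg angle
covarying with foot speed at 0.07 rad per Froude unit) roughly doubles
both slopes. Under the default anthropometry the fixed-geometry compliant
slope computes to about 0.034, above the published 0.0203 +/- 0.010, and
probing plausible anthropometric tables moves it only within about
0.032-0.038; the discrepancy is reported as computed rather than absorbed
into parameter choices.

## Energetics

Metabolic power is `P = 16.58 * VO2 + 4.51 * VCO2` (kJ with litres), the
standard Brockway-type equivalence; the study cites its formula by
reference without printing constants, so these defaults are overridable.
The net rate discards the first 3 min of running and the first minute of
standing, subtracts rest from running, and normalizes by body mass. Visual
steady-state inspection is replaced by a terminal-slope test on the final
2 min: the trace is flagged non-plateau only if the trend exceeds 1 % of
the segment mean per minute *and* is statistically distinguishable from
breath noise (p < 0.01).

## Reproducibility and problem sizes

Every generator is a pure function of its configuration and seed;
`spawn_seeds()` derives per-stage seeds from one global seed so pipeline
stages can be re-run in isolation. The packaged checks use full-size
21.6 m x 0.6 m fields for terrain calibration and scheme convergence
(100,000-step walks, patch tables precomputed once), 1,000-state landing
ensembles for the collision slopes, and 25-60 s synthetic trials for
parameter recovery; these sizes reproduce the study-scale statistics while
keeping a complete run in a few minutes on one core.

## Known limitations

* The 15 mm stance criterion misses steps on higher peaks of the roughest
  terrain; real analyses face the same censoring.
* The directed walk's lateral position performs a bounded random walk, and
  near-edge clamping plus turnaround resets leave sub-percent biases in its
  realized step statistics.
* The collision model is sagittal-plane only, with perfectly inelastic
  point contact and joint stiffness only at the two extremes; intermediate
  stiffness, 3D effects, and elastic restitution are out of scope.
* The synthetic trial's turnarounds are stylized (a single planted dwell),
  so turn-adjacent steps are flagged rather than modelled.
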