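# runeven

Biomechanics of running on undulating uneven terrain: do runners aim their
feet at level ground, or does the body's mechanical response at landing do
the stabilizing work?

`runeven` is an analysis pipeline for that question. It provides, as a
tested R package plus numbered analysis drivers:

* **Terrain**: gridded height fields with patch-level unevenness
  (interquartile range of heights in rear-foot-sized patches, `h_IQR`) and
  track-level roughness (peak-to-valley amplitude, peak-to-peak
  wavelength along the track).
* **Synthetic data with ground truth**: calibrated random terrain for the
  two study classes (amplitude/wavelength 18/102 mm and 28/108 mm),
  back-and-forth running trials rendered as 300 Hz marker and 600 Hz
  force-plate signals, and breath-by-breath respirometry.
* **Kinematics**: heel-criterion stance detection (forward-speed minimum
  within 15 mm of standing height), per-step length, width, speeds, leg
  angle, virtual leg length, landing velocities, retraction rate, meander,
  with %LL and Froude normalizations.
* **Kinetics**: zero-phase Butterworth filtering (8th-order effective,
  270 Hz), threshold touchdown detection, and the normalized fore-aft
  collision impulse
  `J*_y = max_t |∫ F_y dτ|` over the braking phase, divided by the aerial
  forward momentum `m v_y`.
* **Foot-placement models**: a blind (uniform) sampler and a directed
  Markov-chain walker that takes an open-loop step
  `x̂ᵢ₊₁ = xᵢ + (−1)ⁱ s_w`, `ŷᵢ₊₁ = yᵢ + (−1)ʲ s_l`, minimizes patch
  `h_IQR` over a ±σ search window, and adds bounded von Mises noise; plus
  the foot-placement index `p_ij = f_ij / S` over 0.5 × 1.0 foot-length
  cells.
* **Collision model**: a planar four-link chain (foot, shank, thigh,
  torso) undergoing an instantaneous inelastic heel-ground collision with
  joints either perfectly rigid (one shared post-collision rotation) or
  infinitely compliant (independent segment rotations coupled by joint
  reaction impulses), predicting `|J*_y|/(M_b v_y)` from landing
  kinematics.
* **Energetics**: net metabolic rate from V̇O₂/V̇CO₂ via Brockway-type
  energy equivalence, with a plateau diagnostic.

## Worked example

Predict the fore-aft collisional impulse at the mean measured landing
state — body mass 66.1 kg, leg length 0.89 m, touchdown leg angle
0.20 rad, virtual leg 120 %LL, CoM velocity (3.2, −0.7) m/s, forward foot
speed 0.37 Froude, heel-strike foot-strike index 0.15:

```r
library(runeven)
chain <- build_chain(mass = 66.1, leg_length = 0.89, theta = 0.20,
                     s = 0.15, virtual_leg_frac = 1.20)
state <- collision_state(chain, v_com = c(3.2, -0.7),
                         fwd_foot_speed = 0.37 * sqrt(9.81 * 0.89))
compliant_collision(chain, state)
#> <collision_result:compliant> |Jy*| = 11.53 N s, Jb = 211.5 N s, |Jy*|/Jb = 0.0545
rigid_collision(chain, state)
#> <collision_result:rigid> |Jy*| = 23.90 N s, Jb = 211.5 N s, |Jy*|/Jb = 0.1130
```

The compliant chain loses 5.4 % of the forward momentum and the rigid one
11.3 %, bracketing the ~6 % a real runner loses: soft joints at landing,
not precise foot targeting, keep the fore-aft impulse low.

The same end-to-end story on synthetic data:

```r
field <- generate_terrain(terrain_spec("uneven2", seed = 8))
measure_amplitude_wavelength(field)
#> <terrain_stats> amplitude 28.0 +/- 15.6 mm, wavelength 99 +/- 32 mm

report <- run_pipeline(pipeline_config(terrain = terrain_spec("uneven2"),
                                       duration = 30, seed = 9))
```

`report` carries the per-step kinematics, impulse records, the
blind/directed/observed scheme comparison, the foot-placement index table,
per-step collision predictions, and the net metabolic rate (13.1 W/kg for
the flat-condition calibration).

The numbered drivers under `analysis/` (`01_terrain_statistics.R` …
`05_energetics.R`) run each stage as a small narrative and write their
tables under `results/`.

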