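---
title: "VP-corrected dead-reckoning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{VP-corrected dead-reckoning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vptrack)
```

This vignette is the package's account of the science it implements: the
sensor models and their assumptions, the travel-vector construction, the
drift-correction procedure, what the simulator does and does not emulate,
and the numerical choices made where the method leaves room.

## 1. From raw sensors to travel vectors

### Frames and conventions

Body axes are surge (x, anterior, positive forward), sway (y, medio-lateral,
positive right) and heave (z, dorso-ventral, positive dorsal), so an
upright, motionless animal reads acceleration ≈ (0, 0, 1) g. Logger axis
order varies by manufacturer and mounting; the ingest column map
(`read_imu_csv(column_map =)`) and the calibration's `tag_rotation` (a
rotation matrix applied to both acceleration and magnetism,
`apply_tag_rotation()`) move any tag into this convention. Headings are
degrees clockwise from **true** North in [0, 360); magnetic declination
(positive East) is added to the magnetic heading. Heading-correction angles
are signed, wrapped to (−180, 180], positive = clockwise.

### Static/dynamic separation

Gravity is estimated per axis by a centred running mean
(`separate_acceleration()`); the residual is the movement-generated dynamic
acceleration, and the two reconstruct the raw signal exactly. A running mean
was chosen over a high-pass filter because it is the dominant practice in
biologging, has no phase distortion, and its window has a direct physical
reading (the stride-cycle scale). The default window is 2 s, matching the
conventional VeDBA smoothing window; no canonical value exists for the
static window itself, so it is exposed as configuration. Windows shrink at
the series edges (no padding), preserving series length; the first and last
half-window of any smoothed quantity is therefore slightly biased and
deserves suspicion in short records.

The separation degrades under sustained centripetal acceleration or
free-fall, when the smoothed vector no longer approximates gravity. Samples
whose static norm falls below 0.1 g are flagged unreliable and carry the
last reliable posture forward rather than interpolate — the failure is
usually transient, and interpolation would invent postures during exactly
the manoeuvres where nothing is known.

### Posture and heading

Pitch is `asin(static_surge / ||static||)` and roll
`atan2(static_sway, static_heave)`; both are Euler angles and inherit the
Euler singularity. Samples with |pitch| ≥ 89.5° are flagged and carried
forward (`tilt_compensated_heading()` applies the same guard): the
gimbal-lock region is narrow, and no fix short of quaternion attitude
filtering (out of scope, as is gyroscope fusion) is satisfactory there.

The tilt-compensated compass de-rotates the calibrated magnetic vector by
roll then pitch into the horizontal plane and takes
`atan2` of the horizontal components. Where the horizontal field is
vanishingly small (inclination near ±90°, i.e. magnetic poles) heading is
undefined; such samples are flagged and carried forward. Heading and
posture are post-smoothed by 1 s by default (the conventional range is
1–2 s); the heading smoother is a rolling *circular* mean — running means of
sine and cosine recombined — so that averaging 350° and 10° yields 0°,
never 180°.

### Magnetometer calibration

`calibrate_magnetometer()` fits the hard-iron offset by a linear
least-squares sphere fit; the full soft-iron (ellipsoid) fit is behind
`fit_soft_iron = TRUE`. Hard-iron-only is the default because additive
offsets dominate in practice and the ellipsoid fit needs genuinely 3-D
orientation coverage that a deployment on a level-walking animal does not
provide (the function refuses degenerate coverage, naming the deficient
axis — a bench roll of the tag before deployment is the usual source of
coverage). Magnetometer units never matter: heading uses only component
ratios, and the calibration rescales to the mean field strength.

### Pressure

Baseline sensor drift is removed by a Whittaker smoother with asymmetric
weights (`pressure_baseline()`): penalised least squares with a second-
difference penalty (`smoothness`, default 1e6 for 1-Hz records drifting over
hours) and weight `asymmetry` (default 0.01) on points above the baseline,
iterated to a sup-norm change below 1e-8 or 20 iterations. With asymmetry
below 0.5 the baseline hugs the lower envelope — the surface pressure under
dive excursions. Depth is then 0.01 m per hPa of baseline-subtracted
pressure (configurable; clamped at ≥ 0); altitude uses the barometric
formula `44330 · (1 − (P/P₀)^0.1903)` against a reference sea-level pressure
series interpolated in time.

## 2. Speed models

Four routes produce the speed half of the travel vector, mirroring field
practice by medium:

* **VeDBA-linear** (`vedba_speed()`): speed = m·VeDBA + c, floored at 0
  (negative extrapolations are possible when c < 0; the floor is our choice,
  as a negative speed has no meaning in a travel vector). Coefficients come
  from `fit_vedba_speed()`: ordinary least squares against VP-derived speed,
  or scale-matching — c = 0 and m the closed-form ratio of summed VP speed
  to summed VeDBA, which makes the uncorrected path length equal the VP path
  length exactly (the closed form replaces the iterative rescaling
  traditionally used, to which it is equivalent at convergence).
* **Behaviour constants** (`behaviour_speed()`): a per-state lookup table;
  unknown labels are an error rather than a silent zero.
* **Vertical rate** (`vertical_rate_speed()`): |dz/dt| / |tan(pitch)|,
  applied when depth > 0.3 m and |pitch| ≥ 10°, capped at 3 m/s. dz/dt is a
  centred first difference over one sample step, smoothed with the same
  window as pitch (the differencing scheme is our choice; a centred
  difference keeps the estimate phase-aligned with pitch). The depth used in
  the threshold test is baseline-corrected depth.
* **VP-derived** (`vp_derived_speed()`): haversine distance between fixes
  over the interval, interpolated from interval midpoints onto the sample
  grid. This speed inherently contains any current drift; no attempt is made
  to remove it.

When several models are configured the pipeline applies: movement gate →
behaviour override → vertical-rate where its conditions hold → base model.
The movement gate (`movement_gate()`) either thresholds VeDBA (default
0.1 g) or, when behaviour labels are supplied, keeps a configured travelling
set; gated samples get speed 0 and source `gated-zero`, and therefore
contribute exactly zero displacement downstream.

## 3. Integration and current flow

`integrate_track()` integrates per-step powered displacements
speed·dt·(sin h, cos h) on a spherical Earth (R = 6,371,000 m) via the
destination-point formula; the sphere matches the haversine metrics, and the
oblate spheroid enters only in 3-D distances, where the convention is
geodetic → ECEF Cartesian chords. Headings are taken as directions of travel
(the longitudinal-axis assumption); no sideslip model.

A current field (regular lon/lat/time grid; nearest-neighbour in space,
linear in time; out-of-grid queries return zero flow and are counted) is
added as an instantaneous vector sum per sample, evaluated at the pre-step
position and time, before the geodesic step. Current enters at integration
time only; the correction stage afterwards sees whatever track resulted.
Depth/altitude accumulates the per-step dz (depth clamped at the surface).

## 4. Drift correction

Between consecutive matched VPs (nearest sample within half a step;
unmatched fixes are counted and skipped), the distance correction factor is
the ratio of the VP beeline to the dead-reckoned beeline and the heading
correction factor the bearing difference between them. "Distance between
temporally aligned dead-reckoned positions" is read as the **beeline**, not
the cumulative step distance: with one rotation and one scaling per segment,
only the beeline reading makes the corrected endpoint land on the VP (the
planar vector-sum argument); cumulative distance is carried in the report as
a diagnostic (`dr_path_m`).

The correction itself is computed in the local tangent plane at the
segment's starting VP (equirectangular scaling by cos lat) and mapped back:
rotating every step by the HCF and scaling by the DCF is then exactly a
similarity transform, so the anchor alignment is exact to numerical
precision at biologging scales (observed residuals ~1e-13 m; the logged
residual tracks the planar-approximation error and the stated tolerance is
max(0.01 m, 1e-4 × beeline)). The similarity transform also gives two
properties for free: turn-angle structure inside a segment is preserved, and
coincident positions stay coincident — stationary clusters are never
expanded, the "multiplying by zero" property.

Remaining choices, made where the procedure's lineage is silent: the
rotation is constant per segment (not distributed gradually); the spans
before the first and after the last matched VP are rigidly translated to
abut their anchor; segments whose dead-reckoned beeline is zero are
degenerate — the span is translated to the starting VP and its final sample
snapped to the ending VP with the mismatch logged, rather than spreading a
phantom path over stationary samples, since such mismatches are typically
VP error. Extreme factors (DCF > 10 or < 0.1) are flagged, never
auto-rejected: they are diagnostics of speed misallocation or VP error.
Optional VP screening (`screen_vps()`) drops fixes whose implied speed from
the previously kept fix exceeds a physical ceiling — a reproducible
programmatic stand-in for the visual outlier screening practitioners
describe.

## 5. Accuracy metrics

Net error is the haversine distance between every (screened) VP and the
time-matched corrected position; it is zero at anchors by construction, so
correcting at the fix rate zeroes the whole series — a structural property,
not an accuracy claim, and the reason net error at high correction rates
must be read cautiously when the VPs themselves are noisy. The thinning
sweep re-runs thin → correct → evaluate per interval and reports mean and
median net error, dead-reckoned distance (3-D for media with a vertical
dimension), 2-D VP-path distance on the thinned fixes (3-D VP distance is
deliberately not computed: thinning and fix dropouts make it meaningless),
the mean achieved time between corrections (fix failure makes the requested
interval a lower bound), and the standardised rate mean-error /
mean-time-between-corrections.

## 6. The simulator: what it emulates, and what it does not

`simulate_truth()` is a semi-Markov state-switching correlated random walk:
exponential dwell times; per state a mean speed with CV (positive AR(1)
deviations, 30-s autocorrelation, innovated at 1-s nodes and interpolated so
speed is smooth below the stride scale, with a ~2-s ramp of the state mean
at transitions — animals have finite acceleration), a heading random walk
(degrees per √s), and a vertical profile (dive states shuttle between the
surface and their maximum depth; surface states relax to z = 0). The three
presets mirror the media and rates typical of deployments on a terrestrial
carnivore (1-Hz sensors and GPS, travel ~0.9 m/s), a pursuit-diving seabird
(2-Hz sensors, 0.416 m/s surface / 2.1 m/s dive speeds, fixes lost below
0.3 m) and a pelagic flier (10-Hz sensors, ~12 m/s, 1 fix/min).

`simulate_imu()` inverts the processing model: gravity rotated by the true
pitch (roll held at 0 — collar roll is acknowledged but unmodelled, keeping
orientation recovery identifiable), the Earth field at configured
inclination/declination rotated to yaw = heading + `heading_bias` (the
mechanism for injecting a systematic mounting offset), a hard-iron offset
added, and pressure from depth/altitude with optional linear drift. Dynamic
acceleration targets the smoothed VeDBA level implied by the configured
VeDBA–speed coupling (optionally scaled by `speed_scale_error` and
perturbed by `noise_sd`), synthesised as a heave-axis sinusoid completing an
exact integer number of cycles per 2-s smoothing window, so that running
means cancel it exactly and smoothed VeDBA is unbiased for slowly varying
targets. This is deliberately not a realistic stride waveform; closed-loop
tests validate the processing chain, not accelerometry realism.
`simulate_vps()` adds isotropic Gaussian error in the tangent plane (white;
no autocorrelated multipath) and deletes fixes during submersion. All
randomness derives from one seed via fixed per-stream offsets
(`truth`/`imu`/`vps` streams), so outputs are bitwise reproducible and the
streams can be regenerated independently.

What passing closed-loop tests show: the algebra and geometry of the chain
are self-consistent, systematic errors are identifiable, and accuracy scales
with the correction rate as expected. What they do not show: performance
under real stride waveforms, collar roll, centripetal contamination,
magnetic anomalies, or autocorrelated GPS error — all listed limitations of
the approach itself.

## 7. Numerical choices and problem sizes

Tolerances: anchor residual max(0.01 m, 1e-4 × beeline); AsLS convergence
1e-8 sup-norm over ≤ 20 iterations; degenerate-segment threshold 1e-9 m of
dead-reckoned beeline; gimbal guard 0.5°; unreliable-posture threshold
0.1 g; rotation matrices validated to 1e-8. Ties in time matching resolve to
the earlier sample; thinning is greedy (first fix, then earliest ≥ interval,
final fix always kept). The test suite and the acceptance script run
simulated deployments of 10–60 minutes at 1–10 Hz and one 3-h thinning
sweep at 1 Hz — sizes chosen so the whole closed loop, including the
correction ladder, is exercised in seconds to a few minutes on one CPU while
leaving drift enough time to accumulate well above numerical noise.

## 8. Known limitations

Euler-angle attitude (no quaternion filter, no gyroscopes); spherical
geodesy for integration (ellipsoidal geodesics would change step positions
by ~0.2% at most mid-latitudes, far below VP error, and would break the
haversine convention of the accuracy metrics — the 2-D/3-D distance
comparison inherits exactly this sphere-vs-spheroid datum difference);
linear per-segment drift distribution (no spline or Kalman fusion);
behaviour classification is an input, not a capability; GPS latency is not
modelled beyond the at-depth fix dropout.
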