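---
title: "Simulating and reconstructing tendon-driven wrist motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and reconstructing tendon-driven wrist motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristsim)
```

# Overview

`wristsim` is a digital counterpart of a cadaveric wrist motion simulator
and its biplanar X-ray capture pipeline. Cadaveric rigs of this kind drive
the five major wrist tendons (ECRL, ECRB, ECU, FCR, FCU) with linear
actuators under displacement control, record tendon forces at 50 Hz, and
measure bone motion by tracking implanted tantalum beads in two orthogonal
X-ray views. Because no raw recordings from such rigs are publicly
deposited, the package replaces the specimen with a synthetic, fully
controlled stand-in — a two-rod universal-joint "model wrist" — and
implements every downstream step of the analysis so that the whole chain
can be exercised, tested and calibrated against known ground truth:

1. **`synthetic wrist`** — the model wrist, its tendon geometry, motion
   path generation, actuator excursion profiles, bead trajectories and
   biplanar projections with controllable noise
   (`build_default_wrist()`, `generate_motion_path()`,
   `record_excursion_profile()`, `make_trial_bundle()`);
2. **`control`** — the rig's three control features: force equalization
   before each motion, closed-loop displacement tracking, and
   physiological force caps (`equalize_forces()`, `track_profile()`,
   `enforce_force_cap()`);
3. **`reconstruction`** — DLT camera calibration from a 64-bead cube,
   biplanar triangulation, per-bone orthogonal Procrustes fits, and
   zero-phase Butterworth pose smoothing (`calibrate_dlt()`,
   `triangulate()`, `fit_rigid_transform()`, `reconstruct_trial()`);
4. **`kinematics`** — anatomical radius (RCS) and third-metacarpal (MCS)
   coordinate systems, Cardan angle decomposition, static-trial neutral
   correction (`build_rcs()`, `build_mcs()`, `decompose_angles()`,
   `neutral_correct()`);
5. **`metrics`** — trial averaging and truncation, in-/out-of-plane range
   of motion, the dart thrower's motion (DTM) plane fit, the circumduction
   ellipse with its 100-vector RMSE, and inter-trial / inter-specimen
   repeatability (`average_trials()`, `extract_rom()`, `fit_dtm_plane()`,
   `fit_circumduction_ellipse()`, `inter_trial_rmse()`).

# The model wrist

The wrist is two rigid rods joined by a universal joint at the origin of a
right-handed lab frame: x along the forearm pointing distal, y the
radial(−)/ulnar(+) direction, z the volar(−)/dorsal(+) direction. The
radius and ulna (each carrying three beads) belong to the fixed proximal
rod; MCII and MCIII to the moving distal rod. Wrist orientation is an
intrinsic y–z–x Cardan sequence: flexion(+)/extension(−) about y,
ulnar(+)/radial(−) deviation about z, pronation(+)/supination(−) about x.

Each tendon runs in a straight line from a fixed exit point on a proximal
ring to an insertion on a ring at the base of the distal segment, both at
the same azimuth around the shaft. Key geometric choices (all overridable
through the `wrist` section of the run config, since the physical rig's
dimensions are not published):

* **Pentagon azimuths** (ECRL −72°, ECRB 0°, ECU +72°, FCR −144°,
  FCU +144°, measured from dorsal toward ulnar). The five line-of-action
  directions sum to zero, so an equal preload on all tendons is in
  equilibrium exactly at the neutral pose — the rig's "equalize, then zero
  the encoders" step has a well-defined fixed point. Flexors (z < 0) and
  extensors (z > 0) fall out on the correct sides automatically.
* **Matched ring radii (15 mm) and insertions at the joint plane.** With
  tendon lines parallel to the shaft at neutral, the excursion of a tendon
  is `r·θ` to second order — the small-angle moment-arm law holds within
  2% out to 5°, and flexion excursions are exactly antisymmetric in the
  motion direction. This idealization matches how the physical model
  wrist is described (lines routed directly to the base of the distal
  segment); moment-arm realism of a cadaveric wrist is a non-goal.
* **Right arms are mirror images of left arms**: radial/ulnar (y)
  coordinates are negated and the tendon-to-actuator wiring swaps to the
  right-arm column of the rig's axis table. One sign convention
  (ulnar +) then serves both sides.
* **Segment lengths** default to 250 mm (proximal) and 80 mm (distal).

Units are mm, degrees and newtons throughout. Gravity is ignored: the rig
suspends the arm vertically, parallel to the gravity vector, precisely to
minimize its influence.

# Control model

The simulator's feedback loops are represented by their converged
behaviour, not by PID dynamics. Motions are slow, so each frame is solved
quasi-statically: the wrist settles into the pose minimizing the total
elastic energy

$$E(\theta)\;=\;\sum_{i=1}^{5} \tfrac12 k_i\,s_i^2 \;+\;
  \tfrac12 k_p \lVert\theta\rVert^2,
\qquad s_i = \max\!\bigl(0,\; L_i(\theta) + d_i - L_i^{rest}\bigr),$$

where $L_i(\theta)$ is the straight-line tendon length at pose $\theta$,
$d_i$ the actuator pull, $k_i$ the series stiffness of suture plus spring
(default 50 N/mm), and $k_p$ a small passive joint stiffness (default
0.01 N·mm/deg²) that keeps the pose determinate when all tendons are
slack. The `max(0, ·)` makes the springs unilateral: sutures cannot push.
Forces are $F_i = k_i s_i$.

The minimization runs Newton iterations with an analytic gradient (the
length gradients have closed form), warm-started from the previous frame,
with a BFGS fallback for cold starts, to a gradient norm below
10⁻⁸ N·mm/deg. Iterates are clamped to ±89° so line searches cannot cross
the gimbal singularity.

* **Force equalization** iterates "solve equilibrium, move each actuator
  by (target − F)/k" until all five forces are within `tol_n` (default
  0.01 N) of the target (protocol default 2 N), then zeroes the encoders.
  Actuators have 80 mm of absolute travel with the rest-length position at
  mid-travel (40 mm), so both pulls and releases are representable.
* **Displacement tracking** plays a recorded profile (displacement away
  from the encoder zeros, 50 Hz) through the equilibrium model and logs
  forces and displacements per frame.
* **Force caps** (ECRL 80, ECRB 86, ECU 74, FCR 125, FCU 211 N — the
  estimated total physiological muscle forces at a specific tension of
  32 N/cm²) are enforced inclusively: a force exactly at its cap passes;
  `flag` mode reports violations without modifying data, `clamp` mode
  additionally limits the force and still records the event. The 150 N
  load-cell capacity and force non-negativity are asserted on every log
  row.

A recorded excursion profile played back through the tracker reproduces
the generating angle path to within a small bias (the test suite bounds it
at 0.5°, and the acceptance script reports the recovered peak). The bias
is real, not numerical: under displacement control the 2 N preload exerts
small uncompensated moments away from neutral, which is also why the
physical rig cannot command wrist angles exactly.

# Synthetic trials

`make_trial_bundle()` emulates one motion pattern of the capture protocol:
five repeat trials plus one static (neutral) trial, 50 fps for planar
motions and 30 fps for the longer circumduction trials. Two noise sources
are modelled:

* **Trial-to-trial variation**: a smooth two-harmonic angle perturbation
  per axis, pinned to zero at both ends of the trial (trials start from
  the same equalized position and command), with amplitude
  `trial_jitter_deg` (default 0.5°, chosen to land the inter-trial angle
  RMSE below 1°, the repeatability scale the rig demonstrates).
* **Bead centroid noise**: isotropic Gaussian noise of `noise_sigma_mm`
  (default 0.1 mm, the scale of marker-based bead reconstruction error)
  added to the 3D bead positions before projection.

What the generator does **not** emulate: anatomical variation between
specimens, soft-tissue and suture friction, carpal-row internal
kinematics, muscle physiology, bead-detection failures, or image
distortion. Consequently the pipeline's inter-specimen RMSEs on synthetic
specimens (which differ only by jitter and noise realizations) are far
smaller than those measured across real cadaveric specimens, and passing
tests demonstrate correctness of the computations, not biological
fidelity.

Circumduction is generated as one continuous ellipse in the
(deviation, flexion) plane starting and ending at the extension
configuration, but — matching how such rigs handle profile-length limits —
it is commanded and recorded as two half-trials (extension→UD→flexion,
flexion→RD→extension) that `join_circumduction()` rejoins during analysis,
with a 2° junction tolerance.

# Reconstruction chain

The camera model is the classical 11-parameter direct linear transform.
Synthetic cameras are ideal pinholes built from the rig geometry: two
orthogonal beams, each at 45° to the forearm axis, 110 cm source-to-image
distance, with the specimen centered in the capture volume; the
`dlt_camera` object reserves an `undistort` hook, but no distortion is
modelled (the corresponding hardware correction targets image
intensifiers that have no synthetic counterpart). Calibration solves the
linear least-squares system from the 64-bead cube and rejects coplanar or
otherwise rank-deficient bead sets. Triangulation intersects the two DLT
rays in least squares and reports the RMS reprojection residual rather
than failing on inconsistent observations.

Bead groups are fitted per bone per frame with the closed-form orthogonal
Procrustes solution (SVD with a sign correction excluding reflections); a
bone-frame with fewer than three visible beads becomes an explicit gap,
never an interpolation. Pose series are then smoothed with a zero-phase
second-order Butterworth filter at 2 Hz. Filtering operates on
translations and on hemisphere-aligned quaternion components (renormalized
afterwards) rather than on Euler angles, avoiding wrap and gimbal
artifacts; the rotation parameterization the original tracking software
filters internally is not documented, so this choice is a deliberate,
documented deviation. Ends are handled by removing the endpoint-to-
endpoint linear trend, padding by odd reflection, filtering
forward-backward, and restoring the trend: constant series pass through
exactly and a boundary transient of order 10⁻³ of the signal remains
within roughly half a second of the series ends.

# Wrist angles

The RCS places x along the distal radial shaft, origin at the shaft's
intersection with the articular surface, y toward the sigmoid notch center
(orthogonalized), z completing the right-handed frame. The MCS places x
along the MCIII diaphysis and y along the best-fit line through the MCII,
MCIII and MCIV centroids — computed as the principal direction of the
three centered centroids, orthogonalized against x, with its sign fixed by
the MCII centroid. Neither anatomical convention pins down the absolute
sign of these axes; the packaged synthetic landmarks are constructed so
that RCS and MCS coincide with the lab frame at neutral, which realizes
the definition of neutral as the alignment of the two frames.

Wrist rotation per frame is
$R_{rel} = (R_{radius} R_{RCS})^{\top} (R_{mc} R_{MCS})$ — identity for
aligned frames, invariant to whole-arm motion — decomposed with the
intrinsic y–z–x sequence (flexion first, then deviation, then pronation).
The sequence itself is a convention choice: the axis labels are standard
but no decomposition order is universal, so the order is isolated in
`decompose_angles()` and flagged here as the one place to change it.
Gimbal proximity (|deviation| > 89°) warns; all generated paths stay
well inside ±90°.

Because specimens are never mounted in exact neutral, each motion's static
trial defines the neutral reference, composed out in rotation space:
$R_{corrected} = R_{static}^{\top} R_{raw}$ with the static trial's mean
rotation (chordal quaternion mean). This equals angle subtraction for
small offsets and remains exact for large ones; correction with a missing
static trial is an error, never a silent identity. The static trial is
applied per motion, matching a protocol that takes one static capture per
motion pattern.

# Motion metrics

* **Averaging and truncation**: the five trials are truncated to the
  shortest, averaged pointwise, and (except circumduction) cut at the
  maximum joint rotation — |fe| for flexion/extension, |rud| for RD/UD,
  and the combined magnitude for the two DTM motions.
* **ROM**: the in-plane value is the signed extremum on the motion's own
  axis; the out-of-plane value is the *other* axis read at that same
  sample (out-of-plane coupling is not eliminated by displacement
  control, so it is reported, not suppressed).
* **DTM plane**: ordinary least squares of FE on RUD (the plotting
  convention puts RUD on x, FE on y); the plane angle is measured from
  the sagittal axis, taken as the pure-FE direction of that plot, i.e.
  `atan(1/|slope|)`; fits with R² < 0.7 are flagged `excluded`. A
  profile with essentially no RUD variance is refitted on swapped axes,
  which measures the same line.
* **Circumduction ellipse**: the direct least-squares conic fit
  constrained to an ellipse (the numerically stable Halir–Flusser
  partitioning), chosen over geometric least squares because the
  constrained algebraic fit is closed-form, deterministic and cannot
  return a hyperbola; this choice is flagged as one the source protocols
  leave open. Area is πab; orientation is the acute angle of the major
  axis from the sagittal axis. The fit RMSE compares the magnitudes of
  100 vectors on the ellipse with the corresponding envelope vectors at
  equally spaced polar angles about the *ellipse center* (the only origin
  the fit defines), with the envelope radius linearly interpolated in
  polar angle. The envelope must span at least 350° of swept polar angle.
* **Repeatability**: inter-trial RMSE compares each trial with the
  specimen mean (after truncation to the shortest trial) per channel;
  the headline value is the channel with the maximum error, as the rig's
  summary tables report it, and the per-channel detail is returned
  alongside because the maximum of noisy RMSEs is upward-biased — the
  sampling-theory calibration (iid noise σ gives per-channel RMSE
  σ·√((n−1)/n)) is checked against the mean per-channel value.
  Inter-specimen RMSE resamples specimen means to exactly 100 points
  (200 for circumduction) over normalized time (linear interpolation; no
  method is prescribed beyond "interpolated") before comparing with the
  overall mean.

# Default protocol and problem sizes

The default run configuration commands the seven motion patterns at the
mean amplitudes the rig achieved on anatomical wrists — flexion 50.5°,
extension 57.2°, RD 20.9°, UD 29.2°, DTM planes at 20.4° (RE) and 26.2°
(UF) with 40° amplitude, and a circumduction ellipse with semi-axes
46° (FE) and 18° (RUD), whose area (π·46·18 ≈ 2601 deg²) matches the
reported mean ellipse area — with five trials per motion plus a static
trial, at 101 frames per planar trial (2 s at 50 fps) and 180 frames of
circumduction at 30 fps. These sizes keep a full
simulate→reconstruct→analyze run around a minute while leaving every
stage's statistics well resolved; all of them are config entries, not
constants.

```{r, eval = FALSE}
cfg <- default_run_config(seed = 1)
report <- run_pipeline(cfg, "run1")
report$flexion$rom
report$UF$dtm
report$circumduction$ellipse
```

# Known limitations

* The quasi-static, friction-free, five-tendon model reproduces the
  *logic* of displacement-controlled motion simulation, not cadaveric
  mechanics; tendon force magnitudes are only as meaningful as the spring
  constants behind them, which are config parameters with no claim of
  fidelity.
* Bead tracking is by persistent identity; detection and tracking in
  radiographic images are out of scope, as are CT segmentation and mesh
  animation.
* Pose smoothing introduces a boundary transient (see above); derived
  metrics read interior samples in practice because profiles are
  truncated at interior extrema.
* The Cardan sequence and the sagittal-axis convention for the DTM angle
  are documented choices; alternatives would change reported angles by
  small amounts for strongly coupled motions.
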