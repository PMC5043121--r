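---
title: "Models and methods behind dodgekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dodgekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dodgekin)
```

`dodgekin` analyses full-body interception reaches recorded with optical
motion capture during a virtual dodgeball game, and ships the game machinery
and a labelled synthetic-motion generator used to validate the analysis.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the validation does and does not demonstrate.

## Coordinate conventions

All lengths are meters, angles degrees, sampling in Hz. The canonical lab
frame is right-handed with AP = x (forward), ML = y (leftward),
vertical = z (up). Files in other units (TRC in mm) are converted on load;
missing samples are explicit `NA`s, never zeros.

## Segment poses and joint angles

Each body segment carries a rigid cluster of at least three non-collinear
markers. Per frame, the segment pose is the least-squares rigid transform
(orthogonal Procrustes / Kabsch, SVD-based) mapping the cluster template
onto the observed markers; the determinant is forced to +1 so reflections
can never masquerade as poses. Frames with fewer than three valid markers
are flagged unresolvable and propagate `NA` downstream — the pipeline flags
trials rather than inventing data. Dropouts of at most 5 frames are linearly
interpolated first (`interpolate_gaps()`); longer gaps leave the trial
flagged. The 5-frame limit (50 ms at 100 Hz) is conservative relative to the
~500 ms movements of interest.

Joint angles decompose the relative rotation of the child segment in the
parent's frame with the intrinsic Euler sequence flexion–extension (about
ML), lateral bending (about AP), axial rotation (about vertical):
`R = Ry(flexion) Rx(lateral) Rz(axial)`. The sequence order is fixed; the
axis assignment (flexion about ML, positive forward) is the common reading
for sagittal-plane movement analysis and is configurable through the chain
table, which also carries a per-joint sign so that anatomical flexion is
positive for every joint (the raw decomposed angle of, e.g., the knee is
negated). Middle angles within 0.5° of ±90° are flagged as near gimbal
lock; the standing-aligned segment frames used here keep lateral bending
far from that region. Joint centres are fixed points in the segment frames
supplied by the model configuration — no anatomical-landmark calibration or
functional joint-centre estimation is attempted.

## Smoothing, differentiation and events

The fingertip position is smoothed per axis with a Savitzky–Golay filter:
at every sample a fourth-order polynomial is fit by least squares to the
sample and its 20 neighbours on each side (41 points, 0.41 s at 100 Hz),
and the polynomial's first derivative supplies the velocity
(`signal::sgolayfilt`, which also handles the first and last half-windows
with same-order fits on the available asymmetric window, so no
event-relevant samples are discarded at trial boundaries). Speed is the
Euclidean norm of the velocity vector; whether the original analyses
thresholded speed or a signed component is not documented, and speed is the
assumption made here.

Movement onset is found by a backward search from the speed peak: the last
sample at or before the peak with speed ≤ 5% of the peak. Target contact
mirrors it forward. Ties at the threshold resolve to the sample closest to
the peak — a deterministic consequence of the backward/forward scan order.
If the threshold is never crossed the series boundary is returned with a
warning and a `found = FALSE` attribute; `run_pipeline()` flags such trials
(`threshold_not_crossed`) instead of dropping them. The peak itself is the
global speed maximum inside the trial window, which runs from the warning
time to 0.5 s after ball impact — the launch schedule provides natural trial
windows, and the 0.5 s tail accommodates late contacts without capturing the
return movement. Trials whose windowed peak speed is below 0.05 m/s are
flagged `undetectable` (a static recording produces no events).

Joint excursions are contact-minus-onset angle changes by default. An
alternative reading — change from the initial standing posture — is
available via `excursion_reference = "standing"`; the onset-referenced
definition is the one the per-trial reduction uses because it describes the
computation actually applied trial by trial.

## Whole-body centre of mass

The COM is the mass-fraction-weighted mean of segment COMs, each placed a
fixed fraction of the way from the proximal to the distal endpoint. The
shipped table (`inst/extdata/winter_segments.csv`) uses Winter-style
parameters on a 14-segment model with head, neck, trunk and pelvis
consolidated into a single trunk segment (mass fraction 0.578) spanning hip
centre to C7, and bilateral thighs, shanks, feet, upper arms, forearms and
hands; the fractions sum to 1.000. The consolidated-trunk COM location
(0.45 of hip→C7) is a package choice — published segment tables define the
trunk against different landmarks, and the merged segment has no single
canonical value. The table is injectable (`winter_table(path)`) precisely so
alternative parameter sources can be swapped in; validation only requires
that generator and pipeline share whatever table is in use.

## Individualized targets and impact heights

Standardized mid-sagittal reach targets come from a planar two-link model:
hip flexion θ from vertical with the shoulder flexed 90° and the elbow
extended puts the hand at

```
AP       = trunk · sin θ + arm · cos θ
vertical = hip_height + trunk · cos θ − arm · sin θ
```

with θ = 15° (high), 30° (middle), 60° (low). The vertical coordinate is
strictly decreasing in θ, so the inverse map (`recover_hip_flexion()`) is a
bracketed univariate root find (`stats::uniroot`, tolerance 1e-12) followed
by an AP consistency check; points off the reach locus raise a no-solution
error rather than returning a nearest fit.

Impact heights for gameplay level L put IH0 at eye height and IH4 at the
hand height the forward model predicts when the trunk adopts the baseline
lumbar flexion recorded for that level's standardized target (high → L1,
middle → L2, low → L3). Lumbar flexion stands in for trunk inclination
through an injectable mapping (identity by default) because the original
conversion is not documented. IH1–IH3 are linear interpolants between IH0
and IH4 — the published height ladders are evenly spaced and no formula is
given. All heights must stay at or above `shin_height − 0.05 m`
("approximately the shins" is not quantified; 5 cm below the shin landmark
is the package's reading).

## Game engine

Defaults encode the task: four opponents, inter-launch intervals uniform on
3.3 ± 0.3 s (the published jitter is read as a bounded uniform; the
distribution was not stated), 300 ms warning, two sets of 15 balls per
level, three balls per impact height per set with one each at the midline
and ±20 cm, duck trials exactly at IH0, rewards 1/2/5/10 cents, a 25-cent
bonus ball after each game-level set, and straight-line constant-speed ball
flight (impact geometry, not flight realism, is what the analysis needs).
The starting balance equals the summed value of every launched and presented
ball, and each failure loses the level's reward — the only construction
under which an all-failure game ends at exactly zero. The practice level's
ball count was not published; two sets of 15 (like the game levels, at the
Level-1 heights, without bonus balls) makes the all-failure balance
enumerable as 30·(1+2+5+10) + 6·25 = 690 cents. Schedules are
bit-reproducible under a seed, and schedule generation saves and restores
the caller's RNG state.

Block success requires the centre of the hand-held ball (the midpoint of
the two fingertips — the ball is held with both hands at the midline) to
come within the sum of the two ball radii (2 × 0.12 m, a 24 cm regulation
ball) of the launched ball's centre at some instant in flight. Duck success
requires the head top to be below the ball's lower edge by a 0.05 m margin
at the crossing time; no explicit duck geometry was published, so the margin
is a package choice.

## The synthetic-motion generator

The generator emulates the statistical structure the analysis assumes: a
sagittal foot–shank–thigh–pelvis–trunk–upper-arm–forearm–hand linkage driven
by six anatomical joint angles, with segment lengths derived from the
participant's body dimensions (arm split 0.42/0.33/0.25 into upper arm,
forearm and hand; pelvis 0.2 of trunk length). Left and right sides run the
same program at mirrored ML offsets, so hand and ankle centroids sit on the
midline. Marker clusters are rigid 4-marker plates in segment frames that
coincide with the lab frame in standing posture (a static trial therefore
yields identity relative rotations at every joint); markers carry seeded
isotropic Gaussian noise, 0.5 mm SD by default — deliberately conservative
relative to the 0.1 mm resolution of the optical system being emulated —
with no temporal autocorrelation.

A reach apportions excursion across the six joints by the strategy
profile's weights. The aim point is the event's impact location (plus the
profile's `forward_bias`); the posture program is `s·w + δ·e_shoulder`
(plus a fixed knee-dominant squat when `crouch_bias > 0`), solved by
damped Gauss–Newton for the scale `s` and a shoulder adjustment `δ` so the
fingertip lands on the aim. Two degrees of freedom are needed for the 2D
sagittal aim; the shoulder supplies the second because it trades AP reach
against hand height (a squat term cannot — squatting only lowers). A small
penalty (1e-4 per degree) on `δ` makes aims lying exactly on the
one-parameter weight locus solve with `δ = 0`, so a pure-elbow profile
produces a pure elbow excursion. Residuals above 2 cm raise an
infeasible-strategy error instead of bending the linkage. The time course
is minimum-jerk (`10τ³ − 15τ⁴ + 6τ⁵`), timed so contact coincides with ball
impact, with a 0.5 s hold and a minimum-jerk return; duck trials run a
knee-dominant squat (ankle:knee:hip = 1:2:1, which keeps the trunk upright)
deep enough to clear the IH0 ball path (0.35 m by default).

Ground truth is computed from the noiseless forward kinematics. Events
deserve a note: onset and contact are *operational, filter-defined*
quantities in this analysis — the stored ground-truth events therefore
apply the exhaustive 5%-threshold scan to the noiseless fingertip speed
obtained with the same canonical 41-point Savitzky–Golay differentiation.
An instantaneous-derivative reference would disagree by 2–3 samples purely
because of the filter's behaviour at the piecewise-polynomial junctions of
the synthetic program, which would say nothing about the pipeline's
correctness. The scan itself is independent of the packaged detection
functions, which are separately property-tested against brute-force scans.

What passing the validation shows — and what it does not: noiseless
recovery demonstrates that the marker → pose → angle → event → measure
chain is self-consistent to machine precision, and noisy recovery bounds
the bias and variance added by isotropic marker noise. Real recordings add
soft-tissue artifact (correlated, non-isotropic), marker occlusions,
cross-talk from joint-centre misplacement, and genuinely three-dimensional
movement, none of which the planar generator emulates. Synthetic results
validate the software, not the biomechanics of any human dataset.

## Validation problem sizes

The test-suite and acceptance checks use: single standard 15-ball sets
(plus one bonus ball) for noiseless end-to-end recovery; 5-ball single-set
schedules for the faster end-to-end properties; 100 seeded repeats of a
single reach at 1 mm marker noise for the bias/variance bounds; 10,000
generated inter-launch intervals for the schedule-distribution check; and
1,000 Monte-Carlo frames for rigid-pose recovery. These sizes give the
Monte-Carlo estimates standard errors comfortably below the tolerances
being checked while keeping the suite quick to run.

## Known limitations

- The linkage and joint programs are planar; ML components of real
  movement enter only through the fixed cluster geometry. ML effects in
  this task are small (< 2 cm), but the generator cannot emulate them.
- Only the right-side chain is analysed by default (the task is bimanual
  and near-symmetric); the left chain is available through
  `default_chain("l")` with a mirrored cluster set.
- Euler decomposition near gimbal lock (lateral bending near ±90°) is
  flagged, not reparameterized; postures in this task stay far from it.
- The anthropometric table is position-only: no inertia, no kinetics, no
  subject-specific scaling beyond segment lengths.
- Inferential statistics (mixed-model MANOVA and post-hocs) are out of
  scope by design; summaries stop at means, SDs and paired per-trial
  condition differences.
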