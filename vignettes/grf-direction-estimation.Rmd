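---
title: "Estimating ground reaction force direction from skating posture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ground reaction force direction from skating posture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skateGRF)
```

## The problem

Force plates cannot be embedded in an ice rink, so the reaction force a
speed skater receives from the ice is hard to measure without
instrumented blades that interfere with the movement.  If the reaction
force acts perpendicular to the shoe sole, however, its *direction* can
be recovered from ordinary motion-capture data of the supporting leg,
and combined with a separately measured resultant magnitude (a force
plate on land, pressure insoles on ice) to reconstruct the full force
vector.  `skateGRF` implements and verifies that idea for inline speed
skating, where a force plate can serve as ground truth.

## The estimators

All quantities live in a travel-aligned local frame: Y' is the unit
horizontal component of the whole-body centre-of-mass (CM) velocity,
Z' is vertical up, and X' = Y' x Z' points to the skater's right.

Let `rear` and `front` be the blade end markers and `joint` a joint
centre of the supporting leg.  The blade axis is
`y_b = unit(front - rear)`; the lever runs from the blade rear end to
the joint; `x_b = unit(y_b x lever)`; and the estimated force direction
is `z_b = unit(y_b x x_b)`, sign-fixed to point upward.  Algebraically
`z_b` is the unit component of the lever perpendicular to the blade
axis, i.e. the sole normal when the joint sits above the sole.  Two
choices of joint define the two estimators:

* **Est1** — ankle joint centre (short lever, ~0.25 m);
* **Est2** — knee joint centre (long lever, ~0.5 m).

The estimated force vector is the measured resultant magnitude,
expressed in body-weight (BW) units, times the unit direction:
`F_est = F_sigma * e`, where `e = to_local(z_b)`.  Straight skating is
bilaterally symmetric, so left-leg data are mirrored (X' negated) and
pooled with right-leg data; the two legs on the curve are asymmetric
and analysed separately (curve-right, curve-left).

The sign convention deserves a note: the literal cross-product order
yields a *downward* vector, so the implementation enforces
`z_b . (0,0,1) > 0` by an explicit sign flip.  `z_b` is perpendicular
to the blade axis by construction, and the uncorrected component
vector always has the measured resultant as its Euclidean norm.

Marker-position errors rotate the lever and hence `z_b`; the angular
error scales inversely with the lever length, which is why the
knee-based Est2 is expected to be, and in this package's synthetic
verification is, the more accurate estimator.

## Preprocessing

* **Smoothing** — zero-phase Butterworth low-pass, realised as a
  dual-pass 2nd-order filter (effective order 4) with odd-reflection
  padding of about three filter lengths.  The cutoff is chosen per
  marker coordinate by the residual method: RMS residuals between raw
  and filtered series are computed over a 1-30 Hz grid (0.5 Hz steps),
  the top third of the grid is fitted with a straight line whose 0 Hz
  intercept estimates the noise floor, and the lowest cutoff whose
  residual reaches that floor (within twice the fit's standard error)
  is selected, then clipped to 9-15 Hz, the range appropriate for
  skating marker data.  A residual curve that keeps decaying steeply
  through the would-be noise region (noiseless data) has no floor and
  raises a degenerate-signal error; inside `filter_trial()` such
  coordinates fall back to the 15 Hz clip bound, the least aggressive
  smoothing.  For pure noise the method returns a cutoff at the very
  bottom of the grid (nothing to preserve), though the floor-fit
  uncertainty can move it a few grid steps above the exact minimum.
* **Synchronisation** — the 900 Hz force signal is anti-alias filtered
  (zero-phase, effective order 8, cutoff 0.4 x the target Nyquist) and
  decimated to the 300 Hz marker rate, keeping the shared start time.
  Whether to low-pass the force itself is exposed as `filter_forces`
  (default off: the resultant is used as measured).
* **Local frame** — built per frame from the CM velocity obtained by
  central differences of the (smoothed) CM trajectory; one-sided at the
  endpoints.  Frames are undefined below 0.1 m/s horizontal speed, far
  below skating speeds (~9-10 m/s).
* **Units** — forces are divided by body weight in newtons.

## Stride phases and time normalisation

The supporting-leg period is split by four blade events into contact
(analysed blade down, opposite blade still down), single support, and
push-off (opposite blade down again), each phase running to one frame
before its closing event.  Series are resampled onto a fixed 101-point
percent grid with contact mapped to 0-20%, single support to 20-80%
and push-off to 80-100%, using a cubic spline fitted *per phase* on
the usable frames, so phase boundaries act as knots and no information
leaks across support transitions.  A grid point is valid only when its
phase had at least two usable frames and the nearest usable frame lies
within 2% of stride; boundary grid points are owned by the later
phase when both produce a valid value.

Frames are usable for verification only when the force plate measures
the analysed blade alone: both analysed blade endpoints inside the
plate rectangle, and the opposite blade airborne or entirely outside
the plate.  Because the plate (0.6 m x 5.4 m) is shorter than a
stride, the per-grid-point sample size varies, which the aggregation
and reporting code tracks explicitly.

## Agreement statistics

Verification happens at 10% intervals of normalised time (5-95%), per
component, with the force-plate value as truth:

* true-on-estimate OLS regression (truth on the vertical axis);
* ICC(2,1) — two-way random effects, absolute agreement, single
  measure — banded per Koo & Li (poor < 0.5, moderate to 0.75, good to
  0.9, excellent above; half-open intervals), with agreement declared
  at 0.5 or higher;
* Bland-Altman bias (mean of estimate - truth), precision (SD), 95%
  limits of agreement `bias +/- 1.96 * precision`, and a t-based 95%
  CI of the bias whose exclusion of zero flags a *fixed error*;
* a *proportional error* flag from the Pearson correlation between
  per-point means and differences (alpha = 0.05), with the slope's
  repeated-measures CI obtained by resampling participants with
  replacement (2000 draws, seeded) — the cluster bootstrap is this
  package's choice where no method is canonical;
* a correction trigger: any |bias| of 0.08 BW or more (inclusive) at
  any time point recommends a regression correction for that motion.

No multiple-testing adjustment is applied across grid points or
components; the battery is exploratory and the flags are descriptive.
Trials are treated as the independent unit at each grid point;
participant clustering enters only the proportional-error CI.

## The linear correction

For the left leg on the curve the shank leans strongly outward near
push-off while the actual force stays more vertical, so the sole-normal
assumption over-tilts the estimate there.  A per-component linear
recalibration `true ~ slope * est + intercept`, fitted by pooling all
analysable normalised-time samples, repairs most of that systematic
error.  `default_correction_model()` carries the curve-left
coefficients (slopes 0.847 / 0.596 / 0.987, intercepts -0.029 /
-0.025 / +0.030 for X'/Y'/Z'); it is scoped to curve-left data and
warns when applied elsewhere.  `lopo_validate()` checks the correction
out of sample by refitting with each participant held out in turn.

## The synthetic stride generator

No public recordings accompany the method, so the package ships a
simulator that produces every input with known ground truth:

* the CM travels a straight line at 9.79 m/s or a 26 m-radius arc at
  8.87 m/s; phase durations default to 0.16/0.60/0.16 s (straight),
  0.15/0.48/0.14 s (curve-right) and 0.14/0.56/0.15 s (curve-left);
* the blade glides on the course plane; the shank lean follows a half
  sine from a base angle (0 straight, 17 degrees on the curve, leaning
  into the turn) to a push-off maximum (15 / 25 / 30 degrees for
  straight / curve-right / curve-left); a small blade pitch (4 degrees,
  heel rising) gives the direction its propulsive Y' component,
  confined to roughly 0-0.1 BW;
* ankle and knee sit on the sole normal at 0.2 m and 0.45 m from the
  blade, so with clean markers both estimators recover the sole normal
  exactly;
* the resultant follows a raised-cosine bump peaking at 1.8 BW at
  mid-stride; the true direction is the sole normal rotated about the
  blade axis by a configurable perturbation (default 2 degrees),
  emulating the mismatch between shank inclination and force direction;
* observed markers add 3 mm isotropic i.i.d. optical noise, and the
  ankle/knee joint centres additionally carry a slowly varying (2 Hz
  band, 8 mm SD) joint-centre estimation error.  Joint centres are
  virtual points derived from skin markers and carry soft-tissue
  artifact well above optical noise, and being low-frequency it
  largely survives the 9-15 Hz smoothing.  The artifact amplitude is
  deliberately identical for both joints, so only the lever-length
  ratio differentiates Est1 from Est2 — the mechanism under test;
* cohorts draw per-participant random effects (speed, lean, pitch,
  perturbation; normal, SD 5% of nominal or 0.5 degrees) and are fully
  reproducible per seed.

Ground-truth local components are expressed in the local frame derived
from the *sampled* CM trajectory by the same central-difference rule
the pipeline uses, which makes the zero-noise identity exact rather
than accurate to the differentiation error.

What the simulator does **not** model: ankle articulation, ice
friction, centre-of-pressure travel along the blade, and the real
waveforms of the force components.  Passing tests therefore show that
the pipeline is internally correct and that the lever-length mechanism
behaves as expected — not that the error magnitudes match real
skating.  In particular, the simulated Y' errors are much smaller than
real ones: because both estimators share the blade markers, and the
estimated direction is constrained perpendicular to the blade axis,
the Y' component of the estimate is governed almost entirely by the
shared blade-pitch estimate, and the lever-dependent difference enters
Y' only through the small coupling sin(lean) x sin(pitch).  The
expected Est2-better-than-Est1 ordering still holds for Y', but with a
margin far smaller than for X' and Z'.

### Validating the correction machinery

Injecting a distortion into the simulated force signal cannot produce
an *exactly* linear truth~estimate relation, because the estimate's
magnitude is the measured resultant, which would feed back into
itself.  The correction-recovery studies therefore inject the known
linear miscalibration at the estimate level (`inject_distortion()`,
the exact inverse of the correction plus 0.003 BW measurement noise)
on cohorts simulated with the direction perturbation set to zero, so
the prescribed linear model is the only systematic error and the
fitted coefficients can be compared against the generating ones.  The
recovered slope for Y' sits slightly below the generating value — the
ordinary attenuation of OLS slopes under noise in the regressor, and a
real property of the verification design, not an implementation error.

## Numerical choices

* ICC mean squares are computed directly from the two-way sums of
  squares; the residual sum of squares is clamped at zero against
  cancellation, and a zero between-trial variance returns a degenerate
  flag with a warning instead of an error.
* LoA use the literal 1.96 factor; the bias CI uses the t quantile.
* Threshold comparisons are inclusive (a bias of exactly 0.08 BW
  fires the trigger).
* Phase splines use `stats::splinefun(method = "fmm")` (cubic), with
  linear interpolation when a phase has fewer than four usable frames;
  phases with fewer than two usable frames mark their grid band
  invalid rather than erroring.
* Degenerate geometry (coincident blade ends, joint collinear with
  the blade axis within 1e-4 rad) raises errors rather than producing
  unstable directions.

## Problem sizes

The verification studies in the test suite and acceptance script use
16 participants x 7 trials per motion for the ordering and correction
studies (the cohort shape of the verification experiment this package
models) and 8 x 4 cohorts for the per-motion error tables in the
acceptance script; RMSE is computed over all valid points of the 1%
grid, pooled across trials, matching how the method's RMSE between
normalised time series is defined.

## Known limitations

* The correction coefficients shipped as defaults apply to the left
  leg during curve skating only; the package warns, but cannot stop
  you, if you override the scope.
* The proportional-error bootstrap assumes at least two participants;
  with one it falls back to the plain OLS interval with a warning.
* The simulator's force waveform is a smooth bump, not a measured
  skating waveform; quantities that depend on waveform shape (e.g.
  which grid points trigger the correction) should not be read as
  predictions about real data.
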