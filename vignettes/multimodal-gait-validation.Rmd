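---
title: "Multi-modality gait event detection and method agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modality gait event detection and method agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multigait)
```

## The problem

Instrumented gait analysis derives clinically meaningful markers — stride
and step times, stance and swing phases, support times, lengths and
velocities — from the timing of two events per foot per stride: heel
strike (HS, foot contacts the ground) and toe-off (TO, foot leaves it).
Different sensor families observe these events very differently. A
foot-mounted gyroscope sees them directly as extrema of the
medial–lateral angular velocity; a single lumbar accelerometer sees only
their indirect signature in trunk motion; a depth camera sees them as
kinematic transitions of the ankle trajectory. `multigait` implements one
detection pipeline per family, a shared marker layer, and the paired
statistics used to quantify agreement against a reference event stream,
plus a synthetic-data generator that creates all three streams from one
known ground-truth event train.

This vignette records the modelling choices: what each component assumes,
which parameters matter, what the generator does and does not emulate,
and therefore what a passing validation run does and does not show about
real recordings.

## The ground-truth event generator

`generate_event_sequence()` lays out strides on an out-and-back course.
Within a stride of duration $T$ beginning at a left heel strike, the
contralateral toe-off falls at $+\tfrac{d}{2}T$ (initial double support,
with $d$ the double-support fraction), the contralateral heel strike at
the half stride, and the ipsilateral toe-off at $+sT$ (stance fraction
$s$). Each pass is prefixed by the initiating foot's toe-off, so every
heel strike — including the first of a pass — is preceded by a swing that
the camera can observe. Stride durations and step lengths are drawn from
normal distributions truncated at $\pm 3$ SD; a pass ends before the
cumulative step lengths exceed the path length; passes are separated by
an event-free turn.

Two structural points deserve note:

* For both feet to share the same stance fraction in steady state the
  double-support fraction must equal $2s - 1$; that is the default
  (e.g. $s = 0.657$ gives $d = 0.314$, matching the usual ratio of
  double-support to stride time in older adults). The generator accepts
  other values of $d$ — the initiating foot then keeps stance $sT$
  exactly and the other foot absorbs the difference — and every marker
  identity (stance = single support + double support, etc.) still holds
  per foot by construction.
* Defaults describe single-task walking of older adults: stride
  1.08 s, step 0.655 m, stance fraction 0.657, 7 m path, two passes,
  a 3 s turn, 1 s of quiet standing before gait initiation (so that no
  event sits closer to the record edge than the widest analysis kernel).
  The dual-task condition slows the cohort (stride 1.16 s, step 0.62 m).
  Between-subject spread (stride SD 0.08 s, step SD 0.06 m, drawn with a
  −0.5 correlation: slower walkers take shorter steps) mirrors the
  population variability needed for meaningful correlation statistics.

## The three sensor emulations

**Foot gyroscope.** Gaussian angular-velocity lobes (width 120 ms,
−5 rad/s at HS, +3 rad/s at TO) over white noise and a slow sinusoidal
drift. The accelerometer z channel embeds, during each step, a sinusoidal
wave whose peak-to-peak range is $(\mathrm{SL}/0.5)^4$, so a
Weinberg-type quartic-root estimator with a calibrated constant recovers
the step length.

**Lumbar accelerometer.** The anterior–posterior channel carries a
negative lobe at every HS and a positive lobe at every TO of either
foot. The vertical channel carries gravity plus one sine period per step
whose double integral has peak-to-peak excursion $h$ obtained by
inverting the pendulum relation $\mathrm{SL} = 2\sqrt{2lh - h^2}$
(smaller root — physical excursions are small relative to the pendulum
length). A sine is used deliberately: it is exactly invariant under the
endpoint drift resets applied during double integration downstream.

The cohort defaults additionally degrade the lumbar toe-off lobes —
100 ms early with 20 ms jitter (plus 10 ms jitter on all lobes). This
encodes the well-documented behaviour of trunk-level sensing: heel-strike
impacts propagate sharply to the lower spine, so step and stride times
are excellent, while toe-off has no crisp trunk signature, so stance,
swing and support phases are unreliable and stance is systematically
underestimated. The shift is kept moderate — real lumbar pipelines have
been reported far worse — because larger shifts collide with the
heel-strike lobes and stop expressing themselves monotonically.
These degradation parameters are explicit generator arguments that
default to zero; "noiseless" validation runs therefore exercise the pure
geometry.

**Depth camera.** One persistent body id carries the participant. Ankle
depth is constant during stance; during swing the velocity rises with a
Gaussian-smoothed onset whose acceleration peaks exactly at toe-off,
holds a plateau, and stops with a 40 ms raised-cosine whose deceleration
peaks 20 ms before heel strike — so the foot is (to within millimetres)
stationary at contact and the depth read at a heel strike equals the
ground-truth placement. Symmetric stop profiles were rejected: centring
the deceleration on the contact instant leaves half the swing motion
after contact, which corrupts the depth-at-heel-strike readings that the
length computations rely on. Continuous motion is built on an 8× internal
grid and sampled at the frame times, as a camera would. Bystander bodies
appear and disappear ≥ 0.8 m off the walkway centreline with changing
body ids; the turn repositions the feet slowly enough that it cannot
masquerade as a step.

## Detection pipelines and their tunables

All filters are applied zero-phase (forward–backward), because event
*times* are the product — any phase lag would bias every marker.
Butterworth designs are assembled as second-order sections; a 12th-order
high-pass at 0.5 Hz on a 128 Hz grid is numerically unusable as a single
transfer function. End effects are handled by odd-reflection padding
sized to ~6 time constants of the slowest filter pole.

| Parameter | Default | Why |
|---|---|---|
| Foot high-pass cutoff | 0.5 Hz | removes drift, preserves the ~1 Hz stride fundamental |
| Foot FIR low-pass | 10 Hz, 216 taps, Hamming | gait gyro energy lies below ~10 Hz |
| Lumbar low-pass | 10 Hz, 2nd order | standard trunk-acceleration band |
| Wavelet scale rule | $f_s / (2 f_{step})$, $f_{step}$ from the 1.4–2.6 Hz spectral peak | ties the differentiator to the step rhythm |
| Kernel width | $\sigma =$ scale/8 samples | kernel spans about half a step; wider kernels let neighbouring lobes dominate extremum positions |
| Kinect low-pass | 3 Hz, 6th order | joint-trajectory smoothing |
| Peak prominence | max(0.5 × robust SD, 15% of max amplitude) | scale-free, with a floor that rejects filter ringing side-lobes beside isolated lobes |
| Peak distance | half the autocorrelation stride estimate | same-kind events recur once per stride (per step for the lumbar stream) |

Peak picking enforces per-foot HS/TO alternation by keeping the more
extreme of two same-kind events detected without the other kind between
them. The foot and kinect detectors additionally discard peaks smaller
than 40% of the median detected-peak amplitude of their kind: event lobes
cluster tightly in amplitude, noise bumps do not. The lumbar detector
does not use this filter — its toe-off extrema legitimately vary in
amplitude — and instead relies on prominence alone. Laterality from the
single lumbar sensor is assigned by alternation, restarting at each
walking bout from a configurable first side (the turn breaks global
alternation: both passes start with the same foot).

The kinect detector sign-corrects the ankle depth acceleration by
multiplying with −(sign of mean depth velocity): a foot *decelerating*
into ground contact produces a raw depth-acceleration maximum at heel
strike on outbound passes (depth decreasing) and a minimum on the
return, and this correction makes heel strikes maxima in both
directions. Event detection runs on the depth (progression) signal;
a configuration switch selects the vertical signal instead, but the
length formulas operate in depth, which is why depth is the default.
Passes are segmented by thresholding a 0.5 Hz-smoothed body velocity at
half its 80th percentile, and strides spanning a turn are excluded — in
addition, any stride longer than 2 s is discarded as a turn artefact.

## Markers

Temporal markers follow the per-foot, per-stride reading of the standard
event-difference table: within a stride $HS_F(i) \to HS_F(i+1)$, stance
is the ipsilateral toe-off minus $HS_F(i)$, initial double support the
contralateral toe-off minus $HS_F(i)$, terminal double support the
ipsilateral toe-off minus the contralateral heel strike, and single
support the contralateral swing inside the stride. (Read with one global
event index those formulas contradict the physiological identities that
published cohort tables obey — e.g. single support would equal nearly a
full stride — so the per-stride reading is used and verified against a
brute-force interval calculator.) Cadence is
$2 n_{strides} / \sum T \times 60$; average velocity is length-sum over
time-sum across retained strides, walkway-style, so turn intervals never
enter the denominator.

Spatial markers are modality-specific. Foot: Weinberg lengths
$K(a_{max}-a_{min})^{1/4}$ of the pitch-projected vertical acceleration,
with $K$ calibrated on the first walking bout against the reference
distance; a separate stride constant is calibrated the same way, because
a foot-mounted sensor sees one swing per stride and the same $K$ cannot
serve both. Lumbar: pendulum lengths from the per-step vertical
excursion; the pendulum length defaults to 0.94 m (a leg length — the
canonical pendulum limb; note that a foot-length pendulum could not
reach typical step lengths, since the model's maximum step is $2l$).
Kinect: ankle-depth differences at heel strikes, nearest frame.

## Numerical choices

* Drift resets in double integration remove the straight line through
  the first and last samples of each stage (zero net vertical
  displacement and velocity change per step) rather than a least-squares
  fit, which would eat 11% of a one-period sine.
* Event times live on the sample grid of their stream; no sub-sample
  interpolation is attempted (128 Hz ⇒ ±4 ms, 30 fps ⇒ ±17 ms).
* The wavelet differentiator's sign is fixed so heel strikes are minima
  under the default axis convention; a configuration flag flips it.
* Ties in participant selection are broken by the larger depth range
  travelled — the participant walks the path, bystanders do not.

## What validation runs show — and what they don't

The test suite and the acceptance script establish, on synthetic data:
exact recovery of construction parameters at zero variance; ≥ 98%
event recovery at zero noise within ±15 ms (foot), ±30 ms (lumbar) and
±1.5 frames (kinect); graceful degradation under sensor noise; the
stride-level conservation identities against an independent oracle on
1000 random event trains; the closed-form length formulas; and the
qualitative cross-modality ordering (foot best, camera close behind,
lumbar weakest on temporal subphases) across seeded cohorts of 18
subjects. Problem sizes (10–20 seeds × 18 subjects; 8 cohorts in the
acceptance script) were chosen to keep Monte-Carlo variability on these
aggregate rates well below the margins being asserted.

The generator does not emulate: soft-tissue artefact spectra, gait
pathologies or asymmetric timing (only spatial asymmetry is exposed),
skeleton-tracking dropouts or joint swaps for the participant, camera
occlusion by bystanders, cross-device clock drift (the trigger makes
devices simultaneous by construction, as a hardware synchronizer does),
or reference-system timing noise (reference events are taken as exact).
Passing here therefore demonstrates correctness of the signal chain and
statistics, not field performance on pathological gait or adversarial
camera scenes.

## Known limitations

* Laterality from one lumbar sensor is assigned by alternation; a missed
  heel strike inside a bout flips the labels for the rest of that bout.
* The Weinberg calibration requires a known calibration distance (here
  the reference pass); without any reference the foot lengths are
  relative.
* The kinect pipeline assumes an approximately straight path aligned
  with the camera axis; lateral drift folds into the depth differences.
* MAEP is undefined for markers whose reference value can be zero, and
  correlation is undefined for zero-variance cohorts; both are reported
  as `NA` with the rest of the table intact.
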