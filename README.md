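# multigait

Validating wearable and depth-camera gait analysis against a reference
system requires three things at once: sensor-specific event detection
(heel strike, HS; toe-off, TO), a common set of spatiotemporal gait
markers computed from those events, and paired agreement statistics.
`multigait` implements that whole chain for three sensing modalities —
foot-mounted inertial sensors, a single lumbar-mounted accelerometer, and
a markerless depth-camera skeleton stream — together with a synthetic-data
generator that produces synchronized recordings of all three modalities
from a known ground-truth gait event train, so every stage of the pipeline
can be validated against truth.

It is aimed at researchers developing or benchmarking instrumented gait
assessment: the generator emulates a standard clinical protocol
(out-and-back walking over a 7 m course, single- and dual-task
conditions, a TTL trigger channel segmenting the session, bystanders
wandering through the camera's field of view), and the analysis side
mirrors the published practice for each sensor family.

## Methods at a glance

* **Foot IMU** — the medial–lateral angular velocity is filtered with a
  12th-order high-pass Butterworth (second-order sections, zero-phase)
  and a 216-tap FIR low-pass, then mean-centred; HS are the negative and
  TO the positive peaks, constrained by height, prominence, and
  inter-peak distance.
* **Lumbar IMU** — the anterior–posterior acceleration is detrended,
  low-passed at 10 Hz (2nd-order Butterworth), integrated
  (cumulative trapezoid), and differentiated with a first-derivative-of-
  Gaussian wavelet at a scale tied to the step frequency; minima are HS,
  maxima TO. Step length comes from the inverted pendulum model,
  `SL = 2·sqrt(2·l·h − h²)`, with the vertical excursion `h` obtained by
  double integration of the vertical acceleration with per-step drift
  resets.
* **Depth camera** — the participant is selected among tracked bodies by
  coverage and a lateral walkway gate; ankle depth signals are low-passed
  (6th-order Butterworth, 3 Hz), twice differentiated, and sign-corrected
  for walking direction so HS appear as acceleration maxima; step/stride
  lengths are ankle-depth differences at heel strikes.
* **Markers** — step/stride/stance/swing, single and double support (per
  stride, from the merged bilateral event train), cadence, average and
  stride velocity, and step/stride length per modality (Weinberg quartic-
  root lengths with distance calibration for the foot sensors).
* **Agreement** — MAE, MAE percentage, Pearson r with two-sided p, and
  Bland–Altman bias with 95% limits of agreement (±1.96 SD), aggregated
  at the subject-trial level.

## Worked example

```r
library(multigait)

cfg <- default_config()
profile <- gait_profile(stride_time_mean = 1.08, stance_fraction = 0.657,
                        step_length_mean = 0.655)
trial <- simulate_trial(profile, cfg, seed = 1)
res <- analyze_trial(trial, cfg)
res$foot$summary
#> Trial summary [single_task], 18 retained strides:
#>           marker     units         mean+/-sd  n
#>         velocity      cm/s 120.490 +/- 0.000  1
#>          cadence steps/min 110.371 +/- 0.000  1
#>        step_time         s   0.543 +/- 0.012 16
#>      stride_time         s   1.087 +/- 0.021 18
#>      stance_time         s   0.712 +/- 0.015 18
#>       swing_time         s   0.375 +/- 0.008 18
#>   single_support         s   0.375 +/- 0.008 18
#>   double_support         s   0.338 +/- 0.009 18
#>    stride_length        cm 131.001 +/- 3.092 18
#>  stride_velocity      cm/s 120.520 +/- 3.220 18
#>      step_length        cm  65.414 +/- 1.531 18
```

The trial summary reports each marker's mean ± SD over retained strides
(strides spanning the turn are excluded). Comparing a modality against
the reference events over a cohort:

```r
report <- run_cohort(default_config(18), seed = 1, tasks = "single_task")
temporal_maep(report$single_task)
#>       foot     kinect     lumbar
#>  0.3189902 10.0244152 12.7629124
```

meaning the foot sensors track the reference temporal markers to a mean
absolute error percentage of about 0.3%, the depth camera to about 10%,
and the lumbar sensor to about 13% under the default noise model.

A file-based interface (`simulate_dataset()` / `run_dataset()`, or
`inst/cli/gaitpipe.R` from a shell) writes and consumes CSV datasets with
a manifest carrying the configuration hash, and reruns are byte-identical
for a fixed seed.

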