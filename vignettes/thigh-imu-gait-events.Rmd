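---
title: "Detecting gait events from a single thigh-mounted IMU"
author: "thighgait developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gait events from a single thigh-mounted IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thighgait)
```

## The problem

Temporal gait parameters — stance and swing fractions, the symmetry index,
single and double limb support — are the basic clinical currency for
assessing a patient's walking, for example someone relearning gait with a
knee–ankle–foot orthosis.  All of them derive from four events per stride:
the ipsilateral initial contact (IC, 0% of the gait cycle) and toe off
(TO), and the contralateral, "opposite" pair (OIC, OTO).  Force plates
measure these directly but only in a laboratory; a single inertial sensor
on the thigh — a location an orthosis brace already occupies — can recover
all four if one is willing to read the contralateral events out of
ipsilateral thigh motion.

`thighgait` implements a threshold-and-zero-crossing detector for exactly
this setting, the temporal parameters it enables, an evaluation layer
against reference event tables, and a waveform simulator that provides
exact ground-truth event times so the whole pipeline is testable without
laboratory data.

## Feature signals and the four rules

The detector consumes three of the six axes: the anterior–posterior
acceleration $a_x$, the vertical acceleration $a_z$ (both mean-centred at
load, which removes gravity for level walking), and the pitch angular
velocity $\omega_y$ (positive = thigh flexion; a left-side sensor is
negated on read so one convention serves both legs).

Two filtered signals are derived, both with second-order Butterworth
filters applied zero-phase (forward–backward):

* **AZbp** — $a_z$ band-passed around its *main frequency* $f_0 \pm 0.5$
  Hz.  For vertical acceleration of gait, $f_0$ is the step frequency, two
  per stride, so AZbp oscillates twice per gait cycle.
* **GYlp3** — $\omega_y$ low-passed at 3 Hz.

The main frequency is the largest magnitude of the zero-padded spectrum of
the mean-removed signal inside 0.5–3 Hz, refined by parabolic
interpolation around the peak bin (bin width ≤ 0.05 Hz).  The cycle
duration is bootstrapped as $2/f_0$ before any events exist and refined
per cycle from successive ICs.

The rules, in detection order:

1. **TO** — local minima of raw $\omega_y$ below a (negative) threshold
   `th_to_gyro`, de-duplicated so that of two minima closer than
   `min_peak_separation` (a cycle fraction) the deeper survives.
2. **IC** — windows are spanned between adjacent local minima of AZbp;
   with two oscillations per cycle every IC falls strictly inside one
   window.  Inside a window, if $a_x$ exceeds `th_acc_x` (an impact is
   present), IC is the earliest local maximum of $a_z$ above `th_acc_z`
   at or after that gating sample; otherwise IC is the largest
   supra-threshold $a_z$ maximum in the window.  The branch taken is
   recorded per event.
3. **OTO** — the first local peak of raw $\omega_y$ after IC plus a delay
   (`oto_delay`, a cycle fraction), searched up to the cycle's TO.
4. **OIC** — the first descending zero crossing of GYlp3 after OTO (an
   exact-zero sample belongs to the crossing), also bounded by the
   cycle's TO.

A cycle missing any event, or violating the strict ordering
IC < OTO < OIC < TO < next IC, is kept but flagged invalid; the first and
last cycles are flagged `edge` (they see filter edge effects) and excluded
from parameter statistics by default.

### Design choices the source material leaves open

* **Zero-phase filtering.**  Whether the original filters were causal is
  unstated; this package targets offline analysis against reference
  events, where any causal group delay would bias every event time in one
  direction, so zero-phase is the default and a `causal` flag exists for
  on-line experimentation.  Zero-phase application squares the magnitude
  response, which is why the band-pass stopband contract (gain ≤ 0.35 two
  Hz off-centre) is comfortably met.
* **IC branch semantics.**  "A peak above the threshold" does not say
  *which* peak in either branch.  We take the earliest supra-threshold
  peak after the gate in the impact branch (impact immediacy) and the
  largest in the fallback branch (prominence).
* **OTO first-peak rule under noise.**  A literal "first local maximum
  after the delay" is fragile: with noise at 10% of signal RMS the rising
  pitch-rate limb grows noise-scale maxima almost every stride, and the
  rule would fire several samples early routinely.  `detect_events`
  therefore applies the same extremum de-duplication used everywhere else
  (keep the more extreme of two candidates closer than
  `min_peak_separation`) before taking the first survivor.  Because OTO
  sits well within a quarter cycle of the search start, the true peak
  always survives pruning; the exported `detect_oto()` defaults to the
  literal rule (`min_separation = 1`).
* **Search bounds.**  OTO and OIC are searched only up to the cycle's
  detected TO, preventing cross-cycle capture.
* **TO and OTO use raw $\omega_y$**; GYlp3 serves only the OIC crossing.

## Threshold calibration

Numeric thresholds are not portable across sensors and subjects, so the
documented workflow is calibrate-then-detect.  `calibrate_thresholds()`
exhaustively scores a grid over (`th_to_gyro`, `th_acc_x`, `th_acc_z`,
`oto_delay`) against reference events with a lexicographic objective:

1. maximise pooled event-matching F1 at ±50 ms,
2. then minimise the mean absolute timing error of matched events,
3. then prefer the point nearest the grid centre
   (range-normalised Euclidean distance),
4. then the lowest grid index.

Ties are thus fully deterministic, and the result does not depend on the
order of the calibration recordings.  The shipped defaults
(`th_to_gyro = -0.5` rad/s, `th_acc_x = 1.5`, `th_acc_z = 3.0` m/s²,
`oto_delay = 0.05`) are smoke-test values matched to the simulator's
default amplitudes.  Note the IC peak threshold must sit *between* the
opposite-contact acceleration peak and the ipsilateral impact peak — the
vertical acceleration peaks at both contacts — which is why its default
and grid range are higher than the AP gate's.

## Temporal parameters

With $T$ the IC-to-IC interval:

| parameter | definition |
|---|---|
| stance | $(TO - IC)/T \times 100$ |
| swing | $100 -$ stance |
| symmetry index | $(OIC - IC)/T \times 100$; 50% = symmetric timing |
| initial DLS | $(OTO - IC)/T \times 100$ |
| single limb support | $(OIC - OTO)/T \times 100$ |
| terminal DLS | $(TO - OIC)/T \times 100$ |
| double limb support | mean of initial and terminal DLS |
| cadence | $120/T$ steps/min (one contralateral step per stride) |

Reporting double limb support as the *mean* of the two periods makes
stance = SLS + 2·DLS hold exactly, which matches how such tables are
conventionally reported (stance ≈ 62%, SLS ≈ 33%, DLS ≈ 14% in healthy
adults); the total is also returned (`dls_total_pct`).  Single limb
support here is ipsilateral single support (OTO→OIC), the only
single-support interval observable from one-sided events.  These exact
identities are asserted to 1e-9 in the tests.

Evaluation follows the usual conventions: error = detected − reference in
ms (negative = early), error rate = error / reference cycle duration
× 100 (%GC), with the enclosing *reference* IC-to-IC interval as the
normaliser; matching is greedy nearest-neighbour within kind at a
tolerance (default half the median reference cycle); outliers are values
beyond 3×IQR from the quartiles of the per-kind millisecond error.

## The simulator: a stated world, not a biomechanical model

`simulate_gait()` exists so that every detector rule has a unique,
exactly-placed trigger with known ground truth.  Per stride (duration
drawn from a normal truncated at half the mean; canonical 1.2 ± 0.05 s):

* $\omega_y$ is a piecewise-cubic Hermite curve through
  (+amp at OTO) → (0, descending, at OIC) → (−0.9·amp at TO) →
  (0, ascending, at mid-swing) → next OTO.  Extremum anchors get slope
  zero; crossing anchors get the steeper adjacent secant, clamped to 3×
  the smaller secant so each segment stays monotone.  The steeper-secant
  choice makes the waveform locally *odd* around the OIC crossing, so the
  zero-phase 3 Hz low-pass does not displace it — the trigger the OIC
  rule consumes lives in the filtered signal, and a simulator that
  guarantees trigger placement must guarantee it there.  (With naive
  mean-secant slopes the filtered crossing lands ~1 sample early and a
  symmetric gait reads ~49.1% symmetry instead of 50 ± 0.5.)
* $a_z$ = amp·cos(4π·phase) — two oscillations per cycle, minima at
  phases 0.25/0.75 bracketing each IC — plus Gaussian impact pulses
  (σ = width/2) at each IC (3 m/s²) and each OIC (1 m/s²).
* $a_x$ = the IC pulses on a 0.3·amp·sin(2π·phase) baseline.
* The unused axes are noise-only.  White Gaussian noise is added per
  channel; `noise_frac` scales the SDs to a fraction of the noiseless
  vertical-acceleration / pitch-rate RMS.
* The recording is padded by half a stride on each side with
  virtual-stride morphology so edge strides keep the minima and windows
  the detector needs; ground-truth times are on the recording clock.

Default event phases (OTO 12%, OIC 50%, TO 62%) reproduce the healthy
regime of ≈62% stance and ≈50% symmetry.  One seed drives everything;
identical spec ⇒ bit-identical output.

**What a green test does and does not establish.**  The simulator
reproduces the morphology the rules rely on — dominant step-frequency
oscillation, impact transients, an anchored pitch-rate shape — with
controllable phases, variability, asymmetry and noise.  It does not model
musculoskeletal dynamics, orthosis mechanics, sensor drift, soft-tissue
artefact or non-Gaussian noise; real impact sharpness and noise spectra of
brace-mounted sensors are unknown here.  Passing tests establish that the
implementation honours its contracts and recovers events in the stated
world, not clinical accuracy on patient data.

## Numerical notes

* Butterworth designs are computed in-package (analog prototype →
  band transform → bilinear, validated against an independent
  frequency-response oracle in the tests); zero-phase filtering uses odd
  edge extension (3× filter order) with steady-state initial conditions,
  so a constant input passes with machine-precision unity gain.
* Local extrema are strict; a plateau counts once at its first sample.
  De-duplication keeps the more extreme candidate, ties to the earlier
  index — everything downstream is deterministic.
* The main-frequency estimator is scale- and offset-invariant and errors
  out on all-zero input or fewer than 4 s of data.
* Event times are `(sample − 1)/rate` in R's 1-based indexing; CSV output
  uses 0-based `sample_index` so `time_s = sample_index / rate`.
* A degenerate cycle with TO at the next IC yields stance 100%/swing 0%
  and a `boundary` flag rather than an error; inverted orderings are
  errors (detected cycles carry `valid = FALSE` instead).

## Known limitations

* Contralateral events are inferred from ipsilateral thigh motion; the
  rules assume broadly alternating gait and will mis-assemble cycles on
  festinating or severely irregular patterns.
* No orientation estimation or sensor fusion: axes are consumed raw, so
  gross sensor misalignment shows up directly in the feature signals.
* No spatial parameters (step length, speed) — nothing here integrates
  displacement.
* The noise-robustness figures quoted by the tests are for white Gaussian
  noise; structured artefacts (brace impacts, cable snags) are out of
  scope.
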