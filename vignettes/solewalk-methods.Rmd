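---
title: "Recognizing daily-life activities from plantar-pressure insoles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing daily-life activities from plantar-pressure insoles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solewalk)
```

## The problem

Instrumented insoles carry seven force-sensing resistors (FSRs) per foot —
heel, lateral/center midfoot, lateral/center/medial forefoot, and big toe —
each calibrated to newtons over roughly 0.2–20 N and sampled at 100 Hz. A
pair of such shoes yields 14 parallel force time series. The question the
package addresses: how well can those signals, alone, recognize what the
wearer is doing across nine everyday activity classes (sitting, standing,
level walking, walking upstairs, walking downstairs, walking up a slope,
running, cycling, office work), and how small can the sensor set and the
feature set be made before recognition degrades?

The pipeline has four stages: signal conditioning, windowed feature
extraction, subject-wise random-forest evaluation, and a three-stage search
over window length, sensor configuration, and feature count.

## Signal conditioning

Raw 12-bit ADC counts are mapped to newtons through a pluggable monotone
calibration curve (`linear_calibration()`, `lookup_calibration()`), clipped
below at 0 N — FSRs cannot pull. No calibration table for a specific insole
is bundled; the synthetic generator produces forces directly in newtons, so
calibration is exercised only through its own contract tests.

Each channel is then smoothed with a second-order low-pass Butterworth
filter, cutoff 5 Hz. We apply it forward and backward (zero-phase), for a
deliberate reason: half the feature set depends on *where* peaks are, and a
causal filter would shift every gait event by a class- and
frequency-dependent lag. The zero-phase pass squares the magnitude response,
$|H(f)|^2 = 1/(1 + (f/5)^4)$, which the tests check against this closed
form. Odd-reflection padding keeps start-up transients out of the output and
makes the DC gain exactly 1.

Windows are cut at lengths of 1–60 s with 50% overlap: consecutive windows
advance by half a window, and a trailing fragment shorter than one window is
dropped rather than padded. A recording shorter than one window contributes
zero windows (participants sometimes cut bouts short); that is a valid,
empty result, not an error.

## The feature catalog

At the full 7-sensor configuration each 20-s window yields 167 features in
five families:

* **General statistics** (4 × 14 channels = 56): mean, maximum, SD, median.
  SDs throughout the package use the population convention (divide by *n*);
  at 2 000 samples per window the distinction is immaterial, but fixing it
  makes results bit-reproducible.
* **Peak analysis** (7 × 14 = 98): peak count, mean/SD inter-peak interval,
  mean/SD peak magnitude, mean/SD peak width. Peaks are plain local maxima
  with plateau midpoints and *no* height or prominence threshold; widths are
  measured at 30% of each peak's absolute height, as the duration of the
  maximal contiguous stretch that stays above that level. A statistic with
  nothing to average (no peaks, a single peak) is set to 0.
* **Gait phase** (2): per foot we build an envelope — the pointwise maximum
  over the foot's available channels — and call the foot "in contact"
  wherever the envelope exceeds 5% of its window maximum, floored at 0.4 N
  (twice the FSR sensing floor). For each full stance (a contact segment
  entirely inside the window) the first envelope peak of the early half
  (landing) minus the last peak of the late half (lift) is averaged over
  stances and feet. The second feature is the mean duration of double-float
  intervals, where neither foot is in contact — the signature of running.
  Both default to 0 when undefined.
* **Frequency domain** (5): from the magnitude spectrum of the sum of all
  available channels — power density (mean squared magnitude over the
  0.05–50 Hz AC band), the magnitude-weighted mean frequency over
  1.67–10 Hz, the skewness of the components strictly below 10 Hz, and the
  mean and SD of the 2–10 Hz AC magnitudes. The 0 Hz bin is always
  excluded; band edges are inclusive; no taper window is applied.
* **Pressure distribution** (6): anterior–posterior — mean(forefoot
  envelope) − mean(heel) averaged over feet, plus the per-foot Pearson
  correlation between the two series; medial–lateral — the same for medial
  (site 6) versus lateral (site 4) forefoot. Correlations of zero-variance
  series are defined as 0.

### Which features a sensor subset affords

Smaller sensor subsets afford fewer features. The per-channel families
scale as 11 features × 2 feet × |sites|. Gait-phase and frequency features
are computed from whatever sites are present (envelopes and sums degrade
gracefully), so they are always available. The anterior–posterior block
requires the heel plus at least one forefoot site (4–7), with the forefoot
envelope taken over whichever forefoot sites are present; the
medial–lateral block requires sites 4 and 6 specifically. This yields the
closed form

```
count = 22·|sites| + 7 + 3·[heel & forefoot] + 3·[sites 4 & 6]
```

which reproduces every published count: 167, 29 (heel only), 54 vs 51 for
the 2-sensor split, 76, 98, 120, 142, the 101/123/145 variants when both
forefoot sites 4 and 6 are present, and a total of 686 feature-count
combinations across the seven best configurations. These identities are the
package's exact acceptance checks. The availability rule for the AP block
is the only one consistent with all the printed pairs, which is why it is
stated in terms of a forefoot *group* rather than all four forefoot sites.

## Recognition protocol

Forests have 100 trees, Gini splits, bagging, and are grown to purity
(`min_node_size = 1`), so each tree casts one vote and the forest decision
is the mode; exact vote ties are broken by lexicographic activity label so
results are deterministic. Candidate features per split default to
√p. Training and evaluation are *subject-wise*: a training set of 6
subjects (drawn only from subjects who completed all nine activities), all
remaining subjects — including incomplete ones — in the test set, repeated
under 5 distinct assignments × 20 random states = 100 forests per
evaluation round. No window from a test subject ever reaches training; this
is asserted at run time, not just tested. Accuracy is correctly predicted
windows over total test windows, unweighted by class; confusion matrices
are row-normalized per forest and averaged, so the diagonal is per-activity
sensitivity TP/(TP+FN).

The three-stage search:

1. **Window length** (`window_length_sweep()`): features are re-extracted
   at each candidate length. The published selection rule — the point where
   the accuracy-versus-length slope flattens — is qualitative; we implement
   it as the smallest length within δ (default 0.01) of the sweep maximum,
   which prefers temporal resolution over a marginal accuracy gain. δ is a
   parameter, not a constant.
2. **Sensor configuration** (`configuration_sweep()`): independent
   evaluation per configuration at the fixed window length, each with its
   own available feature set; both curated lists and exhaustive
   enumeration (`enumerate_configurations()`) are supported.
3. **Feature count** (`rank_and_eliminate()`): features are ranked by mean
   impurity importance across the round's forests; the least informative
   one is removed and the evaluation repeated, down to a single feature
   (or a caller-chosen floor). Ties are broken by catalog order. The
   importance metric is mean decrease in Gini impurity — the natural
   choice for purity-grown Gini forests.

The forest engine is `ranger`; vote aggregation, tie-breaking, the
subject-wise protocol, elimination, and the sweep drivers are package code.

## The synthetic cohort generator

No public recording set accompanies this problem, so the package ships a
generator (`simulate_recording()`, `simulate_cohort()`) that produces the
*statistical structure* the classifier exploits, not biomechanical ground
truth. Gait activities are alternating-foot stance pulses: a trapezoidal
body-weight base with 0.01 s ramps (so contact onset/offset is sharp enough
for timing oracles) plus one raised-cosine bump per site, positioned within
the stance — heel early and forefoot late for level walking, amplitudes
shifted toward the forefoot for slope walking, forefoot-led timing for
stairs, a 10% flight phase for running. Raised cosines were chosen because
their peak counts, chord widths, and envelope timings have closed forms,
which is what the feature oracles test against. Static activities are
constant loads plus slow sway; office work concatenates standing bouts with
short walks. Subject effects are a log-normal weight scale (σ = 0.12) and a
Gaussian cadence offset (σ = 0.05 Hz); all randomness flows from one master
seed through per-subject and per-recording substreams, so cohorts are
bit-reproducible.

Default bout durations are 4 min (8 min for level walking and running,
mirroring the longer field bouts). Default noise is 0.1 N additive Gaussian,
clipped at 0 N.

What the generator does *not* emulate: sensor drift and hysteresis,
cross-talk between sites, shoe-size and placement variability, within-bout
pace changes, transitional movements between activities. Passing the
recovery tests therefore demonstrates that the pipeline is correct and that
the protocol can recover a learnable structure without subject leakage — it
does not certify field accuracy on human recordings.

## Numerical choices and degenerate inputs

* Peak detection on threshold-free local maxima is exact on noiseless
  constructed signals; on smoothed noisy signals every residual ripple
  counts as a peak, exactly as a threshold-free detector behaves on real
  data. Timing oracles (cadence/peak counts, double-float duration) are
  therefore validated on unsmoothed zero-noise signals; the smoothed
  pipeline keeps those features merely *consistent* per class, which is all
  the classifier needs.
* Zero-phase smoothing slightly blurs contact edges, biasing measured
  double-float durations low by a few tens of milliseconds; this is a
  property of any low-pass pipeline, is identical across classes, and is
  documented rather than "corrected".
* Degenerate statistics resolve to 0 everywhere (no-peak summaries,
  zero-variance correlations, empty spectral bands), so feature vectors are
  always finite and complete.
* Spectral magnitudes below 10⁻¹⁰ of the spectrum maximum are zeroed before
  band statistics, so constant signals yield exactly zero features instead
  of FFT round-off dust.
* `power density` is implemented as the mean squared spectral magnitude
  over the AC band — the term is not standardized, so the definition is
  documented and the band is a parameter.

## Problem sizes used by the tests and the acceptance script

The bundled end-to-end checks run a 12-subject cohort, nine activities at
4 min each, 20 s windows, the full 7-sensor configuration, and 2
assignments × 5 random states (10 forests per round) — about 2 500 windows
and a 167 → 20 elimination trace. These sizes were chosen as the smallest
cohort at which subject-wise recovery is stable; the protocol itself is
exercised at the full 5 × 20 = 100-forest shape on a smaller cohort. The
window-length sweep in the acceptance script uses 6 subjects at 1 min per
bout over lengths {1, 5, 10, 20, 30} s.

## Known limitations

* The curated list of 25 sensor configurations used in the original
  three-stage analysis is not fully reconstructible from published
  information; the package exposes the availability rule and the sweep
  driver instead of guessing the missing memberships.
* The exact peak-detection defaults of the reference implementation are not
  knowable; the documented parameter-free local-maxima rule is the
  package's substitute, with its own oracle tests.
* Whether the landing-minus-lift gait feature is kept per foot or averaged
  is not determined by the feature count alone; we average across feet,
  which is what keeps the gait-phase family at exactly two features.
* Class imbalance (unequal window counts per activity) is deliberately left
  unweighted, matching the plain window-accuracy definition.
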