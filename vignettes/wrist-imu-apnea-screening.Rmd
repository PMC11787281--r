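---
title: "Screening for sleep apnea with wrist-worn IMU signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for sleep apnea with wrist-worn IMU signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnimu)
```

## The problem and the signal model

A wrist-worn inertial measurement unit (IMU) — a triaxial accelerometer plus
a triaxial gyroscope sampled at 60 Hz — picks up three superimposed
physiological signatures during sleep:

* **Mechanocardiogram (MCG)**: cardiac-cycle micro-vibrations, the
  seismocardiogram (SCG) on the accelerometer and the gyrocardiogram (GCG)
  on the gyroscope, with spectral content in **4–11 Hz**;
* **Respiratory wrist motion (RM)**: the slow rise and fall of the wrist
  with breathing, in **0.13–0.70 Hz**;
* **Gross body movement (BM)**: position shifts and limb movements,
  summarised in a **2.0–3.0 Hz** band.

Apnea and hypopnea episodes perturb all three: the respiratory motion
amplitude collapses transiently, the breathing and cardiac frequency
structure destabilises around the event, and arousals at event end produce
movement bursts. `somnimu` turns these signatures into fifteen per-epoch
features and trains classifiers to flag the 30-second epochs that contain a
respiratory event (RE). The hourly rate of flagged epochs — the respiratory
event index (REI) — serves as a surrogate for the polysomnographic
apnea–hypopnea index (AHI).

## Decomposition

Each of the six axes is filtered with a linear-phase Hamming-window FIR
band-pass per band. The filter order is set so the transition width is about
half the band's low edge, which keeps the passband gain within 5% of unity
and attenuates one octave outside the band by well over 20 dB; the
respiratory filter at 60 Hz therefore needs roughly 3,000 taps (about 50 s).
The group delay is compensated exactly (symmetric taps, integer delay), so
filtering is zero-phase and events line up across bands. The first and last
half-filter-length samples carry edge transients; the per-band margins are
recorded on the component object, and epochs overlapping them are still
processed (a whole-night recording loses nothing of substance to edges).

Triaxial components are combined by the pointwise Euclidean norm — the only
scale- and orientation-agnostic reduction that needs no calibration. The BM
scalar mixes all six axes; because G and dps are not commensurate, each
sensor's filtered trio is first divided by its whole-recording robust SD
(MAD about zero). The BM feature of an epoch is the in-epoch maximum of this
scalar.

## The frequency stability index

For a power spectrum $P(f)$ analysed on a band $[F_1, F_2]$ with in-band
peak $F_m$, let $S_L$ be the total in-band power and, for a half-width $u$
from 0 to $U = \max(F_m - F_1, F_2 - F_m)$, let
$f_1 = \max(F_1, F_m - u)$, $f_2 = \min(F_m + u, F_2)$,
$S_\omega$ the power in $[f_1, f_2]$ and $R_\omega = S_\omega / S_L$,
indexed by the window width $\omega = f_2 - f_1$. The FSI is the normalised
area under $R_\omega$:

$$\mathrm{FSI} = \frac{1}{L}\int_0^L R_\omega \, d\omega, \qquad L = F_2 - F_1 .$$

A pure tone gives 1; a flat spectrum gives 0.5; power far from the peak
drives it toward 0.

Numerical choices:

* **Spectra** are single periodograms of mean-removed, Hann-tapered
  segments — one FFT per segment, preserving the $1/\mathrm{length}$
  resolution the segment lengths are designed around. Cardiac FSI uses
  32-s segments centred on each 30-s epoch (1 s overlap each side);
  respiratory FSI uses 64-s segments (17 s each side). At recording edges
  segments truncate and the grid adapts.
* **Discrete integration**: bins are treated as point masses; a bin enters
  the window when $|f_k - F_m| \le u$, making $R_\omega$ a right-continuous
  step function that is integrated exactly over the knots the bins induce.
  Under this convention a single-bin spectrum scores exactly 1 and a flat
  spectrum scores exactly 0.5 at any bin count; the two-point-mass case
  (0.6 at 0.25 Hz, 0.4 at 0.75 Hz on a 0–1 Hz band) integrates to exactly
  0.70. Peak ties break toward the lowest frequency.
* **Degenerate segments** (no in-band power, e.g. a flat-lined channel)
  yield a flagged `NA` that per-epoch wrappers convert to 0, so batch runs
  never abort.
* Per epoch, the larger of the two sensors' FSI values is kept (`mcg_fsi`
  from SCG vs GCG; `rm_fsi` from the per-sensor IQR-selected respiratory
  axis), and for `rm_fsi` the axis with the widest in-epoch interquartile
  range is analysed — the axis that actually carries the breathing motion
  for the current posture.

## Envelope dips and their features

The respiratory scalar (RMS) is tracked by two 95th-percentile moving
envelopes: *fast* (3 s window) and *slow* (20 s). A **dip** is a maximal run
where the fast envelope is strictly below the slow one — the fast envelope
collapses with the breathing amplitude while the slow one holds the recent
typical amplitude. Strict inequality defines the run; zero-measure touches
are not dips, and no minimum-width or merge rule is applied. Each dip
carries: width `w`; area between envelopes `abe` and its ratio `rabe` to
the area under the slow envelope; boundary heights condensed to `h_max` and
`h_ratio` = min/max (1 when both are 0); and the maximum depth `ad` with its
relative version `rd`. The relative features (`w`, `rabe`, `h_ratio`, `rd`)
are invariant to rescaling the signal — deliberately, since absolute wrist
signal strength varies with anatomy and band tightness. Integrals use the
trapezoid rule over the samples inside the run, which keeps the
rectangle-dip case analytically exact (`rabe` = 0.5 for a half-depth
rectangle regardless of the sampling grid).

Windows are centred and truncate at the edges; dips touching the first or
last sample are kept but flagged. The windowed percentile runs in compiled
code (an incrementally maintained sorted buffer), since a whole night at
60 Hz is ~1.7 million samples per sensor.

## From dips and FSI to epoch records

Each 30-s epoch receives: `mcg_fsi`, `rm_fsi`, `bm`, and six dip features
per sensor. A dip is assigned to the epoch containing its **end** — the
moment breathing resumes, which is also where scored events are anchored —
and when several dips end in one epoch the one with the greatest `abe`
wins; epochs without dips get zeros. Ground-truth labels follow the same
end rule: an epoch is RE-positive iff at least one annotated event ends in
it. An overlap-based labelling rule is available behind a flag for
sensitivity analysis; the end rule is the default because event-end
anchoring is how multi-epoch events are resolved to single epochs in
practice, and because the post-event recovery breath is the strongest
signature in the data.

## Classification and severity estimation

Subjects are split ~67/33 into training and test groups, stratified by
severity class (AHI cutoffs 5/15/30). Training epochs are balanced to
exactly 1:1 with SMOTE (synthetic minority samples interpolated between
5-nearest minority neighbours in feature space). Five classifier kinds are
provided — logistic regression, random forest, gradient boosting,
k-nearest neighbours and a single-hidden-layer perceptron — each with a
small hyperparameter grid tuned by 5-fold cross-validated AUC inside the
training set (random forest: `mtry`; boosting: depth and rounds at a 0.1
learning rate; kNN: `k` in 5/11/21; MLP: hidden size and weight decay, on
standardised features). The probability threshold for class predictions is
0.5 by default and exposed. Feature selection mirrors a wrapped backward
elimination: features are ranked by single-feature ROC AUC and eliminated
lowest-first, each subset size scored by the out-of-bag accuracy of a
Gaussian naive Bayes classifier over 25 bootstrap repetitions.

Per-subject severity uses the REI — predicted-positive epochs per analysed
hour, the denominator being whole epochs × 30 s since no sleep staging is
attempted — compared with the reference AHI by Pearson correlation and by
screening sensitivity/specificity at the 15/h and 30/h cutoffs applied
directly to the REI.

## What the synthetic generator emulates

`subject_profile()` / `generate_subject()` synthesise a night of 60 Hz
six-axis data: a quasi-periodic respiratory oscillation (frequency wander
as a slow AR(1), per-breath lognormal amplitude, a fixed random 3-D
orientation per sensor with small per-axis phase offsets), a cardiac
impulse train convolved with a damped oscillation at the subject's
resonance frequency, band-limited 2–3 Hz movement bursts, white sensor
noise, and quantisation at the hardware resolutions (0.0153 mG and
0.0000153 dps). Events are placed by a renewal process with a 10-s
refractory gap; their realised count is Poisson around
`target_ahi × hours`, capped at what physically fits (an expected
occupancy beyond 90% of the recording is rejected as an error).

Two event-model choices deserve comment:

* **Deepening suppression.** The respiratory amplitude during an event is
  not held at a constant reduced level but ramps from ~60% of its peak
  depth to the peak (apneas peak at 80–95% suppression, hypopneas at
  60–80%), ending in a 2–3× recovery breath. Besides mimicking progressive
  event deepening, this is what keeps the slow (20 s) envelope strictly
  above the fast (3 s) one across events longer than the slow window: with
  a flat suppressed plateau the two envelopes tie statistically in the
  interior and a 40-s event fragments into two boundary dips.
* **Type differences.** Central apneas destabilise the per-beat cardiac
  resonance (the MCG-FSI signature); obstructive and mixed events retain a
  small anti-phase paradoxical residual. The default type mix keeps the
  79/17/4 obstructive/central/mixed split among apneas with hypopneas at
  55% of events.

Cohorts allocate subjects 20/30/25/25% across the four severity classes
with uniform AHI within each class band — a right-skewed distribution with
a median in the mild range, all classes represented from n ≈ 5 upward, and
an epoch-level positive prevalence around 15–20%.

What the generator does **not** emulate: sleep staging and wake epochs,
oxygen desaturation, cardiorespiratory coupling (respiratory sinus
arrhythmia, stroke-volume modulation), posture-dependent orientation
changes, sensor drift, and the long-tailed artefact zoo of real wrists
(scratching, cables, bed partners). Tests passing on synthetic cohorts
therefore demonstrate that the pipeline recovers the structure it assumes —
band placement, dip geometry, label bookkeeping, severity ranking — not
that clinical performance on real patients is guaranteed.

## Problem sizes and tolerances

The package's own acceptance checks run at desk scale, chosen to exercise
every code path at full signal rates: dip-recovery fixtures use 140-s
scalars at 60 Hz with suppressions of 10/20/40 s over 20 seeded
repetitions (boundary tolerance 3 s, the smear of the envelope windows);
the end-to-end cohort uses 30 subjects × 2-h recordings (20 train / 10
test after the stratified split), on which the random-forest screen is
required to reach test AUC ≥ 0.75 and REI–AHI Pearson r ≥ 0.8 — deliberate
under-asks relative to what the generator's clean contrast produces, so
the checks are robust to seed choice. FSI integration is validated against
a dense Riemann-sum oracle to 10⁻⁶ on random 512-bin spectra.

## Known limitations

* The fast/slow envelope detector produces many small incidental dips in
  steady breathing (the strict-inequality definition has no noise margin);
  discrimination rests on the dip *features* and the classifier, not on
  dip presence.
* `h_ratio`'s min/max convention is a reconstruction; the boundary heights
  are read from the slow envelope at the run's first and one-past-last
  samples, where the envelopes meet at a true crossing.
* REI uses recording time, not sleep time; with low sleep efficiency it
  underestimates the AHI proportionally.
* The per-subject synchronisation offset between annotations and the
  recording is a single scalar; no clock-drift model is implemented.
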