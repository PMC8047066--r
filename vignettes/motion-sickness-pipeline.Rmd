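---
title: "From platform biosignals to motion-sickness classification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From platform biosignals to motion-sickness classification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mssignal)
```

## The experiment this package models

`mssignal` implements the analysis chain of a wave-platform motion-sickness
study: subjects stand on a motion platform synchronized with a virtual sea,
under three protocols — a 60-s static baseline (`P0`, 0 Hz), a 120-s light
sea (`P1`, 1 Hz waves, amplitude 0.6) and a 120-s hard sea (`P3`, 3 Hz,
amplitude 0.5).  The two wave protocols run in four 30-s segments whose
platform movement amplitude follows the fixed 25/50/75/25 % schedule.
During each protocol three biosignals are recorded — 64-channel dry-electrode
EEG at 500 Hz, surface EMG of both gastrocnemii at 1600 Hz, and heart rate —
and after each protocol the subject scores 13 motion-sickness symptoms on a
0/1/2 ordinal scale.  With 28 subjects and one missed 3-Hz session the
canonical cohort holds $28 \times 3 - 1 = 83$ measurements.

The pipeline has five stages, each an exported function family:

1. **Synthesis** (`simulate_cohort()`, `generate_cohort()`) — the study's
   raw recordings are not redistributable, so a controllable generator
   stands in for them.
2. **Feature extraction** (`extract_features()`) — 19 biometric parameters
   per measurement: 5 EEG relative band powers, 2 EMG rectified areas,
   10 EMG relative spectral shares, heart-rate mean and SD.
3. **Index scoring** (`compute_indexes()`) — eight cohort-relative binary
   motion-sickness indexes from the questionnaire.
4. **Univariate screening** (`significance_matrix()`) — Mann–Whitney tests
   of every feature against every index.
5. **Classification benchmark** (`benchmark_all()`) — six classifier
   families under stratified 10-fold cross-validation repeated over 10
   seeds, plus random-forest feature importance.

`run_all()` chains the stages into a reproducible artifact directory.

## The feature model

**EMG.** Each leg's trace is conditioned by a 50th-order linear-phase FIR
band-pass with 40 and 500 Hz edges (Hamming-windowed sinc, the common
default where the design method is otherwise unconstrained).  One
deliberate correction: with 51 taps at 1600 Hz the sinc main lobe is wider
than the 40-Hz low edge, so the textbook design leaks about 7 % of a DC
offset into the output; we subtract the tap mean, which places an exact
spectral null at DC and changes the passband by less than 0.1 %.  Two
feature types follow: the *rectified-signal area* (mean absolute amplitude,
µV) and the *relative PSD* of five equal 92-Hz bands spanning 40–500 Hz,
computed by a single whole-trace FFT periodogram.  Relative shares use the
union of the named bands as denominator, so they are scale-free and sum
to 1 by construction.

**EEG.** The cleanup chain runs in a fixed order: common average reference;
zero-phase 0.1–40 Hz band-pass; mark any channel exceeding 300 µV bad;
reject the whole trial when more than 20 % of channels are bad (a rejected
trial is a *value* carrying its reason — downstream stages treat its five
EEG features as missing); otherwise reconstruct bad channels by
inverse-distance weighting of the four nearest neighbours on an idealized
10-10 layout (shipped as `inst/extdata/eeg_layout_64.csv`; generated from
the standard polar projection, not measured cap coordinates); subtract
per-channel offsets estimated from the subject's static recording; cut
30-s epochs; and drop epochs that still exceed 300 µV — our reproducible
stand-in for manual artifact review.  Band powers use Welch's method with
2-s Hann windows at 50 % overlap: 0.5-Hz resolution (enough for the 0.5-Hz
delta edge) while averaging 29 segments per epoch.  Shares of
delta/theta/alpha/beta/low-gamma (0.5–4, 4–8, 8–13, 13–35, 35–40 Hz) are
normalized per channel, then averaged across channels and epochs.

Two numerical choices deserve a note.  Bands are half-open (`lo <= f < hi`)
so shared edges are counted once.  The 0.1-Hz high-pass edge cannot be
realized by a short FIR, so the EEG filter is the squared magnitude of a
4th-order Butterworth — exactly the response of a forward–backward pass —
applied spectrally; this is numerically identical to time-domain
forward–backward filtering in steady state, has no edge transients, and
filters all 64 channels with one FFT pair.

**HR.** The heart-rate series is consumed as a 1-Hz beats/min sequence;
features are the arithmetic mean and the sample (n−1) standard deviation,
the usual convention for cohort statistics.

## The index model

Each of the eight indexes reduces the 13 ordinal symptom scores in three
steps: (1) a per-measurement scalar — the raw response for General
Discomfort and Dizziness/Vertigo, the mean of the member symptoms for the
stomach (5 items), head (3), fatigue (3), physiological/vegetative
(stomach + general discomfort) and neurological/muscle-strain
(fatigue + head + general discomfort) groups, and for the overall index
the weighted sum

$$\mathrm{SumMS} = 0.2\,\big(\mathrm{GenDis} + \mathrm{Dizz} +
\textstyle\sum_{5}\mathrm{stomach} + \sum_{3}\mathrm{fatigue} +
\sum_{3}\mathrm{head}\big) \in [0, 5.2];$$

(2) the cohort maximum of those scalars; (3) a binary split at one third
of that maximum.  Three decisions were genuinely open and are resolved as
follows.  A value exactly at the threshold is labelled 1 — "above a third
of the maximum" is read inclusively so a symptomatic tie is never labelled
asymptomatic (`tie = ">"` is available; the integer worked examples are
insensitive to the choice).  An all-zero cohort yields all-zero labels.
Binarization is cohort-relative and pooled across all protocols and
subjects, matching the single cohort-wide marginal table the design
implies; a per-protocol split and a frozen-threshold mode (for scoring new
measurements against a reference cohort) exist as options.

## The synthetic cohort generator

Because no raw data are deposited, the generator is a first-class,
tested component, not a fixture.  Each subject draws a latent state:
susceptibility $s \sim U(0,1)$, resting heart rate
$\mathcal N(70, 6^2)$ bpm, a log-normal EMG tone (median 30 µV) and a
log-normal EEG beta gain.  A protocol's *intensity* is defined as wave
frequency × mean platform amplitude (0, 0.44 and 1.31 for the three
protocols) — the product form encodes that faster waves at comparable
amplitude are harder.  Given a `coupling_config()`:

* **EEG** is stationary Gaussian noise with a $1/f$ background plus
  Gaussian spectral bumps at 2, 6, 10, 22 and 37.5 Hz; the beta bump is
  scaled by $1 + \beta_e \, s \cdot \mathrm{intensity}$.  Channels are
  synthesized by drawing complex-Gaussian Fourier coefficients at the
  in-band bins directly — the exact spectral representation of the model,
  and the reason a 64 × 60000 trial costs a single inverse FFT.
* **EMG** is Gaussian noise shaped to a 40–500 Hz envelope per 30-s
  segment; overall amplitude follows
  $\mathrm{tone}\cdot(0.3 + a\,(1 + e\,s))$ with $a$ the segment's platform
  amplitude fraction, and the envelope concentrates toward the 40–132 Hz
  band as the same drive grows — so both the rectified area and the
  low-band share respond to the platform and, when coupled, to
  susceptibility.
* **HR** is baseline + $h\,s\cdot\mathrm{intensity}$ plus an AR(1) drift
  (coefficient 0.9).
* **Symptoms** follow an ordinal threshold model: each score is the number
  of cut points (0.35, 0.9) lying below $g\,s\cdot\mathrm{intensity}$ plus
  independent Gaussian noise (SD 0.3).

The `symptom_gain` $g$ is deliberately an effect parameter: protocol
intensity drives both the signals and the symptoms, so without it a
"null" generator would still couple features to indexes through the
protocol as a common cause, and null-calibration checks would be
impossible.  The presets are `null` (all four effects 0), `weak`
(0.4, 3 bpm, 0.25, 0.6) and `strong` (1.5, 10 bpm, 0.8, 1.4).  `strong`
is calibrated to the *qualitative* regime the study reports — muscle
features dominate both the significance screen and the importance ranking,
EEG band powers shift modestly — not to any printed p-value or metric;
no quantitative effect sizes are available to calibrate against.

All randomness flows from one master seed through a documented
hierarchical scheme (seed → subject → protocol → modality), so any single
recording can be regenerated bit-identically without replaying the
cohort.  `generate_cohort()` materializes full recordings (about 30 MB per
EEG trial — use it for small cohorts); `simulate_cohort()` streams
generation straight into feature extraction, applying the reference and
band-pass to the Fourier coefficients before the single inverse transform.
The two routes agree to numerical rounding (~1e-15), which the test suite
asserts.

### What the generator does *not* emulate

Real dry-electrode EEG nonstationarity, eye/muscle artifacts, electrode
drift, volume conduction between channels (channels are independent given
the profile), true EMG burst structure, and heart-rate/respiratory
coupling.  Passing tests therefore certify the *pipeline* — its
arithmetic, its calibration under a known null, and its ability to recover
planted couplings — not any physiological claim about real recordings.

## Univariate screening

`mann_whitney()` computes U from midranks.  For `min(n0, n1) <= 8` the
two-sided p-value is exact: the permutation distribution of the rank sum
is built by dynamic programming over (doubled) midrank sums, which
enumerates all $\binom{n}{n_A}$ assignments without listing them; the
test suite checks it against literal enumeration for every split of
$n \le 10$.  Larger groups use the normal approximation with tie
correction and a 0.5 continuity correction (checked against
`wilcox.test`).  A constant pooled sample yields $p = 1$.  The 19 × 8
screen reports raw p-values (the presentation convention of the source
analysis), stars at $p \le .05/.01/.001$ strictly — printed tables of this
kind often star inconsistently; we do not replicate such entries — plus a
Benjamini–Hochberg annex column that does not drive the stars.  Display
values are floored at "0.001".  Two-sided alternatives throughout, the
conservative default where sidedness is unstated.

## Classifier benchmark

Six families: random forest, gradient boosting, AdaBoost, RBF-kernel SVM,
k-nearest-neighbours and a multilayer perceptron.  Hyperparameters are
unstated in the source design, so we document defaults and keep them
overridable only through code: 100 estimators for the three ensembles
(`randomForest`, `xgboost` with depth 3 / learning rate 0.1, and an
AdaBoost.M1 of depth-1 `rpart` stumps written in-package because no
boosting-of-stumps package is part of the stack); SVM and KNN (k = 5) on
training-set-standardized features; MLP with one hidden layer of 32 units
and weight decay 1e-3 (`nnet` has no early stopping; decay plus an
iteration cap is the regularizer).  The original tree analysis reports
gain-ratio splitting; none of the R ensembles expose that criterion, so
the library defaults (Gini/gradient gain) stand — a documented divergence
that affects no contract of this package.

Folds are stratified (with 83 rows, unstratified 10-fold splits can lose a
class entirely), every row is tested exactly once per seed, and the
out-of-fold predictions are pooled into one confusion matrix and one ROC
per seed; accuracy, sensitivity and specificity (class 1 = symptomatic)
and the rank-statistic AUCROC are averaged over 10 seeds with their SD.
Continuous scores: class-1 probability for RF/GB/MLP, signed margins for
AdaBoost and SVM, neighbour-vote fractions for KNN.  Rows with missing
EEG features are dropped listwise and counted.  Cross-validation is
ungrouped — three measurements of a subject may land in different folds —
matching the plain k-fold design it reproduces; grouped CV would be the
statistically safer variant and is a known limitation.  Feature importance
trains one forest per seed on the full usable table, averages the Gini
importances and rescales to sum to 100.

Printed headline metrics of the original cohort (e.g. random-forest
accuracy near 75 % for the overall index) are *not* reproducible without
the original recordings; the package's claims are therefore calibration
and recovery properties on its own generator, verified by the test suite.

## Calibration and recovery study design

The test suite runs three simulation studies whose sizes are design
choices of this package:

* **Default cohort** — 28 subjects, one missing 3-Hz session: 83 rows,
  19 complete features.
* **Null calibration** — one 48-subject (144-row) zero-coupling cohort.
  Feature–index p-values are checked for uniformity with 500 replicates
  in which the questionnaire labels are freshly regenerated against the
  fixed feature table, cycling through all 152 cells; conditional on any
  fixed features, independence of the labels makes each p-value uniform,
  so the pooled sample is a valid uniformity check at a fraction of the
  cost of 500 full signal cohorts.  The same cohort supports the
  permuted-label accuracy check and the chance-level AUCROC band
  [0.4, 0.6]; 144 rows keep the null AUC sampling spread near 0.05 so the
  band is meaningful.  The accuracy check is one-sided — no significant
  excess over the majority-class share — because a calibrated classifier
  under permuted labels has expected accuracy $\pi^2 + (1-\pi)^2$, which
  sits *below* the majority share $\pi$ whenever classes are imbalanced;
  the threshold-free AUCROC band is the two-sided chance check.
* **Recovery** — a 200-subject strong-coupling cohort: random-forest
  AUCROC for the overall index must reach 0.80, muscle features must
  dominate the importance ranking with slow-EEG power absent from the
  top 5, and a planted single informative feature among noise must be
  ranked first.

## Known limitations

* The generator's channels are spatially independent; bad-channel
  interpolation is therefore exercised mostly by constructed fixtures.
* EDF input/output is out of scope; recordings travel as CSV with a JSON
  sidecar (rate, labels, modality), which round-trips exactly.
* No multiple-testing correction drives the starring (by design); the BH
  column is advisory.
* Binarization thresholds are cohort-relative: labels change when the
  cohort changes.  This mirrors the source design and is the reason the
  frozen-threshold mode exists for scoring new data.
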