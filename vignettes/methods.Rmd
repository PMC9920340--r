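---
title: "Identifying worker risk conditions from wearable physiology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying worker risk conditions from wearable physiology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physiorisk)
```

## The problem

Fall-detection systems built on accelerometry recognise a fall after the
impact. This package addresses the step before that: recognising that a
worker is *in* a risk condition — here, standing on an unstable surface
that threatens balance — while they are otherwise engaged in ordinary
physical activity. The two situations are nearly indistinguishable from
trunk and head acceleration alone; the discriminative information sits in
the autonomic response visible in cardiorespiratory activity, electrodermal
activity and skin temperature.

The pipeline classifies 2.5 s windows of multichannel wearable recordings
as RISK (balance perturbation on a stabilometric platform) or NON-RISK
(treadmill exertion), across two thermal environments, with
leave-one-subject-out (LOSO) validation and analyses of which sensors and
features carry the signal.

## Protocol formulas

Two scalar formulas anchor the session protocol:

* **Critical heart rate**, the exertion ceiling used to terminate treadmill
  segments: $HR_c = 220 - \mathrm{age}$ for males and
  $HR_c = 206 - 0.88\,\mathrm{age}$ for females (`critical_hr()`). Treadmill
  stages end when the heart rate crosses 60% and 85% of $HR_c$; the
  threshold pair is an argument of `build_schedule()` so a more demanding
  90% stage is also expressible.
* **Environmental risk coefficient**, a heat-stress index:
  $ERC = T + 0.1\,RH$ with $T$ in °C and $RH$ in %RH (`erc()`). Action
  bands (`erc_category()`): unrestricted work at $ERC \le 29$, frequent
  drinking advised in between, avoidance of high-intensity work at
  $ERC \ge 34$. The band edges printed for the middle category are
  internally inconsistent in common references; we use the open interval
  $(29, 34)$, the only partition consistent with the two anchors.

A session (`build_schedule()`) is a 5 min rest baseline followed by three
1 min platform (RISK) segments interleaved with two threshold-terminated
treadmill (NON-RISK) stages at 5 km/h / 6% and 6 km/h / 9%.

## Signal processing

* **Cardiorespiratory.** Heart and breath events are treated as point
  processes. Instantaneous rates invert the inter-event intervals
  ($HR = 60/IBI$). Respiratory events are local maxima of the breathing
  waveform (maximal rib-cage expansion), detected with a prominence floor
  and a minimum separation (`detect_events()`). Heart-rate variability is
  RMSSD — the root mean square of successive inter-beat-interval
  differences. As printed, the sum's index range would read one interval
  past the end of the sequence; we use the standard definition with $N-1$
  successive differences and divisor $N-1$, which is what the metric's
  name denotes. Because a 2.5 s window holds only 2–4 beats, the
  per-sample HRV channel is RMSSD over a trailing 30 s beat buffer
  (configurable), sample-and-held at the recording rate.
* **Electrodermal.** The conductance is denoised with a 5 Hz low-pass
  Butterworth filter; the tonic level (SCL) is the 0.1 Hz low-pass of the
  result and the phasic response (SCR) its 0.1 Hz high-pass
  (`decompose_gsr()`). All filters are 4th order and applied
  forward–backward: zero phase preserves SCR peak timing and makes the
  low/high branches exactly complementary in magnitude
  ($|H_{lp}|^2 + |H_{hp}|^2 = 1$ for same-order Butterworth), so
  SCL + SCR reconstructs the denoised signal. Plain forward–backward
  filtering with zero end-padding produces large boundary transients on a
  signal with a multi-microsiemens level, so the series is extended by odd
  reflection at both ends before filtering and trimmed after. SCR peaks
  are local maxima whose rise from the preceding trough reaches 0.03 µS,
  the permissive end of the conventional 0.03–0.05 µS band
  (`detect_scr_peaks()`).
* **Energy.** The windowed conductance energy integrates the FFT
  auto-spectrum with the normalisation that makes it equal the time-domain
  energy $\sum x^2 \Delta t$ (Parseval); the test suite holds the two
  routes to 10⁻⁹ relative agreement (`gsr_energy()`).
* **Movement.** The two tri-axial accelerometers are summarised per sample
  by the acceleration vector magnitude
  $AVM = \sqrt{a_x^2 + a_y^2 + a_z^2}$ (`avm()`), a rotation-invariant
  norm.
* **Normalization.** HR, HRV, RR, SCL and ST are expressed as relative
  deviations from the subject's 5 min rest baseline,
  $x_{norm} = (x - \bar{x}_{base})/\bar{x}_{base}$
  (`normalize_baseline()`), which removes inter-subject offsets before any
  cross-subject learning. The phasic SCR is excluded: it is zero-mean by
  construction, so the ratio is ill-posed; it enters features in raw µS.
  Whether tonic/phasic splitting should precede or follow normalization is
  not decidable from common practice alone; we decompose first and
  normalize the tonic level only, and document rather than claim that
  choice.

## Windows and feature tables

Features are computed on non-overlapping 2.5 s windows (100 samples at
40 Hz); non-overlap is the only windowing consistent with the bookkeeping
of 320,000 pooled samples → 3,200 windows. Each window yields six
statistics per channel: mean, SD, min, max, and the means of the first and
second finite differences scaled by the sampling rate (so derivative
features are in units/s and units/s², independent of the rate). Windows
that contain baseline samples or straddle a label change are dropped — in
the synthetic study segment lengths are whole multiples of the window, so
nothing straddles and the counts are exact.

The **PHY** table applies the six statistics to HR, HRV, RR, SCL, |SCR|
and ST (36 columns; the absolute value for the zero-mean SCR) plus four
phasic extras — peak count, mean and SD of peak amplitudes, spectral
energy — for 40 columns, tagged by sensor group: CR (18), GSR (16),
ST (6). The printed count of 36 requires six channels although the usual
brace lists five; skin temperature belongs in the statistical block (it is
measured by the same monitoring system) and resolves the count. The
**ACC** table summarises 2 sensors × 4 channels (three axes + AVM) with
{mean, SD, max} for the printed 24 columns; the full 6-statistic variant
(48 columns) stays available via `variant = "full48"`, since the printed
24 cannot arise from all six statistics and the exact composition is not
recoverable — both variants are documented conventions, not claimed
knowledge of the original choice.

## Feature selection

`relieff_weights()` implements ReliefF for binary labels and continuous
features: min-max scaling to $[0,1]$, Euclidean nearest neighbours, and
for every instance the $k$ nearest hits (same class) and misses (other
class) accumulate $|x_f - m_f| - |x_f - h_f|$ per feature, averaged over
$n \cdot k$. All instances are used (no subsampling): the tables are small
and determinism keeps the procedure testable; neighbour ties break by row
order. Weights land in $[-1, 1]$; a perfectly separating binary feature
scores exactly 1. Two finite-sample caveats are worth knowing: an
uninformative feature's expected weight is close to, but not exactly,
zero (neighbour selection couples weakly to every feature), and
duplicating the data set changes weights (each instance's nearest hit
becomes its own zero-distance copy). The default ranking uses $k = 5$;
weights are reported for $k \in \{1, 3, 5, 10\}$.

`optimal_feature_set()` then grows the feature set from the heaviest
feature down, records the median LOSO fold accuracy at each size, and
picks the smallest size attaining the maximum. By default the ranking is
recomputed on each fold's training rows (`per_fold`), so the held-out
subject never influences its own feature selection; a `global` mode is
available for exploratory use.

## Classifiers

Four families behind one train/predict contract (`model_spec()`,
`train_model()`, `predict_model()`), at fixed hyperparameters:
1-nearest-neighbour with Euclidean distance; LDA with a shared covariance;
a Gaussian-kernel SVM with kernel scale 1 and box constraint 1
(`e1071::svm` with `gamma = 1/scale²`, `cost = 1`); and a CART tree with
Gini splits, minimum branch size 10 and minimum leaf size 1 (`rpart` with
`cp = 0`). kNN and LDA standardize features with training-fold statistics
— unscaled nearest-neighbour distances on mixed-unit features are
dominated by whichever column happens to have the largest variance. The
SVM and the tree consume raw features, matching the defaults of the
reference implementations these settings come from; this matters for the
SVM, whose fixed kernel scale of 1 is calibrated to the raw
baseline-normalized feature magnitudes of order 0.1–1. Standardizing
first inflates expected squared distances to about twice the feature
count, the Gaussian kernel vanishes, and the SVM degenerates into a
majority vote — we measured exactly that before making raw features the
SVM default (`standardize` remains an explicit argument for both
behaviours). 1-NN distance ties resolve to the lowest training-row index,
so predictions are deterministic.

## Validation and statistics

`loso_folds()` holds out one subject at a time; a hard test asserts
train/test subject disjointness on every fold. Metrics are accuracy,
precision, recall and F1 with RISK as the positive class (the original
metric tables do not fix a positive class; risk detection makes RISK the
natural choice). Train/prediction wall-clock times are recorded for
information only — they depend on hardware and are never part of any
acceptance quantity.

Paired comparisons use the Wilcoxon signed-rank test at 0.05 with
Bonferroni correction $0.05/n_c$, where $n_c$ is computed from the
comparison list actually run. With eight folds the normal approximation is
poor and fold accuracies routinely tie, which rules out the classical
exact tables; `paired_wilcoxon()` therefore enumerates all $2^m$ sign
assignments of the (tied-average) ranks for $m \le 16$ non-zero
differences — exact under ties — and falls back to the corrected normal
approximation above that. Comparisons are paired by fold: under LOSO the
fold (subject) is the natural blocking unit.

The sensor-ablation analysis (`sensor_ablation()`) evaluates each family
on the seven sensor-group subsets I–VII (full PHY down to single-sensor
tables); the environment analysis (`environment_split()`) scores each
fold's E1 and E2 test windows separately and compares them pairwise.

## The synthetic study

No recording of this protocol is publicly deposited, so
`generate_study()` produces one: 8 subjects (4 male, 4 female, ages from a
rounded Normal(24, 2.6) clipped to 18–35) × 2 environments × 20,000
labeled task samples at 40 Hz — 320,000 samples, 3,200 windows. The rest
baseline is recorded *in addition to* the 20,000-sample task budget: a
500 s task session cannot contain a 300 s baseline plus 180 s of platform
time, so the budget is taken to count the labeled task samples, and
baseline windows never enter the feature tables.

What it emulates:

* heartbeats and breaths as point processes whose instantaneous rates
  follow first-order dynamics toward segment targets (treadmill: the HRc
  threshold plus a margin, so crossing terminates the segment; platform: a
  sympathetic +12 bpm shift over the recovering trajectory with 1.8×
  inter-beat jitter and +6 breaths/min), projected to the 40 Hz grid by
  sample-and-hold of the last completed interval, exactly how wearable
  monitors report instantaneous HR/RR;
* electrodermal activity as a tonic level (baseline + heat offset + drift
  + slow wander) plus phasic events at label-dependent Poisson rates
  (10/min under RISK vs 2/min otherwise) with a bi-exponential kernel
  (1 s rise, 4 s decay) — the standard phenomenological SCR shape; the
  protocol defines no generative form, so this is a modelling choice;
* heat stress in E2 as +1.5 °C skin temperature, +0.5 µS tonic offset and
  a 0.10 µS/min tonic drift (vs 0.02 in E1), with ambient traces drawn
  around the recorded E1/E2 temperature and humidity summaries;
* accelerometry whose oscillation amplitude is drawn from one class-shared
  distribution for platform and treadmill segments alike
  (`acc_class_overlap = 0.97` leaves 3% of platform segments with reduced
  sway), so motion alone is nearly uninformative — the empirical situation
  that motivates physiological sensing here.

Segment lengths round up to whole windows; treadmill stages are capped so
each session fits its budget, and leftover budget becomes NON-RISK
walking. All randomness descends from one study seed through per-recording
substreams; the same seed reproduces byte-identical CSVs.

Effect sizes between RISK and NON-RISK are nowhere quantified in the
protocol's source material; the defaults above are plausible sympathetic
responses chosen once, and are parameters of `effect_config()`, not
claims. What passing tests on this generator show is that the *pipeline*
recovers structure it is pointed at — formula fidelity, selection and
validation mechanics, direction of effects; they cannot certify
performance on real recordings, where motion artifacts, sensor detachment,
non-stationary baselines and individual response heterogeneity are all
absent from the simulation. No morphological ECG, no thermoregulatory
dynamics, no gravity component in the accelerometer model.

### Null calibration

`null_effects()` removes every class-informative mechanism: risk shifts,
the exertion HR/RR response, heat and time drifts (segment order is
deterministic, so *any* time-varying process would leak the label), and
class-specific sway. Null studies use a class-balanced schedule variant
(equal platform and treadmill time): a chance-level check is only
interpretable at matched priors, since with the protocol's 36/64 class
split a prior-following classifier sits at 0.64 regardless of signal.
The acceptance band around 0.5 is binomial on the fold's window count
deflated by a design effect of 3 — windows within a segment share the
segment's slowly varying state, so the effective number of independent
windows is smaller than the count.

## Problem sizes used by the test suite

Structural checks run one full-scale study (8 × 2 × 20,000 task samples).
The stochastic checks (null calibration over 10 seeds, direction recovery
over 10 seeds) use scaled sessions — 30 s platforms, 150 s task budgets
(180 s balanced for the null) — which keep every mechanism intact at 60–72
windows per recording; these sizes are the package's desk-scale defaults
for simulation-heavy work.

## Known limitations

* The ACC feature composition (24 columns) and the six-channel statistical
  block are documented conventions matching the printed counts; the
  original compositions are not recoverable.
* ReliefF weights carry small finite-sample biases (see above); rankings
  are robust to this in practice, point values of near-zero weights are
  not.
* The SVM at kernel scale 1 is sensitive to feature scaling by
  construction; use `standardize = TRUE` only with a retuned kernel scale.
* Timing measurements are environment-dependent and informational.
* The synthetic generator is a verification instrument, not a claim about
  human physiology; every effect size is a tunable default.
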