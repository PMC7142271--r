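---
title: "From multichannel EEG to connectivity images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From multichannel EEG to connectivity images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fcnet)
```

## The problem this package addresses

Resting and task EEG capture the joint dynamics of many cortical sources at
millisecond resolution. A widely used way to summarize those dynamics is
*functional connectivity*: for every pair of electrodes, a scalar describing
how strongly the two signals co-vary inside a frequency band. The resulting
symmetric channels-by-channels matrix can be studied two ways, and `fcnet`
implements both ends of that pipeline:

1. **As a graph.** Thresholding the matrix yields a binary network whose
   clustering coefficient `C` (local segregation) and characteristic path
   length `L` (global integration) can be compared against matched random
   networks, giving the small-world index `S = (C/Cr)/(L/Lr)`. Deviations
   of `S` from healthy norms — e.g. longer path lengths and weaker
   clustering — have been reported across psychiatric and neurological
   conditions, including depression.
2. **As an image.** The strictly-upper triangle of the matrix, read line by
   line, is reshaped into the largest square that fits and handed to a
   small convolutional network that learns to classify subjects (for
   example, mildly depressed vs. healthy) from single trials, under
   subject-wise cross-validation.

Because clinical EEG datasets are rarely redistributable, the package ships
a synthetic generator producing epoched multichannel signals with *known*
band-specific phase coupling. Every downstream stage can therefore be
tested against ground truth, and the full experiment can be rehearsed
end-to-end on data whose separability is under the analyst's control.

## Connectivity estimators

All four estimators operate per trial on band-limited signals. Band limits
are half-open intervals `[f_lo, f_hi)` in Hz with the usual defaults: delta
1–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–70 (`eeg_bands()`).

* **Coherence** `|⟨S_xy⟩| / sqrt(⟨S_xx⟩⟨S_yy⟩)`: cross- and auto-spectra
  are averaged over Hann-tapered windows *inside* the trial (default 1 s,
  50 % overlap, so a 6 s trial contributes 11 windows), then the
  per-frequency coherence is averaged over the FFT bins whose centers fall
  in the band. A single window would make the estimator identically 1, so
  fewer than two windows is an error. Windowing choices are exposed as
  arguments; the defaults trade frequency resolution (1 Hz) against enough
  averaging units for a per-trial estimate.
* **Correlation**: Pearson correlation of the band-filtered time series.
  The signed value is retained on the matrix; thresholding and imaging use
  the magnitude, since the threshold sweep runs over `(0, 1)` and image
  pixels are nonnegative.
* **PLV** (phase-locking value): modulus of the time-averaged unit phasor
  of the instantaneous phase difference. Phases come from the analytic
  signal (frequency-domain Hilbert transform) of the band-filtered series.
* **PLI** (phase-lag index): absolute time-average of the sign of the
  phase difference wrapped to `(-π, π]`. The wrapping convention is what
  makes the sign meaningful; `sign(0) = 0`. The PLI ignores zero-lag
  coupling — the property that makes it robust to volume conduction — so
  perfectly locked zero-phase pairs score 0.

For the phase metrics the first and last 0.5 s of each trial are excluded
(`trim_s`), because analytic-signal phase estimates are unreliable near
epoch edges. The trim is configurable and is not applied to coherence or
correlation.

Filtering is a 4th-order Butterworth band-pass applied forward and
backward (zero phase), the standard EEG practice that leaves phase
relations intact for PLV/PLI. The forward–backward pass is implemented in
compiled code with odd-reflection padding of `3 × (taps − 1)` samples. The
choice of time-domain filtering (rather than spectral masking) for the
band-limited series is a deliberate interpretation; it is the common
reading when instantaneous phase is subsequently taken via the Hilbert
transform.

## Graph analysis

`binarize()` places an edge where the connectivity value strictly exceeds
the threshold `T` (a value exactly equal to `T` gives no edge). The sweep
grids are `seq(step, 1 - step, step)` with `step = 0.025` for coherence,
correlation and PLV, and `step = 0.005` for the PLI, whose values are an
order of magnitude smaller.

Node clustering follows the triangle definition `2 e_i / (k_i (k_i − 1))`
with `C_i = 0` for degree below 2; `L` is the mean shortest-path length
over *connected* ordered pairs. Excluding infinite distances (rather than
failing, or substituting the harmonic mean) keeps the sweep defined at
sparse thresholds; each row records how many pairs were excluded so the
analyst can judge how disconnected the graph was. Random references are
uniform `G(n, m)` graphs with the node and edge count of the observed
network (20 per network by default, seeded); `Cr`/`Lr` are their means, and
`S = (C/Cr)/(L/Lr)`. At extreme thresholds `Cr` can be 0 and the index is
reported as missing rather than fabricated.

Group comparisons use subject-level networks: a subject's trial matrices
are averaged first, binarized at a fixed `T` (0.15 is the conventional
operating point for electrode-wise comparisons), and per-electrode
clustering coefficients are compared across groups with Welch two-sample
t-tests. p-values are reported uncorrected — matching the tabulated
convention this analysis reproduces, with flags `**` (p < 0.05) and `*`
(0.05 ≤ p < 0.1) — and an FDR-adjusted column is included alongside so the
corrected view is always available.

## Matrix-to-image encoding

For `n` channels the strictly-upper triangle holds `n(n−1)/2` values;
row-major ("line by line") enumeration places every pair involving the
last channels at the tail. The image side is `floor(sqrt(n(n−1)/2))` and
the tail beyond `side²` is discarded: for 128 channels, 8128 values give a
90 × 90 image and the 28 dropped values are exactly the pairs among
channels 121–128 — the facial electrodes most affected by myogenic and
ocular artifacts, which is why dropping the tail (rather than the head) is
the sensible orientation. Row-major order is load-bearing here: it is the
only enumeration for which the discarded set is precisely those pairs.
Pixel values stay on the metric's natural scale; no per-image
normalization is applied by default (metrics are already bounded), though
the classifier accepts externally normalized images unchanged.

Three-channel images stack the three best single-band images of one metric
as R, G, B in descending single-band accuracy. The stacking function
records the band order and refuses mixed metrics or mismatched sides.

## The classifier

The CNN is intentionally small: two stacked 3 × 3 convolutions (32 filters,
stride 1, one-pixel padding) → ReLU → one 2 × 2 max-pool with stride 2 →
fully connected 512 → ReLU → dropout 0.5 → fully connected 2 → softmax.
A 90 × 90 input therefore flattens to 45 × 45 × 32 = 64 800 features. The
single pooling stage requires an even input side; odd sides are rejected
with an explicit message rather than silently cropped.

Training is Adam (learning rate 10⁻³, moment decays 0.9/0.999) on the
cross-entropy loss, batch size 30, 15 epochs, Xavier-uniform
initialization. Early stopping keeps the weights of the epoch with the
best validation accuracy inside the fixed 15-epoch budget (no patience
abort); with no validation set the final weights are kept and a warning is
raised. Dropout is applied after the hidden fully connected layer only.
All stochastic elements (initialization, shuffling, dropout masks) are
driven by R's RNG from a single seed, so a run is exactly reproducible.
The forward/backward passes run in single precision through compiled
im2col + BLAS routines; gradients are verified in the test suite against a
double-precision reference implementation written independently in R.

## Evaluation protocol

`make_subjectwise_folds()` builds leave-one-pair-out folds: with two
balanced groups of `n`, fold *i* tests the *i*-th subject of each group
(by sorted id), validates on the cyclically next pair, and trains on the
rest — with 24 subjects per group that is 44 training subjects per fold.
No subject ever contributes trials to two sets; the constructor enforces
this structurally. The pairing rule (sorted ids, cyclic-next validation)
is a convention chosen for determinism; the protocol it implements only
fixes the set sizes.

Classification is per trial: each test trial's image is classified
independently, a repeat's accuracy is the fraction of correct test trials
pooled over folds, and the headline numbers are the mean ± sd over
repeated runs (9 by default) that differ only in their seeds. ROC curves
are computed per repeat from the pooled case-class probabilities with
trapezoid AUC; `autoplot()` shades the per-repeat curves under the
vertically averaged mean curve.

Baseline classifiers consume the per-trial mean of the upper-triangle
values (one scalar per band; three bands give an N × 3 table): naive
Bayes (standing in for a Bayesian-network classifier), logistic
regression, kNN at k = 1, 5, 10, and a random forest, all at default
settings, under the same folds; the customary summary is the best accuracy
across classifiers. Baselines have no early stopping, so the validation
pair joins their training set.

## The synthetic generator

Each channel carries an independent *narrowband stochastic oscillator*:
white Gaussian noise band-filtered to the target rhythm, normalized to
unit variance. Filtered noise rather than a sinusoid is essential — pure
tones would drive every estimator to saturation and make every test
trivially pass. For each coupled pair a shared carrier is mixed into both
channels with weight ρ (`strength`), the second copy rotated by the
specified lag through the analytic signal, and the channel's own carrier
is scaled by `sqrt(1 − Σρ²)` so variance is preserved. Broadband Gaussian
noise of standard deviation `noise_sd` is added throughout, and an
optional shared slowly varying envelope induces amplitude correlation.

This construction gives analytic ground truth at the extremes — ρ = 1 with
no noise yields PLV = 1 exactly, and a π/2 lag yields PLI = 1 — and a
monotone PLV–ρ relationship in between (a property test checks the rank
correlation across a 5-point grid). Per-subject seeds are derived
deterministically from the master seed (a Lehmer-style integer hash), so
cohorts are bit-reproducible while subjects remain independent streams.

What the generator does *not* emulate: volume conduction and field spread,
1/f background spectra, artifacts (blinks, EMG), electrode geometry, or
nonstationarity across trials. Passing tests on synthetic cohorts
therefore demonstrate that the pipeline's machinery is correct and
calibrated, not that any particular clinical effect is detectable in real
recordings.

One idealization worth flagging: for *uncoupled* channels the phase
differences are not independent across samples (band-filtering makes
phases heavily autocorrelated, and even broadband analytic phases retain
some dependence), so the null PLV is larger than the iid
`E|mean of n unit phasors|` closed form. The test suite calibrates nulls
against a resampling oracle that reimplements the estimator definition in
plain R instead.

## Reference experiment and problem sizes

The packaged reference experiment (`alpha_coupling_cohort()`) uses two
groups of 12 subjects, 30 epochs of 6 s at 250 Hz and 32 channels, with 10
disjoint channel pairs coupled in the alpha band at strength 0.15 for
controls and 0.85 for cases over broadband noise of 0.5 — parameters fixed
once as a clearly separable regime (effect sizes for real group
differences are unknown, so the synthetic effect is a free design choice,
not a calibration to any study). The 32-channel matrix yields 22 × 22
images. The matched null sets the case coupling back to 0.15, making the
groups exchangeable. Under 12-fold subject-wise CV with 3 repeats the
effect condition should classify nearly perfectly and the null should stay
inside chance bounds computed at subject resolution (24 subjects), which
is the honest effective sample size given within-subject trial
correlation. These sizes are the package's own scaled reference
conditions; the estimators and classifier accept the full 128-channel,
24-per-group geometry unchanged.

```{r example}
spec <- alpha_coupling_cohort(seed = 1)
cohort <- generate_cohort(spec)
images <- cohort_connectivity(cohort, "plv", "alpha") |>
  connectivity_images()
cv <- run_cv(images, cnn_config(in_channels = 1), n_folds = 12,
             repeats = 3, seed = 2)
glance(cv)
autoplot(cv)
```

## Numerical choices and degenerate inputs

* Phase wrapping `(−π, π]` via `π − (π − Δ) mod 2π`; `sign(0) = 0`.
* Symmetry is enforced to 1e−10 and matrices are symmetrized by averaging
  with their transpose after floating-point assembly.
* Softmax is log-sum-exp stabilized; probabilities sum to 1 within 1e−9
  even for logits of ±1000.
* Zero-variance channels make correlation undefined and raise an error
  naming the offending channels; NaN/Inf samples are rejected at container
  construction with the trial/channel index.
* Edgeless graphs have no path length (error); empty graphs inside a
  threshold sweep become `NA` rows instead, since hitting them mid-sweep
  is routine.
* Ties in max-pooling resolve to the first element scanned
  (column-major); ties in classification argmax resolve to the first
  class. Both choices are deterministic.

## Known limitations

* The EDF reader covers the common continuous 16-bit single-rate layout
  only — enough for interchange and testing, not EDF+ annotations.
* Artifact removal is a pluggable hook (`clean()`), not an implementation;
  synthetic data is clean by construction and real preprocessing pipelines
  typically delegate this to dedicated ICA tooling.
* Graph metrics are binary-graph metrics; weighted variants and
  directed/effective connectivity (partial directed coherence, Granger
  tools) are out of scope.
* The random-network null is edge-count matched, not degree-sequence
  matched; with degree-preserving rewiring the `γ` baseline would shift
  slightly.
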