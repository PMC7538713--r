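---
title: "Interhemispheric asymmetry and cross-correlation features for EEG-based depression screening"
author: "eegmdd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{eegmdd methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Resting-state EEG of people with major depressive disorder (MDD) differs
from healthy controls (HC) in at least two well-replicated ways: the
balance of band power between hemispheres — frontal alpha asymmetry being
the classic marker — and interhemispheric connectivity. `eegmdd`
implements a screening pipeline built on exactly these two families of
features, computed per short epoch over 28 symmetric electrode pairs of a
64-channel 10-20 montage and three frequency bands (theta 4–8 Hz, alpha
8–13 Hz, beta 13–40 Hz):

* **Interhemispheric asymmetry.** For a pair with left-electrode band
  power $P_L$ and right-electrode band power $P_R$ (Welch estimates,
  integrated over the band),
  $$A = \ln P_L - \ln P_R .$$
  Positive values mean more power on the left. The statistic is
  scale-invariant (amplifier gain cancels) and antisymmetric under
  swapping hemispheres.

* **Cross-correlation.** For the band-limited signals $x, y$ of a pair,
  the full discrete cross-correlation sequence
  $r[\tau] = \sum_t x[t]\,y[t+\tau]$ is computed over all lags
  $\tau \in [-(n-1), n-1]$, min–max normalized to $[0,1]$, and the
  normalized value **at lag 0** is the scalar feature
  $$R_0 = \frac{r[0] - \min_\tau r[\tau]}
               {\max_\tau r[\tau] - \min_\tau r[\tau]} .$$
  $R_0 = 1$ exactly when alignment (lag 0) attains the sequence maximum.
  The normalized *maximum* would always be 1 and carry no information;
  lag 0 — simultaneity, which is what "connectivity between mirror
  electrodes" means physically — is the one defensible scalar reduction,
  and we flag this choice prominently because the normalization makes
  $R_0$ a *relative* quantity: it measures where the lag-0 correlation
  sits within the sequence's range, not absolute coupling strength.

* **Feature fusion.** With coefficients $k_1, k_2 \in [0,1]$,
  $k_1 + k_2 > 0$ (defaults 0.5 each),
  $$\mathrm{MIX1} = \tfrac{k_1}{k_1+k_2} F_1 + \tfrac{k_2}{k_1+k_2} F_2,
    \qquad
    \mathrm{MIX2} = \tfrac{k_1}{k_1+k_2} F_1 - \tfrac{k_2}{k_1+k_2} F_2,$$
  applied cell-wise to the asymmetry matrix $F_1$ and cross-correlation
  matrix $F_2$ of each band. With $k_1 = k_2$ the pair $(\mathrm{MIX1},
  \mathrm{MIX2})$ is an invertible linear map of $(F_1, F_2)$ — no
  information is lost, the representation is merely rotated. $F_1$ is
  unbounded while $F_2 \in [0,1]$; the formulas are applied on these raw
  scales by design, so MIX layers inherit mostly-$F_1$ variance. An
  optional z-scoring switch exists in the classifiers (below) where
  scale actually matters.

Per epoch, each feature fills a 7 × 4 spatial grid (one cell per
electrode pair). Single-feature tensors stack the alpha, beta, theta
layers (7 × 4 × 3); mixed tensors stack MIX1 and MIX2 of each band in
the order alpha, beta, theta (7 × 4 × 6).

## Preprocessing choices

**Re-referencing** to the averaged mastoids (M1/M2, configurable alias
TP9/TP10) runs before filtering, matching the acquisition description
order of mastoid-referenced clinical recordings.

**Band-pass filter.** A windowed-sinc (Hamming) FIR, pass band
0.5–47 Hz. The transition width is 0.5 Hz at the low edge (where a
narrow transition is needed to separate 0.5 Hz from DC drift) and 4 Hz
at the high edge, giving a high-pass of ~1650 taps and a low-pass of
~200 taps at 250 Hz, cascaded. Application is zero phase — important
because the cross-correlation feature depends on inter-channel timing —
implemented as a single FFT convolution with the kernel's
self-convolution, which is algebraically the forward–backward response;
edges are handled by signal reflection. The squared response is down
more than 40 dB at 0.1 Hz and 55 Hz (`bandpassResponse()` verifies
this), and recordings shorter than three filter lengths (~22 s at
250 Hz) are rejected rather than filtered badly.

**Segmentation** cuts non-overlapping 1, 2 or 3 s epochs (other
durations are allowed with a warning); the trailing remainder that does
not fill an epoch is discarded so all epochs have equal length. ICA
artifact removal is out of scope — a user-supplied epoch-rejection hook
(`segmentEpochs(reject = ...)`) is the supported attachment point, and
surviving epochs are re-indexed contiguously.

**Spectral estimation.** Welch's method with Hamming windows, segments
of `min(epoch length, 256)` samples, 50% overlap, a 1024-point
(zero-padded) FFT grid, per-segment mean removal, and one-sided density
normalization so the integral over frequency equals mean power. Band
power integrates the piecewise-linear density from the exact lower to
the exact upper band edge (interpolated endpoints), so adjacent bands
tile the spectrum without gaps or double counting. Band *extraction*
for the cross-correlation input uses FFT masking: zero every bin outside
$[low, high)$ (beta closes its 40 Hz edge; the half-open convention
prevents the shared 8 and 13 Hz bins from being counted twice) and
invert. Both paths exist deliberately: band power needs a density
estimate, cross-correlation needs a time-domain band-limited signal.

## The synthetic cohort generator

Clinical recordings of this kind are not publicly shareable, so the
package ships a generator whose statistical structure is exactly what
the analysis measures. For each band $b$ and each symmetric pair,
narrowband Gaussian sources with unit *expected* RMS (FFT-masked white
noise — noise rather than sinusoids, because pure tones make the
min–max-normalized cross-correlation trivially periodic) are mixed as

$$x_L = a_b\, e^{+\delta_b/4} \left( \sqrt{\rho_b}\, s +
        \sqrt{1-\rho_b}\, p_L \right), \qquad
  x_R = a_b\, e^{-\delta_b/4} \left( \sqrt{\rho_b}\, s +
        \sqrt{1-\rho_b}\, p_R \right),$$

with $s$ shared and $p_L, p_R$ private. Because power scales as the
squared amplitude, the left–right log-power difference is exactly
$\delta_b$ in expectation — the exponent $\delta/4$ (not $\delta/2$) is
what makes the downstream asymmetry estimator recover the injected value
rather than twice it. $\rho_b \in [0,1]$ is the shared-variance
fraction, which the cross-correlation feature increases in. Source
scaling is analytic (divide by the square root of the kept-bin
fraction), **not** a per-realization normalization: forcing every
realization to exactly unit RMS would pin each recording's total band
energy, make epoch powers within a subject negatively correlated, and
render group-level tests conservative — a stationary process's natural
chi-square energy fluctuation is part of the null the ANOVA calibration
checks. Independent 1/f background noise (FFT-shaped, spectrum
flattened below 1 Hz, also analytically scaled) is added per channel;
M1/M2 carry 1/f noise only. Optional blink-like
artifacts (one windowed 0.5–2 Hz sine cycle, 40 µV, frontal channels)
are off by default and exist to exercise the band-pass filter.

Defaults are the study conditions the pipeline is evaluated under: 16 +
16 subjects, 180 s at 250 Hz, band RMS amplitudes (theta, alpha, beta) =
(4, 5, 3) µV against a 1 µV 1/f background — amplitudes chosen so
in-band background power is ≪ oscillation power and the log-power bias
it causes stays well under the ±0.1 recovery tolerance — with alpha
asymmetry $\delta_\alpha = 0.5$ in the MDD group (0 in HC) and coupling
$\rho = 0.5$ (MDD) vs $0.2$ (HC) in every band. 250 Hz is a free choice
(it covers the 40 Hz band edge with ample margin and keeps simulation
cheap), not a claim about any particular acquisition system. Per-subject
seeds are `seed + subject index`, so any subject is reproducible in
isolation.

**What the generator does not emulate** — and hence what green tests do
*not* establish about clinical data: volume conduction and realistic
source geometry, non-stationarity (drowsiness, drift), muscle/cardiac
artifacts, per-subject idiosyncrasies beyond sampling noise, and any
realistic effect-size distribution across pairs (the injected effect is
uniform over pairs within a band). Passing the discrimination tests
shows the pipeline recovers the structure it assumes, at the stated
sizes — not that clinical accuracy figures transfer.

## Statistics

Group differences are screened cell-wise — one two-group one-way ANOVA
per (pair, band, feature kind), i.e. 28 × 3 × 4 = 336 tests — via
`stats::oneway.test(var.equal = TRUE)`. The default unit of analysis is
the **epoch**, pooled across subjects within a group, which mirrors how
pooled-epoch classification studies count their samples but inflates the
effective n (epochs of one subject are not independent evidence about
the population); `unit = "subject"` tests subject means instead and is
the statistically conservative choice. No multiple-testing correction is
applied by default — reproducing the raw-threshold convention — with
`adjust = "BH"` available. Flags: `*` for $p < \alpha$ (default 0.05),
`**` for $p < 0.01$; values below 0.001 also print `**` since the flag
vocabulary has no third level.

## Classifiers and evaluation

All three classifiers consume the per-epoch tensors; MDD is the positive
class everywhere.

* **KNN**: Euclidean, $k = 7$ (odd, so binary votes cannot tie).
* **SVM**: polynomial kernel $(\gamma u^\top v)^3$ with $\gamma = 2$,
  $C = 1$ ($C$ is not specified by the feature design; 1 is the
  conventional default). The configured 30,000-iteration budget is
  recorded but libsvm terminates on its convergence tolerance.
* **CNN**: two 2 × 2 × L convolution kernels with shape-preserving
  padding and ReLU, 2 × 2 max pooling at stride 1 (also shape
  preserving — the stated flatten length of 56 = 7 × 4 × 2 forces
  same-padding in both layers), dropout 0.5 on the flattened layer,
  dense softmax over two classes, cross-entropy loss, Adam. Training
  protocol: learning rate 0.01, batch 32, 30 epochs, fixed seed. The
  rate was chosen because 0.001 demonstrably underfits this
  few-hundred-parameter network within 30 epochs on cleanly separable
  inputs (gradients were verified against numerical differentiation);
  0.01 trains it to convergence without instability.

KNN and SVM operate on the flattened tensor (84 or 168 values),
z-scored per feature with statistics fitted **on the training fold
only** (the polynomial kernel with $\gamma = 2$ is scale-sensitive;
fitting the scaler on all data would leak). The CNN sees raw tensors.

**Cross-validation**: shuffled 10-fold, repeated (10 by default),
fold sizes differing by at most one, per-repeat seeds derived
deterministically from the pipeline seed. The default `splitUnit =
"epoch"` lets epochs of one subject span training and test folds —
faithful to pooled-epoch evaluation but optimistic about generalization
to unseen subjects; `splitUnit = "subject"` is provided and recommended
when subject-level generalization is the question. Metrics are accuracy,
sensitivity (MDD recall), specificity (HC recall) and F1, each reported
as mean ± standard error over all repeat × fold cells; a metric with a
zero denominator in a fold is NA, not silently zero.

## Numerical and degenerate-input choices

* Cross-correlation uses FFT products at the next power of two ≥ 2n−1,
  so circular wrap-around never aliases a lag; agreement with an
  explicit all-lags loop is tested to 1e−10.
* A constant (all-equal) cross-correlation sequence makes the min–max
  normalization undefined; this raises an error naming the pair and
  band rather than returning a conventional value.
* Asymmetry requires strictly positive powers (log); zero or negative
  power errors out.
* EDF output is 16-bit with per-channel physical scaling, so round-trip
  error is bounded by (channel range)/65535; physical bounds are
  re-parsed from their written 8-character fields before scaling so the
  file is self-consistent.
* Ties in the CNN's softmax argmax resolve to the first class;
  dropout is inverted (scaling at train time), disabled at prediction.

## Problem sizes used by the tests

The acceptance-style tests and `scripts/acceptance.R` evaluate the
discrimination properties on the full study conditions (16 + 16
subjects, 180 s, 2 s epochs → 2,880 epochs) with cross-validation at 10
folds × 3 repeats; ANOVA type-I calibration uses ten independent null
cohorts of 5 + 5 subjects × 30 s (3,360 tests), with replicate seeds
spaced widely because per-subject seeds are `base + index` and nearby
base seeds would share subjects; the null-classification check uses an
8 + 8 × 60 s cohort. These sizes are the package's chosen trade-off
between statistical resolution and simulation cost.

## Known limitations

* The lag-0-of-normalized-sequence reduction of the cross-correlation is
  one defensible reading of an ambiguous construction; results are not
  invariant to that choice.
* Welch windowing leaks a few percent of a strong oscillation's power
  into adjacent bands; with the default settings an alpha log-power
  asymmetry of 0.5 induces a spurious theta/beta asymmetry of roughly
  0.04–0.06. This is inherent to windowed band-power estimation, and it
  means neighbouring-band effects smaller than the leakage floor cannot
  be attributed.
* Epoch-level pooling (in both ANOVA and CV defaults) overstates
  evidence and accuracy relative to subject-level analysis; the
  subject-level modes are the honest alternative and are one argument
  away.
* The CNN is intentionally tiny and trained without early stopping or
  validation-based tuning; it is an architecture reproduction, not a
  tuned model.
* EDF support covers continuous 16-bit recordings with one common
  sampling rate; EDF+ annotations and mixed-rate signals are out of
  scope.
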