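---
title: "Dynamic stopping for spatially-coded SSVEP BCIs: models, parameters and design choices"
author: "ssvepDS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic stopping for spatially-coded SSVEP BCIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The paradigm and the model

A spatially-coded SSVEP BCI presents a single high-frequency flicker (60 Hz
here) and lets the user select one of C = 5 targets by gaze position relative
to the flicker. Because the flickering annulus stimulates a different part of
the retina for each gaze target, the steady-state response arrives with a
class-specific scalp topography; the classifier decodes *where* the user
looks from *how* the 60 Hz response distributes over the electrodes.

The pipeline is classical and deliberately linear end to end:

* **Filtering.** A zero-phase FIR band-pass (55–65 Hz) isolates the response
  band. "Zero-phase" is realised as forward–backward application of a
  linear-phase windowed-sinc (Hamming) filter, with mirror-reflection padding
  of one filter length at both ends. Forward–backward application doubles
  the attenuation and cancels the phase exactly, which matters because
  windows as short as 131 samples (~64 ms) are classified.
* **CCA filter bank.** For each class, the training trials are trimmed to
  the analysis window length and concatenated along time, and canonical
  correlation analysis against the quadrature reference
  `Y = [sin(2πft); cos(2πft)]` yields a spatial filter and a reference
  filter. The two reference rows let the filter absorb any fixed response
  phase. At test time the *fixed* trained filters are applied; CCA is never
  re-solved on test data.
* **Features and LDA.** The absolute first canonical correlation under each
  class's filters forms a C-dimensional feature vector in [0, 1]^C. A
  Gaussian equal-covariance discriminant supplies class posteriors via
  Bayes' rule.
* **Dynamic stopping.** Online, the window grows by one amplifier chunk at a
  time. Each chunk-aligned window is classified by models retrained at
  exactly that window length (the *model cache*), and the decision is final
  when N consecutive evaluations return the same label, each with winning
  posterior at least P. The operating point N = 2, P = 0.95 is the package
  default.

# Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| filter order | 66 | taps − 1 | trade-off between selectivity and the shortest filterable window; found by `searchFilterOrder()` |
| pass band | 55–65 | Hz | ±5 Hz around the stimulation frequency |
| chunk size | 131 | samples | amplifier delivery quantum at 2048 Hz (15.6 updates/s) |
| N | 2 | evaluations | consecutive-agreement requirement |
| P | 0.95 | posterior | confidence threshold |
| max window | 4 | s | training trial length; timeout for forced decisions |
| feature dimension | C = 5 | — | first canonical correlation per class (configurable to 2C via `nComponents`) |
| LDA priors | uniform | — | the cueing protocol is balanced |

Grid searches: `searchFilterOrder()` scores each order by the ITR of the full
offline pipeline and breaks ties toward the *lowest* order (shorter minimum
windows). `gridSearchNP()` replays the stopping rule over per-chunk traces —
which do not depend on (N, P) — so the whole surface costs one evaluation
pass; ties prefer larger N then larger P (the more conservative rule), and
the search is 5-fold cross-validated over sequences by default to avoid the
optimism of tuning and scoring on the same trials.

# The synthetic generator and its calibration

No recordings are distributed with this paradigm, so `simulateSession()`
emulates the study conditions: 32 channels at 2048 Hz, five classes, 4 s
trials, 30-sequence training sessions, balanced randomized target order.
Each trial is

```
X(t) = a · w_c · sin(2π f t + φ) + noise(t)
```

with `w_c` the unit-norm class topography, per-trial phase jitter φ (sd
0.2 rad) and relative amplitude jitter (sd 0.2), plus spatially mixed
1/f^α Gaussian background noise (α = 1; α = 0 gives the analytically
convenient white-noise floor). Topographies are random unit vectors with a
configurable pairwise-similarity bound (default |cos| ≤ 0.5 — real
inter-class similarity is unknown, so this stays a parameter).

**SNR calibration.** The narrow-band SNR estimator (`snr60Hz()`) divides the
periodogram power at the stimulation bin by the mean power of the ten
0.25 Hz bins within ±1.25 Hz. The stimulation bin also contains noise, so
the estimator has a floor of 1 on signal-free data. The generator therefore
calibrates the tone power analytically (from the known synthesis spectrum)
so that the *expected estimator output equals* `max(snr, 1)`; configured
values at or below 1 produce no stimulus-locked component at all. The
calibration is anchored at the estimator's canonical 4 s window and is
verified to within 20% by Monte-Carlo in the test suite.

**What the generator does not model:** eye blinks and movement artifacts,
electrode drift, non-stationary background rhythms, harmonics of the
response (the pipeline band-passes 55–65 Hz, so harmonics would be discarded
anyway), and photic-driving physiology. Passing tests on synthetic data
therefore demonstrate the *mechanics* of the method — calibration,
leakage-free cross-validation, stopping-rule behaviour, latency/accuracy
trade-offs — not its performance on real EEG.

# Numerical choices

* **CCA from sufficient statistics.** Every CCA in the package is solved
  from centered scatter matrices via symmetric-eigen whitening and an SVD,
  with eigenvalues below 1e-10 of the maximum treated as rank deficiency
  (reduced number of canonical pairs, warning at the user-facing entry
  point). The scatter formulation is what makes per-window-length
  retraining and leave-one-trial-out refits cheap: removing a trial is a
  subtraction and each refit costs O(L³). Tests verify the solver against
  `stats::cancor` and against a brute-force direction-search oracle.
* **Reference phase at training.** Concatenating trimmed trials raises the
  question of the reference's phase across trial boundaries. The package
  restarts the reference at t = 0 for every concatenated trial — exactly
  what every test window sees — keeping training and application
  consistent. (A phase-continuous reference would misalign trials that are
  phase-locked to their own onset, since the window length is not a whole
  number of stimulation cycles.)
* **Degenerate windows.** A zero-variance projection (e.g. an all-zero
  window) yields feature 0 with a warning instead of NaN.
* **LDA regularisation.** Pooled covariance uses unbiased (n − C) scaling.
  If ill-conditioned (condition number ≥ 1e8), it is shrunk toward its
  diagonal with the smallest γ ∈ {1e-4, 1e-2, 1e-1} that restores
  conditioning; with d = 5 features this rarely triggers. All densities are
  evaluated in log space with a log-sum-exp normalisation; classification
  ties resolve to the lowest class index.
* **Stopping-rule corner cases.** A sub-threshold evaluation resets the
  agreement counter to zero (an optional `holdOnWeak` mode leaves it
  untouched when the label repeats); an above-threshold evaluation with a
  new label restarts the counter at one. N = 1 degenerates to a pure
  posterior threshold, P = 0 to pure label stability. The first evaluation
  happens at the first chunk multiple exceeding both the configured minimum
  window and the filter length. If the criterion is never met, a **forced**
  decision (flagged, included in accuracy by default) is emitted at the
  timeout — the underlying study leaves this case unspecified, but an
  always-responding BCI must terminate.
* **ITR below chance.** The Wolpaw bits-per-trial expression is convex in G
  with its minimum (zero) exactly at chance, so below-chance accuracies
  yield small positive values again; the package returns the formula value
  with a warning rather than clamping.

# Problem sizes used in the shipped analyses

The unit tests run a miniature montage (8 channels at 512 Hz, 1–2 s trials)
that preserves every property of the full setup at a fraction of the cost.
The cohort benchmark (`runDSBenchmark()`, also executed by
`scripts/acceptance.R`) uses the full study conditions — 32 channels,
2048 Hz, 30 training sequences of 4 s, chunk size 131, N = 2, P = 0.95 —
with 20 synthetic subjects whose target SNRs are geometrically spaced over
0.5–8 and 5 online sequences (25 selections) per subject, a size chosen so
the complete benchmark runs in minutes on one core.

# Known limitations

* **The exactly noiseless limit is degenerate.** Any nonzero projection of
  a pure rank-1 sinusoid correlates perfectly with the reference, so as
  SNR → ∞ the feature vector saturates at 1 for *every* class and
  discrimination collapses. Spatial coding with correlation features relies
  on a noise background against which the matched spatial filter's gain
  differs between classes; separation is best at moderate SNR. The test
  suite therefore checks exact canonical-correlation limits on noiseless
  fixtures but separability on strong-yet-finite-SNR fixtures with
  orthogonal topographies.
* **Subjects below the estimator floor carry no signal.** Because requested
  SNR is defined through the narrow-band estimator (floor 1), configured
  values ≤ 1 mean "background only". In the benchmark such subjects perform
  at chance, where both ITRs are near zero and their ratio is not
  informative; the dynamic rule, which waits out its 4 s timeout, then
  compares unfavourably against a short fixed window scored at the same
  chance accuracy.
* **Filter-then-trim vs trim-then-filter.** Cached models are trained on
  full-length filtered trials trimmed to the window length, while an online
  window is necessarily filtered after truncation; the two differ in their
  edge transients. With realistic noise levels the difference is buried in
  the noise floor, but it is measurable on near-noiseless data and is
  inherent to any causal online system.
* The EDF/BDF writer quantises to 16/24 bits; the native columnar + JSON
  interchange exists precisely so that regression tests are exact.
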