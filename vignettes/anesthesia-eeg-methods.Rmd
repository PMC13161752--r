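---
title: "Methods: spectral signatures of anesthetic maintenance agents"
author: "anesEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral signatures of anesthetic maintenance agents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anesEEG)
```

# The problem and the model

During the maintenance phase of general anesthesia the frontal EEG settles
into a quasi-stationary regime whose power spectrum carries a drug-specific
fingerprint. Propofol maintenance produces a strong spindle-like alpha
oscillation near 11 Hz; sevoflurane shifts the dominant oscillation toward
the slow-alpha/theta range (~8.8 Hz), roughly doubles relative theta power,
and steepens the aperiodic (1/f) decay of the spectral background — a proxy
for a shift in cortical excitation–inhibition balance toward inhibition.

`anesEEG` models an epoch's one-sided power spectral density as

$$S(f) = \underbrace{10^{L} f^{-x}}_{\text{aperiodic background}} +
\sum_k p_k\, N(f;\, c_k, \sigma_k),$$

where $L$ is the broadband offset in $\log_{10}(\mu V^2/\mathrm{Hz})$ at
1 Hz, $x$ the aperiodic exponent, and each oscillatory peak deposits total
power $p_k$ ($\mu V^2$) as a unit-area Gaussian density with center $c_k$
and width $\sigma_k$, truncated and renormalized to 0.5–45 Hz. Two sides of
the package meet at this model: the synthetic cohort generator *samples*
from it, and the extraction pipeline *recovers* its parameters and the band
powers it implies, which is the package's core internal-consistency check.

Peaks are additive in **linear power**. This makes band-power calibration an
exactly solvable nonnegative linear problem (next section). The extraction
side, following the specparam convention, fits peaks in **log power**; the
two parameterizations coincide only approximately, and the recovery
tolerances used in the tests absorb that deliberate mild mismatch.

# The synthetic cohort generator

## What it emulates

The generator emulates steady-state maintenance EEG of the kind recorded by
frontal electrode arrays at 250 Hz: a 1/f background with slow/delta, theta,
alpha and beta oscillatory bumps, between-subject variation in the
background and in alpha peak location, plus two realistic artifact classes —
signal dropouts (lead-off) and broadband electrocautery interference. Each
synthetic patient contributes 30 clean-duration epochs of 30 s; defaults
give a 20 + 20 subject cohort (1,200 epochs), a deliberately smaller but
structurally faithful mirror of clinical epoch pools.

It does **not** emulate induction/emergence transients, burst suppression,
age-dependent spectral changes, non-stationarity within an epoch, inter-channel
topography (the optional multi-channel mode duplicates one source with 10%
independent noise), or non-Gaussian waveform features such as phase-amplitude
coupling. Tests passing on these cohorts therefore demonstrate the
*pipeline's* correctness and sensitivity under the stated spectral model,
not performance on any specific clinical dataset.

## Drug-specific presets

Preset centers are transcribed from published group means for
maintenance-phase frontal EEG:

| parameter | propofol | sevoflurane |
|---|---|---|
| aperiodic exponent (mean ± between-subject SD) | 2.07 ± 0.40 | 2.37 ± 0.21 |
| alpha peak center, Hz | 10.88 ± 0.74 | 8.78 ± 0.87 |
| target band fractions (δ, θ, α, β, γ) | ∝ (0.60, 0.10, 0.17, 0.13, 0.01) | ∝ (0.63, 0.20, 0.15, 0.06, 0.005) |
| artifact rate | 0.034 | 0.034 |

Band-fraction vectors are renormalized to sum to one. Choices not pinned by
published values, made once on realism grounds:

* **Offset mean 1.0** $\log_{10}(\mu V^2/\mathrm{Hz})$ for both groups, SD
  0.3. All features except the offset itself are scale-free, so the absolute
  level is a free parameter; the published offset difference between agents
  was not significant.
* **Peak geometry** (both groups): slow bump 1.2 Hz (σ 0.6), theta 6 Hz
  (σ 1.0 — its ±2σ support spans the 4–8 Hz band), beta 18 Hz (σ 3.0), alpha
  σ 1.2 Hz. Only the alpha *center* differs between drugs and varies between
  subjects (truncated to 8–13 Hz); the exponent draw is truncated below at
  0.5.
* **Artifact mix**: a corrupted epoch is a dropout (amplitude × 0.02) or a
  cautery burst (added white noise, SD = 30 × session median epoch RMS) with
  equal probability.

## Calibrating peak powers to band fractions

Given a background and the four peak geometries, the generator solves for
nonnegative powers $p_k$ such that the analytic band fractions of $S(f)$
over the five canonical bands equal the preset targets $r_b$. Writing
$A_{bk}$ for the fraction of peak $k$'s mass in band $b$ (Gaussian CDF
differences), $t_b$ for the background's band integral (closed form), and
$C_k = \sum_b A_{bk}$:

$$\sum_k (A_{bk} - r_b C_k)\, p_k = r_b \sum_b t_b - t_b,$$

a rank-4 linear system solved by nonnegative least squares
(`pracma::lsqnonneg`). `calibrate_peak_powers()` errors (naming the worst
band) if the achieved fractions miss any target by more than 0.01 — e.g.
when a large gamma fraction is requested with no gamma peak available.
Within `draw_subject()` the calibration instead keeps the best nonnegative
fit without a tolerance: extreme-but-legal aperiodic draws (a propofol
exponent near 1.2 or 3.2) make the exact group-mean fractions geometrically
unattainable, and a subject whose achieved fractions deviate by a few
percent is itself realistic between-subject variation. Fixed-mode cohorts
(all parameters at preset means) always calibrate exactly.

## Signal synthesis

Epochs are synthesized by inverse-FFT spectral shaping: deterministic bin
amplitudes $\sqrt{S(f_k)\, f_s\, n / 2}$ with i.i.d. uniform phases,
Hermitian-symmetrized. Every realization's full-length periodogram equals
$S(f)$ *exactly* on the synthesis grid — there is no estimator noise in the
expected spectrum, which keeps the correctness argument for every downstream
oracle short. Shaping is band-limited to 0.5–45 Hz; a half-cosine roll-off
between 0.25 and 0.5 Hz replaces the hard spectral cliff, whose smearing
under the Welch window would otherwise bias measured delta power by several
percent. With the roll-off, the mean Welch PSD over 200 epochs reproduces
every canonical band's analytic power within 3%.

# Preprocessing

Recordings with event annotations are first trimmed to the steady-state
maintenance window [LOC + 20 min, end-of-surgery − 10 min); synthetic
cohorts, generated in steady state, bypass this step. Channels are averaged
in the time domain, the signal is cut into non-overlapping 30-s epochs
(remainder discarded), and each epoch's total power over 0.5–45 Hz is
integrated from its Welch PSD and $\log_{10}$-transformed.

The artifact screen is a single pass: with session mean $\mu$ and sample SD
$\sigma$ of the log powers, epochs below $\mu - 2.5\sigma$ are rejected as
dropouts and epochs above $\mu + 2.5\sigma$ as broadband interference. Design
notes: the low-side threshold mirrors the published high-side rule
symmetrically (dropout powers sit orders of magnitude below the mean, which
the log transform turns into a clean separation); thresholds are computed
once, not iteratively re-estimated; the sample (not population) SD is used,
which matters for short sessions; a zero-variance session rejects nothing.
On default cohorts the measured rejection rate tracks the injected 3.4%
rate within 1.5 percentage points with sensitivity above 0.95, and clean
sessions lose at most ~1% of epochs (2.5σ two-sided tail ≈ 1.2%).

# Spectral features

`welch_psd()` uses 4-s Hann segments at 50% overlap with per-segment
constant detrending — 13 averaged segments per 30-s epoch and exactly
0.25 Hz resolution, so every band edge falls on a grid point and the 2.1-Hz
alpha-gap between the drug presets spans ~8 bins. Band powers are
trapezoidal integrals with interpolated edges, making adjacent bands exactly
additive; the five relative powers always sum to 1 and each stored ratio
equals the quotient of stored fractions (zero-denominator ratios become
missing values and flag the epoch — never infinities).

Other definitions and the reasoning where a choice had to be made:

* **Peak_Freq**: argmax of the *raw* Welch density over 8–13 Hz, refined by
  a three-point parabola and clamped to the band, ties toward the lower
  frequency. The raw (not background-flattened) spectrum is used, matching
  the band-power definition of the feature.
* **Alpha_Bandwidth**: FWHM $2\sqrt{2\ln 2}\,\sigma$ of the dominant fitted
  alpha peak, clipped to the 5-Hz band width; when no alpha peak is fitted,
  the half-maximum width of the background-subtracted spectrum around its
  alpha-band argmax. The clip acknowledges that a width measure on a 5-Hz
  band cannot meaningfully exceed the band.
* **SEF50/SEF95**: smallest frequency at which the cumulative trapezoid
  power over 0.5–30 Hz reaches 50%/95% of the total, interpolated within
  the crossing bin.
* **SpecEn**: Shannon entropy in nats of the density over 0.5–30 Hz bins
  normalized to a probability vector. The value depends on bin count (119
  bins at 0.25 Hz; uniform spectrum ⇒ $\ln 119 \approx 4.78$), which is why
  only within-grid comparisons are meaningful.

# Aperiodic decomposition

The decomposition is a simplified spectral parameterization in the specparam
tradition, fit over 1–30 Hz (below 1 Hz windowing bias dominates; 30 Hz
matches the feature ceiling), with no knee term:

1. **Stage-1 line**: ordinary least squares of $\log_{10}$ power on
   $\log_{10} f$, robustified by a lower-envelope refit — bins at or below
   the line (up to the 2.5th percentile of positive residuals) are kept and
   the line refit. This step is essential here: with realistic band
   fractions the oscillatory peaks cover most of 1–30 Hz, and a plain OLS
   line tilts enough that no peak would clear the detection threshold.
2. **Peak detection**: iteratively take the maximum positive residual; stop
   if it falls below $\max(2\,\hat\sigma_{\text{noise}}, 0.05)$ log10 units
   or after 6 peaks. $\hat\sigma_{\text{noise}}$ is estimated from the
   *negative* half of the residual, since peaks only push it positive; a raw
   residual SD would be inflated by the very peaks being hunted. Each peak
   is least-squares fit (`minpack.lm::nlsLM`) within a local window of ±3
   seed-widths around the maximum, the seed width taken from the local
   half-maximum extent; the window and a center bound of ± one seed-width
   keep neighbouring peaks (e.g. sevoflurane's theta and alpha) from
   blending into one broad Gaussian. Fitted widths are bounded to 0.5–6 Hz.
3. **Peak-masked refit**: bins within ±2 fitted widths of any detected peak
   are excluded and the line refit, *provided* at least 5 bins survive and
   they still span ≥ 50% of the log-frequency axis — a refit on (say) only
   the 26–30 Hz sliver left by two broad masks extrapolates wildly, so such
   cases fall back to the robust stage-1 line with a flag.
4. `parameterize_spectrum()` runs fit → peaks → one background refit →
   final peaks, and stores the flattened residual so that background +
   peaks + flattened reconstructs the input log spectrum to $10^{-9}$.

On noise-free power laws the fit is exact to $10^{-6}$ and exactly scale-
equivariant (density × c shifts the offset by $\log_{10} c$). On analytic
spectra with additive peaks the exponent error stays below 0.05 across
$x \in [1, 3]$. On full synthetic epochs the reconstruction explains ≥ 85%
(typically ~93%) of log-power variance; the residual reflects the
deliberate linear-vs-log peak model mismatch, not estimation failure.

# Classification and attribution

The epoch-level model is a 500-tree random forest (propofol = positive
class): $\lfloor\sqrt{17}\rfloor = 4$ candidate features per split,
effectively unlimited depth (cap 15), and per-tree row subsampling at 0.632
without replacement — the expected unique fraction of a bootstrap resample.
The forest is trained through xgboost's random-forest mode (one boosting
round of 500 parallel trees, unit learning rate, unregularized mean-of-label
leaves, so each tree votes its leaf class fraction); predictions and SHAP
values are then computed from the exported node table in double precision
by the package's own C++ implementation of the path-dependent TreeSHAP
algorithm. This guarantees the local-accuracy identity
$\text{base} + \sum_j \phi_j = \hat p$ to ~$10^{-12}$ per epoch (float32
attribution pipelines lose it at the $10^{-5}$ level on 500 trees).

Evaluation is strictly subject-independent: subjects are shuffled by seed
and dealt round-robin into 5 folds (sizes differ by ≤ 1), so all epochs of a
patient are held out together; a leakage assertion verifies the train/test
subject sets are disjoint in every fold. Out-of-fold epoch probabilities are
arithmetically averaged per subject and thresholded at 0.5 — an exact tie
counts as propofol (arbitrary but fixed). SHAP values are computed on
out-of-fold epochs only, with the fold's own model, avoiding optimistic
attribution; importance is the pooled mean absolute SHAP, ranked with ties
broken by feature-table order.

On default variable cohorts the subject-level accuracy is ≥ 0.90 (typically
40/40), and a subject-level label permutation collapses it to chance within
binomial noise — the leakage control's sanity check.

# Group statistics

Features are compared with Welch's unequal-variance t-test, implemented from
the textbook formulas (statistic, Welch–Satterthwaite df) with the p-value
from the t distribution, and verified against both brute-force arithmetic
and `stats::t.test` to $10^{-9}$. Epoch values are **averaged within subject
first**, so each patient contributes one observation — epoch-level testing
would pseudo-replicate heavily autocorrelated data; an epoch-level mode
remains available for sensitivity analysis. Rows are ranked by ascending p,
printed to three decimals with a `<0.001` floor. No multiple-testing
correction is applied to the primary column (raw p-values are the reported
quantity); a Benjamini–Hochberg column is emitted alongside as clearly
supplementary output.

Feature redundancy uses Spearman's ρ over epochs, signed distance $1-\rho$,
and average-linkage agglomerative clustering; constant features get zero
correlation with a flag rather than `NA`. In generated cohorts the theta
block (Theta_Rel and its ratios) clusters tightly, while the offset — drawn
independently of the oscillatory structure — stays nearly uncorrelated with
every periodic feature. Note that because the generator draws offset and
exponent independently and both are recovered nearly unbiasedly, the two
aperiodic parameters do *not* correlate strongly in synthetic cohorts, in
contrast to clinical data where shared physiological drivers couple them.

# Validation strategy and problem sizes

The test suite validates each primitive against an independent oracle
(dense-grid numeric integration for band powers, edges and entropy;
closed-form truncated-normal moments for subject draws; brute-force formulas
for Welch's t; the additivity identity for SHAP), then checks end-to-end
parameter recovery on fixed-mode cohorts — all subject parameters pinned at
preset means, 20 subjects × 30 clean epochs per drug — where the cohort
grand means of Peak_Freq, Exponent and Theta_Rel must land on the preset
centers within ±0.15 Hz, ±0.10 and ±0.02 respectively. Classification, QC
and permutation properties run on the default variable cohort (20 + 20
subjects, artifacts at 3.4%). Type-I calibration of the group-comparison
pipeline runs on 200 seeded null cohorts generated at the feature-table
level (both groups drawn from one subject-level distribution, 8 + 8 subjects
× 5 epochs): the pipeline under calibration consumes only the feature
table, so synthesizing full waveforms 200 times would test the same code
path at two orders of magnitude more cost. The full suite runs in a few
minutes on one CPU.

# Known limitations

* **Sevoflurane alpha-peak bias.** With the sevoflurane preset the theta
  bump's upper tail and the steep 1/f background tilt the raw-PSD argmax
  slightly below the true alpha center: the recovered cohort mean sits
  ~0.15 Hz below 8.78 Hz (about −0.11 Hz deterministic, −0.05 Hz from Welch
  smoothing). This is a property of the argmax-on-raw-density definition
  under overlapping components, shared with any implementation of that
  definition; the propofol preset, whose alpha stands clear of theta, shows
  no such bias.
* **Peak-model mismatch.** Generation adds Gaussian peaks in linear power;
  extraction fits them in log power. Exponent/offset recovery is robust to
  this, but fitted peak heights/widths are not directly comparable to the
  generator's $p_k, \sigma_k$, and reconstruction $R^2$ plateaus near
  0.87–0.94 on realistic spectra.
* **Independent aperiodic draws.** Offset and exponent are sampled
  independently; synthetic cohorts cannot reproduce clinically observed
  offset–exponent coupling.
* **Unbalanced cohorts.** An unbalanced mode (per-subject epoch counts) is
  available but not exercised by the recovery tests, which use equal epochs
  per subject.
* **Classifier surrogate detail.** Random-forest row sampling is 0.632
  without replacement rather than a true bootstrap; at 500 trees the
  practical difference is negligible for this feature set.
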