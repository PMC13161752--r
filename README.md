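# anesEEG

Quantitative EEG analysis of the anesthetic maintenance phase: which drug is
keeping the patient asleep? Propofol- and sevoflurane-maintained general
anesthesia leave distinct signatures in frontal EEG — a fast spindle-like
alpha rhythm near 11 Hz under propofol versus a slowed alpha (~8.8 Hz) with
prominent theta under sevoflurane, and a steeper aperiodic (1/f) spectral
decay under the volatile agent. `anesEEG` implements the full analysis
pipeline for epoch-level spectral features, agent classification and group
statistics, together with a calibrated synthetic cohort generator so the
entire pipeline can be exercised and validated without clinical recordings.

The package is aimed at researchers in clinical neurophysiology and
depth-of-anesthesia monitoring who want a tested, reproducible reference
implementation of this feature set and evaluation protocol.

## What it computes

Every 30-s epoch (250 Hz, channel-averaged frontal EEG) is reduced to a
Welch power spectral density (4-s Hann segments, 50% overlap, 0.25-Hz
resolution) and then to 17 features:

* **Relative band powers** over 0.5–30 Hz: Delta (0.5–4), Theta (4–8),
  Alpha (8–13), Beta (13–25), Gamma (25–30 Hz) — fractions of total power.
* **Band ratios**: Theta/Alpha, Theta/Delta, Beta/Delta, Beta/Alpha,
  Alpha/Delta.
* **Oscillatory/distribution**: alpha peak frequency (argmax in 8–13 Hz with
  parabolic refinement), alpha bandwidth (FWHM of the fitted alpha peak),
  spectral edge frequencies SEF50 and SEF95, spectral entropy (nats).
* **Aperiodic parameters** from a specparam-style decomposition
  `log10 P(f) = L − x·log10 f` plus Gaussian peaks over 1–30 Hz: offset `L`
  and exponent `x`.

Artifacted epochs are rejected by the two-stage power-threshold rule: epochs
whose log10 total power (0.5–45 Hz) falls below μ − 2.5σ (dropout/lead-off)
or above μ + 2.5σ (electrocautery-like broadband interference) of the
session statistics are discarded in a single pass.

Classification is subject-independent: a 500-tree random forest under
5-fold grouped cross-validation (all epochs of a patient in one fold),
out-of-fold epoch probabilities averaged into a composite subject score and
thresholded at 0.5. Feature importance is the mean absolute TreeSHAP value
(exact, double precision — implemented in C++ over the trained forest).
Group differences are tested per feature with Welch's unequal-variance
t-test on subject-level means, and feature redundancy is summarized by a
Spearman correlation matrix with average-linkage clustering.

The synthetic generator produces cohorts whose expected epoch spectra follow
`S(f) = 10^L f^(−x) + Σ_k p_k N(f; c_k, σ_k)` with drug-specific presets
(alpha center 10.88 vs 8.78 Hz, exponent 2.07 vs 2.37, theta fraction 0.10
vs 0.20, ...), peak powers calibrated by nonnegative least squares to hit
the target band fractions exactly, inverse-FFT phase-randomized synthesis
with exactly known expected PSD, and injected dropout/cautery artifacts with
per-epoch ground truth.

## Worked example

```r
library(anesEEG)

cohort <- generate_cohort(seed = 42)        # 20 + 20 subjects x 30 epochs
feat   <- extract_cohort_features(cohort)   # QC + 17 features per epoch
res    <- classify_cohort(feat, seed = 42)  # grouped CV + SHAP
res$subjects
#> Subject-level accuracy: 100.00% (40/40 subjects)
#>              predicted
#> truth         propofol sevoflurane
#>   propofol          20           0
#>   sevoflurane        0          20

aggregate(feat[, c("Theta_Rel", "Peak_Freq", "Exponent")],
          list(group = feat$group), mean)
#>         group Theta_Rel Peak_Freq Exponent
#> 1    propofol     0.101     10.85     1.96
#> 2 sevoflurane     0.193      9.07     2.25
```

The recovered group means track the generator's drawn ground truth (for this
seed the drawn group-mean exponents are 1.966 and 2.386): sevoflurane shows
roughly doubled relative theta power, a ~1.8-Hz downshift of the alpha peak
and a steeper aperiodic decay, and the classifier separates the groups
perfectly at the subject level. `compare_groups(feat)` reproduces the
Welch-t table (Theta_Rel, Theta_Alpha_Ratio and Peak_Freq at p < 0.001 with
the expected signs), and `res$importance` ranks features by mean |SHAP|.

The numbered drivers under `analysis/` run the same workflow as a scripted
pipeline, writing its tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # cohort + ground-truth tables
Rscript analysis/02_extract_features.R  # QC mask + feature table
Rscript analysis/03_classify.R          # subject predictions, confusion, SHAP
Rscript analysis/04_group_stats.R       # Welch-t table, correlation structure
```

## Documentation

The methods vignette (`vignettes/anesthesia-eeg-methods.Rmd`) documents the
spectral model, the calibration mathematics, every tunable parameter with
its default and rationale, the validation strategy, and known limitations.
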