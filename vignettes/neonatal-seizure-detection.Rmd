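---
title: "Methods: probabilistic neonatal seizure detection, its displays and audification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic neonatal seizure detection, its displays and audification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoseize)
```

## The problem and the model

Neonatal seizures — most often a consequence of hypoxic ischaemic
encephalopathy — are electrographic events on the multi-channel EEG:
rhythmic discharges whose dominant frequency lies between 0.5 and 6 Hz,
frequently focal (visible on a single channel) and embedded in an
abnormal background. `neoseize` implements a per-channel probabilistic
detector and the clinical output layer built on it.

The detector is a classical feature-based classifier chain:

* **Front end.** Referential EEG is reduced to eight bipolar
  derivations (F4–C4, C4–O2, F3–C3, C3–O1, T4–C4, C4–Cz, Cz–C3, C3–T3),
  low-passed at 12.8 Hz and downsampled to 32 Hz, then cut into 8 s
  epochs with 50 % overlap. The 8 s window is matched to the minimum
  clinically meaningful seizure duration on an abnormal background and
  suppresses brief seizure-like transients.
* **Features.** Each (epoch, channel) signal is summarised by 55
  descriptors across three families: time domain (RMS and absolute
  amplitude, peak-to-peak, line length, zero crossings, the three Hjorth
  parameters, skewness, kurtosis, Teager nonlinear energy, RMS of the
  first difference), frequency domain (total 0.5–12.8 Hz power, absolute
  and relative power on a 1 Hz band comb, peak frequency, spectral
  centroid and bandwidth, 80/90/95 % spectral edge frequencies, spectral
  slope), and information theory (amplitude-histogram entropy,
  normalized spectral entropy, SVD embedding entropy, autoregressive
  prediction-error variances at orders 1–8). The registry is a data
  object (`feature_registry()`): its row order *is* the feature-vector
  order everywhere downstream, and alternative registries can be passed
  to `extract_features()` without code changes.
* **Classifier.** Features are normalized anisotropically — subtract the
  training mean, divide by the training standard deviation, template
  frozen and re-applied to test data — and classified by an RBF-kernel
  SVM applied *separately to each channel*, because neonatal seizures
  can be confined to one channel. Decision values are mapped to
  probabilities by a Platt sigmoid fitted on cross-validated decision
  values, not on training scores, to avoid optimistic calibration.
* **Post-processing.** Per-channel probability traces are smoothed with
  a centered moving average; the fused trace is the per-epoch maximum
  across channels; thresholding at θ gives binary decisions; each
  detection is extended by a collar on both sides (compensating
  smoothing delay and onset/offset uncertainty) and touching detections
  merge.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| anti-alias cutoff | 12.8 | Hz | upper edge of the analysed band |
| epoch length / overlap | 8 / 50 % | s / – | clinical window, 4 s hop |
| smoothing window | 15 | epochs (60 s) | suppresses isolated-epoch flickers; our choice, configurable |
| decision threshold θ | 0.5 | – | the value fixed for clinical use |
| collar | 32 | s | covers the smoothing half-window plus onset/offset slack; our choice |
| SVM cost / γ | 1 / 1/55 | – | fixed defaults with balanced class weights (see below) |
| colormap bins | 10 | – | discrete blue–white–red, 0.5 in the first warm bin |
| aEEG band / smooth / step | 2–15 / 0.5 / 15 | Hz / s / s | standard aEEG practice; external to the detector |
| vocoder stretch / rate | 100 / 32000 | – / Hz | 0.5–13 Hz → 0.5–13 kHz; 1 h plays in ≈ 6 min |
| gain floor | 0.2 | – | keeps background audible under probability gain |

Where a value is not fixed by the published design (smoothing window,
collar, aEEG constants, vocoder STFT geometry, gain law), the default is
this package's documented choice and is exposed in `run_config()` /
`audify_config()`.

**Hyperparameters instead of a grid search.** The SVM uses fixed
defaults (RBF, cost 1, γ = 1/55, inverse-frequency class weights,
training rows capped at 4000 by stratified subsampling) rather than a
per-fold grid search. On the synthetic cohorts the fixed setting already
separates the classes nearly perfectly, so a search would tune noise
while multiplying runtime; all knobs remain exposed for real data.

## The synthetic generator

`simulate_recording()` produces channels of 1/f-shaped Gaussian noise
(power ∝ 1/f, clamped at the lowest resolvable frequency) scaled to a
30 µV RMS background — a typical moderately-abnormal neonatal level —
and adds, per seizure event, a Hann-enveloped sinusoid at the configured
discharge frequency (0.5–6 Hz enforced) plus a half-amplitude second
harmonic, at 100 µV peak by default, on an explicit channel subset so
both focal and generalized seizures are producible. `simulate_cohort()`
draws records with two ~60–120 s seizures each, discharge frequencies
uniform over 0.5–6 Hz and a random contiguous run of 2–4 affected
channels.

The generator emulates the *spectral* contrast between rhythmic
discharge and coloured background that the feature set keys on. It does
**not** emulate artefacts (ECG, respiration, electrode pops), state
changes (trace alternant, sleep cycling), evolving seizure morphology
(frequency gliding, spike-wave shape), or inter-record background
variability. Passing the recovery tests therefore demonstrates that the
chain is wired correctly and can learn a genuine discriminative target
end to end — not that clinical-grade performance would be obtained on
real neonatal EEG.

## Numerical choices

* **Zero-phase filtering.** The anti-alias filter is a ~1 s
  linear-phase FIR (Hamming design, cutoff 12.8 Hz) applied by
  convolution with the group delay trimmed, so annotation times need no
  correction. Whether the deployed clinical filter was zero-phase is not
  derivable from the published description; zero phase is our choice.
  Non-integer rate ratios are handled by filtering followed by
  cubic-spline interpolation onto the exact 32 Hz grid.
* **Time convention.** Epochs are indexed by start; probabilities are
  timestamped at start + 4 s, and a decision epoch covers the half-open
  4 s interval at its timestamp. All intervals are half-open.
* **Degenerate epochs.** A zero-variance epoch yields 0 for entropy-,
  mobility-, edge- and peak-type features; no NaN/Inf ever leaves
  `extract_features()`.
* **Welch spectra.** 128-sample Hann segments at 50 % overlap on the
  256-sample epoch (0.25 Hz resolution) — robustness over a raw
  periodogram.
* **Moving average at edges.** Centered with shrinking windows, so a
  constant trace is a fixed point and no padding bias is introduced.
* **Colormap tie-break.** bin = min(⌊10p⌋, 9): bins are right-open
  except the top, so p = 0.5 falls in the first warm bin.
* **aEEG semilog map.** d(x) = x below 10 µV and 10·(1 + log10(x/10))
  above is the unique continuous map that is linear with unit slope to
  10 µV and spans the 10–100 µV decade with equal display height;
  amplitudes above 100 µV clip at the ceiling. The published description
  states the scale qualitatively; the closed form is ours.
* **ROC endpoints.** Both AUC orders augment the sweep with the forced
  endpoints (SE, SP) = (1, 0) and (0, 1) so the trapezoid spans the unit
  square; `endpoints = FALSE` reproduces the literal truncated-grid
  sums. Epoch-level scoring of a decision trace uses the trace's own hop
  grid, so a sliver before the first epoch timestamp is never scored.
* **Confidence bound.** The threshold guide uses a percentile bootstrap
  (2000 resamples, seeded) across patients for the 95 % upper bound of
  mean FD/h; a normal approximation is available behind `ci_method`.
  The construction of the published bound is not specified; bootstrap is
  our choice.
* **Phase vocoder.** STFT with a 64-sample (2 s) periodic Hann window
  and hop 16; the time base is resampled by the stretch factor with
  linear magnitude interpolation and per-bin phase propagation by
  measured instantaneous frequency; windowed overlap-add resynthesis
  normalized by the accumulated squared window. Output length is pinned
  to round(n × factor). Per-channel gain uses each selected channel's
  own probability (the fused trace is selectable); hemisphere channel
  selection uses the cumulative probability over the whole rendered
  segment — the simplest reading of "cumulative".
* **Determinism.** Every stochastic stage (generator, training-row
  subsampling, libsvm's internal calibration folds, bootstrap) is seeded
  from the configuration; identical configurations give byte-identical
  artifacts.

## Problem sizes used by the test and acceptance runs

The shipped suites run on sizes a laptop handles in minutes, chosen as
the smallest cohorts on which the measured properties are stable: the
leave-one-record-out recovery check uses the generator's default
6-record cohort (900 s per record, two seizures each, 256 Hz); oracle
equivalence suites use hundreds of randomized small interval cases; the
audification checks use the canonical 1000 s worked size and one-hour
records at 32 Hz.

## Known limitations

* The 55-feature registry is a documented reconstruction of the named
  feature families, not a bit-level replication of the original
  system's feature set; the registry-as-data design exists precisely so
  an exact set can be swapped in.
* Event-level scoring uses the any-overlap rule throughout; clinical
  scoring variants (minimum-overlap fractions, onset-latency credit)
  are not implemented.
* The EDF writer/reader covers the continuous, single-rate case the
  package produces; it is not a general EDF(+) implementation.
* aEEG here is the standard symmetric band-pass variant; vendor-specific
  asymmetric filters are not reproduced.
* No artefact detection: on real EEG, respiration or movement artefact
  would inflate false detections relative to the synthetic results.
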