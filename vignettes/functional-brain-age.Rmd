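---
title: "Estimating functional brain age from preterm EEG and scoring raters against it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating functional brain age from preterm EEG and scoring raters against it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neofba)
library(dplyr)
```

## The problem

The EEG of a preterm infant changes rapidly and systematically between about
25 and 38 weeks postmenstrual age (PMA): the background starts out
discontinuous — high-amplitude bursts separated by long, low-amplitude
inter-burst intervals (IBIs) — and becomes progressively continuous towards
term, while burst amplitude falls and trough amplitude rises. Clinicians
exploit this to judge whether a baby's brain activity "looks its age", either
from the raw EEG or from the amplitude-integrated EEG (aEEG), a compressed
envelope trend used at the cot side.

This package implements both sides of that assessment problem:

* a **functional brain age (FBA)** estimator: quantitative EEG (qEEG)
  features of one-hour epochs, fed to a support-vector regression of PMA,
  validated by leave-one-infant-out cross-validation; and
* the **reliability and accuracy framework** used to score panels of human
  raters and the FBA against the true PMA: ICC(2,1) agreement with
  closed-form and bootstrap confidence intervals, bootstrap comparison of
  two panels' ICCs, systematic/random error decomposition,
  Pitman–Morgan and Bartlett variance tests, per-infant trajectory
  analysis, and Bonferroni-corrected subgroup comparisons.

Because no public preterm serial-EEG corpus with expert age estimates
exists, the package ships a first-class synthetic generator for both the
signals and the rater panels. Every statistical claim the test suite makes
is made against data whose generative truth is known.

## The synthetic cohort

`simulate_preterm_eeg()` produces amplitude-modulated 1/f^γ noise whose
burst-suppression structure follows a maturation curve parameterised in
`sim_params()`. All anchors are linearly interpolated between 25 and 38
weeks:

| parameter | 25 wk | 38 wk | meaning |
|---|---|---|---|
| `ibi_mean` | 8 s | 1.5 s | mean inter-burst interval |
| `burst_dur_mean` | 3 s | 6 s | mean burst duration |
| `burst_amp` | 120 µV | 60 µV | burst amplitude (≈ peak-to-peak) |
| `interburst_amp` | 8 µV | 25 µV | inter-burst amplitude |

These are literature-scale values for discontinuous preterm EEG; what the
analyses rely on is only their monotone direction, and all are
configurable. IBI and burst durations are drawn lognormal (positive,
right-skewed, as discontinuous EEG is). Amplitude parameters are quoted as
approximate peak-to-peak values; the generator uses a per-sample SD of
amp/4, so the 0.5-s RMS envelope sits near amp/4. Channels share a common
process mixed with channel-independent noise at `channel_correlation`
(default 0.7 — preterm bursts are broadly synchronous across the scalp);
the 1/f^γ background uses γ = 2 (delta-dominant, as in neonatal EEG) and is
AC-coupled at 0.5 Hz, as an EEG amplifier would be. Movement-like artefact
events (~800 µV, 1 s) occur at `artefact_rate` per hour (default 2).

What the generator deliberately does **not** emulate: sleep-state cycling,
delta brushes and other transient waveforms, seizures, asymmetries,
electrode-specific artefact. Passing tests therefore demonstrate that the
pipeline recovers a monotone maturational signal embedded in realistic
amplitude statistics — not that it handles every physiological pattern of
real recordings.

`simulate_cohort()` mimics the serial-recording design of preterm
monitoring studies: each infant is recorded every 2 weeks from an initial
PMA drawn uniformly (default 25–34 wk), truncated at 38 wk. One RNG stream
is derived per recording by hashing `(seed, recording_id)`, so a cohort is
reproducible regardless of generation order.

`simulate_rater_panel()` is the generative inverse of the error
decomposition: rater *r* reports `truth + bias_r + N(0, sd_r²)`, optionally
rounded and clipped. Two presets mirror the published panel structure:

* `rater_panel_eeg()` — four raters, mean bias +0.8 wk but biases spread
  with SD ≈ 2.7 wk (raw-EEG readers disagree systematically), random error
  2.5 wk → panel ICC ≈ 0.52;
* `rater_panel_aeeg()` — three nearly interchangeable raters, mean bias
  −1.8 wk (bias SD ≈ 0.3 wk), random error 2.3 wk → panel ICC ≈ 0.72.

Whether raters report integer weeks is unknown territory, so rounding is a
switch (`rounding = 1`), not a default; likewise clipping to the known
25–38 wk range is available but off.

```{r cohort}
rec <- simulate_preterm_eeg(27, duration = 120, fs = 128, seed = 1)
rec
head(rec$truth_bursts)
```

## Signal layer

`write_edf()` / `read_edf()` implement 16-bit EDF with symmetric physical
and digital (±32767) ranges, so zero microvolts is representable exactly
and the round-trip error is bounded by the quantization step.
`apply_montage()` builds the ten-derivation neonatal review montage
(`montage_default_eeg()`) or the single central derivation C3–C4 used for
the aEEG. `compute_aeeg()` follows conventional cerebral-function-monitor
processing — 2–15 Hz band-pass, rectification, 0.5-s RMS envelope, 15-s
min/max windows; none of these constants is standardised anywhere, so all
are arguments. The semilogarithmic display (linear below 10 µV) is purely a
plotting transform in `autoplot()`.

`detect_artefacts()` masks samples exceeding 500 µV on any channel and 2-s
windows flat below 2 µV peak-to-peak on all channels, dilated by 1 s.
`segment_epochs()` cuts consecutive 1-h epochs, drops epochs less than half
clean (so a single transient does not void an hour), and falls back to a
single whole-recording epoch for recordings shorter than one epoch but
longer than 10 min — the fallback that admits ~0.4-h clinical recordings.
`apply_exclusion_rules()` encodes the panel-level exclusion rules (≥2
artefact flags, ≥2 too-brief flags, any missing estimate) with a fixed
precedence — artefact > brief > missing — chosen arbitrarily but fixed so
reason codes are reproducible.

## The qEEG feature vector

Seventeen features per epoch (`qeeg_feature_names()`), spanning the seven
families a clinician's eye and the regression both read: rEEG amplitude
percentiles (5/50/95 of 2-s peak-to-peak), IBI statistics from a
hysteresis burst detector, suppression fraction, relative band powers
(δ/θ/α/β over 0.5–30 Hz, Welch), sample entropy, suppression-curve
summaries (AUC and the 50% threshold), and burst duration/shape statistics
(log-mean and log-SD of durations; temporal skewness and excess kurtosis
of the average time/amplitude-normalised burst shape). Features are
computed per montage derivation on artefact-free samples and aggregated by
the median, robust to one bad derivation.

Numerical choices worth knowing:

* **Burst detector** (`detect_bursts()`): hysteresis on the 0.5-s RMS
  envelope, defaults on 10 / off 6 µV, minimum burst 0.5 s, gaps under 1 s
  bridged. The thresholds are set for *bipolar derivations*: a derivation
  retains only the channel-independent part of the common burst process,
  scaling envelopes by √(2(1−ρ)) ≈ 0.77 at the default channel
  correlation, which puts the term-age burst envelope near 11.6 µV and the
  inter-burst envelope at 25 wk near 1.5 µV. The defaults sit strictly
  between the two across the whole 25–38 wk range; higher thresholds
  saturate above ~34 weeks.
* **Sample entropy**: m = 2, r = 0.2·SD, on the signal decimated to 64 Hz,
  capped at 4096 samples (the template search is quadratic; the cap bounds
  it at ~10⁷ comparisons with no measurable loss on hour-scale epochs). A
  zero-variance signal is perfectly regular: entropy 0 by definition.
* **Suppression curve**: thresholds 0–50 µV in 1-µV steps; summarised by
  the normalised trapezoidal AUC and the smallest threshold at which half
  the epoch is suppressed.
* **Missing burst features** (fewer than 3 bursts on every derivation —
  continuous term-age EEG) are imputed at model-fit time with the training
  median, stored in the model.

```{r features}
feats <- assemble_features(rec, epoch = c(0, 120),
                           config = qeeg_config(epoch_s = 120,
                                                min_duration_s = 120))
round(unlist(feats[, c("reeg_p50", "ibi_median", "suppression_fraction",
                       "relpow_delta", "sampen")]), 3)
```

## The FBA regressor

`train_fba()` z-scores the features with training statistics and fits an
RBF-kernel support-vector regression of PMA. Hyperparameters are selected
by infant-grouped inner cross-validation over C ∈ {1, 10, 100},
γ ∈ {0.01, 0.1, 1}/n_features, ε ∈ {0.25, 0.5, 1} wk — a deliberately
small, logged grid; with 17 features and a few hundred epochs a finer grid
buys nothing reproducible. Constant features are dropped with a recorded
warning. Predictions are averaged over a recording's epochs
(`predict_fba()`), which is both the clinical reporting unit and a
variance-reduction step.

`loo_cv()` validates with **one fold per infant**: all serial recordings
of the held-out infant are predicted by a model trained, tuned and imputed
on the remaining infants only. Holding out single recordings instead would
let a model recognise an infant from its other recordings and inflate
accuracy; the per-recording mode exists behind `unit = "recording"` for
exactly that comparison. No output clipping is applied — downstream
consumers see raw regression output.

The test suite exercises the full chain on a 40-infant × 3-recording
cohort of 10-minute, 64-Hz recordings with 300-s epochs — sizes chosen so
the whole synthetic study runs in minutes while keeping ≥ 100 recordings
and a realistic serial structure; at that scale the cross-validated FBA
correlates with PMA at r ≈ 0.99 with random error ≈ 0.2 wk, and a
label-shuffle control (age trajectories permuted across infants, averaged
over three shuffles) abolishes the correlation.

## Agreement and accuracy statistics

**ICC(2,1)** (`icc_agreement()`): two-way random-effects,
absolute-agreement, single-rater intraclass correlation — the model in
which the panel is a random sample of interchangeable judges, and the
single rater (not the panel average) is the clinical unit. Computed from
the two-way mean squares; the default 95% CI is the closed-form F-based
interval, with a recording-resampling bootstrap as the labelled
alternative (`ci_method = "bootstrap"`) since the study-style ΔICC
comparison is bootstrap anyway. `bootstrap_icc_difference()` resamples
recordings jointly from both panels (pairing preserved) and calls the
difference significant when the percentile CI excludes zero; an unpaired
mode serves disjoint subgroups. The resampling unit is the recording, not
the infant — an infant-blocked variant would be a sensitivity analysis,
not the primary method, and is deliberately not the default.

**Error decomposition** (`error_summary()`): systematic error =
mean(estimate − PMA), random error = SD(estimate − PMA), plus Pearson r
and the percentage of recordings within 1 and 2 weeks (boundaries
inclusive — the boundary convention is unstated in clinical practice, so
it is fixed and documented here). The identity
MSE = bias² + SD²·(n−1)/n holds exactly and is tested.

**Mean and variance comparisons**: paired t / Welch's t for systematic
error (Cohen's d uses the SD of differences when paired, pooled SD
otherwise — recorded in the output); Pitman–Morgan for random error of
paired estimators (equality of correlated variances ⇔ zero correlation
between pairwise sums and differences), Bartlett for unpaired. Identical
inputs are a defined boundary: statistic 0, p = 1.

**Trajectories** (`trajectory_analysis()`): the per-infant SD of the
estimation error over serial recordings — the quantity that decides
whether an individual's maturation can be tracked. Infants with fewer than
two recordings are excluded; SDs are log-transformed for the one-way
ANOVA across methods (zeros floored at 0.01 wk first, configurable —
log 0 is undefined and a zero SD is a sampling fluke, not a physical
value), with Levene's test (absolute deviations from group means)
checking homogeneity and Tukey's HSD giving pairwise adjusted p-values.

**Subgroups** (`subgroup_analysis()`): per-group ICC and ensemble error
summary, Welch t on systematic error, Bartlett on random error, and an
unpaired bootstrap ICC difference between groups; p-values are multiplied
by the number of alternative grouping definitions (default 3, capped at
1) and CI levels divided accordingly — the correction an abnormality
analysis owes when it is repeated under several label definitions.

```{r agreement}
truth <- tibble::tibble(recording_id = sprintf("r%03d", 1:179),
                        infant_id = sprintf("i%02d", rep(1:62, length.out = 179)),
                        pma_weeks = runif(179, 25, 38))
panel <- simulate_rater_panel(truth, rater_panel_aeeg(), seed = 2)
icc_agreement(panel)
panel_error_summary(panel)
```

## Design choices that were genuinely open

* **ICC form.** Fixed to ICC(2,1) rather than offering the consistency or
  average-rater variants: raters are modelled as a random sample and a
  clinician acts on a single expert's estimate.
* **CV unit.** Infant-wise leave-one-out is the default; the literature on
  serial biosignal cohorts is unambiguous that subject-wise exclusion is
  required to prevent identity leakage, and the package treats the
  per-recording variant as a diagnostic.
* **Detector thresholds** are absolute (µV) rather than adaptive: adaptive
  thresholds would erase part of the maturational amplitude signal the
  features are supposed to carry.
* **Epoch fallback.** Clinical cohorts contain recordings shorter than the
  1-h epoch; refusing them would discard data the study design explicitly
  kept (minimum ~0.4 h), so a single whole-recording epoch down to 10 min
  is accepted and flagged by its length.
* **Ensemble estimate** is the unweighted mean across raters; weighting
  raters by historical accuracy would presuppose the accuracy analysis the
  ensemble feeds.

## Known limitations

* The synthetic generator's maturation curve is linear between its two
  anchors; real maturation is not, and no claim about curve shape
  transfers to real data.
* The rEEG amplitude median is not monotone in PMA under the default
  amplitude curve (burst amplitude falls towards term while continuity
  rises, so the median peaks around 34 wk); the regression uses the full
  feature vector and does not depend on any single feature being monotone.
* The feature set names and implements the seven published families, but
  equivalence with any specific prior implementation's exact feature list
  is not claimed.
* EDF support is 16-bit EDF with equal per-channel rates; EDF+
  annotation channels are out of scope.
* With only three raters in a panel, the between-rater variance component
  is estimated from three values; ICC confidence intervals at small k are
  honest but wide, and simulation checks must treat the panel bias spread
  as a design constant (see the test suite) to be well-posed.
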