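---
title: "Modeling learned categorical perception: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling learned categorical perception: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catperc)
```

## The scientific problem

Learned categorical perception (CP) is the phenomenon in which, after a
person learns to sort stimuli into categories by trial and error with
corrective feedback, members of *different* categories come to look more
dissimilar (**between-category separation**) and members of the *same*
category sometimes come to look more similar (**within-category
compression**). `catperc` implements the full computational workflow of a
texture category-learning experiment with EEG: stimulus generation,
learning-curve classification, dissimilarity-judgement CP statistics, ERP
component measurement keyed to each subject's learning point, and a
two-phase neural-network model that reproduces the effect in a hidden
representation space. A synthetic-cohort generator with known injected
effects stands in for human subjects, so every stage of the pipeline can be
verified against ground truth.

## Texture stimuli

Stimuli are 30 x 30 grids of 6 x 6-pixel binary tiles. Twelve distinct tile
patterns, each with exactly 18 black and 18 white pixels, are paired into
six mutually exclusive binary feature pairs; a texture selects one polarity
per pair and arranges the six selected tiles in a uniformly random grid with
each tile occurring exactly 150 times (900 tiles / 6 features). A *category
scheme* fixes `k` of the six pairs as **covariant**: their polarity is fully
determined by the category (K or L), while the remaining pairs flip fair
coins per stimulus. Four difficulty levels (k = 6, 5, 4, 3) span "all
features relevant" to "half the features are noise".

Design notes:

* The grid is canonically 30 x 30 tiles = 180 x 180 px. Rendered images can
  be smoothly resampled to 275 x 275 px for display, but the analysis
  pipeline only ever consumes tile grids, never resized pixels, so the
  resampling filter is cosmetic.
* "Placed at random" and "equally represented in each stimulus" conflict if
  placement is sampled with replacement; we resolve this as an exact-count
  balanced placement (a random permutation of a multiset holding each
  selected tile 150 times), because equal representation is stated as a
  per-stimulus property.
* Non-covariant randomness is drawn per stimulus (each texture contains
  exactly 6 tile types), not per tile.
* The twelve base patterns are generated pseudo-randomly under the 18/18
  constraint; with `r format(choose(36, 18), big.mark = ",")` possible
  patterns, collisions are checked for but essentially impossible.
* A single master seed fans out to per-object sub-seeds
  (`derive_seed()`), so any stimulus, schedule, subject or network is
  reproducible in isolation.

Training schedules show each of the 180 stimuli two or three times
(40 stimuli get a third showing to reach 400 trials), shuffled uniformly.
The dissimilarity task uses 40 fixed pairs — 10 K-K, 10 L-L and 20
between-category — presented in the same order before and after training.

## Learning-curve classification

Accuracy is computed in consecutive, non-overlapping 20-trial windows
(`window_accuracy()`). A subject is a **Learner** if there is a first window
from which accuracy stays at or above 80% through the end of the session,
with the sustained run covering at least 60 trials; the **learning point**
is the first trial of that window. A run starting at the very first window
marks an **Immediate** learner (learning point 1, excluded from
before/after ERP contrasts because the "before" part is empty). Subjects
who touch 80% somewhere but do not sustain it are **Borderline**; subjects
who never reach it are **Non-Learners**.

Open choices we fixed:

* Windows tile rather than slide; the sustained-run rule is evaluated on the
  tiled series.
* "At least 60 trials before the end" means the sustained run must begin
  with 60 or more trials remaining (three or more windows).
* The learning point is placed at the first trial of the qualifying window
  rather than at the trial that achieves 16/20 within it; nothing downstream
  is sensitive to this at the 20-trial granularity.
* The Non-Learner/Borderline boundary is "never reaches 80% in any window"
  vs "reaches but does not sustain"; no numeric "around chance" rule is
  used.

For ERP contrasts, Learners split at their learning point and Non-Learners
and Borderlines split in half, so that the first/second-half contrast
controls for mere exposure.

## CP statistics and inferential helpers

For each subject, `cp_stats()` averages the 1-9 dissimilarity ratings by
pair type and phase into `Wpre`, `Wpost`, `Bpre`, `Bpost`, and derives
`diffW = Wpost - Wpre`, `diffB = Bpost - Bpre` and
`global_cp = diffB - diffW`. Global CP is amplified exactly when separation
(positive diffB) and compression (negative diffW) co-occur.

Paired effect sizes are standardized as `d = t / sqrt(df + 1)` (identical
to `mean(diff)/sd(diff)` for raw paired samples; both paths are exposed and
cross-checked in the tests). The shipped reported-outcome tables contain two
effect-size entries that are not consistent with this identity under any
standard paired formula we know; the package standardizes on `t/sqrt(n)`
and carries the reported values unmodified in the data tables.

Rank correlations (`spearman_fisher()`) use mid-rank ties and report a 95%
interval formed on the Fisher scale, `atanh(rho) +/- 1.96/sqrt(n - 3)`,
back-transformed. This is the standard large-sample construction; reported
intervals in the reference tables are not exactly reproducible by any
textbook method we tried, so the package documents and uses this one.

## ERP measurement

Epochs are channels x samples x trials arrays at 500 Hz spanning -1000 to
+2000 ms around stimulus onset. The measurement path is:

1. **Baseline correction** over the 200 ms before onset (per channel, per
   trial).
2. **Extreme-value rejection**: any sample beyond +/-100 uV discards the
   trial.
3. **Probability filter**: per channel, a Gaussian is fitted to that
   channel's voltages pooled over all samples and trials; each trial's
   channel statistic is its mean negative log-density, z-scored across
   trials. A trial is rejected when any channel statistic is improbably
   high — the 2-SD single-channel limit is applied familywise across
   channels with a Sidak adjustment, so the false-rejection rate of clean
   data matches a one-channel test — or when the across-channel mean
   statistic exceeds the 6-SD global limit. Under homogeneous Gaussian
   trials this rejects about 2-4% of trials; a naive per-channel 2-SD union
   test would reject ~20% at 10 channels, which is inconsistent with the
   5-7% rejection regime this filter is meant to reproduce.
4. **Split and average** into before/after ERPs; subjects with more than
   20% of trials rejected in either condition are excluded.
5. **Window/cluster means**: the N1 is measured at 150-220 ms over an
   occipital cluster and the LPC at 600-800 ms over a parietal cluster
   (inclusive window bounds; `component_presets()` ships both experiments'
   published cluster variants, since the reports differ slightly between
   them — the results-section definitions are the defaults).

Continuous-data preprocessing (downsampling, filtering, ICA, bad-channel
interpolation, re-referencing) is out of scope: epochs are assumed to
arrive clean of ocular artifacts, as the synthetic generator produces them.

## The two-phase network model

The model is a single-hidden-layer network over binary N-dimensional
stimuli in which `k_cov` dimensions covary perfectly with the category and
the rest are fair coins. Architecture choices (the sketch leaves them open):
tanh hidden units — activations strictly inside (-1, 1) — with +/-1-coded
inputs, a linear reconstruction head, and a linear single-output category
head with +/-1 targets; full-batch gradient descent with momentum; L2 decay
on non-bias weights. Phase 1 (**unsupervised**) trains the autoencoder,
modeling passive exposure; phase 2 (**supervised**) trains the category
head while fine-tuning the encoder (a flag freezes it). The "before
learning" snapshot is the post-unsupervised state.

A net is a **Learner net** when its final regularized MSE on the last layer
— output MSE plus the L2 penalty on the head's non-bias weights — is at or
below 1e-3 (inclusive bound). CP is measured as mean pairwise Euclidean
distance between hidden representations of a fresh probe set, between- vs
within-category, before vs after supervised learning; **separation** is the
between-distance increase, **compression** the within-distance decrease.
Dimensional reduction is read out as per-input-dimension salience: the norm
of each input dimension's encoder weight row. For Learner nets the
covariant dimensions' salience exceeds the non-covariant dimensions' after
supervision.

Defaults — N = 12, h = 8, 40 items per category, learning rate 0.1,
momentum 0.9, 500/3000 epochs, L2 1e-5 — are desk-scale choices (a full
80-net sweep runs in under half a minute), not published values; none were
published. One empirical subtlety: with momentum on, time-to-threshold is
oscillatory and the Learner fraction at a tight epoch budget is not
monotone in k. With plain gradient descent (momentum 0) the expected
difficulty ordering emerges cleanly — fewer covariant dimensions, lower
Learner fraction at a fixed budget — so the difficulty-trend property test
runs the sweep with momentum off, while the defaults keep momentum for
reliable convergence.

## The synthetic cohort generator

The generator is the package's stand-in for human subjects, and its
defaults *are* the study conditions it emulates:

* **Learning curves**: per-trial correctness is Bernoulli in a logistic
  curve `p(t) = 0.5 + (a - 0.5)/(1 + exp(-(t - t0)/s))` with archetype
  defaults (Learner: onset 150, steepness 10, asymptote 0.95; Immediate:
  onset -50; Borderline: asymptote 0.80 plus a small oscillation;
  Non-Learner: asymptote 0.55). Reaction times are lognormal with a mean
  that declines as the curve rises.
* **Ratings**: `round(clip(base + noise, 1, 9))` with base dissimilarities
  5.0 (between) and 4.3 (within), rating noise SD 1, and injected
  post-training shifts matching the observed regimes — Learners +1.8
  between / -0.43 within; Non-Learners +0.776 / +0.376 (the small
  same-direction "expanding universe" drift).
* **Epochs**: Gaussian N1 template (peak 185 ms, width 25 ms, occipital
  channels, -4 uV attenuating by +1.1 uV after the learning point) and a
  slow LPC template (peak 700 ms, width 80 ms, parietal channels, +2 uV
  boosted by +0.5 uV), plus per-trial DC drift, white noise (SD 8 uV) and
  6% artifact trials carrying 150 uV excursions. The closed-form window
  mean of a template (`template_window_factor()`) provides exact ground
  truth for recovery tests; measured window means agree with it to
  discretization error (< 1% at 500 Hz).

What the generator does **not** emulate: 1/f background spectra, channel
covariance, ocular artifacts, latency jitter, fatigue or strategy shifts,
and rating-scale end-use idiosyncrasies. Passing recovery tests therefore
demonstrates that the analysis operators are correct and unbiased under
white-noise conditions, not that they are robust to every property of real
EEG.

## Problem sizes and numerical choices

The test suite and the worked examples run at desk scale by choice: 1000
random curves for the learner-classification oracle; 50-subject rating
cohorts (recovery bias well under 0.1 rating units); eight 400-trial epoch
sets for ERP recovery (cohort-level Monte-Carlo CI of a few hundredths of a
uV); 20 seeds per k in {3..6} for the net sweep. The default montage is 10
channels rather than 64. Degenerate inputs fail loudly: empty accuracy
series, missing rating phases, baseline windows outside the epoch, unknown
cluster channels, all-trials-rejected subjects, infeasible schedules and
odd set sizes all raise informative errors rather than returning partial
results.

## Known limitations

* The probability filter is a documented, self-contained definition of a
  joint-probability artifact statistic, not a bit-exact reimplementation of
  any particular EEG toolbox.
* Mixed/repeated-measures ANOVA families are deliberately out of scope;
  standard tools (`aov`, `lme4`) apply directly to the exported tables.
* EDF import and HDF5 epoch storage are not provided; epochs are built in
  memory by the generator, and measures are exported as CSV/JSON.
* The net model is a minimal mechanism model; it makes no claim of neural
  realism beyond the separation/compression/dimension-weighting phenomena
  it is built to exhibit.
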