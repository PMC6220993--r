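---
title: "Temporal-generalization decoding of performance monitoring signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal-generalization decoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tgdecode)
```

## The scientific problem

Error-related (ERN) and feedback-related (FRN) evoked responses suggest that
the brain monitors action outcomes with a common machinery regardless of
whether the error is generated by one's own motor act, by an unreliable
effector such as a brain–computer interface (BCI), or signaled by external
feedback. The quantitative test implemented here is *cross-condition
temporal generalization*: train a linear classifier to separate negative
from positive outcomes at every timepoint of one condition and test it at
every timepoint of another condition. Successful transfer requires that the
discriminative neural sources are both spatially similar and functionally
similar across the two settings — a strictly stronger claim than
correlating topographies.

`tgdecode` packages that analysis end to end — per-timepoint decoding,
group-level cluster-mass permutation inference, activation-pattern (Haufe)
extraction and dSPM-style source mapping — together with the online
SSVEP-BCI decoding stack used to run such an experiment, and a
synthetic-data module that generates every input the pipeline consumes, so
that each stage is verifiable without access to recordings.

## The synthetic world

No public recordings exist for this paradigm, so the generator *is* the
experimental world, and its defaults are the stated study design:

* **Task**: 5 blocks x 72 trials (360 total); four stimuli with
  positive-feedback probabilities (0.8, 0.66, 0.33, 0.2); artificial
  decoder errors injected on 15% of trials; when the decoder errs, feedback
  follows the *decoded* stimulus. 500-ms decoding segments, 5-s timeout.
* **Sensors**: a cyclic mix of magnetometers, planar gradiometers and EEG
  electrodes simulated at realistic native magnitudes (hundreds of fT, fT/cm,
  µV via `channel_type_scales()`), so the absolute rejection thresholds
  (12,000 fT / 4,000 fT/cm / 150 µV) are meaningful on synthetic data.
* **Lead field**: random per-type-orthonormalized gain columns with sources
  on a unit hemisphere grid. This supports localization oracles without an
  MRI; it does not emulate realistic field spread.
* **Evoked components**: Gaussian temporal envelopes at a fixed source with
  class-dependent amplitude. Sharing a source index across conditions (at
  different latencies) creates exactly the cross-condition overlap the
  analysis is designed to detect; using different (orthogonalized) columns
  creates the negative control.
* **Noise**: rank-limited spatially mixed AR(1) Gaussian noise plus an
  optional 10-Hz background with per-trial random phase — the minimal model
  with both spatial and temporal correlation. There are no ocular/cardiac
  artifacts, no learning drifts, no head movement; a green test therefore
  establishes algorithmic correctness and statistical calibration under
  exchangeable structured noise, not robustness to real artifacts.
* **Learning**: block-wise probabilities of choosing the better stimulus
  are an *input curve*, not a reinforcement-learning model; the analysis
  only consumes block-wise choice statistics.

Defaults chosen where the design was silent: 20 trials per class per
condition for desk-scale cohorts (commensurate with the late-block surprise
cells of a 360-trial session), 12 channels and 6 sources for the reduced
test world, and a 20 x 20 time grid (0–475 ms at 40 Hz) standing in for the
63 x 63 grid at 125 Hz. These sizes were fixed before the calibration
experiments were run and are not tuned.

## Preprocessing

Filtering uses a Hamming-windowed FIR whose tap count follows the
`6.6 x sfreq / shortest-transition` rule, rounded up to the next odd
integer for symmetric linear phase. Transition bandwidths default to 0.5 Hz
(lower) and 5 Hz (upper) — conventional for a 0.5–20 Hz band; the length
rule is driven by the 0.5-Hz edge. The filter is applied once with
group-delay compensation and odd-reflection edge padding, preserving
component latencies (zero phase). Downsampling to 125 Hz regenerates the
time axis from the epoch start (endpoint-inclusive grid: 0–500 ms at
125 Hz gives 63 samples) and interpolates after a protective anti-alias
low-pass; in intended use the prior 20-Hz low-pass makes this operation
band-limited interpolation.

Epoch rejection uses the **maximum absolute amplitude** per channel
against its type threshold with a *strict* inequality at the boundary; the
wording "amplitudes greater than" favors absolute amplitude over the
peak-to-peak convention of some toolboxes, and we document this as an
explicit choice. Class-count equalization selects the dropped epochs of the
larger class to minimize the summed distance of every remaining trial to
its nearest opposite-class neighbor; the subset is found exhaustively when
the search space is small (and this is verified against brute force) with
a greedy fallback for large problems, ties broken toward dropping the
earliest events.

## Decoding

At each timepoint the feature vector is the concatenation of all channels,
z-scored by *training-fold* statistics (population SD; constant features
are centered, left unscaled and flagged). Z-scoring handles the unit
disparity between magnetometers, gradiometers and EEG. The classifier is
l2-penalized logistic regression in the `C` parameterization
(`0.5*||w||^2 + C*sum(logloss)`, intercept unpenalized, `C = 0.1`),
fitted by Newton/IRLS; no feature selection. Scores are ROC AUC with
midrank tie handling.

Within-condition maps use 3-fold stratified cross-validation with
contiguous-in-time blocks per class (limits leakage through temporally
correlated noise; the original design states only 66/33 splits, so the fold
geometry is our choice, seed-controlled). Cross-condition maps are
bidirectional: three classifiers per direction, each trained on 66% of the
training condition and tested on *all* trials of the other condition; the
six fold maps are averaged after orienting the reverse-direction maps so
rows always index the first condition's time axis. Testing on the full
other condition (sub-sampling only the training side) compresses the null
distribution of the grand-average AUC around 50%, which the null-calibration
acceptance test verifies empirically. The "negative outcome" class (error,
negative feedback, high surprise) is the positive class everywhere;
cross-condition analyses refuse to run unless both collections declare
their polarity.

## Group inference

Subject maps are reduced to deviations from the theoretical 50% chance
level; a one-sample t map is thresholded at the one-tailed t critical value
for p < .01 (df = n−1), and suprathreshold cells are clustered under
**4-connectivity** on the time x time grid (the conservative standard for
2-D cluster tests; the design was silent). Cluster mass is the sum of
signed t values. The null records, for each of 10,000 random sign
assignments of the subjects' deviation maps, the maximum positive cluster
mass; cluster p = (1 + #{perm max >= mass}) / (1 + n_perm), so p is never
zero. Only positive (above-chance) clusters are formed. Degenerate
zero-variance cells receive an infinite-t sentinel and are flagged.

One caveat we document rather than hide: a literal invariance of p to
adding a constant to every subject's map cannot hold when the chance
reference is fixed — the test verifies instead that shifting all maps *and*
the chance reference together leaves p unchanged. The ERP-level check is a
standard two-sample max-|t| permutation test with family-wise correction by
the permutation maximum (two-tailed, 10,000 permutations by default).

## Patterns and sources

For each subject the peak of the generalization map inside a cluster (or
time-window box) defines a 3-sample (16 ms at 125 Hz) train-time window;
ties break toward the earliest train then test time, and edge-clipped
windows are flagged. Classifier weights are backward-model coefficients and
are not interpretable as activations, so they are transformed to patterns
by multiplication with the signal covariance, computed from the original
(non-downsampled) data within the same 16-ms window with a *global* channel
demeaning — per-trial demeaning would remove precisely the evoked structure
the pattern should reflect.

The inverse is a minimum-norm estimate on the synthetic lead field: noise
whitening from the 200-ms pre-stimulus covariance (diagonal-loading
shrinkage when ill-conditioned), a loose orientation constraint
implemented as variance weight 0.2 on two auxiliary tangential gain columns
per source, Tikhonov regularization `lambda^2 = 1/snr^2` (trace-ratio SNR)
after scaling the whitened source-weighted gain to unit mean power, and
dSPM normalization of the per-source amplitude by its noise sensitivity.
The exact whitening and regularization constants of production MEG software
are not reproduced; the inverse is validated by synthetic localization
oracles (planted single and double sources, monotone improvement with SNR),
not by matching any published source figure. Maps are thresholded at 90% of
the global maximum, inclusively.

## The online BCI stack

Spatio-spectral decomposition (SSD) solves the generalized eigenproblem of
signal-band versus flanking-band covariance. The default band layout covers
both SSVEP tags with one filter set (signal 11–16 Hz; 2-Hz flanks separated
by 1-Hz gaps), returning 4 components; the flank covariance is rescaled by
the filters' equivalent-noise-bandwidth ratio so white noise yields
eigenvalues near 1, making the eigenvalue scale interpretable as in-band
enhancement. Per 500-ms segment, component time courses are fit with a GLM
(sine/cosine pairs at 12, 15, 10, 50 Hz plus DC and trend), and the
amplitude at each target frequency is the norm of its sine/cosine pair —
exact for noiseless in-band content regardless of phase.

The 8 amplitude features (2 frequencies x 4 components) feed a linear
max-margin classifier (squared-hinge primal, `C = 0.5`) with Platt-style
sigmoid calibration fitted on 3-fold cross-validated decision values (the
fold count is our choice; the design says only "cross validation"). The
sequential rule decides when two consecutive segments agree with calibrated
posterior above 0.75, bounding the decision error at `0.25^2 = 0.0625`
under per-segment independence, and times out after 10 segments (5 s).
SSD filters and the classifier are fixed after calibration, matching a
design where online blocks follow a calibration block.

## Numerical choices and degenerate inputs

* FIR taps forced odd; passband gain normalized at the band's geometric
  center frequency.
* IRLS ridge keeps weights finite on separable data; solver tolerance 1e-6
  on the gradient, max 1000 iterations.
* Zero-variance features: divisor 1, flagged. Zero-SE t cells: ±Inf
  sentinel, flagged. Empty cluster lists are valid results.
* All stochastic operations route through one seed utility that restores
  the caller's RNG state; identical seeds give bit-identical outputs.
* Covariance shrinkage: 10% diagonal loading toward the mean variance when
  pooled samples < channels + 1 or condition number > 1e8.

## Known limitations

The synthetic lead field has no realistic geometry, so source-level results
validate the *algorithm*, not anatomical claims. The noise model contains
no artifacts, so rejection thresholds are exercised only by construction.
The acceptance-scale cohorts run on a reduced grid (20 x 20) and modest
channel counts; the full 63 x 63 analysis is supported but not exercised in
the default test run for time reasons. The cohort-level results of the
original study (within-condition AUC maxima in the high 50s to mid 60s,
cross-condition maxima in the mid 50s) depend on real recordings and are
out of scope here by design.
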