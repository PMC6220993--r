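# tgdecode

Time-resolved multivariate decoding of multichannel neural recordings
(MEG/EEG), built around one scientific question: do different kinds of
performance errors — an erroneous motor act, a misbehaving brain–computer
interface (BCI), surprising negative feedback — engage a *common*
outcome-monitoring process? The quantitative instrument is
**cross-condition temporal generalization**: a classifier trained to
separate negative from positive outcomes at time *t* of one condition is
tested at every time *t′* of another condition, giving a train-time ×
test-time ROC-AUC map per subject. Transfer above chance requires the
discriminative sources to be shared across conditions, both spatially and
functionally.

The package implements, for R users:

* **Synthetic data** — forward models (lead fields), condition-structured
  epochs with class-dependent evoked components and structured noise,
  probabilistic-feedback task sessions (5 × 72 trials, reward probabilities
  0.8/0.66/0.33/0.2, 15% injected decoder errors), and amplitude-modulated
  SSVEP streams. Every downstream stage is testable without recordings.
* **Preprocessing** — Hamming-window FIR band-pass (0.5–20 Hz, the
  6.6×/transition length rule), downsampling to 125 Hz, absolute-amplitude
  epoch rejection (12,000 fT / 4,000 fT/cm / 150 µV), baseline correction,
  and class-count equalization that minimizes inter-trial time gaps.
* **Decoding** — per-timepoint l2-logistic classifiers (`C = 0.1`,
  train-set standardization), within-condition 3-fold and bidirectional
  cross-condition 6-fold generalization maps (`scores[i, j]` = AUC for
  train time i, test time j).
* **Inference** — one-sample sign-flip cluster-mass permutation test
  (cluster-forming p < .01, mass = sum of signed t, 10,000 permutations)
  and a two-sample max-statistic permutation test for sensor ERPs.
* **Patterns & sources** — Haufe transformation of classifier weights into
  activation patterns (16-ms windows around subject-level generalization
  peaks) and a dSPM-style noise-normalized minimum-norm inverse (loose
  orientation 0.2, trace-ratio SNR, 90%-of-peak thresholding) on the
  synthetic lead field.
* **BCI decoder** — the online SSVEP stack: spatio-spectral decomposition
  (4 components), per-500-ms GLM amplitude estimation at 12/15 Hz (with
  10-Hz alpha, 50-Hz line, DC and trend nuisances), calibrated linear
  classification (`C = 0.5`), and the sequential rule "two consecutive
  segments above posterior 0.75" (decision error ≤ 0.25² = 0.0625),
  timing out at 5 s.

See `vignettes/methods.Rmd` for the models, assumptions, parameter
defaults and limitations.

## Worked example

Thirteen simulated subjects share one generative source that discriminates
outcomes at 100 ms in a "motor" condition and at 350 ms in a "bci"
condition; the cross-condition map should light up around (100 ms, 350 ms):

```r
library(tgdecode)

fm <- make_forward_model(n_channels = 12, n_sources = 6, seed = 1)
shared <- function(cond, latency, seed) {
  cmp <- source_component(3, latency, width = 0.03,
                          amplitude_by_class = c(pos = 0, neg = 2),
                          conditions = cond)
  simulate_epochs(fm, list(cmp), noise_spec(seed = seed),
                  n_per_class = c(pos = 20, neg = 20), cond,
                  window = c(0, 0.475), sfreq = 40, seed = seed,
                  positive_label = "neg")
}
maps <- lapply(1:13, function(s) {
  a <- shared("motor", 0.10, 100 + 2 * s)
  b <- shared("bci",   0.35, 101 + 2 * s)
  cross_condition_generalization(a, b, seed = s)
})
maps[[1]]
#> <generalization_map> 20x20 [cross-6fold-bidirectional], mean AUC 0.517

signflip_cluster_test(maps, n_perm = 1000, seed = 7)
#> <cluster_result> 13 subjects, threshold t > 2.681, 1000 perms
#>   cluster: 24 cells, mass 207.1, p = 0.0010
#>   cluster: 1 cells, mass 3.0, p = 0.7962
#>   cluster: 1 cells, mass 2.9, p = 0.8212
```

The 24-cell cluster (p = .001) is the planted transfer: its cells sit
around train times near 100 ms and test times near 350 ms, while the
stray single-cell clusters are noise and not significant. Per-subject
extraction then locates each subject's peak inside the cluster mask:

```r
res <- signflip_cluster_test(maps, n_perm = 1000, seed = 7)
find_subject_maxima(maps[[1]], res$clusters[[1]]$mask)
#> subject 1 peak: train 100 ms, test 350 ms, AUC 0.970
```

From there, `weights_to_patterns()` + `signal_cov_window()` turn the
classifier weights at the peak into activation patterns, and `dspm_map()`
projects them onto the synthetic source grid (`threshold_map()` keeps
sources within 90% of the peak).

## Command line

A thin CLI ships at `inst/cli/tgdecode`:

```sh
tgdecode=$(Rscript -e 'cat(system.file("cli/tgdecode", package = "tgdecode"))')
Rscript "$tgdecode" simulate session --out session.csv --seed 1
Rscript "$tgdecode" simulate epochs --config cfg.json --out epochs.json --seed 1
Rscript "$tgdecode" decode within --in epochs.json --out map.json --seed 1
```
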