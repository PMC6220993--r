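# Shared fixtures: small forward models and epoch simulators sized for fast
# tests. All randomness is seeded through the package API.

quiet_noise <- function(seed = 1, alpha = 0) {
  noise_spec(sensor_sd_by_type = c(mag = 0, grad = 0, eeg = 0),
             alpha_amplitude = alpha, seed = seed)
}

test_fm <- function(n_channels = 12, n_sources = 6, seed = 1, ...) {
  make_forward_model(n_channels, n_sources, seed = seed, ...)
}

std_noise <- function(seed = 1, sd_scale = 1, rank = 6) {
  noise_spec(sensor_sd_by_type = sd_scale * c(mag = 300, grad = 100, eeg = 10),
             ar_coefficient = 0.5, spatial_mixing_rank = rank, seed = seed)
}

# Epochs with no class-dependent signal on a 20-sample grid (0-475 ms @40 Hz)
null_epochs <- function(seed, condition = "A", fm = test_fm(),
                        n_per_class = c(pos = 20, neg = 20)) {
  simulate_epochs(fm, list(), std_noise(seed = 1000 + seed), n_per_class,
                  condition, window = c(0, 0.475), sfreq = 40, seed = seed,
                  positive_label = "neg")
}

# Epochs with a class-discriminative source at `latency` through gain column
# `src`; amplitude in units of the per-type sensor scale.
planted_epochs <- function(seed, condition, src, latency, amplitude = 4,
                           fm = test_fm(), width = 0.03,
                           n_per_class = c(pos = 20, neg = 20)) {
  cmp <- source_component(src, latency, width,
                          c(pos = 0, neg = amplitude), conditions = condition)
  simulate_epochs(fm, list(cmp), std_noise(seed = 1000 + seed), n_per_class,
                  condition, window = c(0, 0.475), sfreq = 40, seed = seed,
                  positive_label = "neg")
}

# trial table built by hand for counting tests
manual_trial_table <- function(block, decoded, other, valence,
                               artificial_error = FALSE,
                               probs = c(0.8, 0.66, 0.33, 0.2)) {
  n <- length(block)
  tbl <- data.frame(block = block, stim_a = decoded, stim_b = other,
                    intended = decoded, decoded = decoded,
                    artificial_error = rep_len(artificial_error, n),
                    valence = valence, surprise = "none",
                    stringsAsFactors = FALSE)
  attr(tbl, "reward_probabilities") <- probs
  class(tbl) <- c("trial_table", "data.frame")
  tbl
}
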