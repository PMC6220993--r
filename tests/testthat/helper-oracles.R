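# Independent brute-force oracles used by both the module tests and the
# acceptance suite. These deliberately avoid the package's own algorithms.

# O(n^2) pairwise-count AUC with half credit for ties
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# minimal epoch collection with prescribed per-class event times
make_timed_epochs <- function(ev_a, ev_b) {
  n <- length(ev_a) + length(ev_b)
  ord <- order(c(ev_a, ev_b))
  labels <- c(rep("A", length(ev_a)), rep("B", length(ev_b)))[ord]
  epoch_collection(array(rnorm(n * 2 * 3), dim = c(n, 2, 3)), labels, "c",
                   times = c(0, 0.1, 0.2), sfreq = 10,
                   channel_types = c("eeg", "eeg"),
                   event_times = sort(c(ev_a, ev_b)))
}

# exhaustive minimizer over all drop subsets of the larger class
brute_force_mintime <- function(x) {
  classes <- sort(unique(x$labels))
  counts <- table(factor(x$labels, levels = classes))
  larger <- classes[which.max(counts)]
  n_drop <- abs(diff(as.vector(counts)))
  if (n_drop == 0) return(seq_len(n_trials(x)))
  cand <- which(x$labels == larger)
  subsets <- utils::combn(cand, n_drop)
  best_cost <- Inf; best_keep <- NULL
  for (j in seq_len(ncol(subsets))) {
    keep <- setdiff(seq_len(n_trials(x)), subsets[, j])
    cost <- tgdecode:::mintime_cost(
      x$event_times[keep[x$labels[keep] == larger]],
      x$event_times[keep[x$labels[keep] != larger]])
    if (cost < best_cost - 1e-12) { best_cost <- cost; best_keep <- keep }
  }
  best_keep
}
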