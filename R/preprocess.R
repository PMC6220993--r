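#' Absolute-amplitude rejection criteria
#'
#' Default thresholds: 12,000 fT for magnetometers, 4,000 fT/cm for planar
#' gradiometers, 150 uV for EEG.
#'
#' @param max_abs_by_type Named numeric vector of per-type thresholds in
#'   native units; all > 0.
#' @return A `rejection_criteria` object.
#' @export
rejection_criteria <- function(max_abs_by_type = c(mag = 12000, grad = 4000,
                                                   eeg = 150)) {
  if (any(max_abs_by_type <= 0)) stop("thresholds must be > 0", call. = FALSE)
  structure(list(max_abs_by_type = max_abs_by_type),
            class = "rejection_criteria")
}

#' Reject epochs by maximum absolute amplitude
#'
#' An epoch is dropped iff any channel's maximum absolute amplitude
#' *strictly* exceeds the threshold for its channel type; values exactly at
#' threshold are kept. Survivor order is preserved.
#'
#' @param x An `epoch_collection`.
#' @param crit A [rejection_criteria()].
#' @return List with elements `epochs` (the surviving collection) and
#'   `rejected` (integer indices of dropped epochs).
#' @export
reject_by_amplitude <- function(x, crit = rejection_criteria()) {
  stopifnot(inherits(x, "epoch_collection"))
  thr <- crit$max_abs_by_type[x$channel_types]
  if (anyNA(thr)) {
    stop("rejection criteria missing a threshold for a present channel type",
         call. = FALSE)
  }
  n <- n_trials(x)
  bad <- vapply(seq_len(n), function(i) {
    peak <- apply(abs(x$data[i, , , drop = TRUE]), 1L, max)
    any(peak > thr)
  }, logical(1L))
  if (all(bad)) stop("empty result: all epochs rejected", call. = FALSE)
  list(epochs = x[which(!bad)], rejected = which(bad))
}

#' Baseline correction
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window from the whole epoch.
#'
#' @param x An `epoch_collection`.
#' @param baseline Length-2 `(start, stop)` in seconds, `start < stop`,
#'   within the epoch's time range.
#' @return The corrected `epoch_collection`.
#' @export
baseline_correct <- function(x, baseline = c(-0.2, 0)) {
  stopifnot(inherits(x, "epoch_collection"))
  if (baseline[2L] <= baseline[1L]) {
    stop("invalid window: baseline start must precede stop", call. = FALSE)
  }
  sel <- x$times >= baseline[1L] - 1e-9 & x$times <= baseline[2L] + 1e-9
  if (!any(sel)) stop("invalid window: baseline outside epoch", call. = FALSE)
  means <- apply(x$data[, , sel, drop = FALSE], c(1L, 2L), mean)
  x$data <- x$data - as.vector(means)    # recycles over the samples dimension
  x
}

# total nearest-opposite-class gap after removing `drop` (indices into
# event_times) from the larger class
mintime_cost <- function(ev_a, ev_b) {
  cost <- 0
  for (t in ev_a) cost <- cost + min(abs(ev_b - t))
  for (t in ev_b) cost <- cost + min(abs(ev_a - t))
  cost
}

#' Equalize class counts by minimal inter-trial time gaps
#'
#' Drops epochs from the initially larger class until counts are equal so
#' that the retained classes are maximally interleaved in time: the dropped
#' subset minimizes the sum, over all remaining epochs, of the distance to
#' the nearest opposite-class event. When the number of candidate subsets
#' is small (up to `max_exhaustive`) the minimizer is found exhaustively;
#' larger problems use a greedy one-epoch-at-a-time approximation. Ties
#' break toward dropping the earliest event times.
#'
#' @param x An `epoch_collection` with exactly two classes and event times.
#' @param max_exhaustive Subset-count limit for the exact search.
#' @return The equalized `epoch_collection`.
#' @export
equalize_classes_mintime <- function(x, max_exhaustive = 10000) {
  stopifnot(inherits(x, "epoch_collection"))
  classes <- sort(unique(x$labels))
  counts <- table(factor(x$labels, levels = classes))
  if (length(classes) != 2L || any(counts == 0L)) {
    stop("insufficient trials: need two non-empty classes", call. = FALSE)
  }
  if (counts[[1L]] == counts[[2L]]) return(x)
  larger <- classes[which.max(counts)]
  keep <- seq_len(n_trials(x))
  n_drop <- abs(counts[[1L]] - counts[[2L]])
  cand_all <- which(x$labels == larger)
  if (choose(length(cand_all), n_drop) <= max_exhaustive) {
    # exact: enumerate drop subsets (event_times increase with index, so the
    # first strict minimum realizes the earliest-time tie-break)
    subsets <- utils::combn(cand_all, n_drop)
    best_cost <- Inf
    best_keep <- NULL
    for (j in seq_len(ncol(subsets))) {
      kp <- setdiff(keep, subsets[, j])
      cost <- mintime_cost(x$event_times[kp[x$labels[kp] == larger]],
                           x$event_times[kp[x$labels[kp] != larger]])
      if (cost < best_cost - 1e-12) {
        best_cost <- cost
        best_keep <- kp
      }
    }
    return(x[best_keep])
  }
  for (step in seq_len(n_drop)) {
    cand <- keep[x$labels[keep] == larger]
    other_ev <- x$event_times[keep[x$labels[keep] != larger]]
    best <- NULL
    best_cost <- Inf
    for (i in cand) {
      rest <- setdiff(keep, i)
      cost <- mintime_cost(x$event_times[rest[x$labels[rest] == larger]],
                           other_ev)
      if (cost < best_cost - 1e-12 ||
          (abs(cost - best_cost) <= 1e-12 &&
           !is.null(best) && x$event_times[i] < x$event_times[best])) {
        best <- i
        best_cost <- cost
      }
    }
    keep <- setdiff(keep, best)
  }
  x[keep]
}
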