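#' Epoch collection container
#'
#' Trials x channels x samples array with labels, condition tag, time axis,
#' sampling rate and channel metadata — the package's canonical container
#' for epoched sensor data.
#'
#' @param data Numeric array, trials x channels x samples, native units.
#' @param labels Character vector of per-trial class labels.
#' @param condition Single condition tag.
#' @param times Numeric vector of sample times in seconds relative to the
#'   reference event; must be uniformly spaced at `1/sfreq`.
#' @param sfreq Sampling rate, Hz.
#' @param channel_types Per-channel type tags (`mag`, `grad`, `eeg`).
#' @param event_times Per-trial absolute onsets in seconds, strictly
#'   increasing.
#' @param positive_label Optional class label to treat as the positive class
#'   (convention: the "negative outcome" class — error, negative feedback,
#'   high surprise).
#' @return An `epoch_collection` object.
#' @export
epoch_collection <- function(data, labels, condition, times, sfreq,
                             channel_types, event_times = NULL,
                             positive_label = NULL) {
  stopifnot(length(dim(data)) == 3L)
  labels <- as.character(labels)
  if (length(labels) != dim(data)[1L]) {
    stop("`labels` length must equal trial count", call. = FALSE)
  }
  if (length(times) != dim(data)[3L]) {
    stop("`times` length must equal sample count", call. = FALSE)
  }
  if (length(times) > 1L) {
    dt <- diff(times)
    if (max(abs(dt - 1 / sfreq)) > 1e-6 / sfreq) {
      stop("`times` must be uniformly spaced at 1/sfreq", call. = FALSE)
    }
  }
  if (length(channel_types) != dim(data)[2L]) {
    stop("`channel_types` length must equal channel count", call. = FALSE)
  }
  if (is.null(event_times)) {
    event_times <- seq_len(dim(data)[1L]) * 2.0
  }
  if (is.unsorted(event_times, strictly = TRUE)) {
    stop("`event_times` must be strictly increasing", call. = FALSE)
  }
  structure(list(data = data, labels = labels, condition = condition,
                 times = as.numeric(times), sfreq = sfreq,
                 channel_types = channel_types,
                 event_times = as.numeric(event_times),
                 positive_label = positive_label),
            class = "epoch_collection")
}

#' @export
print.epoch_collection <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_collection> '%s': %d trials x %d channels x %d samples @ %g Hz, %.0f-%.0f ms\n",
    x$condition, d[1L], d[2L], d[3L], x$sfreq,
    1000 * min(x$times), 1000 * max(x$times)))
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$labels)),
                                  table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset trials of an epoch collection
#'
#' @param x An `epoch_collection`.
#' @param i Trial index vector.
#' @param ... Ignored.
#' @return The subsetted `epoch_collection`.
#' @export
`[.epoch_collection` <- function(x, i, ...) {
  epoch_collection(x$data[i, , , drop = FALSE], x$labels[i], x$condition,
                   x$times, x$sfreq, x$channel_types, x$event_times[i],
                   x$positive_label)
}

#' Number of trials
#' @param x An `epoch_collection`.
#' @return Integer trial count.
#' @export
n_trials <- function(x) dim(x$data)[1L]

# Structured noise: rank-limited spatially mixed AR(1) plus optional 10-Hz
# sinusoid with per-trial random phase. Mixing/topography are drawn from the
# noise spec's own seed so the spatial noise structure is a property of the
# spec, not of the simulation call.
make_noise_generator <- function(noise, channel_types, n_samples, times) {
  n_channels <- length(channel_types)
  rank <- min(noise$spatial_mixing_rank, n_channels)
  sds <- noise$sensor_sd_by_type[channel_types]
  if (anyNA(sds)) stop("noise spec missing SD for a present channel type",
                       call. = FALSE)
  mix_alpha <- with_seed(noise$seed, {
    m <- matrix(stats::rnorm(n_channels * rank), n_channels, rank)
    m <- m / sqrt(rowSums(m^2))          # unit channel variance before SD scale
    a <- stats::rnorm(n_channels)
    a <- a / sqrt(mean(a^2))
    list(mix = m * sds, alpha_topo = a * sds)
  })
  ar <- noise$ar_coefficient
  innov_sd <- sqrt(1 - ar^2)
  function() {                            # one trial's channels x samples noise
    z <- matrix(stats::rnorm(rank * n_samples), rank, n_samples)
    if (ar > 0) {
      z[, 1L] <- z[, 1L]                  # marginal N(0,1)
      for (s in 2:max(2L, n_samples)) {
        if (s > n_samples) break
        z[, s] <- ar * z[, s - 1L] + innov_sd * z[, s]
      }
    }
    out <- mix_alpha$mix %*% z
    if (noise$alpha_amplitude > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      out <- out + noise$alpha_amplitude *
        outer(mix_alpha$alpha_topo, sin(2 * pi * 10 * times + phase))
    }
    out
  }
}

#' Simulate condition-structured epochs
#'
#' Each trial is the sum, over components active in `condition`, of the
#' component's gain column times its class amplitude times a Gaussian
#' temporal envelope, plus one realization of the structured noise. The
#' signal model is exactly linear in the component amplitudes.
#'
#' @param fm A [make_forward_model()] object.
#' @param components List of [source_component()] objects.
#' @param noise A [noise_spec()].
#' @param n_per_class Named integer vector: trials per class label.
#' @param condition Condition tag attached to the collection.
#' @param window Length-2 numeric `(start, stop)` in seconds; must cover
#'   every active component's latency +/- 3 widths.
#' @param sfreq Sampling rate, Hz.
#' @param seed Integer seed; data are bit-reproducible in it.
#' @param positive_label Forwarded to [epoch_collection()].
#' @return An `epoch_collection`.
#' @export
simulate_epochs <- function(fm, components, noise, n_per_class, condition,
                            window = c(0, 0.5), sfreq = 125, seed = 1,
                            positive_label = NULL) {
  stopifnot(inherits(fm, "forward_model"))
  stopifnot_scalar_num(sfreq, "sfreq", 0, strict_lower = TRUE)
  classes <- names(n_per_class)
  if (is.null(classes)) stop("`n_per_class` must be named", call. = FALSE)
  active <- Filter(function(cp) is.null(cp$conditions) ||
                     condition %in% cp$conditions, components)
  for (cp in active) {
    if (cp$source_index > ncol(fm$gain)) {
      stop("component source_index outside forward model", call. = FALSE)
    }
    if (!all(classes %in% names(cp$amplitude_by_class))) {
      missing_cl <- setdiff(classes, names(cp$amplitude_by_class))
      stop(sprintf("labeling error: class '%s' missing from amplitude_by_class",
                   missing_cl[1L]), call. = FALSE)
    }
    if (cp$latency - 3 * cp$width < window[1L] - 1e-9 ||
        cp$latency + 3 * cp$width > window[2L] + 1e-9) {
      stop("window must cover component latencies +/- 3 widths", call. = FALSE)
    }
  }
  times <- seq(window[1L], window[2L] + 1e-9, by = 1 / sfreq)
  n_samples <- length(times)
  n_channels <- nrow(fm$gain)
  n_tot <- sum(n_per_class)

  with_seed(seed, {
    labels <- sample(rep(classes, times = n_per_class))
    event_times <- cumsum(1.5 + stats::runif(n_tot, 0, 1))
    gen_noise <- make_noise_generator(noise, fm$channel_types, n_samples, times)

    # class-specific noise-free templates (channels x samples)
    templates <- lapply(classes, function(cl) {
      tpl <- matrix(0, n_channels, n_samples)
      for (cp in active) {
        env <- exp(-(times - cp$latency)^2 / (2 * cp$width^2))
        tpl <- tpl + cp$amplitude_by_class[[cl]] *
          outer(fm$gain[, cp$source_index], env)
      }
      tpl
    })
    names(templates) <- classes

    data <- array(0, dim = c(n_tot, n_channels, n_samples))
    for (i in seq_len(n_tot)) {
      data[i, , ] <- templates[[labels[i]]] + gen_noise()
    }
    epoch_collection(data, labels, condition, times, sfreq,
                     fm$channel_types, event_times, positive_label)
  })
}
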