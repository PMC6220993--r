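#' Simulate a continuous SSVEP sensor stream
#'
#' Each tagged frequency is carried by its own forward-model gain column
#' (column `k` for the `k`-th entry of `amplitudes`), with the attended
#' frequency given the larger amplitude by the caller. A 10-Hz alpha
#' background and 50-Hz line interference use the next two gain columns, and
#' structured sensor noise is added on top.
#'
#' @param duration Stream length in seconds (>= one 0.5-s segment).
#' @param sfreq Sampling rate, Hz (> twice the highest simulated frequency).
#' @param attended_freq Attended flicker frequency; must be a name of
#'   `amplitudes`.
#' @param amplitudes Named numeric vector, frequency (Hz, as names) to
#'   source amplitude.
#' @param alpha_amplitude Amplitude of the 10-Hz background.
#' @param line_amplitude Amplitude of the 50-Hz interference.
#' @param fm [make_forward_model()] with at least `length(amplitudes) + 2`
#'   sources.
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @return Channels x samples matrix with attributes `sfreq`, `times`,
#'   `attended_freq` and `channel_types`.
#' @export
simulate_ssvep <- function(duration, sfreq, attended_freq, amplitudes,
                           alpha_amplitude = 0, line_amplitude = 0,
                           fm, noise = noise_spec(), seed = 1) {
  freqs <- as.numeric(names(amplitudes))
  if (anyNA(freqs)) stop("`amplitudes` must be named by frequency",
                         call. = FALSE)
  if (!any(abs(freqs - attended_freq) < 1e-9)) {
    stop("attended_freq must be among `amplitudes`", call. = FALSE)
  }
  if (duration < 0.5) stop("duration must cover at least one 0.5-s segment",
                           call. = FALSE)
  active <- c(freqs,
              if (alpha_amplitude > 0) 10,
              if (line_amplitude > 0) 50)
  if (sfreq < 2 * max(active)) {
    stop(sprintf("aliasing error: sfreq %g < 2 x %g Hz", sfreq, max(active)),
         call. = FALSE)
  }
  n_need <- length(freqs) + 2L
  if (ncol(fm$gain) < n_need) {
    stop(sprintf("forward model needs >= %d sources", n_need), call. = FALSE)
  }
  n <- floor(duration * sfreq)
  times <- (seq_len(n) - 1L) / sfreq
  with_seed(seed, {
    x <- matrix(0, nrow(fm$gain), n)
    for (k in seq_along(freqs)) {
      phase <- stats::runif(1, 0, 2 * pi)
      x <- x + amplitudes[[k]] *
        outer(fm$gain[, k], sin(2 * pi * freqs[k] * times + phase))
    }
    if (alpha_amplitude > 0) {
      x <- x + alpha_amplitude *
        outer(fm$gain[, length(freqs) + 1L],
              sin(2 * pi * 10 * times + stats::runif(1, 0, 2 * pi)))
    }
    if (line_amplitude > 0) {
      x <- x + line_amplitude *
        outer(fm$gain[, length(freqs) + 2L],
              sin(2 * pi * 50 * times + stats::runif(1, 0, 2 * pi)))
    }
    gen <- make_noise_generator(noise, fm$channel_types, n, times)
    x <- x + gen()
    attr(x, "sfreq") <- sfreq
    attr(x, "times") <- times
    attr(x, "attended_freq") <- attended_freq
    attr(x, "channel_types") <- fm$channel_types
    x
  })
}
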