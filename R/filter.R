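#' Band-pass FIR filter specification
#'
#' Hamming-windowed FIR band-pass whose length follows the rule: number of
#' taps = `length_factor` times the reciprocal of the shortest transition
#' band (in seconds of signal), i.e. `length_factor * sfreq /
#' min(transition_low, transition_high)`, rounded up to the next odd integer
#' for a symmetric linear-phase filter. Transition bandwidths default to
#' 0.5 Hz at the lower edge and 5 Hz at the upper edge — conventional for a
#' 0.5-20 Hz evoked-response band.
#'
#' @param low_cut Lower pass edge, Hz.
#' @param high_cut Upper pass edge, Hz.
#' @param window Taper name; only `"hamming"` is implemented.
#' @param length_factor Filter-length factor (default 6.6).
#' @param transition_low,transition_high Transition bandwidths, Hz.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(low_cut = 0.5, high_cut = 20, window = "hamming",
                        length_factor = 6.6, transition_low = 0.5,
                        transition_high = 5) {
  stopifnot_scalar_num(low_cut, "low_cut", 0, strict_lower = TRUE)
  if (high_cut <= low_cut) stop("need low_cut < high_cut", call. = FALSE)
  stopifnot_scalar_num(length_factor, "length_factor", 0, strict_lower = TRUE)
  if (!identical(window, "hamming")) {
    stop("only the hamming window is supported", call. = FALSE)
  }
  structure(list(low_cut = low_cut, high_cut = high_cut, window = window,
                 length_factor = length_factor,
                 transition_low = transition_low,
                 transition_high = transition_high),
            class = "filter_spec")
}

#' Number of FIR taps implied by a filter spec
#'
#' @param spec A [filter_spec()].
#' @param sfreq Sampling rate, Hz.
#' @return Odd integer tap count.
#' @export
fir_n_taps <- function(spec, sfreq) {
  n <- ceiling(spec$length_factor * sfreq /
                 min(spec$transition_low, spec$transition_high))
  as.integer(if (n %% 2 == 0) n + 1 else n)
}

# Windowed-sinc band-pass taps. Cutoffs sit at the band edges +/- half a
# transition width so the nominal edges fall at ~-6 dB, matching firwin-style
# designs. low_cut = NULL gives a low-pass.
fir_design <- function(spec, sfreq) {
  n <- fir_n_taps(spec, sfreq)
  m <- (n - 1L) / 2L
  k <- seq(-m, m)
  win <- 0.54 + 0.46 * cos(pi * k / m)    # hamming
  f_hi <- (spec$high_cut + spec$transition_high / 2) / sfreq
  if (f_hi >= 0.5) stop("high_cut too close to Nyquist", call. = FALSE)
  sinc <- function(f) ifelse(k == 0, 2 * f, sin(2 * pi * f * k) / (pi * k))
  h <- sinc(f_hi)
  if (!is.null(spec$low_cut) && spec$low_cut > 0) {
    f_lo <- max(0, (spec$low_cut - spec$transition_low / 2)) / sfreq
    h <- h - sinc(f_lo)
  }
  h <- h * win
  # normalize passband gain to 1 at the band's geometric center
  fc <- if (is.null(spec$low_cut) || spec$low_cut == 0) 0 else
    sqrt(spec$low_cut * spec$high_cut) / sfreq
  gain <- sum(h * cos(2 * pi * fc * k))
  h / gain
}

# Zero-phase application of a symmetric FIR to the rows of a matrix
# (channels x samples): FFT convolution with reflective edge padding and
# group-delay compensation. `check_length` enforces the too-short-signal
# contract for user-facing filtering.
apply_fir <- function(x, h, check_length = TRUE) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  L <- length(h)
  m <- (L - 1L) %/% 2L
  if (check_length && n < L) {
    stop(sprintf("too-short signal: %d samples < %d filter taps", n, L),
         call. = FALSE)
  }
  # reflective padding (repeat-reflect when the signal is shorter than m)
  pad_idx <- function(idx) {
    p <- 2L * n - 2L
    if (p <= 0) return(rep(1L, length(idx)))
    idx <- ((idx - 1L) %% p) + 1L
    ifelse(idx > n, p - idx + 2L, idx)
  }
  left <- if (m > 0L) pad_idx(rev(seq_len(m)) + 1L) else integer(0)
  right <- if (m > 0L) pad_idx(n - seq_len(m)) else integer(0)
  # odd (antisymmetric) reflection about the endpoint values limits edge kinks
  xp <- cbind(2 * x[, 1L] - x[, left, drop = FALSE], x,
              2 * x[, n] - x[, right, drop = FALSE])
  np <- ncol(xp)
  nfft <- stats::nextn(np + L - 1L, 2)
  H <- stats::fft(c(h, numeric(nfft - L)))
  out <- t(apply(xp, 1L, function(row) {
    y <- Re(stats::fft(stats::fft(c(row, numeric(nfft - np))) * H,
                       inverse = TRUE)) / nfft
    y[(m + 1L):(m + np)]
  }))
  out <- out[, (m + 1L):(m + n), drop = FALSE]
  if (vec) drop(out) else out
}

#' Zero-phase band-pass filtering
#'
#' Applies the Hamming-windowed FIR band-pass of `spec` to a continuous
#' channels x samples matrix or to every trial of an [epoch_collection()].
#' The linear-phase filter is applied once with group-delay compensation and
#' reflective edge padding, so event latencies are preserved.
#'
#' @param x `epoch_collection` or numeric matrix (channels x samples) or
#'   vector.
#' @param spec A [filter_spec()].
#' @param sfreq Sampling rate, required when `x` is a bare matrix/vector.
#' @return Filtered object of the same shape.
#' @export
bandpass_filter <- function(x, spec = filter_spec(), sfreq = NULL) {
  if (inherits(x, "epoch_collection")) {
    if (x$sfreq <= 2 * spec$high_cut) {
      stop("sfreq must exceed twice the upper pass edge", call. = FALSE)
    }
    h <- fir_design(spec, x$sfreq)
    d <- x$data
    for (i in seq_len(dim(d)[1L])) {
      d[i, , ] <- apply_fir(d[i, , , drop = TRUE], h)
    }
    x$data <- d
    x
  } else {
    if (is.null(sfreq)) stop("`sfreq` required for matrix input", call. = FALSE)
    if (sfreq <= 2 * spec$high_cut) {
      stop("sfreq must exceed twice the upper pass edge", call. = FALSE)
    }
    apply_fir(x, fir_design(spec, sfreq))
  }
}

#' Downsample an epoch collection
#'
#' Regenerates the time axis at `target_sfreq` (keeping the original start
#' time) and interpolates each channel onto the new grid with a natural
#' cubic spline after a protective anti-alias low-pass at 0.45 x target
#' rate. In the intended use the data are already low-passed well below the
#' target Nyquist, so the operation is effectively band-limited
#' interpolation. Upsampling is not supported.
#'
#' @param x An `epoch_collection`.
#' @param target_sfreq Target rate, Hz (<= current rate).
#' @return The downsampled `epoch_collection`.
#' @export
resample_epochs <- function(x, target_sfreq) {
  stopifnot(inherits(x, "epoch_collection"))
  if (target_sfreq > x$sfreq) {
    stop("unsupported: upsampling requested", call. = FALSE)
  }
  if (target_sfreq == x$sfreq) return(x)
  new_times <- seq(x$times[1L], x$times[length(x$times)] + 1e-9,
                   by = 1 / target_sfreq)
  new_times <- new_times[new_times <= x$times[length(x$times)] + 1e-9]
  aa <- NULL
  if (0.45 * target_sfreq < x$sfreq / 2) {
    aa_spec <- structure(list(low_cut = NULL, high_cut = 0.35 * target_sfreq,
                              window = "hamming", length_factor = 6.6,
                              transition_low = Inf,
                              transition_high = 0.2 * target_sfreq),
                         class = "filter_spec")
    aa <- fir_design(aa_spec, x$sfreq)
  }
  d <- x$data
  nd <- array(0, dim = c(dim(d)[1L], dim(d)[2L], length(new_times)))
  for (i in seq_len(dim(d)[1L])) {
    tr <- d[i, , , drop = TRUE]
    if (length(dim(tr)) < 2L) tr <- matrix(tr, nrow = dim(d)[2L])
    if (!is.null(aa)) tr <- apply_fir(tr, aa, check_length = FALSE)
    for (ch in seq_len(dim(d)[2L])) {
      nd[i, ch, ] <- stats::spline(x$times, tr[ch, ], xout = new_times,
                                   method = "natural")$y
    }
  }
  epoch_collection(nd, x$labels, x$condition, new_times, target_sfreq,
                   x$channel_types, x$event_times, x$positive_label)
}
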