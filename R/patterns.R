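#' Locate a subject's generalization peak and extraction window
#'
#' Finds the maximum score inside a mask (cluster mask or time-window box)
#' and returns the 3-sample train-time window centered on the peak (16 ms at
#' 125 Hz). Ties break toward the earliest train, then test time; windows
#' clipped at the grid edge are flagged.
#'
#' @param map A [generalization_map()].
#' @param mask Logical matrix the size of `map$scores`, or a list
#'   `list(train = c(t0, t1), test = c(t0, t1))` of time windows in seconds.
#' @return A `pattern_extract` stub: `peak` (train/test indices),
#'   `peak_times`, `window_idx` (train-time sample indices), `window_times`,
#'   `edge_clipped` flag.
#' @export
find_subject_maxima <- function(map, mask) {
  sc <- map$scores
  if (is.list(mask) && !is.matrix(mask)) {
    tr <- map$train_times >= mask$train[1L] - 1e-9 &
      map$train_times <= mask$train[2L] + 1e-9
    te <- map$test_times >= mask$test[1L] - 1e-9 &
      map$test_times <= mask$test[2L] + 1e-9
    mask <- outer(tr, te, `&`)
  }
  if (!any(mask)) stop("empty mask", call. = FALSE)
  best <- -Inf
  peak <- NULL
  cells <- which(mask, arr.ind = TRUE)
  cells <- cells[order(cells[, 1L], cells[, 2L]), , drop = FALSE]
  for (k in seq_len(nrow(cells))) {
    v <- sc[cells[k, 1L], cells[k, 2L]]
    if (v > best + 1e-15) {
      best <- v
      peak <- cells[k, ]
    }
  }
  ti <- peak[[1L]]
  window <- intersect(seq(ti - 1L, ti + 1L), seq_along(map$train_times))
  structure(list(peak = c(train = ti, test = peak[[2L]]),
                 peak_times = c(train = map$train_times[ti],
                                test = map$test_times[peak[[2L]]]),
                 score = best,
                 window_idx = window,
                 window_times = map$train_times[window],
                 edge_clipped = length(window) < 3L),
            class = "pattern_extract")
}

#' Activation patterns from classifier weights (Haufe transformation)
#'
#' Converts backward-model weight vectors into forward-model activation
#' patterns by multiplying with the signal covariance: `pattern =
#' signal_cov %*% weights`. In the intended use the covariance is computed
#' from the original (non-downsampled) data within the same 16-ms window as
#' the weights.
#'
#' @param weights Channel vector or channels x k matrix of weight vectors.
#' @param signal_cov Symmetric positive semi-definite channels x channels
#'   covariance.
#' @return Pattern vector/matrix of the same shape as `weights`.
#' @export
weights_to_patterns <- function(weights, signal_cov) {
  W <- as.matrix(weights)
  if (nrow(signal_cov) != ncol(signal_cov) ||
      max(abs(signal_cov - t(signal_cov))) >
      1e-8 * max(1, max(abs(signal_cov)))) {
    stop("signal covariance must be symmetric", call. = FALSE)
  }
  if (nrow(W) != nrow(signal_cov)) {
    stop("dimension mismatch between weights and covariance", call. = FALSE)
  }
  out <- signal_cov %*% W
  if (is.null(dim(weights))) drop(out) else out
}

#' Empirical signal covariance in a time window
#'
#' Channel covariance pooled over all samples of all trials in the window,
#' after per-trial channel demeaning.
#'
#' @param epochs An `epoch_collection`.
#' @param window Length-2 `(start, stop)` in seconds.
#' @return Channels x channels covariance matrix.
#' @export
signal_cov_window <- function(epochs, window) {
  sel <- epochs$times >= window[1L] - 1e-9 & epochs$times <= window[2L] + 1e-9
  if (!any(sel)) stop("empty window", call. = FALSE)
  pooled_cov(epochs$data[, , sel, drop = FALSE], demean = "global")
}

# Channel covariance pooled over (trial, sample) observations. For the
# *noise* covariance each trial is demeaned separately (removes slow
# offsets); for the *signal* covariance a single global channel mean is
# removed so evoked/class structure survives.
pooled_cov <- function(d, demean = c("trial", "global")) {
  demean <- match.arg(demean)
  n_ch <- dim(d)[2L]
  flat <- matrix(aperm(d, c(2L, 1L, 3L)), nrow = n_ch)  # channels x obs
  if (demean == "global") {
    flat <- flat - rowMeans(flat)
    return(tcrossprod(flat) / max(1L, ncol(flat) - 1L))
  }
  acc <- matrix(0, n_ch, n_ch)
  n_obs <- 0L
  for (i in seq_len(dim(d)[1L])) {
    seg <- d[i, , , drop = TRUE]
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = n_ch)
    seg <- seg - rowMeans(seg)
    acc <- acc + tcrossprod(seg)
    n_obs <- n_obs + ncol(seg)
  }
  acc / max(1L, n_obs - 1L)
}

#' Noise covariance from the pre-stimulus baseline
#'
#' Empirical channel covariance over all baseline samples pooled across
#' trials. When the pooled sample count is below `channels + 1` or the
#' matrix is ill-conditioned, diagonal-loading shrinkage toward
#' `mean(diag) * I` engages (10%) and is flagged via the `shrunk`
#' attribute.
#'
#' @param epochs An `epoch_collection` whose time axis covers `window`.
#' @param window Baseline window in seconds (default the 200-ms
#'   pre-stimulus interval).
#' @return Covariance matrix with attribute `shrunk` (logical).
#' @export
estimate_noise_cov <- function(epochs, window = c(-0.2, 0)) {
  sel <- epochs$times >= window[1L] - 1e-9 & epochs$times <= window[2L] + 1e-9
  if (!any(sel)) {
    stop("empty window: epochs do not cover the baseline interval",
         call. = FALSE)
  }
  d <- epochs$data[, , sel, drop = FALSE]
  C <- pooled_cov(d)
  n_obs <- dim(d)[1L] * dim(d)[3L]
  n_ch <- ncol(C)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ill <- n_obs < n_ch + 1L || min(ev) <= 0 ||
    max(ev) / max(min(ev), .Machine$double.eps) > 1e8
  if (ill) {
    C <- 0.9 * C + 0.1 * mean(diag(C)) * diag(n_ch)
  }
  attr(C, "shrunk") <- ill
  C
}

#' Trace-ratio signal-to-noise ratio
#'
#' SNR (amplitude) defined from the ratio of the traces of the signal and
#' noise covariance matrices: `sqrt(trace(signal_cov) / trace(noise_cov))`.
#'
#' @param signal_cov,noise_cov Covariance matrices on the same channels.
#' @return Scalar SNR.
#' @export
snr_trace_ratio <- function(signal_cov, noise_cov) {
  sqrt(sum(diag(signal_cov)) / sum(diag(noise_cov)))
}

#' Inverse-solution configuration
#'
#' @param snr Amplitude SNR; the Tikhonov regularization is `lambda^2 =
#'   1/snr^2` on the whitened, source-weighted gain Gram matrix.
#' @param loose Loose orientation weight in [0, 1] applied to the variance
#'   of the auxiliary tangential source components (default 0.2).
#' @param noise_cov Channels x channels noise covariance (see
#'   [estimate_noise_cov()]).
#' @param baseline Baseline window the covariance came from (metadata).
#' @return An `inverse_config` object.
#' @export
inverse_config <- function(snr = 3, loose = 0.2, noise_cov = NULL,
                           baseline = c(-0.2, 0)) {
  if (!is.numeric(snr) || snr <= 0) {
    stop("config error: snr must be > 0", call. = FALSE)
  }
  stopifnot_scalar_num(loose, "loose", 0, 1)
  structure(list(snr = snr, loose = loose, noise_cov = noise_cov,
                 baseline = baseline),
            class = "inverse_config")
}

#' Condition-specific evoked source-window presets
#'
#' The 100-ms windows centered on each condition's evoked-difference peak.
#'
#' @return Named list of `(start, stop)` windows in seconds.
#' @export
condition_source_windows <- function() {
  list(motor = c(0.020, 0.120),
       feedback_expectancy = c(0.300, 0.400),
       feedback_valence = c(0.330, 0.430),
       bci = c(0.330, 0.430))
}

#' dSPM-style noise-normalized source map
#'
#' Minimum-norm linear inverse on the synthetic lead field with noise
#' whitening, loose-orientation source weighting (tangential components
#' down-weighted by `loose`) and Tikhonov regularization `lambda^2 =
#' 1/snr^2`; the per-source amplitude (norm over the three orientation
#' components) is divided by its noise sensitivity, yielding a
#' dimensionless dSPM value per source.
#'
#' @param vec Channel-space pattern or evoked-difference vector.
#' @param fm A [make_forward_model()] object.
#' @param cfg An [inverse_config()] carrying a valid `noise_cov`.
#' @return Numeric vector of per-source normalized activity (>= 0).
#' @export
dspm_map <- function(vec, fm, cfg) {
  stopifnot(inherits(fm, "forward_model"), inherits(cfg, "inverse_config"))
  if (is.null(cfg$noise_cov)) stop("noise covariance required", call. = FALSE)
  n_src <- ncol(fm$gain)
  n_ch <- nrow(fm$gain)
  # whitener from the noise covariance
  eg <- eigen((cfg$noise_cov + t(cfg$noise_cov)) / 2, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  if (!any(pos)) stop("noise covariance is singular", call. = FALSE)
  W <- eg$vectors[, pos, drop = FALSE] %*%
    (t(eg$vectors[, pos, drop = FALSE]) / sqrt(eg$values[pos]))
  # full gain: normal + 2 tangential columns per source, with sqrt(R) weights
  G <- matrix(0, n_ch, 3L * n_src)
  rw <- numeric(3L * n_src)
  for (s in seq_len(n_src)) {
    G[, 3L * s - 2L] <- fm$gain[, s]
    G[, 3L * s - 1L] <- fm$aux_gain[, s, 1L]
    G[, 3L * s] <- fm$aux_gain[, s, 2L]
    rw[(3L * s - 2L):(3L * s)] <- sqrt(c(1, cfg$loose, cfg$loose))
  }
  A <- (W %*% G) * rep(rw, each = n_ch)
  # scale source variance so trace(A A')/n_ch = 1, making 1/snr^2 meaningful
  sc <- sqrt(sum(A^2) / n_ch)
  A <- A / sc
  lambda2 <- 1 / cfg$snr^2
  K <- t(A) %*% solve(tcrossprod(A) + lambda2 * diag(n_ch))   # sources*3 x ch
  Kw <- K %*% W                       # applies to unwhitened channel vectors
  est <- drop(Kw %*% vec)
  # dSPM denominator: per-source noise sensitivity under whitened noise = I
  sens <- rowSums(K^2)
  out <- numeric(n_src)
  for (s in seq_len(n_src)) {
    idx <- (3L * s - 2L):(3L * s)
    out[s] <- sqrt(sum(est[idx]^2)) / sqrt(sum(sens[idx]))
  }
  out
}

#' Threshold a source map at a fraction of its peak
#'
#' @param map Numeric per-source map (non-empty).
#' @param fraction Retention fraction of the global maximum (default 0.9);
#'   retention is inclusive (`value >= fraction * max`).
#' @return Integer indices of retained sources.
#' @export
threshold_map <- function(map, fraction = 0.9) {
  if (length(map) == 0L) stop("empty map", call. = FALSE)
  which(map >= fraction * max(map))
}
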