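#' Spatio-spectral decomposition configuration
#'
#' Band layout around a center frequency: the signal band is
#' `center +/- signal_bw/2`; two flanking noise bands of width `flank_bw`
#' sit `flank_gap` away from the signal-band edges. Defaults cover both
#' 12- and 15-Hz SSVEP tags with one filter set (signal 11-16 Hz, flanks
#' 8-10 and 17-19 Hz).
#'
#' @param center Center frequency, Hz.
#' @param signal_bw Signal bandwidth, Hz.
#' @param flank_gap Gap between signal band and each flank, Hz.
#' @param flank_bw Width of each flanking band, Hz.
#' @param n_components Number of retained components (default 4).
#' @return An `ssd_config` object.
#' @export
ssd_config <- function(center = 13.5, signal_bw = 5, flank_gap = 1,
                       flank_bw = 2, n_components = 4) {
  stopifnot_scalar_num(center, "center", 0, strict_lower = TRUE)
  stopifnot_scalar_num(signal_bw, "signal_bw", 0, strict_lower = TRUE)
  stopifnot_scalar_num(flank_gap, "flank_gap", 0, strict_lower = TRUE)
  structure(list(center = center, signal_bw = signal_bw,
                 flank_gap = flank_gap, flank_bw = flank_bw,
                 n_components = as.integer(n_components)),
            class = "ssd_config")
}

ssd_band_spec <- function(lo, hi, trans = 1) {
  filter_spec(low_cut = lo, high_cut = hi, transition_low = trans,
              transition_high = trans)
}

shrink_cov <- function(C, gamma = 0.05) {
  (1 - gamma) * C + gamma * mean(diag(C)) * diag(nrow(C))
}

#' Fit spatio-spectral decomposition filters
#'
#' Maximizes narrowband signal power against flanking-band power via the
#' generalized eigendecomposition of the signal-band covariance with
#' respect to the summed flank covariance. The flank covariance is rescaled
#' by the ratio of the filters' equivalent noise bandwidths so that
#' spatially white broadband noise yields eigenvalues near 1. Filters are
#' sorted by descending eigenvalue (signal-to-flank power ratio); patterns
#' are the covariance-consistent forward projections of the filters, with
#' the sign fixed so each pattern's largest-magnitude entry is positive.
#'
#' @param x Continuous channels x samples matrix (>= ~5 s of data for
#'   stable covariances).
#' @param sfreq Sampling rate, Hz.
#' @param cfg An [ssd_config()].
#' @return List with `filters` (channels x n_components), `patterns`
#'   (channels x n_components), `eigenvalues` (all, descending), and `cfg`.
#' @export
ssd_fit <- function(x, sfreq, cfg = ssd_config()) {
  if (ncol(x) < 5 * sfreq) {
    warning("less than 5 s of data: SSD covariances may be unstable")
  }
  if (cfg$n_components > nrow(x)) {
    stop("n_components exceeds channel count", call. = FALSE)
  }
  s_lo <- cfg$center - cfg$signal_bw / 2
  s_hi <- cfg$center + cfg$signal_bw / 2
  h_sig <- fir_design(ssd_band_spec(s_lo, s_hi), sfreq)
  h_lf <- fir_design(ssd_band_spec(s_lo - cfg$flank_gap - cfg$flank_bw,
                                   s_lo - cfg$flank_gap), sfreq)
  h_rf <- fir_design(ssd_band_spec(s_hi + cfg$flank_gap,
                                   s_hi + cfg$flank_gap + cfg$flank_bw),
                     sfreq)
  xs <- apply_fir(x, h_sig, check_length = FALSE)
  xl <- apply_fir(x, h_lf, check_length = FALSE)
  xr <- apply_fir(x, h_rf, check_length = FALSE)
  cov_of <- function(m) {
    m <- m - rowMeans(m)
    tcrossprod(m) / (ncol(m) - 1L)
  }
  Cs <- cov_of(xs)
  Cn <- cov_of(xl) + cov_of(xr)
  # equivalent-noise-bandwidth normalization: for white input the filtered
  # variance scales with sum(h^2)
  Cn <- Cn * (sum(h_sig^2) / (sum(h_lf^2) + sum(h_rf^2)))
  solve_gevd <- function(Cs, Cn) {
    eg <- eigen((Cn + t(Cn)) / 2, symmetric = TRUE)
    if (min(eg$values) <= max(eg$values) * 1e-10) stop("singular")
    Wh <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
    M <- Wh %*% Cs %*% Wh
    em <- eigen((M + t(M)) / 2, symmetric = TRUE)
    list(values = em$values, filters = Wh %*% em$vectors)
  }
  res <- tryCatch(solve_gevd(Cs, Cn), error = function(e) NULL)
  if (is.null(res)) {
    Cs <- shrink_cov(Cs)
    Cn <- shrink_cov(Cn)
    res <- tryCatch(solve_gevd(Cs, Cn),
                    error = function(e) {
                      stop("flank covariance singular even after shrinkage",
                           call. = FALSE)
                    })
  }
  F_all <- res$filters
  Fk <- F_all[, seq_len(cfg$n_components), drop = FALSE]
  # covariance-consistent patterns: Cs F (F' Cs F)^-1, ridged if near-singular
  Gm <- crossprod(Fk, Cs %*% Fk)
  P <- tryCatch(Cs %*% Fk %*% solve(Gm), error = function(e) {
    Cs %*% Fk %*% solve(Gm + diag(1e-10 * mean(diag(Gm)), ncol(Gm)))
  })
  for (k in seq_len(ncol(P))) {
    s <- sign(P[which.max(abs(P[, k])), k])
    if (s < 0) {
      P[, k] <- -P[, k]
      Fk[, k] <- -Fk[, k]
    }
  }
  list(filters = Fk, patterns = P, eigenvalues = res$values, cfg = cfg)
}
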