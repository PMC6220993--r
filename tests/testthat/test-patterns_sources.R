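test_that("find_subject_maxima respects the mask, ties and edges", {
  sc <- matrix(0.5, 10, 10)
  sc[4, 7] <- 0.9
  sc[9, 9] <- 0.95                      # global max outside the mask
  m <- generalization_map(sc, seq(0, 0.072, by = 0.008),
                          seq(0, 0.072, by = 0.008))
  box_mask <- matrix(FALSE, 10, 10)
  box_mask[2:6, 5:8] <- TRUE
  pe <- find_subject_maxima(m, box_mask)
  expect_equal(unname(pe$peak), c(4L, 7L))
  expect_equal(pe$window_idx, 3:5)      # 3 samples centered on the peak
  expect_false(pe$edge_clipped)
  # time-window box mask
  pe2 <- find_subject_maxima(m, list(train = c(0.008, 0.04),
                                     test = c(0.032, 0.056)))
  expect_equal(unname(pe2$peak), c(4L, 7L))
  # tie-break toward the earliest (train, then test) time
  sc_tie <- matrix(0.5, 4, 4); sc_tie[2, 3] <- 0.8; sc_tie[3, 2] <- 0.8
  m_tie <- generalization_map(sc_tie, 1:4 * 0.01, 1:4 * 0.01)
  expect_equal(unname(find_subject_maxima(m_tie,
                                          matrix(TRUE, 4, 4))$peak), c(2L, 3L))
  # edge peak -> clipped 2-sample window, flagged
  sc_e <- matrix(0.5, 4, 4); sc_e[1, 2] <- 0.9
  pe_e <- find_subject_maxima(generalization_map(sc_e, 1:4 * 0.01,
                                                 1:4 * 0.01),
                              matrix(TRUE, 4, 4))
  expect_equal(pe_e$window_idx, 1:2)
  expect_true(pe_e$edge_clipped)
  expect_error(find_subject_maxima(m, matrix(FALSE, 10, 10)), "empty mask")
})

test_that("Haufe transformation recovers the generative mixing column", {
  # identity covariance -> pattern equals weights
  w <- rnorm(8)
  expect_equal(weights_to_patterns(w, diag(8)), w)
  expect_error(weights_to_patterns(w, matrix(rnorm(64), 8, 8)), "symmetric")
  expect_error(weights_to_patterns(w, diag(5)), "dimension mismatch")
  # generative recovery: x = a s + noise at SNR >= 10
  set.seed(4)
  n <- 400; ch <- 10
  a <- rnorm(ch); a <- a / sqrt(sum(a^2))
  s <- rnorm(n, sd = sqrt(10))
  X <- outer(s, a) + matrix(rnorm(n * ch), n, ch)
  y <- as.integer(s > 0)
  wfit <- tgdecode:::fit_logreg_l2(X, y, classifier_config(C = 1))
  patt <- weights_to_patterns(wfit[-1], cov(X))
  cosine <- abs(sum(patt * a)) / sqrt(sum(patt^2) * sum(a^2))
  expect_gt(cosine, 0.95)
  # linearity: scaling weights scales patterns
  expect_equal(weights_to_patterns(3 * wfit[-1], cov(X)), 3 * patt)
})

test_that("noise covariance estimation: sampling accuracy and shrinkage guard", {
  fm <- test_fm(6, 3)
  sigma <- c(mag = 300, grad = 100, eeg = 10)
  ns <- noise_spec(sensor_sd_by_type = sigma, ar_coefficient = 0,
                   spatial_mixing_rank = 6, seed = 2)
  x <- simulate_epochs(fm, list(), ns, c(A = 60, B = 60), "c",
                       window = c(-0.2, 0.3), sfreq = 100, seed = 3)
  C <- estimate_noise_cov(x, c(-0.2, 0))
  expect_false(attr(C, "shrunk"))
  expected_var <- sigma[x$channel_types]^2
  expect_lt(max(abs(diag(C) / expected_var - 1)), 0.10)
  # fewer samples than channels -> shrinkage engages, finite condition number
  fm_big <- test_fm(24, 4)
  xs <- simulate_epochs(fm_big, list(), std_noise(), c(A = 2, B = 2), "c",
                        window = c(-0.04, 0.06), sfreq = 50, seed = 4)
  Cs <- estimate_noise_cov(xs, c(-0.04, 0))
  expect_true(attr(Cs, "shrunk"))
  ev <- eigen(Cs, only.values = TRUE)$values
  expect_lt(max(ev) / min(ev), 1e8)
  # window outside epochs -> error
  xd <- simulate_epochs(fm, list(), ns, c(A = 2, B = 2), "c",
                        window = c(0, 0.3), sfreq = 100, seed = 5)
  expect_error(estimate_noise_cov(xd, c(-0.2, -0.05)), "empty window")
})

test_that("dSPM-style inverse localizes planted sources on the synthetic grid", {
  fm <- test_fm(30, 12, seed = 5)
  ncov <- diag(channel_type_scales()[fm$channel_types]^2)
  cfg <- inverse_config(snr = 10, noise_cov = ncov)
  # single-source localization oracle
  for (src in c(2, 7, 11)) {
    map <- dspm_map(fm$gain[, src] * 3, fm, cfg)
    expect_equal(which.max(map), src)
  }
  # zero input -> all-zero map
  expect_equal(dspm_map(numeric(30), fm, cfg), rep(0, 12))
  # two equal far-apart sources both retained at the 90% threshold
  map2 <- dspm_map(fm$gain[, 2] + fm$gain[, 9], fm, cfg)
  expect_true(all(c(2, 9) %in% threshold_map(map2, 0.9)))
  # dSPM value is invariant to input scaling direction-wise (normalization)
  m1 <- dspm_map(fm$gain[, 4], fm, cfg)
  m5 <- dspm_map(5 * fm$gain[, 4], fm, cfg)
  expect_equal(m5, 5 * m1, tolerance = 1e-9)
  expect_equal(which.max(m5), which.max(m1))
  expect_error(inverse_config(snr = -1), "config error")
})

test_that("localization error decreases with SNR on average", {
  fm <- test_fm(30, 12, seed = 8)
  ncov <- diag(channel_type_scales()[fm$channel_types]^2)
  set.seed(9)
  err_at <- function(snr, noise_scale) {
    errs <- vapply(1:12, function(src) {
      vec <- fm$gain[, src] +
        noise_scale * rnorm(30, sd = channel_type_scales()[fm$channel_types])
      pos <- fm$source_positions
      est <- which.max(dspm_map(vec, fm, inverse_config(snr = snr,
                                                        noise_cov = ncov)))
      sqrt(sum((pos[est, ] - pos[src, ])^2))
    }, numeric(1))
    mean(errs)
  }
  expect_lte(err_at(10, 0.05), err_at(1, 1))
})

test_that("threshold_map retains >= 90% of peak, inclusively", {
  expect_setequal(threshold_map(1:10, 0.9), c(9L, 10L))
  expect_setequal(threshold_map(rep(2, 5), 0.9), 1:5)
  expect_equal(threshold_map(c(1, 5, 3), 1.0), 2L)
  expect_error(threshold_map(numeric(0)), "empty map")
})

test_that("signal covariance window matches the generative structure", {
  fm <- test_fm(6, 3)
  cmp <- source_component(1, 0.25, 0.05, c(A = 8, B = 0))
  ns <- noise_spec(sensor_sd_by_type = c(mag = 30, grad = 10, eeg = 1),
                   seed = 2)
  x <- simulate_epochs(fm, list(cmp), ns, c(A = 40, B = 40), "c",
                       window = c(0, 0.5), sfreq = 250, seed = 6)
  C <- signal_cov_window(x, c(0.242, 0.258))   # 16-ms window at the peak
  # dominant eigenvector aligns with the active gain column
  v <- eigen(C, symmetric = TRUE)$vectors[, 1]
  a <- fm$gain[, 1]
  expect_gt(abs(sum(v * a)) / sqrt(sum(a^2)), 0.9)
  expect_error(signal_cov_window(x, c(0.9, 1)), "empty window")
})
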