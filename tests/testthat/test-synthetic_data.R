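test_that("forward model satisfies normalization, determinism and dimension contracts", {
  fm <- make_forward_model(32, 3, seed = 1)
  expect_equal(dim(fm$gain), c(32L, 3L))
  scales <- channel_type_scales()
  # each column has unit norm after dividing out the per-type unit scale
  norm2 <- numeric(3)
  for (ty in unique(fm$channel_types)) {
    rows <- fm$channel_types == ty
    norm2 <- norm2 + colSums(fm$gain[rows, ]^2) / scales[[ty]]^2
  }
  expect_equal(norm2, rep(1, 3), tolerance = 1e-10)
  # distinct columns
  expect_gt(min(abs(fm$gain[, 1] - fm$gain[, 2])), 0)
  # no all-zero column
  expect_true(all(colSums(fm$gain^2) > 0))
  # bit-identical regeneration
  expect_identical(fm$gain, make_forward_model(32, 3, seed = 1)$gain)
  expect_false(identical(fm$gain, make_forward_model(32, 3, seed = 2)$gain))
  # invalid dimensions
  expect_error(make_forward_model(2, 5, seed = 1), "invalid dimension")
  expect_error(make_forward_model(4, 0, seed = 1), "invalid dimension")
  # hemisphere positions
  expect_true(all(fm$source_positions[, "z"] >= 0))
  expect_equal(rowSums(fm$source_positions^2), rep(1, 3), tolerance = 1e-9)
})

test_that("noise-free epochs reproduce the closed-form forward projection", {
  fm <- make_forward_model(32, 3, seed = 1)
  # latency on the sample grid so the envelope peak is exactly 1
  cmp <- source_component(1, 0.25, 0.05, c(A = 2, B = 0))
  x <- simulate_epochs(fm, list(cmp), quiet_noise(), c(A = 5, B = 5), "c1",
                       window = c(0, 0.5), sfreq = 100, seed = 2)
  pk <- which.min(abs(x$times - 0.25))
  dA <- colMeans(x$data[x$labels == "A", , pk])
  dB <- colMeans(x$data[x$labels == "B", , pk])
  expect_equal(dA - dB, 2 * fm$gain[, 1], tolerance = 1e-12)
  # forward linearity: doubling all amplitudes doubles noise-free data
  cmp2 <- source_component(1, 0.25, 0.05, c(A = 4, B = 0))
  x2 <- simulate_epochs(fm, list(cmp2), quiet_noise(), c(A = 5, B = 5), "c1",
                        window = c(0, 0.5), sfreq = 100, seed = 2)
  expect_equal(x2$data, 2 * x$data, tolerance = 1e-12)
})

test_that("simulate_epochs contracts: determinism, condition gating, errors", {
  fm <- test_fm()
  cmp <- source_component(2, 0.2, 0.03, c(pos = 1, neg = 2),
                          conditions = "B")
  ns <- std_noise()
  x1 <- simulate_epochs(fm, list(cmp), ns, c(pos = 4, neg = 4), "A",
                        window = c(0, 0.4), sfreq = 50, seed = 7)
  x2 <- simulate_epochs(fm, list(cmp), ns, c(pos = 4, neg = 4), "A",
                        window = c(0, 0.4), sfreq = 50, seed = 7)
  expect_identical(x1$data, x2$data)
  # component for another condition is silently inactive
  x0 <- simulate_epochs(fm, list(), ns, c(pos = 4, neg = 4), "A",
                        window = c(0, 0.4), sfreq = 50, seed = 7)
  expect_identical(x1$data, x0$data)
  # unknown class label -> labeling error
  bad <- source_component(2, 0.2, 0.03, c(other = 1), conditions = "A")
  expect_error(simulate_epochs(fm, list(bad), ns, c(pos = 4, neg = 4), "A",
                               window = c(0, 0.4), sfreq = 50, seed = 7),
               "labeling error")
  # window must cover latency +/- 3 widths
  late <- source_component(2, 0.39, 0.05, c(pos = 1, neg = 1))
  expect_error(simulate_epochs(fm, list(late), ns, c(pos = 4, neg = 4), "A",
                               window = c(0, 0.4), sfreq = 50, seed = 7),
               "3 widths")
  # epoch container invariants
  expect_true(is.unsorted(x1$event_times) == FALSE)
  expect_equal(diff(x1$times), rep(1 / 50, length(x1$times) - 1L),
               tolerance = 1e-9)
})

test_that("simulate_session matches the task design and flag statistics", {
  tbl <- simulate_session(task_design(), rep(0.8, 5), seed = 1)
  expect_equal(nrow(tbl), 360L)
  expect_equal(as.vector(table(tbl$block)), rep(72L, 5))
  # artificial error implies decoded != intended
  expect_true(all(tbl$decoded[tbl$artificial_error] !=
                    tbl$intended[tbl$artificial_error]))
  expect_true(all(tbl$decoded[!tbl$artificial_error] ==
                    tbl$intended[!tbl$artificial_error]))
  # rate 0 -> no flags
  tbl0 <- simulate_session(task_design(artificial_error_rate = 0),
                           rep(0.8, 5), seed = 1)
  expect_false(any(tbl0$artificial_error))
  # long-run flag rate within the 99% binomial interval of 0.15
  big <- simulate_session(task_design(n_blocks = 10, trials_per_block = 1000),
                          rep(0.8, 10), seed = 1)
  rate <- mean(big$artificial_error)
  half <- qnorm(0.995) * sqrt(0.15 * 0.85 / 10000)
  expect_lt(abs(rate - 0.15), half)
  # positive-feedback rate conditional on having chosen the 0.8 stimulus
  best <- simulate_session(task_design(n_blocks = 10, trials_per_block = 1000,
                                       artificial_error_rate = 0),
                           rep(1, 10), seed = 4)
  sel <- best$decoded == 1L
  p_pos <- mean(best$valence[sel] == "positive")
  half80 <- qnorm(0.995) * sqrt(0.8 * 0.2 / sum(sel))
  expect_lt(abs(p_pos - 0.8), half80)
  # config errors
  expect_error(task_design(reward_probabilities = c(1.2, 0.5, 0.5, 0.5)),
               "config error")
  expect_error(simulate_session(task_design(), rep(1.5, 5), seed = 1),
               "config error")
  # determinism
  expect_identical(simulate_session(seed = 11), simulate_session(seed = 11))
})

test_that("label_surprise implements the high/low rule on late-block negative feedback", {
  probs <- c(0.8, 0.66, 0.33, 0.2)
  tbl <- manual_trial_table(block = c(4, 4, 4, 2),
                            decoded = c(1L, 3L, 1L, 1L),
                            other = c(3L, 2L, 3L, 3L),
                            valence = c("negative", "negative", "positive",
                                        "negative"),
                            probs = probs)
  out <- label_surprise(tbl, blocks = c(4, 5))
  # negative feedback after choosing 0.8 in block 4 -> high surprise
  expect_equal(out$surprise[1], "high")
  # negative feedback after choosing 0.33 in a 0.66-vs-0.33 pair -> low
  expect_equal(out$surprise[2], "low")
  # positive feedback -> none
  expect_equal(out$surprise[3], "none")
  # outside the selected blocks -> none
  expect_equal(out$surprise[4], "none")
})

test_that("balance_valence_subsets equalizes expectancy within each valence group", {
  # pos: 10 high (worse choice), 10 low (better choice);
  # neg: 20 high (better choice), 10 low (worse choice)
  tbl <- manual_trial_table(
    block = rep(4, 50),
    decoded = c(rep(3L, 10), rep(1L, 10), rep(1L, 20), rep(3L, 10)),
    other = c(rep(1L, 10), rep(3L, 10), rep(3L, 20), rep(1L, 10)),
    valence = c(rep("positive", 20), rep("negative", 30)))
  out <- balance_valence_subsets(tbl, seed = 1)
  expect_equal(nrow(out$positive), 20L)
  expect_equal(nrow(out$negative), 20L)
  neg_better <- out$negative$decoded == 1L
  expect_equal(sum(neg_better), 10L)       # high-surprise down-sampled to 10
  expect_equal(sum(!neg_better), 10L)
  # already balanced input returned unchanged up to ordering
  bal <- balance_valence_subsets(tbl[c(1:20, 21:30, 41:50), ], seed = 1)
  expect_equal(nrow(bal$negative), 20L)
  # empty category -> named error
  no_high <- tbl[tbl$decoded != 1L | tbl$valence != "negative", ]
  expect_error(balance_valence_subsets(no_high, seed = 1),
               "insufficient trials.*neg_high")
})

test_that("simulate_ssvep construction, determinism and aliasing guard", {
  fm <- make_forward_model(16, 4, seed = 7, channel_types = rep("grad", 16))
  ns <- noise_spec(sensor_sd_by_type = c(grad = 5), seed = 3)
  x <- simulate_ssvep(2, 250, 12, c(`12` = 5, `15` = 1), fm = fm, noise = ns,
                      seed = 4)
  expect_equal(dim(x), c(16L, 500L))
  expect_identical(x, simulate_ssvep(2, 250, 12, c(`12` = 5, `15` = 1),
                                     fm = fm, noise = ns, seed = 4))
  # attended frequency must be among amplitudes
  expect_error(simulate_ssvep(2, 250, 20, c(`12` = 5, `15` = 1), fm = fm,
                              noise = ns, seed = 4), "attended_freq")
  # aliasing guard
  expect_error(simulate_ssvep(2, 25, 12, c(`12` = 5, `15` = 1), fm = fm,
                              noise = ns, seed = 4), "aliasing")
  # GLM sees the attended frequency as stronger (construction oracle)
  d <- glm_design()
  segs <- tgdecode:::split_segments(x, 250, 0.5)
  amps <- rowMeans(sapply(segs, function(s) {
    rowMeans(glm_amplitudes(s, d, 250))
  }))
  expect_gt(amps[["12"]], amps[["15"]])
})
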