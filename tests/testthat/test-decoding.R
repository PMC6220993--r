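test_that("roc_auc matches examples and the pairwise-count oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(1, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "undefined AUC")
  set.seed(1)
  for (rep in 1:10) {
    n <- sample(5:25, 1)
    s <- sample(round(rnorm(n), 1))       # rounding forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), auc_oracle(s, y))
  }
  # label flip symmetry
  s <- rnorm(20); y <- rep(0:1, 10)
  expect_equal(roc_auc(s, y), 1 - roc_auc(s, 1 - y))
})

test_that("standardize uses training statistics only and guards constants", {
  st <- standardize(matrix(c(1, 3), 2, 1))
  expect_equal(drop(st$train), c(-1, 1))
  tr <- matrix(rnorm(40), 20, 2)
  te <- matrix(rnorm(40, mean = 5), 20, 2)
  out <- standardize(tr, te)
  expect_equal(colMeans(out$train), c(0, 0), tolerance = 1e-12)
  expect_equal(colMeans(out$train^2), c(1, 1), tolerance = 1e-12)
  # test columns are transformed with train stats, not their own
  expect_gt(abs(mean(out$test[, 1])), 1)
  # constant train column: centered, unscaled, flagged
  cst <- standardize(cbind(rnorm(10), rep(2, 10)))
  expect_true(cst$stats$zero_sd[2])
  expect_equal(cst$train[, 2], rep(0, 10))
})

test_that("penalized logistic fit minimizes the stated objective", {
  set.seed(5)
  X <- matrix(rnorm(200), 50, 4)
  y <- rbinom(50, 1, plogis(X %*% c(1.5, -1, 0, 0.5)))
  for (C in c(0.1, 1)) {
    w <- tgdecode:::fit_logreg_l2(X, y, classifier_config(C = C))
    obj <- function(p) {
      f <- p[1] + X %*% p[-1]
      0.5 * sum(p[-1]^2) + C * sum(log1p(exp(-(2 * y - 1) * f)))
    }
    ref <- optim(rep(0, 5), obj, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 2000))
    expect_lt(max(abs(w - ref$par)), 1e-5)
  }
})

test_that("within-condition generalization recovers planted structure", {
  fm <- test_fm()
  # discriminative component only around 250-300 ms
  x <- planted_epochs(seed = 3, condition = "A", src = 2, latency = 0.275,
                      amplitude = 5, n_per_class = c(pos = 24, neg = 24))
  m <- within_condition_generalization(x, seed = 1)
  expect_s3_class(m, "generalization_map")
  expect_equal(dim(m$scores), c(20L, 20L))
  expect_true(all(m$scores >= 0 & m$scores <= 1))
  sig_idx <- which(m$train_times >= 0.225 & m$train_times <= 0.325)
  early <- which(m$train_times <= 0.1)
  expect_gt(mean(m$scores[sig_idx, sig_idx]), 0.75)
  expect_lt(abs(mean(m$scores[early, early]) - 0.5), 0.08)
  # signal-free data: map mean close to chance
  x0 <- null_epochs(seed = 9)
  m0 <- within_condition_generalization(x0, seed = 1)
  expect_lt(abs(mean(m0$scores) - 0.5), 0.05)
  # grid arithmetic: 63 timepoints at 125 Hz over 0-500 ms
  x63 <- simulate_epochs(test_fm(6, 3), list(), std_noise(),
                         c(pos = 3, neg = 3), "A", window = c(0, 0.5),
                         sfreq = 125, seed = 1)
  expect_length(x63$times, 63L)
  # class-starved fold -> fold error
  tiny <- null_epochs(seed = 2, n_per_class = c(pos = 3, neg = 20))
  expect_error(within_condition_generalization(tiny, seed = 1), "fold error")
})

test_that("cross-condition generalization transfers shared sources and not orthogonal ones", {
  fm <- test_fm()
  # shared source (column 3) at 100 ms in A, 350 ms in B
  a <- planted_epochs(seed = 11, condition = "A", src = 3, latency = 0.1,
                      amplitude = 5, fm = fm)
  b <- planted_epochs(seed = 12, condition = "B", src = 3, latency = 0.35,
                      amplitude = 5, fm = fm)
  m <- cross_condition_generalization(a, b, seed = 1)
  expect_equal(m$scheme, "cross-6fold-bidirectional")
  near <- function(times, t0) which(abs(times - t0) <= 0.05)
  hot <- m$scores[near(m$train_times, 0.1), near(m$test_times, 0.35)]
  cold <- m$scores[near(m$train_times, 0.4), near(m$test_times, 0.1)]
  expect_gt(mean(hot), 0.7)
  expect_lt(mean(cold), 0.62)
  # orthogonal gain columns: within-decodable but no transfer
  b_orth <- planted_epochs(seed = 13, condition = "B", src = 4,
                           latency = 0.35, amplitude = 5, fm = fm)
  m_orth <- cross_condition_generalization(a, b_orth, seed = 1)
  expect_lt(abs(mean(m_orth$scores) - 0.5), 0.04)
  w_b <- within_condition_generalization(b_orth, seed = 1)
  expect_gt(mean(w_b$scores[near(w_b$train_times, 0.35),
                            near(w_b$train_times, 0.35)]), 0.7)
  # degenerate reduction: b = a behaves like a within-condition analysis
  m_self <- cross_condition_generalization(a, a, seed = 2)
  w_a <- within_condition_generalization(a, seed = 2)
  expect_gt(cor(as.vector(m_self$scores), as.vector(w_a$scores)), 0.8)
  # polarity mapping required
  a_np <- a; a_np$positive_label <- NULL
  expect_error(cross_condition_generalization(a_np, b, seed = 1),
               "configuration error")
})

test_that("cross-condition maps are consistent under direction swap", {
  fm <- test_fm()
  a <- planted_epochs(seed = 21, condition = "A", src = 1, latency = 0.15,
                      amplitude = 5, fm = fm)
  b <- planted_epochs(seed = 22, condition = "B", src = 1, latency = 0.3,
                      amplitude = 5, fm = fm)
  m_ab <- cross_condition_generalization(a, b, seed = 3)
  m_ba <- cross_condition_generalization(b, a, seed = 3)
  # same bidirectional analysis up to fold noise; axes transpose
  expect_gt(cor(as.vector(m_ab$scores), as.vector(t(m_ba$scores))), 0.8)
  expect_lt(abs(mean(m_ab$scores) - mean(m_ba$scores)), 0.02)
})

test_that("generalization is approximately invariant to a common orthonormal sensor remixing", {
  fm <- test_fm()
  a <- planted_epochs(seed = 31, condition = "A", src = 2, latency = 0.2,
                      amplitude = 5, fm = fm)
  Q <- qr.Q(qr(matrix(rnorm(144), 12, 12)))
  a_mix <- a
  for (i in seq_len(n_trials(a))) {
    a_mix$data[i, , ] <- Q %*% a$data[i, , ]
  }
  m1 <- within_condition_generalization(a, seed = 4)
  m2 <- within_condition_generalization(a_mix, seed = 4)
  # equivariance of regularized linear decoding is approximate (z-scoring is
  # channel-wise): loose tolerance
  expect_gt(cor(as.vector(m1$scores), as.vector(m2$scores)), 0.75)
  expect_lt(mean(abs(m1$scores - m2$scores)), 0.08)
})
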