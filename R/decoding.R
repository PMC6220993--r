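#' Classifier configuration
#'
#' l2-penalized logistic regression in the sklearn-style parameterization:
#' minimize `0.5 * ||w||^2 + C * sum(logistic loss)`, intercept included and
#' unpenalized. `C = 0.1` is the working default for single-timepoint sensor
#' decoding; no feature selection is performed.
#'
#' @param C Inverse regularization strength (> 0).
#' @param tol Convergence tolerance on the gradient norm.
#' @param max_iter Maximum Newton iterations.
#' @return A `classifier_config` object.
#' @export
classifier_config <- function(C = 0.1, tol = 1e-6, max_iter = 1000) {
  stopifnot_scalar_num(C, "C", 0, strict_lower = TRUE)
  structure(list(penalty = "l2", C = C, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "classifier_config")
}

# Newton/IRLS for the penalized logistic objective above.
# X: n x d (no intercept column), y: 0/1. Returns c(intercept, weights).
fit_logreg_l2 <- function(X, y, cfg = classifier_config()) {
  n <- nrow(X)
  d <- ncol(X)
  Xi <- cbind(1, X)
  pen <- diag(c(0, rep(1, d)), d + 1L)
  w <- numeric(d + 1L)
  for (it in seq_len(cfg$max_iter)) {
    eta <- drop(Xi %*% w)
    p <- stats::plogis(eta)
    g <- cfg$C * drop(crossprod(Xi, p - y)) + pen %*% w
    if (max(abs(g)) < cfg$tol) break
    wgt <- pmax(p * (1 - p), 1e-10)
    H <- cfg$C * crossprod(Xi * wgt, Xi) + pen
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8, d + 1L), g)
    })
    w <- w - step
  }
  drop(w)
}

#' Area under the ROC curve
#'
#' Probability that a random positive-class score exceeds a random
#' negative-class score, ties counted one half (midrank estimator).
#'
#' @param scores Numeric per-trial scores (higher = more positive-class).
#' @param labels Logical/0-1 vector (`TRUE`/1 = positive class).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("undefined AUC: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Standardize features with training-set statistics
#'
#' Centers and scales the columns of `train` to mean 0, SD 1, and applies
#' the *training* statistics to `test`. Constant training columns are
#' centered but left unscaled (divisor 1) and flagged.
#'
#' @param train,test Numeric matrices with the same number of columns
#'   (`test` may be `NULL`).
#' @return List with `train`, `test`, and `stats` (per-feature `mean`, `sd`,
#'   and logical `zero_sd` flags).
#' @export
standardize <- function(train, test = NULL) {
  mu <- colMeans(train)
  # population SD (divisor n), matching the usual train-set scaler
  sd <- sqrt(colMeans(sweep(train, 2L, mu)^2))
  zero <- !is.finite(sd) | sd == 0
  sd[zero] <- 1
  tr <- sweep(sweep(train, 2L, mu), 2L, sd, "/")
  te <- if (!is.null(test)) {
    if (ncol(test) != ncol(train)) {
      stop("train and test feature dimensions differ", call. = FALSE)
    }
    sweep(sweep(test, 2L, mu), 2L, sd, "/")
  }
  list(train = tr, test = te,
       stats = list(mean = mu, sd = sd, zero_sd = zero))
}

#' Generalization map container
#'
#' @param scores Train-time x test-time ROC-AUC matrix (values in [0, 1]).
#' @param train_times,test_times Time axes in seconds.
#' @param scheme Fold-scheme tag.
#' @param subject Subject identifier.
#' @return A `generalization_map` object.
#' @export
generalization_map <- function(scores, train_times, test_times,
                               scheme = "within-3fold", subject = NA) {
  stopifnot(nrow(scores) == length(train_times),
            ncol(scores) == length(test_times))
  if (any(scores < -1e-9 | scores > 1 + 1e-9, na.rm = TRUE)) {
    stop("AUC scores must lie in [0, 1]", call. = FALSE)
  }
  structure(list(scores = scores, train_times = train_times,
                 test_times = test_times, scheme = scheme, subject = subject),
            class = "generalization_map")
}

#' @export
print.generalization_map <- function(x, ...) {
  cat(sprintf("<generalization_map> %dx%d [%s], mean AUC %.3f\n",
              nrow(x$scores), ncol(x$scores), x$scheme, mean(x$scores)))
  invisible(x)
}

# Stratified fold assignment with contiguous-in-time blocks per class, which
# limits leakage from temporally correlated noise. The block -> fold mapping
# is permuted under `seed`.
assign_folds <- function(labels, event_times, n_folds, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[order(event_times[idx])]
      chunk <- ceiling(seq_along(idx) / (length(idx) / n_folds))
      chunk <- pmin(chunk, n_folds)
      perm <- sample.int(n_folds)
      folds[idx] <- perm[chunk]
    }
  })
  folds
}

# labels -> 0/1 with the positive class mapped to 1
labels01 <- function(x) {
  pos <- x$positive_label
  if (length(pos) == 0L) {
    lev <- sort(unique(x$labels))
    if (length(lev) != 2L) stop("need binary labels", call. = FALSE)
    pos <- lev[[2L]]
  }
  as.integer(x$labels == pos)
}

# Train one classifier per train time on `train_idx` trials of `x`, test it
# at every test time on `test_data`/`test_y`; returns a T_train x T_test
# AUC matrix. Standardization uses train statistics only; predictions fold
# the standardization into the weights, so testing at all times is a single
# tensor product.
fold_generalization_map <- function(x, train_idx, test_data, test_y, cfg) {
  n_t <- length(x$times)
  n_test_t <- dim(test_data)[3L]
  n_test <- dim(test_data)[1L]
  test_flat <- matrix(aperm(test_data, c(1L, 3L, 2L)),
                      nrow = n_test * n_test_t)   # (trial,time) x channels
  train_y <- labels01(x)[train_idx]
  if (length(unique(train_y)) < 2L) {
    stop("fold error: training fold contains a single class", call. = FALSE)
  }
  scores <- matrix(NA_real_, n_t, n_test_t)
  for (ti in seq_len(n_t)) {
    Xtr <- x$data[train_idx, , ti, drop = TRUE]
    if (is.null(dim(Xtr))) Xtr <- matrix(Xtr, ncol = dim(x$data)[2L])
    st <- standardize(Xtr)
    w <- fit_logreg_l2(st$train, train_y, cfg)
    w_scaled <- w[-1L] / st$stats$sd
    b <- w[1L] - sum(st$stats$mean * w_scaled)
    dv <- matrix(test_flat %*% w_scaled + b, n_test, n_test_t)
    for (tj in seq_len(n_test_t)) {
      scores[ti, tj] <- roc_auc(dv[, tj], test_y)
    }
  }
  scores
}

#' Within-condition temporal generalization
#'
#' Trains a separate l2-logistic classifier at every time point (features =
#' all channels at that time, z-scored by training-fold statistics) and
#' tests each classifier at every time point of the held-out fold;
#' `scores[i, j]` is the fold-averaged held-out ROC AUC for training time
#' `i`, testing time `j`. The diagonal is ordinary time-resolved decoding.
#'
#' @param x An `epoch_collection` with binary labels.
#' @param cfg A [classifier_config()].
#' @param n_folds Number of stratified folds (default 3: train on 2/3, test
#'   on 1/3).
#' @param seed Integer seed controlling fold assignment.
#' @return A [generalization_map()] with scheme `"within-3fold"`.
#' @export
within_condition_generalization <- function(x, cfg = classifier_config(),
                                            n_folds = 3, seed = 1) {
  stopifnot(inherits(x, "epoch_collection"))
  y <- labels01(x)
  folds <- assign_folds(x$labels, x$event_times, n_folds, seed)
  per_class <- table(x$labels, folds)
  if (any(per_class < 2L)) {
    bad <- which(apply(per_class < 2L, 2L, any))[1L]
    stop(sprintf("fold error: fold %d has < 2 trials in a class", bad),
         call. = FALSE)
  }
  maps <- lapply(seq_len(n_folds), function(f) {
    tr <- which(folds != f)
    te <- which(folds == f)
    fold_generalization_map(x, tr, x$data[te, , , drop = FALSE], y[te], cfg)
  })
  generalization_map(Reduce(`+`, maps) / n_folds, x$times, x$times,
                     scheme = sprintf("within-%dfold", n_folds))
}

#' Bidirectional cross-condition temporal generalization
#'
#' Classifiers trained on 66% of condition `a` (the three complements of a
#' stratified 3-way partition) are tested on *all* trials of condition `b`,
#' and vice versa; the six fold maps are averaged after orienting the
#' direction-`b -> a` maps so that rows always index condition-`a` time and
#' columns condition-`b` time. Both collections must declare
#' `positive_label` so class polarity (the negative-outcome class) is
#' aligned across the two label problems.
#'
#' @param a,b `epoch_collection`s on identical time grids.
#' @param cfg A [classifier_config()].
#' @param seed Integer seed controlling partitions.
#' @return A [generalization_map()] with scheme
#'   `"cross-6fold-bidirectional"`; `train_times` are condition-`a` times,
#'   `test_times` condition-`b` times.
#' @export
cross_condition_generalization <- function(a, b, cfg = classifier_config(),
                                           seed = 1) {
  stopifnot(inherits(a, "epoch_collection"), inherits(b, "epoch_collection"))
  if (is.null(a$positive_label) || is.null(b$positive_label)) {
    stop("configuration error: both conditions need `positive_label` set",
         call. = FALSE)
  }
  if (length(a$times) != length(b$times) ||
      max(abs(a$times - b$times)) > 1e-9) {
    stop("conditions must share the same time grid", call. = FALSE)
  }
  one_direction <- function(src, dst, seed_off) {
    folds <- assign_folds(src$labels, src$event_times, 3L, seed + seed_off)
    dst_y <- labels01(dst)
    maps <- lapply(1:3, function(f) {
      fold_generalization_map(src, which(folds != f), dst$data, dst_y, cfg)
    })
    Reduce(`+`, maps)
  }
  ab <- one_direction(a, b, 0L)             # rows: a-time, cols: b-time
  ba <- one_direction(b, a, 1L)             # rows: b-time -> transpose
  generalization_map((ab + t(ba)) / 6, a$times, b$times,
                     scheme = "cross-6fold-bidirectional")
}
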