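#' GLM design for per-segment SSVEP amplitude estimation
#'
#' Regressors: DC offset, linear trend, and sine/cosine pairs at both target
#' modulation frequencies (12 and 15 Hz), the alpha rhythm (10 Hz) and line
#' interference (50 Hz). The sine/cosine pairing accommodates unknown
#' phase; the amplitude estimate at each target frequency is the Euclidean
#' norm of its (sine, cosine) coefficient pair.
#'
#' @param target_freqs Target modulation frequencies, Hz.
#' @param alpha_freq Alpha nuisance frequency, Hz.
#' @param line_freq Line-interference nuisance frequency, Hz (dropped from
#'   the design when at/above Nyquist).
#' @param segment_length Segment length, seconds (default 0.5).
#' @return A `glm_design` object.
#' @export
glm_design <- function(target_freqs = c(12, 15), alpha_freq = 10,
                       line_freq = 50, segment_length = 0.5) {
  structure(list(target_freqs = target_freqs, alpha_freq = alpha_freq,
                 line_freq = line_freq, segment_length = segment_length),
            class = "glm_design")
}

glm_design_matrix <- function(design, n, sfreq) {
  t <- (seq_len(n) - 1L) / sfreq
  freqs <- c(design$target_freqs, design$alpha_freq, design$line_freq)
  freqs <- freqs[freqs < sfreq / 2]
  cols <- list(dc = rep(1, n), trend = t - mean(t))
  for (f in freqs) {
    cols[[sprintf("sin_%g", f)]] <- sin(2 * pi * f * t)
    cols[[sprintf("cos_%g", f)]] <- cos(2 * pi * f * t)
  }
  X <- do.call(cbind, cols)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop(sprintf("rank-deficient design: collinear columns %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  X
}

#' Per-segment SSVEP amplitude estimates
#'
#' Least-squares fit of the [glm_design()] regressors to each component's
#' time course within one segment; returns the nonnegative amplitude (norm
#' of the sine/cosine coefficient pair) at each target frequency.
#'
#' @param segment Components x samples matrix (one 500-ms segment of
#'   SSD-reduced data).
#' @param design A [glm_design()].
#' @param sfreq Sampling rate, Hz.
#' @return Matrix: target frequencies (rows, named) x components.
#' @export
glm_amplitudes <- function(segment, design, sfreq) {
  if (is.null(dim(segment))) segment <- matrix(segment, nrow = 1L)
  n <- ncol(segment)
  if (abs(n - design$segment_length * sfreq) > 1) {
    stop(sprintf("segment length %d does not match design (%g s at %g Hz)",
                 n, design$segment_length, sfreq), call. = FALSE)
  }
  X <- glm_design_matrix(design, n, sfreq)
  coefs <- qr.coef(qr(X), t(segment))     # p x components
  out <- matrix(0, length(design$target_freqs), nrow(segment),
                dimnames = list(sprintf("%g", design$target_freqs), NULL))
  for (f in design$target_freqs) {
    s <- coefs[sprintf("sin_%g", f), , drop = FALSE]
    cc <- coefs[sprintf("cos_%g", f), , drop = FALSE]
    out[sprintf("%g", f), ] <- sqrt(s^2 + cc^2)
  }
  out
}

# primal squared-hinge linear SVM: 0.5*||w||^2 + C * sum(max(0, 1 - y f)^2)
fit_linear_svm <- function(X, y_pm, C) {
  d <- ncol(X)
  obj <- function(par) {
    w <- par[-1L]
    f <- drop(X %*% w) + par[1L]
    xi <- pmax(0, 1 - y_pm * f)
    0.5 * sum(w^2) + C * sum(xi^2)
  }
  grad <- function(par) {
    w <- par[-1L]
    f <- drop(X %*% w) + par[1L]
    xi <- pmax(0, 1 - y_pm * f)
    gc <- -2 * C * y_pm * xi
    c(sum(gc), w + drop(crossprod(X, gc)))
  }
  fit <- stats::optim(numeric(d + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(b = fit$par[1L], w = fit$par[-1L])
}

#' Train a calibrated linear classifier for SSVEP features
#'
#' Linear max-margin (SVM-style, squared hinge, `C = 0.5`) decision
#' function on standardized amplitude features, with posterior
#' probabilities from a Platt-style sigmoid fitted to decision values
#' obtained by internal 3-fold cross-validation.
#'
#' @param features Segments x features matrix (amplitudes at each target
#'   frequency for each SSD component).
#' @param labels Per-segment attended-target labels (two classes).
#' @param C Regularization parameter (default 0.5).
#' @param seed Integer seed for the internal CV folds.
#' @return A `bci_classifier` with a [predict.bci_classifier()] method.
#' @export
train_calibrated_classifier <- function(features, labels, C = 0.5, seed = 1) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) {
    stop("calibration data must contain exactly two classes", call. = FALSE)
  }
  y_pm <- ifelse(labels == lev[2L], 1, -1)
  st <- standardize(features)
  svm <- fit_linear_svm(st$train, y_pm, C)
  # cross-validated decision values for the sigmoid
  folds <- assign_folds(labels, seq_along(labels), 3L, seed)
  dv_cv <- numeric(length(labels))
  for (f in 1:3) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2L) next
    m <- fit_linear_svm(st$train[tr, , drop = FALSE], y_pm[tr], C)
    dv_cv[!tr] <- drop(st$train[!tr, , drop = FALSE] %*% m$w) + m$b
  }
  # Platt targets guard against perfect separation
  n_pos <- sum(y_pm > 0)
  n_neg <- sum(y_pm < 0)
  targ <- ifelse(y_pm > 0, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  cal <- fit_logreg_l2(matrix(dv_cv, ncol = 1L), targ,
                       classifier_config(C = 1000, max_iter = 200))
  structure(list(levels = lev, w = svm$w, b = svm$b,
                 feat_mean = st$stats$mean, feat_sd = st$stats$sd,
                 platt = cal),
            class = "bci_classifier")
}

#' Posterior class probabilities for SSVEP segments
#'
#' @param object A `bci_classifier`.
#' @param features Segments x features matrix.
#' @param ... Ignored.
#' @return Data frame with `class` (predicted label) and `posterior`
#'   (probability of the predicted class); the full two-class probability
#'   matrix (rows summing to 1) is in the `prob` attribute.
#' @export
predict.bci_classifier <- function(object, features, ...) {
  features <- as.matrix(features)
  Xs <- sweep(sweep(features, 2L, object$feat_mean), 2L, object$feat_sd, "/")
  dv <- drop(Xs %*% object$w) + object$b
  p2 <- stats::plogis(object$platt[1L] + object$platt[2L] * dv)
  prob <- cbind(1 - p2, p2)
  colnames(prob) <- object$levels
  cls <- object$levels[1L + (p2 > 0.5)]
  out <- data.frame(class = cls,
                    posterior = pmax(p2, 1 - p2),
                    stringsAsFactors = FALSE)
  attr(out, "prob") <- prob
  out
}

#' Sequential decision rule for online decoding
#'
#' @param threshold Posterior threshold (in (0.5, 1), default 0.75).
#' @param consecutive Required consecutive agreeing segments (default 2);
#'   with independent per-segment error `e`, the error rate of a decision is
#'   `e^consecutive` (0.25^2 = 0.0625 at the defaults).
#' @param timeout Decision timeout in seconds (default 5).
#' @param segment_length Segment length in seconds (default 0.5).
#' @return A `decision_rule` object.
#' @export
decision_rule <- function(threshold = 0.75, consecutive = 2, timeout = 5,
                          segment_length = 0.5) {
  stopifnot_scalar_num(threshold, "threshold", 0.5, 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  if (consecutive < 1) stop("consecutive must be >= 1", call. = FALSE)
  structure(list(threshold = threshold, consecutive = as.integer(consecutive),
                 timeout = timeout, segment_length = segment_length),
            class = "decision_rule")
}

#' Apply the sequential decision rule to a segment stream
#'
#' Decides class `k` at the first segment such that the last `consecutive`
#' segments all classified `k` with posterior above threshold; returns a
#' timeout after `timeout / segment_length` segments without a decision.
#'
#' @param segments Data frame with columns `class` and `posterior`, one row
#'   per segment in arrival order (e.g. from [predict.bci_classifier()]).
#' @param rule A [decision_rule()].
#' @return List with `decision` (class label or `NA`), `segment` (index at
#'   which the decision fired, `NA` on timeout), `timeout` (logical), and
#'   `latency` in seconds.
#' @export
sequential_decision <- function(segments, rule = decision_rule()) {
  max_seg <- floor(rule$timeout / rule$segment_length + 1e-9)
  n <- min(nrow(segments), max_seg)
  run_class <- NA_character_
  run_len <- 0L
  for (i in seq_len(n)) {
    ok <- segments$posterior[i] > rule$threshold
    if (ok && identical(segments$class[i], run_class)) {
      run_len <- run_len + 1L
    } else if (ok) {
      run_class <- segments$class[i]
      run_len <- 1L
    } else {
      run_class <- NA_character_
      run_len <- 0L
    }
    if (run_len >= rule$consecutive) {
      return(list(decision = run_class, segment = i, timeout = FALSE,
                  latency = i * rule$segment_length))
    }
  }
  list(decision = NA_character_, segment = NA_integer_, timeout = TRUE,
       latency = max_seg * rule$segment_length)
}

split_segments <- function(x, sfreq, segment_length, max_segments = Inf) {
  n_per <- round(segment_length * sfreq)
  n_seg <- min(floor(ncol(x) / n_per), max_segments)
  lapply(seq_len(n_seg), function(i) {
    x[, ((i - 1L) * n_per + 1L):(i * n_per), drop = FALSE]
  })
}

#' Amplitude feature vector for one segment
#'
#' @param segment Channels x samples sensor segment.
#' @param filters SSD spatial filters (channels x components).
#' @param design A [glm_design()].
#' @param sfreq Sampling rate, Hz.
#' @return Numeric feature vector: amplitudes at each target frequency for
#'   each component (frequency-major order).
#' @export
bci_segment_features <- function(segment, filters, design, sfreq) {
  comp <- crossprod(filters, segment)     # components x samples
  as.vector(t(glm_amplitudes(comp, design, sfreq)))
}

#' Calibrate the full SSVEP decoding stack
#'
#' Fits one SSD filter set on the concatenated calibration streams, builds
#' per-segment amplitude features, and trains the calibrated classifier.
#'
#' @param streams List of channels x samples calibration streams.
#' @param attended Per-stream attended-frequency labels.
#' @param sfreq Sampling rate, Hz.
#' @param ssd_cfg An [ssd_config()].
#' @param design A [glm_design()].
#' @param C SVM regularization (default 0.5).
#' @param seed Integer seed.
#' @return List with `ssd`, `classifier`, `design`.
#' @export
bci_calibrate <- function(streams, attended, sfreq, ssd_cfg = ssd_config(),
                          design = glm_design(), C = 0.5, seed = 1) {
  stopifnot(length(streams) == length(attended))
  ssd <- ssd_fit(do.call(cbind, streams), sfreq, ssd_cfg)
  feats <- list()
  labs <- character(0)
  for (i in seq_along(streams)) {
    segs <- split_segments(streams[[i]], sfreq, design$segment_length)
    for (sg in segs) {
      feats[[length(feats) + 1L]] <-
        bci_segment_features(sg, ssd$filters, design, sfreq)
      labs <- c(labs, sprintf("%g", attended[i]))
    }
  }
  clf <- train_calibrated_classifier(do.call(rbind, feats), labs, C = C,
                                     seed = seed)
  list(ssd = ssd, classifier = clf, design = design)
}

#' Decode one trial's sensor stream online
#'
#' Segments the stream, extracts SSD/GLM amplitude features per segment,
#' classifies each segment and applies the sequential decision rule.
#'
#' @param stream Channels x samples sensor stream for one trial.
#' @param calib Output of [bci_calibrate()].
#' @param sfreq Sampling rate, Hz.
#' @param rule A [decision_rule()].
#' @return As [sequential_decision()], plus `segments` (the per-segment
#'   classification table).
#' @export
bci_decode_stream <- function(stream, calib, sfreq, rule = decision_rule()) {
  max_seg <- floor(rule$timeout / rule$segment_length + 1e-9)
  segs <- split_segments(stream, sfreq, rule$segment_length, max_seg)
  feats <- do.call(rbind, lapply(segs, bci_segment_features,
                                 filters = calib$ssd$filters,
                                 design = calib$design, sfreq = sfreq))
  pred <- predict(calib$classifier, feats)
  out <- sequential_decision(pred, rule)
  out$segments <- pred
  out
}
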