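#' Pointwise one-sample t map of AUC deviations from chance
#'
#' For each (train, test) cell, `t = mean(AUC - chance) / SE` across
#' subjects. Cells with zero between-subject variance get a `+Inf`/`-Inf`
#' sentinel (sign of the mean) and are flagged.
#'
#' @param maps List of [generalization_map()]s on identical time grids.
#' @param chance Chance level subtracted before testing (default 0.5).
#' @return A `tmap` object: fields `t` (matrix), `df`, `chance`,
#'   `degenerate` (logical matrix flagging zero-SE cells), plus the time
#'   axes.
#' @export
pointwise_tmap <- function(maps, chance = 0.5) {
  n <- length(maps)
  if (n < 2L) stop("insufficient subjects: need >= 2 maps", call. = FALSE)
  dims <- dim(maps[[1L]]$scores)
  for (m in maps) {
    if (!all(dim(m$scores) == dims)) {
      stop("maps must share the same time grid", call. = FALSE)
    }
  }
  e <- array(unlist(lapply(maps, function(m) m$scores - chance)),
             dim = c(dims, n))
  mu <- apply(e, c(1L, 2L), mean)
  sdv <- apply(e, c(1L, 2L), stats::sd)
  se <- sdv / sqrt(n)
  t <- mu / se
  degen <- se == 0
  t[degen] <- sign(mu[degen]) * Inf
  t[degen & mu == 0] <- 0
  structure(list(t = t, df = n - 1L, chance = chance, degenerate = degen,
                 train_times = maps[[1L]]$train_times,
                 test_times = maps[[1L]]$test_times),
            class = "tmap")
}

#' Suprathreshold clusters and their masses
#'
#' Connected components (4-neighborhood on the train x test grid) of cells
#' with `t > threshold`; the mass of a cluster is the sum of its signed t
#' values. Only positive (above-chance) clustering is performed.
#'
#' @param t A `tmap` or a bare numeric t matrix.
#' @param threshold Cluster-forming threshold, typically the one-tailed t
#'   critical value at p = .01 with `n - 1` df.
#' @return List of clusters, each with `cells` (two-column index matrix),
#'   `mask` (logical matrix) and `mass`; ordered by decreasing mass.
#' @export
cluster_mass_clusters <- function(t, threshold) {
  tm <- if (inherits(t, "tmap")) t$t else t
  lab <- label_components4(tm > threshold)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  clusters <- lapply(ids, function(id) {
    mask <- lab == id
    list(cells = which(mask, arr.ind = TRUE), mask = mask,
         mass = sum(tm[mask]))
  })
  clusters[order(vapply(clusters, `[[`, numeric(1L), "mass"),
                 decreasing = TRUE)]
}

# t statistics for a stack of effect maps E (subjects x cells) under sign
# pattern rows S (n_perm x subjects). Sum of squares is flip-invariant, so
# each permutation costs one matrix product.
signed_tstats <- function(S, E, ss) {
  n <- ncol(S)
  m <- (S %*% E) / n
  v <- (matrix(ss, nrow(S), length(ss), byrow = TRUE) - n * m^2) / (n - 1L)
  t <- m / sqrt(v / n)
  t[v <= 0] <- ifelse(m[v <= 0] == 0, 0, sign(m[v <= 0]) * Inf)
  t
}

max_cluster_mass <- function(tvec, nr, nc, threshold) {
  above <- tvec > threshold
  if (!any(above)) return(0)
  lab <- label_components4(matrix(above, nr, nc))
  tm <- matrix(tvec, nr, nc)
  max(vapply(setdiff(unique(as.vector(lab)), 0L),
             function(id) sum(tm[lab == id]), numeric(1L)))
}

#' One-sample sign-flip cluster-mass permutation test
#'
#' Group test for above-chance generalization. Subject maps are reduced to
#' deviations from chance, a pointwise one-tailed t map is thresholded at
#' the t critical value for p < .01, and suprathreshold 4-connected clusters
#' are scored by their mass (sum of signed t). The null is built by randomly
#' negating each subject's deviation map and recording the maximum positive
#' cluster mass per permutation; cluster p = `(1 + #{perm max >= mass}) /
#' (1 + n_perm)`, so p is never zero.
#'
#' @param maps List of [generalization_map()]s (>= 2 subjects).
#' @param n_perm Number of sign permutations (default 10,000; a warning is
#'   issued below 100).
#' @param alpha Significance level recorded in the result.
#' @param seed Integer seed for the permutation draws.
#' @param cluster_p Cluster-forming pointwise p (one-tailed; default .01).
#' @param chance Chance level (default 0.5).
#' @return A `cluster_result`: `clusters` (each with `cells`, `mask`,
#'   `mass`, `p`), `threshold`, `n_perm`, `n_subjects`, `null_max_mass`
#'   (the permutation null), `tmap`, and `alpha`.
#' @export
signflip_cluster_test <- function(maps, n_perm = 10000, alpha = 0.05,
                                  seed = 1, cluster_p = 0.01, chance = 0.5) {
  n <- length(maps)
  if (n == 0L) stop("no subjects", call. = FALSE)
  if (n < 2L) stop("insufficient subjects: need >= 2 maps", call. = FALSE)
  if (n_perm < 100) warning("n_perm < 100: permutation p-values are coarse")
  tm <- pointwise_tmap(maps, chance = chance)
  threshold <- stats::qt(1 - cluster_p, df = tm$df)
  nr <- nrow(tm$t)
  nc <- ncol(tm$t)
  E <- t(vapply(maps, function(m) as.vector(m$scores - chance),
                numeric(nr * nc)))
  ss <- colSums(E^2)
  # observed statistics through the same code path as the permutations, so
  # ties with the identity sign pattern are numerically exact
  t_obs <- matrix(signed_tstats(matrix(1, 1L, n), E, ss)[1L, ], nr, nc)
  clusters <- cluster_mass_clusters(t_obs, threshold)
  null_max <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    Tperm <- signed_tstats(S, E, ss)
    vapply(seq_len(n_perm), function(p) {
      max_cluster_mass(Tperm[p, ], nr, nc, threshold)
    }, numeric(1L))
  })
  clusters <- lapply(clusters, function(cl) {
    tol <- 1e-9 * max(1, abs(cl$mass))
    cl$p <- (1 + sum(null_max >= cl$mass - tol)) / (1 + n_perm)
    cl
  })
  structure(list(clusters = clusters, threshold = threshold,
                 n_perm = as.integer(n_perm), n_subjects = n,
                 null_max_mass = null_max, tmap = tm, alpha = alpha),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d subjects, threshold t > %.3f, %d perms\n",
              x$n_subjects, x$threshold, x$n_perm))
  if (length(x$clusters) == 0L) {
    cat("  no suprathreshold clusters\n")
  } else {
    for (cl in x$clusters) {
      cat(sprintf("  cluster: %d cells, mass %.1f, p = %.4f\n",
                  nrow(cl$cells), cl$mass, cl$p))
    }
  }
  invisible(x)
}

#' Two-sample max-statistic permutation test on a sensor time course
#'
#' Pointwise two-sample t tests (pooled variance) between the two trial
#' groups at one sensor, with family-wise correction by the permutation
#' distribution of the maximum |t| over time: corrected p at each timepoint
#' is `(1 + #{perm max |t| >= observed |t|}) / (1 + n_perm)` (two-tailed).
#'
#' @param class_a,class_b Trials x time matrices for the two classes.
#' @param n_perm Number of label permutations (default 10,000).
#' @param seed Integer seed.
#' @return List with `t` (observed t values), `p_corrected`, and
#'   `null_max` (permutation null of max |t|).
#' @export
erp_maxstat_test <- function(class_a, class_b, n_perm = 10000, seed = 1) {
  class_a <- as.matrix(class_a)
  class_b <- as.matrix(class_b)
  na <- nrow(class_a)
  nb <- nrow(class_b)
  if (na < 2L || nb < 2L) {
    stop("need >= 2 trials per class", call. = FALSE)
  }
  pooled <- rbind(class_a, class_b)
  n <- na + nb
  sq <- pooled^2
  tstat <- function(idx_a) {
    ina <- logical(n)
    ina[idx_a] <- TRUE
    sa <- colSums(pooled[ina, , drop = FALSE])
    sb <- colSums(pooled) - sa
    ssa <- colSums(sq[ina, , drop = FALSE])
    ssb <- colSums(sq) - ssa
    ma <- sa / na
    mb <- sb / nb
    sp2 <- (ssa - na * ma^2 + ssb - nb * mb^2) / (n - 2L)
    sp2 <- pmax(sp2, .Machine$double.eps)    # degenerate-variance guard
    (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  t_obs <- tstat(seq_len(na))
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      max(abs(tstat(sample.int(n, na))))
    }, numeric(1L))
  })
  p_corr <- vapply(abs(t_obs), function(tv) {
    (1 + sum(null_max >= tv)) / (1 + n_perm)
  }, numeric(1L))
  list(t = t_obs, p_corrected = p_corr, null_max = null_max)
}
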