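#' Probabilistic-feedback BCI task design
#'
#' Defaults follow the study design this package simulates: 5 blocks of 72
#' trials (360 total), four stimuli with positive-feedback probabilities
#' (0.8, 0.66, 0.33, 0.2), artificial decoder errors injected on 15% of
#' trials, 500-ms decoding segments and a 5-s decision timeout.
#'
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials per block.
#' @param reward_probabilities Length-4 vector of per-stimulus
#'   positive-feedback probabilities, each in (0, 1).
#' @param artificial_error_rate Probability of an injected decoder error per
#'   trial, in [0, 1].
#' @param segment_length Online decoding segment length, seconds.
#' @param decision_timeout Online decision timeout, seconds.
#' @return A `task_design` object.
#' @export
task_design <- function(n_blocks = 5, trials_per_block = 72,
                        reward_probabilities = c(0.8, 0.66, 0.33, 0.2),
                        artificial_error_rate = 0.15,
                        segment_length = 0.5, decision_timeout = 5) {
  if (any(reward_probabilities <= 0) || any(reward_probabilities >= 1)) {
    stop("config error: reward probabilities must lie in (0, 1)", call. = FALSE)
  }
  stopifnot_scalar_num(artificial_error_rate, "artificial_error_rate", 0, 1)
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 reward_probabilities = reward_probabilities,
                 artificial_error_rate = artificial_error_rate,
                 segment_length = segment_length,
                 decision_timeout = decision_timeout),
            class = "task_design")
}

#' Simulate a probabilistic-learning BCI session
#'
#' Produces a trial table: on each trial a random pair of the four stimuli is
#' presented, the agent intends the higher-value one with the block's
#' learning-curve probability, an artificial decoder error flips the decoded
#' choice with probability `artificial_error_rate`, and feedback is drawn
#' from the reward probability of the *decoded* stimulus (when the decoder
#' errs, feedback follows the stimulus the decoder indicated, not the
#' intended one).
#'
#' @param design A [task_design()].
#' @param learning_curve Per-block probability of intending the better
#'   stimulus of the pair; length `n_blocks`, values in [0, 1].
#' @param seed Integer seed.
#' @return A `data.frame` of class `trial_table` with columns `block`,
#'   `stim_a`, `stim_b` (stimulus indices into `reward_probabilities`),
#'   `intended`, `decoded`, `artificial_error`, `valence`
#'   (`positive`/`negative`/`none`) and `surprise` (filled by
#'   [label_surprise()], initially `none`). Reward probabilities are carried
#'   in the `reward_probabilities` attribute.
#' @export
simulate_session <- function(design = task_design(),
                             learning_curve = rep(0.8, design$n_blocks),
                             seed = 1) {
  if (length(learning_curve) != design$n_blocks) {
    stop("`learning_curve` length must equal n_blocks", call. = FALSE)
  }
  if (any(learning_curve < 0) || any(learning_curve > 1)) {
    stop("config error: learning_curve values must lie in [0, 1]",
         call. = FALSE)
  }
  probs <- design$reward_probabilities
  n_stim <- length(probs)
  n <- design$n_blocks * design$trials_per_block
  with_seed(seed, {
    block <- rep(seq_len(design$n_blocks), each = design$trials_per_block)
    pairs <- t(replicate(n, sample.int(n_stim, 2L)))
    better <- ifelse(probs[pairs[, 1L]] >= probs[pairs[, 2L]],
                     pairs[, 1L], pairs[, 2L])
    worse <- ifelse(better == pairs[, 1L], pairs[, 2L], pairs[, 1L])
    pick_better <- stats::runif(n) < learning_curve[block]
    intended <- ifelse(pick_better, better, worse)
    artificial_error <- stats::runif(n) < design$artificial_error_rate
    other <- ifelse(intended == pairs[, 1L], pairs[, 2L], pairs[, 1L])
    decoded <- ifelse(artificial_error, other, intended)
    positive <- stats::runif(n) < probs[decoded]
    tbl <- data.frame(block = block, stim_a = pairs[, 1L],
                      stim_b = pairs[, 2L], intended = intended,
                      decoded = decoded, artificial_error = artificial_error,
                      valence = ifelse(positive, "positive", "negative"),
                      surprise = "none", stringsAsFactors = FALSE)
    attr(tbl, "reward_probabilities") <- probs
    class(tbl) <- c("trial_table", "data.frame")
    tbl
  })
}

#' Subset a trial table, preserving design metadata
#' @param x A `trial_table`.
#' @param ... Passed to the data.frame method.
#' @return The subsetted `trial_table`.
#' @export
`[.trial_table` <- function(x, ...) {
  probs <- attr(x, "reward_probabilities")
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "reward_probabilities") <- probs
    class(out) <- c("trial_table", "data.frame")
  }
  out
}

trial_table_probs <- function(table) {
  probs <- attr(table, "reward_probabilities")
  if (is.null(probs)) stop("trial table lacks reward_probabilities attribute",
                           call. = FALSE)
  probs
}

# TRUE when the decoded stimulus was the higher-value member of its pair.
chose_better <- function(table) {
  probs <- trial_table_probs(table)
  other <- ifelse(table$decoded == table$stim_a, table$stim_b, table$stim_a)
  probs[table$decoded] > probs[other]
}

#' Label negative-feedback trials by outcome surprise
#'
#' Within the selected (late) blocks, negative feedback that resulted from
#' picking the better alternative of the pair is labeled `high` surprise;
#' negative feedback after picking the worse alternative is `low` surprise.
#' All other trials keep `none`. By default only blocks 4 and 5 are labeled,
#' when expectations about stimulus values have formed.
#'
#' @param table A [simulate_session()] trial table with valence filled.
#' @param blocks Block indices eligible for labeling (non-empty).
#' @return The trial table with the `surprise` column filled.
#' @export
label_surprise <- function(table, blocks = c(4, 5)) {
  if (length(blocks) == 0L) stop("`blocks` must be non-empty", call. = FALSE)
  better <- chose_better(table)
  sel <- table$valence == "negative" & table$block %in% blocks
  table$surprise <- ifelse(sel & better, "high",
                           ifelse(sel & !better, "low", "none"))
  table
}

#' Valence-balanced trial subsets
#'
#' Builds positive- and negative-feedback subsets in which high- and
#' low-surprise (expectancy) trial counts are equal within each subset, so a
#' valence classifier cannot exploit expectancy. Expectancy of
#' positive-feedback trials is defined by the mirror rule: positive feedback
#' after the better choice is expected (low surprise), after the worse
#' choice unexpected (high surprise). Only correctly decoded trials in the
#' selected blocks enter; each category is randomly down-sampled to the
#' common minimum count.
#'
#' @param table A trial table (surprise labels are recomputed internally).
#' @param seed Integer seed for the down-sampling.
#' @param blocks Block indices considered (defaults to late blocks 4-5).
#' @return A list with elements `positive` and `negative`, two equally sized
#'   trial tables each containing equally many high- and low-surprise trials.
#' @export
balance_valence_subsets <- function(table, seed = 1, blocks = c(4, 5)) {
  better <- chose_better(table)
  eligible <- !table$artificial_error & table$block %in% blocks
  # expectancy category: negative/better and positive/worse are "high"
  cat_high <- ifelse(table$valence == "negative", better, !better)
  groups <- list(
    pos_high = which(eligible & table$valence == "positive" & cat_high),
    pos_low  = which(eligible & table$valence == "positive" & !cat_high),
    neg_high = which(eligible & table$valence == "negative" & cat_high),
    neg_low  = which(eligible & table$valence == "negative" & !cat_high))
  counts <- lengths(groups)
  if (any(counts == 0L)) {
    stop(sprintf("insufficient trials: category '%s' is empty",
                 names(groups)[which(counts == 0L)[1L]]), call. = FALSE)
  }
  k <- min(counts)
  with_seed(seed, {
    keep <- lapply(groups, function(idx) {
      if (length(idx) == k) idx else sort(sample(idx, k))
    })
    list(positive = table[sort(c(keep$pos_high, keep$pos_low)), ],
         negative = table[sort(c(keep$neg_high, keep$neg_low)), ])
  })
}
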