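#' Task configuration for the stochastic tokens task
#'
#' Describes the structure of one block of the token reinforcement task:
#' how many completed trials make a block, the four cue-to-token mappings,
#' the stochastic delivery probability, and the uniform cash-out interval.
#' The default configuration is the task as run with monkeys: 108-trial
#' blocks, six cue-pair conditions each shown 18 times, token deltas
#' (+2, +1, -1, -2) delivered with probability 0.75, and a cash-out every
#' 4--6 trials at which accumulated tokens convert one-for-one to juice
#' drops.
#'
#' @param block_length completed trials per block.
#' @param n_conditions number of cue-pair conditions.
#' @param presentations_per_condition times each condition is shown per
#'   block.
#' @param outcome_deliver_prob probability that the chosen cue's token
#'   change is actually applied (otherwise no change).
#' @param cue_deltas signed token change for each cue, ordered best to
#'   worst.
#' @param cashout_support inclusive set of possible cash-out intervals
#'   (trials since the previous cash-out), sampled uniformly.
#' @param nobs_max number of observations of a cue pair tracked within a
#'   block (the learning-progress state feature).
#' @param max_tokens token-count ceiling of the state space; defaults to
#'   the maximum reachable count, `max(cue_deltas) * max(cashout_support)`.
#'
#' @return An object of class `task_config`.
#' @export
task_config <- function(block_length = 108L,
                        n_conditions = 6L,
                        presentations_per_condition = 18L,
                        outcome_deliver_prob = 0.75,
                        cue_deltas = c(2L, 1L, -1L, -2L),
                        cashout_support = 4:6,
                        nobs_max = 18L,
                        max_tokens = NULL) {
  block_length <- as.integer(block_length)
  n_conditions <- as.integer(n_conditions)
  presentations_per_condition <- as.integer(presentations_per_condition)
  cashout_support <- sort(as.integer(cashout_support))
  if (block_length != n_conditions * presentations_per_condition)
    stop("block_length must equal n_conditions * presentations_per_condition")
  if (block_length %% (2L * n_conditions) != 0L)
    stop("block_length must be divisible by one 2x-per-condition window (",
         2L * n_conditions, " trials)")
  if (!(outcome_deliver_prob > 0 && outcome_deliver_prob <= 1))
    stop("outcome_deliver_prob must be in (0, 1]")
  if (any(diff(cashout_support) != 1L))
    stop("cashout_support must be a contiguous range of trial counts")
  if (block_length %% nobs_max != 0L)
    stop("block_length must be divisible by nobs_max")
  cfg <- list(
    block_length = block_length,
    n_conditions = n_conditions,
    presentations_per_condition = presentations_per_condition,
    outcome_deliver_prob = outcome_deliver_prob,
    cue_deltas = as.integer(cue_deltas),
    cashout_support = cashout_support,
    max_tokens = if (is.null(max_tokens))
      max(cue_deltas) * max(cashout_support) else as.integer(max_tokens),
    nobs_max = as.integer(nobs_max),
    # unordered cue pairs defining the conditions, in canonical order:
    # 1: best-vs-second ... built from the delta ordering below.
    conditions = default_condition_pairs(n_conditions, length(cue_deltas)),
    trials_per_nobs = block_length %/% as.integer(nobs_max)
  )
  class(cfg) <- "task_config"
  cfg
}

# Canonical condition order used throughout: with cues indexed 1..4 by
# descending delta (+2, +1, -1, -2), conditions are
# 1: +2 v +1, 2: +1 v -1, 3: +2 v -1, 4: +1 v -2, 5: +2 v -2, 6: -2 v -1.
default_condition_pairs <- function(n_conditions, n_cues) {
  full <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L),
               c(2L, 4L), c(1L, 4L), c(4L, 3L))
  if (n_cues == 4L && n_conditions == 6L) return(full)
  # reduced tasks (used for miniature models): take the first pairs over
  # the available cues
  pairs <- utils::combn(n_cues, 2L, simplify = FALSE)
  pairs[seq_len(n_conditions)]
}

#' Task-epoch identifiers
#'
#' Epoch numbering used by the MDP state space: 1 = fixation,
#' `2 .. n_conditions+1` = the cue conditions, then token outcome,
#' cash-out and the intertrial interval (ITI).  For the default task this
#' is TE 1--10.
#'
#' @param config a [task_config()].
#' @return Named integer vector of epoch ids.
#' @export
epoch_ids <- function(config) {
  C <- config$n_conditions
  ids <- c(1L, seq_len(C) + 1L, C + 2L, C + 3L, C + 4L)
  names(ids) <- c("fixation", paste0("condition", seq_len(C)),
                  "outcome", "cashout", "iti")
  ids
}

#' Conditional cash-out hazard
#'
#' Probability that a cash-out occurs after the current trial's token
#' outcome, given the number of trials since the last cash-out (TSCO).
#' With the cash-out interval uniform on \{4,5,6\} the hazard is 0 for
#' TSCO 1--3, 1/3 at TSCO 4, 1/2 at TSCO 5 and 1 at TSCO 6.
#'
#' @param tsco trials since cash-out (the current trial counts).
#' @param config a [task_config()]; its `cashout_support` defines the
#'   uniform interval distribution.
#' @return Conditional probability of cashing out after this trial.
#' @export
cashout_hazard <- function(tsco, config = task_config()) {
  support <- config$cashout_support
  tmax <- max(support)
  if (any(tsco < 1L | tsco > tmax))
    stop("tsco must be between 1 and ", tmax)
  hazard_from_support(support)[tsco]
}

#' Derive the hazard function from a uniform interval distribution
#'
#' Enumerates the equiprobable cash-out intervals and computes, for every
#' trial index t, P(cash-out at t | reached t).  This is the independent
#' derivation behind [cashout_hazard()].
#'
#' @param support integer vector of equiprobable interval lengths.
#' @return Numeric vector of hazards indexed by trials since cash-out.
#' @export
hazard_from_support <- function(support) {
  support <- sort(as.integer(support))
  tmax <- max(support)
  # P(interval = t) uniform; survival P(interval >= t)
  pmf <- as.numeric(seq_len(tmax) %in% support) / length(support)
  surv <- rev(cumsum(rev(pmf)))
  ifelse(surv > 0, pmf / surv, 0)
}

#' Apply a token outcome
#'
#' Applies a signed token change to the current count when the outcome is
#' delivered; token counts floor at zero (the animal can never owe
#' tokens).  Non-delivered outcomes leave the count unchanged.
#'
#' @param tokens current token count (>= 0).
#' @param delta signed token change of the chosen cue.
#' @param delivered logical; whether the outcome was delivered.
#' @return The new token count.
#' @export
apply_outcome <- function(tokens, delta, delivered) {
  if (any(tokens < 0)) stop("tokens must be non-negative")
  ifelse(delivered, pmax(0L, tokens + delta), tokens)
}

#' Build one block's pseudorandom condition schedule
#'
#' Conditions are scheduled so that every disjoint window of
#' `2 * n_conditions` trials contains each condition exactly twice, with
#' the two occurrences on opposite sides (same images, mirrored layout).
#' Over the default 108-trial block each condition therefore appears 18
#' times, 9 with the first cue of the pair on the left and 9 on the
#' right.
#'
#' @param config a [task_config()].
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @return A data frame with one row per completed trial and columns
#'   `trial`, `condition`, and `first_cue_left` (logical side
#'   assignment).
#' @export
build_schedule <- function(config = task_config(), seed = 1L) {
  C <- config$n_conditions
  window <- 2L * C
  n_windows <- config$block_length %/% window
  with_seed(seed, {
    cond <- integer(0)
    side <- logical(0)
    for (w in seq_len(n_windows)) {
      # each window: every condition twice, opposite sides
      first_side <- stats::runif(C) < 0.5
      slots <- sample(rep(seq_len(C), 2L))
      occ <- integer(C)
      s <- logical(window)
      for (i in seq_along(slots)) {
        k <- slots[i]
        occ[k] <- occ[k] + 1L
        s[i] <- if (occ[k] == 1L) first_side[k] else !first_side[k]
      }
      cond <- c(cond, slots)
      side <- c(side, s)
    }
    data.frame(trial = seq_len(config$block_length),
               condition = cond, first_cue_left = side)
  })
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Per-trial learning-progress index (NObs)
#'
#' Maps a completed-trial index within a block to the block-level
#' observation counter used as the MDP's learning-progress feature.  With
#' the balanced schedule each cue pair is seen once per
#' `n_conditions` trials, so the counter advances every
#' `block_length / nobs_max` completed trials (6 for the default task).
#'
#' @param trial completed-trial index within the block (1-based).
#' @param config a [task_config()].
#' @return Integer NObs in `1:nobs_max`.
#' @export
nobs_of_trial <- function(trial, config = task_config()) {
  pmin((as.integer(trial) - 1L) %/% config$trials_per_nobs + 1L,
       config$nobs_max)
}

#' Validate the task invariants on a session table
#'
#' Checks the structural invariants every well-formed session must
#' satisfy: token dynamics (floor at zero, `tokens_after <= 2 * TSCO`),
#' TSCO reset after cash-outs, exact block lengths, per-condition counts
#' and side balance, juice only at cash-out, and abort attempts that are
#' repeated with the same condition and sides.
#'
#' @param session a session data frame as produced by
#'   [simulate_session()].
#' @param config a [task_config()].
#' @return Invisibly `TRUE`; stops with a message on the first violated
#'   invariant.
#' @export
validate_session <- function(session, config = task_config()) {
  df <- session
  max_delta <- max(config$cue_deltas)
  completed <- df[df$abort_code == "none", ]
  if (nrow(completed) %% config$block_length != 0L)
    stop("completed trials are not a whole number of blocks")
  if (any(completed$tokens_after < 0)) stop("negative token count")
  if (any(completed$tokens_after > max_delta * completed$tsco))
    stop("tokens_after exceeds ", max_delta, " * TSCO")
  expected <- apply_outcome(completed$tokens_before, completed$delta,
                            completed$delivered)
  if (any(expected != completed$tokens_after))
    stop("token update inconsistent with delta/delivered")
  if (any(completed$juice_drops[!completed$cashout] != 0))
    stop("juice delivered outside cash-out")
  if (any(completed$juice_drops[completed$cashout] !=
          completed$tokens_after[completed$cashout]))
    stop("juice drops must equal tokens at cash-out")
  for (b in unique(completed$block)) {
    blk <- completed[completed$block == b, ]
    if (nrow(blk) != config$block_length)
      stop("block ", b, " has ", nrow(blk), " completed trials")
    counts <- tabulate(blk$condition, nbins = config$n_conditions)
    if (any(counts != config$presentations_per_condition))
      stop("unbalanced condition counts in block ", b)
    left <- tapply(blk$first_cue_left, blk$condition, sum)
    if (any(left != config$presentations_per_condition / 2))
      stop("unbalanced side counts in block ", b)
    # TSCO resets to 1 on the trial after a cash-out
    nxt <- which(blk$cashout[-nrow(blk)])
    if (length(nxt) && any(blk$tsco[nxt + 1L] != 1L))
      stop("TSCO does not reset after cash-out in block ", b)
  }
  # aborted attempts precede a repeat of the same condition and sides
  idx <- which(df$abort_code != "none")
  idx <- idx[idx < nrow(df)]
  if (length(idx)) {
    same <- df$condition[idx] == df$condition[idx + 1L] &
      df$first_cue_left[idx] == df$first_cue_left[idx + 1L] &
      df$block[idx] == df$block[idx + 1L]
    if (!all(same)) stop("aborted attempt not repeated immediately")
    if (any(df$delta[idx] != 0L)) stop("aborted attempt carries a token change")
  }
  invisible(TRUE)
}
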