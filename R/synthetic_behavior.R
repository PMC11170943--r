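#' Ground-truth generative parameters for synthetic sessions
#'
#' Parameters of the monkey-like behavioural generator: a
#' Rescorla-Wagner chooser (per-cue learning rates and softmax inverse
#' temperature), log-linear couplings from latent state value to
#' fixation and choice reaction times, and a logistic coupling from
#' state value to trial aborts.  Defaults describe a plausible animal:
#' faster learning for gain cues than loss cues, moderately consistent
#' choices, mildly value-coupled RTs and a few-percent abort rate that
#' decreases with state value.
#'
#' @param alpha per-cue learning rates in `[0, 1]` (ordered as the cue
#'   deltas, best to worst).
#' @param beta_rw softmax inverse temperature (>= 0).
#' @param rt_fix_coefs `(b0, b1)`: `log RT_fix = b0 + b1 * V_fix`.
#' @param rt_choice_coefs `(c0, c1, c2)`:
#'   `log RT_choice = c0 + c1 * V_cue + c2 * (V_cue - V_fix)`.
#' @param abort_coefs `(a0, a1)`: logit abort probability
#'   `a0 + a1 * V`, applied to `V_fix` before cue onset and `V_cue`
#'   after.  Use `c(-Inf, 0)` for an abort-free generator.
#' @param rt_noise_sd log-scale Gaussian RT noise (>= 0).
#' @param seed integer seed; simulations are deterministic given the
#'   truth object.
#' @return An object of class `behavior_truth`.
#' @export
behavior_truth <- function(alpha = c(0.3, 0.3, 0.1, 0.1),
                           beta_rw = 2,
                           rt_fix_coefs = c(b0 = -0.4, b1 = -0.05),
                           rt_choice_coefs = c(c0 = -1.1, c1 = -0.02,
                                               c2 = -0.05),
                           abort_coefs = c(a0 = 1.5, a1 = -0.2),
                           rt_noise_sd = 0.2,
                           seed = 1L) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha components must be in [0, 1]")
  if (beta_rw < 0) stop("beta_rw must be non-negative")
  if (rt_noise_sd < 0) stop("rt_noise_sd must be non-negative")
  structure(list(alpha = alpha, beta_rw = beta_rw,
                 rt_fix_coefs = rt_fix_coefs,
                 rt_choice_coefs = rt_choice_coefs,
                 abort_coefs = abort_coefs,
                 rt_noise_sd = rt_noise_sd,
                 seed = as.integer(seed)),
            class = "behavior_truth")
}

# Does the generator couple behaviour to latent state values?
truth_needs_values <- function(truth) {
  truth$rt_fix_coefs[2] != 0 || any(truth$rt_choice_coefs[2:3] != 0) ||
    (is.finite(truth$abort_coefs[1]) && truth$abort_coefs[2] != 0)
}

#' Simulate one behavioural session of the tokens task
#'
#' Generates a session of `n_blocks` blocks with the full task
#' mechanics: balanced pseudorandom schedules, a Rescorla-Wagner
#' softmax chooser updated online from realized token outcomes, 75\%
#' stochastic outcome delivery with a floor at zero tokens, uniform
#' 4--6-trial cash-outs converting tokens to juice, and abort-and-repeat
#' attempts.  Reaction times are drawn log-normally around linear
#' predictors of the latent state values looked up from `value_table`;
#' aborts are drawn from a logistic predictor (fixation-stage aborts use
#' the fixation-state value, choice-stage aborts the cue-state value).
#'
#' @param config a [task_config()].
#' @param truth a [behavior_truth()].
#' @param value_table an `mdp_value_table` supplying latent state
#'   values, or `NULL` if all couplings are zero.
#' @param n_blocks number of completed blocks to simulate.
#' @param session_id,subject_id identifiers stored in the output.
#' @return A session data frame, one row per trial attempt.
#' @export
simulate_session <- function(config = task_config(),
                             truth = behavior_truth(),
                             value_table = NULL,
                             n_blocks = 9L,
                             session_id = 1L, subject_id = 1L) {
  if (is.null(value_table) && truth_needs_values(truth))
    stop("a value_table is required when RT or abort couplings are nonzero")
  lookup <- function(ntk, tsco, te, nobs) {
    if (is.null(value_table)) 0
    else value_lookup(value_table, ntk, tsco, te, nobs)
  }
  hz <- hazard_from_support(config$cashout_support)
  deltas <- config$cue_deltas
  pairs <- do.call(rbind, config$conditions)
  b0 <- truth$rt_fix_coefs[1]; b1 <- truth$rt_fix_coefs[2]
  c0 <- truth$rt_choice_coefs[1]; c1 <- truth$rt_choice_coefs[2]
  c2 <- truth$rt_choice_coefs[3]
  a0 <- truth$abort_coefs[1]; a1 <- truth$abort_coefs[2]
  cap <- n_blocks * config$block_length * 2L
  rec <- new.env(parent = emptyenv())
  rec$i <- 0L
  cols <- list(block = integer(cap), trial = integer(cap),
               attempt = integer(cap), condition = integer(cap),
               first_cue_left = logical(cap), choice = integer(cap),
               delivered = logical(cap), delta = integer(cap),
               tokens_before = integer(cap), tokens_after = integer(cap),
               tsco = integer(cap), cashout = logical(cap),
               juice_drops = integer(cap), rt_fix = numeric(cap),
               rt_choice = numeric(cap), abort_code = character(cap))
  push <- function(vals) {
    i <- rec$i + 1L
    if (i > length(cols$block))
      cols <<- lapply(cols, function(v) c(v, v[seq_along(v)]))
    for (nm in names(vals)) cols[[nm]][i] <<- vals[[nm]]
    rec$i <- i
  }
  tokens <- 0L
  tsco <- 1L
  with_seed(truth$seed, {
    for (b in seq_len(n_blocks)) {
      sched <- build_schedule_raw(config)
      v <- numeric(length(deltas))
      for (t in seq_len(config$block_length)) {
        cc <- sched$condition[t]
        side <- sched$first_cue_left[t]
        nobs <- nobs_of_trial(t, config)
        v_fix <- lookup(tokens, tsco, 1L, nobs)
        v_cue <- lookup(tokens, tsco, 1L + cc, nobs)
        attempt <- 0L
        repeat {
          attempt <- attempt + 1L
          base <- list(block = b, trial = t, attempt = attempt,
                       condition = cc, first_cue_left = side,
                       tokens_before = tokens, tsco = tsco,
                       tokens_after = tokens, choice = NA_integer_,
                       delivered = FALSE, delta = 0L, cashout = FALSE,
                       juice_drops = 0L, rt_fix = NA_real_,
                       rt_choice = NA_real_)
          if (stats::runif(1) < stats::plogis(a0 + a1 * v_fix)) {
            push(c(base, abort_code = "fixation_abort"))
            next
          }
          rt_fix <- exp(b0 + b1 * v_fix +
                          stats::rnorm(1, 0, truth$rt_noise_sd))
          if (stats::runif(1) < stats::plogis(a0 + a1 * v_cue)) {
            base$rt_fix <- rt_fix
            push(c(base, abort_code = "choice_abort"))
            next
          }
          i <- pairs[cc, 1L]; j <- pairs[cc, 2L]
          d_j <- 1 / (1 + exp(truth$beta_rw * (v[i] - v[j])))
          chosen <- if (stats::runif(1) < d_j) j else i
          delivered <- stats::runif(1) < config$outcome_deliver_prob
          delta <- deltas[chosen]
          after <- apply_outcome(tokens, delta, delivered)
          R <- if (delivered) delta else 0
          v[chosen] <- rw_update(v[chosen], R, truth$alpha[chosen])
          cash <- stats::runif(1) < hz[tsco]
          base$rt_fix <- rt_fix
          base$rt_choice <- exp(c0 + c1 * v_cue + c2 * (v_cue - v_fix) +
                                  stats::rnorm(1, 0, truth$rt_noise_sd))
          base$choice <- chosen
          base$delivered <- delivered
          base$delta <- delta
          base$tokens_after <- as.integer(after)
          base$cashout <- cash
          base$juice_drops <- if (cash) as.integer(after) else 0L
          push(c(base, abort_code = "none"))
          if (cash) { tokens <- 0L; tsco <- 1L }
          else { tokens <- as.integer(after); tsco <- tsco + 1L }
          break
        }
      }
    }
  })
  n <- rec$i
  df <- as.data.frame(lapply(cols, function(v) v[seq_len(n)]))
  df$session <- session_id
  df$subject <- subject_id
  df[c("session", "subject", setdiff(names(df), c("session", "subject")))]
}

# Schedule draw using the current RNG stream (no reseeding); shared by
# build_schedule() and the simulator.
build_schedule_raw <- function(config) {
  C <- config$n_conditions
  window <- 2L * C
  n_windows <- config$block_length %/% window
  cond <- integer(0)
  side <- logical(0)
  for (w in seq_len(n_windows)) {
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
  data.frame(trial = seq_len(config$block_length), condition = cond,
             first_cue_left = side)
}

#' Parameter-recovery harness for the synthetic generator
#'
#' Simulates independent sessions from a known ground truth, refits the
#' Rescorla-Wagner model and (when a value table is supplied) the three
#' motivation regressions on each, and reports per-seed estimates with
#' bias and sign-recovery summaries.  This closes the loop that makes
#' the generator a testing instrument: every fitted quantity has a known
#' target.
#'
#' @param truth a [behavior_truth()]; each seed offsets `truth$seed`.
#' @param n_seeds number of independent replicate sessions (>= 2).
#' @param config a [task_config()].
#' @param value_table latent value table for the couplings (or `NULL`).
#' @param n_blocks blocks per replicate.
#' @param fit_rw_model refit the RW chooser per replicate (slowest
#'   step; disable when only regression recovery is of interest).
#' @return A list with `estimates` (one row per seed) and `summary`
#'   (bias of each recovered parameter and sign-agreement counts).
#' @export
recover_parameters_harness <- function(truth, n_seeds, config = task_config(),
                                       value_table = NULL, n_blocks = 9L,
                                       fit_rw_model = TRUE) {
  if (n_seeds < 2L) stop("n_seeds must be >= 2")
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    tr <- truth
    tr$seed <- truth$seed + s - 1L
    ses <- simulate_session(config, tr, value_table, n_blocks,
                            session_id = s)
    est <- list(seed = tr$seed)
    if (fit_rw_model) {
      fit <- fit_rw(ses, config)
      for (k in seq_along(fit$alpha)) est[[paste0("alpha", k)]] <- fit$alpha[k]
      est$beta_rw <- fit$beta
    }
    if (!is.null(value_table)) {
      fx <- fit_fixation_rt(ses, value_table, config)
      est$b0 <- unname(fx$coefficients[1])
      est$b1 <- unname(fx$coefficients[2])
      ch <- fit_choice_rt(ses, value_table, config)
      est$c1 <- unname(ch$coefficients[2])
      est$c2 <- unname(ch$coefficients[3])
      ab <- tryCatch(fit_abort_logistic(ses, value_table, config),
                     error = function(e) NULL)
      est$a1 <- if (is.null(ab)) NA_real_ else unname(ab$coefficients[2])
    }
    rows[[s]] <- as.data.frame(est)
  }
  estimates <- do.call(rbind, rows)
  summ <- list()
  if (fit_rw_model) {
    a_hat <- as.matrix(estimates[grep("^alpha", names(estimates))])
    summ$alpha_bias <- colMeans(a_hat) - truth$alpha
    summ$beta_bias <- mean(estimates$beta_rw) - truth$beta_rw
  }
  if (!is.null(value_table)) {
    tgt <- c(b1 = unname(truth$rt_fix_coefs[2]),
             c1 = unname(truth$rt_choice_coefs[2]),
             c2 = unname(truth$rt_choice_coefs[3]),
             a1 = unname(truth$abort_coefs[2]))
    for (nm in names(tgt)) {
      if (!nm %in% names(estimates)) next
      summ[[paste0(nm, "_bias")]] <- mean(estimates[[nm]], na.rm = TRUE) -
        tgt[[nm]]
      summ[[paste0(nm, "_sign_matches")]] <-
        sum(sign(estimates[[nm]]) == sign(tgt[[nm]]), na.rm = TRUE)
    }
  }
  list(estimates = estimates, summary = summ)
}
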