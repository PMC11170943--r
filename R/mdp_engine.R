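#' Enumerate the MDP state space
#'
#' Builds the tabular state grid over token count (NTk), trials since
#' cash-out (TSCO), task epoch (TE) and cue-pair observations (NObs).
#' For the default task this is 13 x 6 x 10 x 18 = 14,040 states.  With
#' `prune_infeasible = TRUE`, states violating the token feasibility
#' bound `NTk <= max_gain * TSCO` (8 tokens at TSCO 4, for instance)
#' are dropped.
#'
#' @param config a [task_config()].
#' @param prune_infeasible drop unreachable token counts.
#' @return A data frame with columns `ntk`, `tsco`, `te`, `nobs`.
#' @export
enumerate_states <- function(config = task_config(),
                             prune_infeasible = FALSE) {
  grid <- expand.grid(ntk = 0:config$max_tokens,
                      tsco = seq_len(max(config$cashout_support)),
                      te = seq_len(config$n_conditions + 4L),
                      nobs = seq_len(config$nobs_max),
                      KEEP.OUT.ATTRS = FALSE)
  if (prune_infeasible) {
    gain <- max(config$cue_deltas)
    grid <- grid[grid$ntk <= gain * grid$tsco, , drop = FALSE]
    rownames(grid) <- NULL
  }
  grid
}

#' Bayesian posterior over token outcomes for a chosen cue
#'
#' Infers the learner's belief about which token outcome follows the
#' choice of a cue, given how well separated the mean cue values are at
#' the current learning stage.  No-change outcomes occur with fixed
#' probability 0.25 (the 25\% non-delivery rate); the remaining 0.75 is
#' split over the four token outcomes in proportion to Gaussian
#' likelihoods `N(x; mu_j, sigma)`, where `x` is the chosen cue's scaled
#' mean value and `mu_j` the scaled mean of the cue that truly yields
#' outcome `j` (uniform priors cancel).
#'
#' @param curves a [cue_value_curves] object (collapsed curves).
#' @param k scale applied to the mean cue values before use.
#' @param nobs learning-stage index (1..nobs_max).
#' @param condition condition id (the cue pair shown).
#' @param choice chosen cue id; must belong to the condition's pair.
#' @param config a [task_config()].
#' @return Named probability vector over token changes, names are the
#'   signed deltas plus `"0"`; sums to 1.
#' @export
outcome_posterior <- function(curves, k, nobs, condition, choice,
                              config = task_config()) {
  pair <- config$conditions[[condition]]
  if (!(choice %in% pair)) stop("choice is not part of the condition's pair")
  mu <- k * curves$collapsed[, nobs]
  posterior_from_means(mu, choice, curves$sigma[nobs],
                       config$outcome_deliver_prob, config$cue_deltas)
}

#' Posterior over token outcomes from scaled means
#'
#' Lower-level form of [outcome_posterior()] taking the (already
#' scaled) mean cue values and dispersion directly; used for the
#' worked-example probabilities printed in the source analysis.
#'
#' @param mu scaled mean value of each cue, ordered as `deltas`.
#' @param choice index of the chosen cue.
#' @param sigma Gaussian likelihood standard deviation (> 0 unless all
#'   means are tied, in which case the posterior is uniform).
#' @param deliver_prob delivery probability (mass not assigned to the
#'   no-change outcome).
#' @param deltas signed token change of each cue.
#' @return Named probability vector over `c(deltas, 0)`.
#' @export
posterior_from_means <- function(mu, choice, sigma, deliver_prob = 0.75,
                                 deltas = c(2L, 1L, -1L, -2L)) {
  n <- length(mu)
  if (all(abs(mu - mu[choice]) < 1e-12)) {
    p <- rep(deliver_prob / n, n)
  } else {
    if (!is.finite(sigma) || sigma <= 0)
      stop("degenerate likelihood: sigma must be positive when cue means differ")
    x <- mu[choice]
    lik <- stats::dnorm(x, mean = mu, sd = sigma)
    p <- deliver_prob * lik / sum(lik)
  }
  stats::setNames(c(p, 1 - deliver_prob), c(deltas, 0L))
}

#' Calibrate the likelihood dispersion from a target posterior
#'
#' The posterior probability of the chosen (best-separated) cue's own
#' outcome decreases monotonically in `sigma`, from `deliver_prob` at
#' `sigma -> 0` to the uniform `deliver_prob / 4` as `sigma -> Inf`, so
#' a printed posterior value identifies `sigma` by 1-D root finding.
#'
#' @param mu scaled mean cue values.
#' @param choice chosen cue index.
#' @param target target posterior probability of the chosen cue's
#'   outcome.
#' @param deliver_prob delivery probability.
#' @param interval search interval for `sigma`.
#' @return The calibrated `sigma`.
#' @export
calibrate_sigma <- function(mu, choice, target, deliver_prob = 0.75,
                            interval = c(1e-3, 25)) {
  n <- length(mu)
  if (target <= deliver_prob / n || target >= deliver_prob)
    stop("target must lie strictly between deliver_prob/", n,
         " and deliver_prob")
  f <- function(s)
    posterior_from_means(mu, choice, s, deliver_prob)[choice] - target
  stats::uniroot(f, interval, tol = 1e-10)$root
}

#' Assemble the full task transition model
#'
#' Combines the task-given transitions (fixation to each cue condition
#' with probability 1/6, the outcome-to-cash-out hazard from the uniform
#' 4--6-trial interval, cash-out resetting tokens) with the learned
#' cue-to-outcome posteriors derived from the mean cue-value curves
#' scaled by `k`.  The learning-progress feature NObs advances by one
#' with probability `nobs_max / block_length` per completed trial (the
#' balanced schedule shows each cue pair once per six trials); by
#' default the final NObs level is absorbing, modelling a single block
#' of trials.  With `nobs_wrap = TRUE` the final level instead re-enters
#' NObs 1, emulating the reset at a block boundary.
#'
#' @param curves a [cue_value_curves] object.
#' @param k value-scale parameter applied to the mean cue values.
#' @param config a [task_config()].
#' @param nobs_wrap logical; see Details.
#' @param naive_first use the naive uniform outcome posterior at
#'   NObs = 1: on the first presentation of a novel cue pair the animal
#'   has no experience to condition on, so every token outcome is
#'   equally likely and the two action values are identical.
#' @return An object of class `transition_model`.
#' @export
build_transition_model <- function(curves, k = 1, config = task_config(),
                                   nobs_wrap = FALSE, naive_first = TRUE) {
  C <- config$n_conditions
  O <- config$nobs_max
  n_cues <- length(config$cue_deltas)
  outcome <- array(NA_real_, dim = c(C, 2L, O, n_cues + 1L))
  naive <- posterior_from_means(numeric(n_cues), 1L, 1,
                                config$outcome_deliver_prob,
                                config$cue_deltas)
  for (cc in seq_len(C)) {
    pair <- config$conditions[[cc]]
    for (a in 1:2) {
      for (o in seq_len(O)) {
        outcome[cc, a, o, ] <-
          if (o == 1L && naive_first) naive
          else outcome_posterior(curves, k, o, cc, pair[a], config)
      }
    }
  }
  structure(list(
    p_cues = 1 / C,
    hazards = hazard_from_support(config$cashout_support),
    outcome = outcome,
    deltas = c(config$cue_deltas, 0L),
    p_nobs_inc = config$nobs_max / config$block_length,
    nobs_wrap = nobs_wrap,
    k = k,
    sigma = curves$sigma,
    config = config
  ), class = "transition_model")
}

#' Solve an MDP by value iteration
#'
#' Synchronous Bellman backups `u(s) = max_a [r(s,a) + gamma * sum_j
#' p(j|s,a) u(j)]`, stopping at the earlier of `sweeps` sweeps or a
#' stable greedy policy with maximum value change below `tol`.  Two
#' forms of `transitions` are accepted: a [build_transition_model()]
#' object (solved with the structured task backup; reward is the token
#' count at cash-out, in juice drops) or a plain list of per-action
#' `S x S` transition matrices with a `reward` vector/matrix (generic
#' dense solver, used for small reference problems).
#'
#' @param transitions a `transition_model` or list of transition
#'   matrices.
#' @param gamma discount factor in (0, 1].
#' @param reward for the generic solver: reward vector (length S) or
#'   `S x n_actions` matrix.  For the task solver: a function of the
#'   token count giving the immediate cash-out reward (default
#'   identity, one juice drop per token).
#' @param sweeps maximum number of sweeps (the default 100 matches the
#'   iteration budget under which the task model's utilities are
#'   reported; absolute utilities scale with this cap).
#' @param tol convergence tolerance on the value change.
#' @return For the task solver, an object of class `mdp_value_table`;
#'   for the generic solver, a list with `u` and `policy`.
#' @export
value_iteration <- function(transitions, gamma, reward = NULL,
                            sweeps = 100L, tol = 1e-6) {
  if (!(gamma >= 0 && gamma <= 1)) stop("gamma must be in [0, 1]")
  if (sweeps < 1L) stop("sweeps must be >= 1")
  if (inherits(transitions, "transition_model")) {
    solve_task_mdp(transitions, gamma, reward = reward, sweeps = sweeps,
                   tol = tol)
  } else {
    value_iteration_dense(transitions, gamma, reward, sweeps, tol)
  }
}

# Generic dense value iteration over a list of per-action S x S
# transition matrices.
value_iteration_dense <- function(P_list, gamma, reward, sweeps, tol) {
  if (is.null(reward)) stop("the generic solver requires a reward")
  S <- nrow(P_list[[1]])
  nA <- length(P_list)
  for (P in P_list) {
    if (any(abs(rowSums(P) - 1) > 1e-10))
      stop("non-stochastic transition row")
  }
  R <- if (is.matrix(reward)) reward else matrix(reward, S, nA)
  u <- numeric(S)
  pol <- rep(1L, S)
  for (s in seq_len(sweeps)) {
    Q <- vapply(seq_len(nA), function(a) R[, a] + gamma * P_list[[a]] %*% u,
                numeric(S))
    Q <- matrix(Q, S, nA)
    u_new <- apply(Q, 1, max)
    pol_new <- max.col(Q, ties.method = "first")
    done <- max(abs(u_new - u)) < tol && all(pol_new == pol)
    u <- u_new
    pol <- pol_new
    if (done) break
  }
  list(u = u, policy = pol, sweeps_run = s)
}

# Structured value iteration for the tokens-task transition model.
# Epoch value arrays are [NTk+1, TSCO, NObs] (cue epochs add a condition
# dimension); TE indexing in the output follows epoch_ids().
solve_task_mdp <- function(model, gamma, reward = NULL, sweeps = 100L,
                           tol = 1e-6) {
  cfg <- model$config
  if (is.null(reward)) reward <- identity
  N <- cfg$max_tokens + 1L
  T_ <- max(cfg$cashout_support)
  O <- cfg$nobs_max
  C <- cfg$n_conditions
  nD <- length(model$deltas)
  h <- model$hazards
  if (any(abs(apply(model$outcome, 1:3, sum) - 1) > 1e-10))
    stop("non-stochastic outcome transition row")
  p_inc <- model$p_nobs_inc
  o_next <- if (model$nobs_wrap) c(seq_len(O)[-1L], 1L)
            else c(seq_len(O)[-1L], O)
  idx_shift <- lapply(model$deltas, function(d)
    pmin(pmax(seq_len(N) + d, 1L), N))
  idx_t1 <- pmin(seq_len(T_) + 1L, T_)
  dimv <- c(N, T_, O)
  r_cash <- array(reward(0:(N - 1L)), dimv)
  H <- array(rep(rep(h, each = N), times = O), dimv)
  # broadcast outcome probabilities over (NTk, TSCO) once
  PB <- vector("list", C)
  for (cc in seq_len(C)) {
    PB[[cc]] <- lapply(1:2, function(a)
      lapply(seq_len(nD), function(d)
        array(rep(model$outcome[cc, a, , d], each = N * T_), dimv)))
  }
  zero <- array(0, dimv)
  u_fix <- u_out <- u_cash <- u_iti <- zero
  u_cue <- array(0, c(N, T_, C, O))
  Q <- array(0, c(N, T_, C, O, 2L))
  pol <- array(1L, c(N, T_, C, O))
  for (s in seq_len(sweeps)) {
    # cash-out: immediate juice then ITI with zero tokens, TSCO reset
    cash_new <- r_cash +
      gamma * array(rep(u_iti[1L, 1L, ], each = N * T_), dimv)
    # ITI: next fixation; NObs advances with prob p_inc
    iti_new <- gamma * ((1 - p_inc) * u_fix + p_inc * u_fix[, , o_next])
    # token outcome: cash-out hazard vs straight to ITI of next trial
    out_new <- gamma * (H * u_cash + (1 - H) * u_iti[, idx_t1, ])
    # cue states: two actions, each mixing over the 5 token outcomes
    shifted <- lapply(idx_shift, function(ix) u_out[ix, , ])
    cue_new <- u_cue
    Q_new <- Q
    for (cc in seq_len(C)) {
      for (a in 1:2) {
        acc <- zero
        for (d in seq_len(nD)) acc <- acc + PB[[cc]][[a]][[d]] * shifted[[d]]
        Q_new[, , cc, , a] <- gamma * acc
      }
      cue_new[, , cc, ] <- pmax(Q_new[, , cc, , 1L], Q_new[, , cc, , 2L])
    }
    # fixation: uniform mix over the cue conditions
    acc <- array(0, dimv)
    for (cc in seq_len(C)) acc <- acc + u_cue[, , cc, ]
    fix_new <- (gamma / C) * acc
    pol_new <- (Q_new[, , , , 2L] > Q_new[, , , , 1L]) + 1L
    diffmax <- max(abs(fix_new - u_fix), abs(cue_new - u_cue),
                   abs(out_new - u_out), abs(cash_new - u_cash),
                   abs(iti_new - u_iti))
    stable <- all(pol_new == pol)
    u_fix <- fix_new; u_cue <- cue_new; u_out <- out_new
    u_cash <- cash_new; u_iti <- iti_new; Q <- Q_new; pol <- pol_new
    if (diffmax < tol && stable) break
  }
  TE <- C + 4L
  u <- array(NA_real_, c(N, T_, TE, O),
             dimnames = list(ntk = 0:(N - 1L), tsco = seq_len(T_),
                             te = seq_len(TE), nobs = seq_len(O)))
  u[, , 1L, ] <- u_fix
  for (cc in seq_len(C)) u[, , 1L + cc, ] <- u_cue[, , cc, ]
  u[, , C + 2L, ] <- u_out
  u[, , C + 3L, ] <- u_cash
  u[, , C + 4L, ] <- u_iti
  structure(list(u = u, q = Q, policy = pol, gamma = gamma,
                 sweeps_run = s, last_delta = diffmax,
                 converged = diffmax < tol, config = cfg, model = model),
            class = "mdp_value_table")
}

#' @export
print.mdp_value_table <- function(x, ...) {
  cat("MDP value table:", paste(dim(x$u), collapse = " x "),
      "(NTk x TSCO x TE x NObs), gamma =", x$gamma, "\n")
  cat("sweeps run:", x$sweeps_run, "; last max value change:",
      signif(x$last_delta, 3), "\n")
  cat("value range:", paste(signif(range(x$u), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' Look up state values
#'
#' Vectorized lookup of `u(NTk, TSCO, TE, NObs)` from a value table.
#'
#' @param vt an `mdp_value_table`.
#' @param ntk,tsco,te,nobs state feature vectors (recycled).
#' @return Numeric vector of state values.
#' @export
value_lookup <- function(vt, ntk, tsco, te, nobs) {
  n <- max(length(ntk), length(tsco), length(te), length(nobs))
  idx <- cbind(rep_len(ntk + 1L, n), rep_len(tsco, n),
               rep_len(te, n), rep_len(nobs, n))
  vt$u[idx]
}

#' Softmax choice probability from MDP action values
#'
#' @param q numeric pair of action values.
#' @param beta_mdp inverse temperature (>= 0).
#' @return Probability pair summing to 1.
#' @export
mdp_choice_prob <- function(q, beta_mdp) {
  if (beta_mdp < 0) stop("beta_mdp must be non-negative")
  z <- beta_mdp * (q - max(q))
  exp(z) / sum(exp(z))
}

#' Model choice-probability curves over learning
#'
#' Probability that the model chooses the objectively better cue of each
#' condition at each learning stage, obtained by averaging the two
#' action values over the feasible (NTk, TSCO) states and passing them
#' through a softmax with inverse temperature `beta_mdp`.
#'
#' @param vt an `mdp_value_table`.
#' @param beta_mdp softmax inverse temperature.
#' @return `n_conditions x nobs_max` matrix of choice probabilities.
#' @export
model_choice_curves <- function(vt, beta_mdp) {
  cfg <- vt$config
  C <- cfg$n_conditions
  O <- cfg$nobs_max
  N <- cfg$max_tokens + 1L
  T_ <- max(cfg$cashout_support)
  gain <- max(cfg$cue_deltas)
  feas <- outer(0:(N - 1L), seq_len(T_), function(n, t) n <= gain * t)
  out <- matrix(NA_real_, C, O)
  for (cc in seq_len(C)) {
    pair <- cfg$conditions[[cc]]
    better_slot <- which.max(cfg$cue_deltas[pair])
    for (o in seq_len(O)) {
      q1 <- mean(vt$q[, , cc, o, 1L][feas])
      q2 <- mean(vt$q[, , cc, o, 2L][feas])
      out[cc, o] <- mdp_choice_prob(c(q1, q2), beta_mdp)[better_slot]
    }
  }
  out
}

#' Successor distribution of a single state
#'
#' Explicit enumeration of the successor states, probabilities and
#' immediate reward for one state (and action, at cue epochs), suitable
#' for independent dynamic-programming or Monte-Carlo checks of the
#' structured solver.
#'
#' @param model a `transition_model`.
#' @param ntk,tsco,te,nobs the state.
#' @param action chosen slot (1 or 2) at cue epochs; ignored elsewhere.
#' @return List with `reward` (immediate, collected in this state) and
#'   `next` (data frame of successor states with probabilities).
#' @export
transition_dist <- function(model, ntk, tsco, te, nobs, action = 1L) {
  cfg <- model$config
  C <- cfg$n_conditions
  O <- cfg$nobs_max
  T_ <- max(cfg$cashout_support)
  ids <- epoch_ids(cfg)
  succ <- function(ntk, tsco, te, nobs, prob)
    data.frame(ntk = ntk, tsco = tsco, te = te, nobs = nobs, prob = prob)
  reward <- 0
  if (te == ids[["fixation"]]) {
    nxt <- succ(ntk, tsco, 1L + seq_len(C), nobs, rep(1 / C, C))
  } else if (te >= 2L && te <= C + 1L) {
    cc <- te - 1L
    p <- model$outcome[cc, action, nobs, ]
    ntk_next <- pmin(pmax(ntk + model$deltas, 0L), cfg$max_tokens)
    nxt <- succ(ntk_next, tsco, ids[["outcome"]], nobs, p)
  } else if (te == ids[["outcome"]]) {
    hz <- model$hazards[tsco]
    nxt <- rbind(
      if (hz > 0) succ(ntk, tsco, ids[["cashout"]], nobs, hz),
      if (hz < 1) succ(ntk, min(tsco + 1L, T_), ids[["iti"]], nobs, 1 - hz))
  } else if (te == ids[["cashout"]]) {
    reward <- ntk
    nxt <- succ(0L, 1L, ids[["iti"]], nobs, 1)
  } else if (te == ids[["iti"]]) {
    o2 <- if (model$nobs_wrap) (nobs %% O) + 1L else min(nobs + 1L, O)
    p <- model$p_nobs_inc
    nxt <- rbind(succ(ntk, tsco, 1L, nobs, 1 - p),
                 succ(ntk, tsco, 1L, o2, p))
    nxt <- stats::aggregate(prob ~ ntk + tsco + te + nobs, nxt, sum)
  } else stop("unknown epoch")
  # merge duplicate successors (token clamp can collide)
  nxt <- stats::aggregate(prob ~ ntk + tsco + te + nobs, nxt, sum)
  list(reward = reward, next_states = nxt)
}
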