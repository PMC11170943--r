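# Shared fixtures, memoized so expensive objects are built once per run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

default_cfg <- function() fixture("cfg", task_config())

# Full-size value table built from idealized (exactly monotone) curves.
default_vt <- function() fixture("vt", {
  value_iteration(build_transition_model(idealized_curves(default_cfg()),
                                         1, default_cfg()),
                  0.999, sweeps = 100)
})

# Miniature task: 4 tokens max, cash-out over {2,3}, 2 conditions.
mini_cfg <- function() fixture("mini_cfg", {
  task_config(block_length = 8L, n_conditions = 2L,
              presentations_per_condition = 4L, cashout_support = 2:3,
              nobs_max = 4L, max_tokens = 4L)
})

mini_model <- function() fixture("mini_model", {
  build_transition_model(idealized_curves(mini_cfg(), tau = 1.5),
                         k = 1, mini_cfg())
})

# A choice-only simulated session set with smooth ground-truth curves.
choice_truth <- function(seed = 3L)
  behavior_truth(rt_fix_coefs = c(-0.4, 0), rt_choice_coefs = c(-1.1, 0, 0),
                 abort_coefs = c(-Inf, 0), seed = seed)

choice_sessions <- function() fixture("choice_sessions", {
  lapply(1:6, function(i) {
    tr <- choice_truth(100L + i)
    simulate_session(default_cfg(), tr, NULL, 9L, session_id = i)
  })
})

fitted_curves <- function() fixture("fitted_curves", {
  cfg <- default_cfg()
  tr <- choice_truth()
  traj <- unlist(lapply(choice_sessions(), rw_value_trajectories,
                        alpha = tr$alpha, config = cfg),
                 recursive = FALSE)
  extract_mean_curves(traj, cfg)
})

# Dense explicit representation of a transition model, built through
# transition_dist() state by state -- the independent route used to
# cross-check the structured solver.
dense_mdp <- function(model) {
  cfg <- model$config
  states <- expand.grid(ntk = 0:cfg$max_tokens,
                        tsco = seq_len(max(cfg$cashout_support)),
                        te = seq_len(cfg$n_conditions + 4L),
                        nobs = seq_len(cfg$nobs_max),
                        KEEP.OUT.ATTRS = FALSE)
  key <- function(ntk, tsco, te, nobs)
    paste(ntk, tsco, te, nobs, sep = "_")
  idx <- stats::setNames(seq_len(nrow(states)),
                         key(states$ntk, states$tsco, states$te,
                             states$nobs))
  n_actions <- 2L
  trans <- vector("list", n_actions)
  for (a in seq_len(n_actions)) trans[[a]] <- vector("list", nrow(states))
  reward <- numeric(nrow(states))
  for (s in seq_len(nrow(states))) {
    for (a in seq_len(n_actions)) {
      td <- transition_dist(model, states$ntk[s], states$tsco[s],
                            states$te[s], states$nobs[s], action = a)
      reward[s] <- td$reward
      j <- idx[key(td$next_states$ntk, td$next_states$tsco,
                   td$next_states$te, td$next_states$nobs)]
      stopifnot(!anyNA(j))
      trans[[a]][[s]] <- list(j = unname(j), p = td$next_states$prob)
    }
  }
  list(states = states, trans = trans, reward = reward, idx = idx,
       key = key)
}

# Plain-loop finite-horizon backward induction on a dense MDP.
backward_induction <- function(dense, gamma, horizon) {
  S <- nrow(dense$states)
  u <- numeric(S)
  for (h in seq_len(horizon)) {
    u_new <- numeric(S)
    for (s in seq_len(S)) {
      q <- vapply(dense$trans, function(tr)
        dense$reward[s] + gamma * sum(tr[[s]]$p * u[tr[[s]]$j]),
        numeric(1))
      u_new[s] <- max(q)
    }
    u <- u_new
  }
  u
}

# Monte-Carlo discounted return from one state under a fixed policy.
mc_return <- function(dense, policy, start, gamma, n_episodes = 400L,
                      horizon = 150L) {
  returns <- vapply(seq_len(n_episodes), function(e) {
    s <- start
    g <- 0
    disc <- 1
    for (t in seq_len(horizon)) {
      g <- g + disc * dense$reward[s]
      tr <- dense$trans[[policy[s]]][[s]]
      s <- if (length(tr$j) == 1L) tr$j else sample(tr$j, 1L, prob = tr$p)
      disc <- disc * gamma
    }
    g
  }, numeric(1))
  list(mean = mean(returns), se = stats::sd(returns) / sqrt(n_episodes))
}

# Map a state table row of the structured solver to u for comparison.
vt_lookup_states <- function(vt, states)
  vt$u[cbind(states$ntk + 1L, states$tsco, states$te, states$nobs)]
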