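test_that("state enumeration matches the printed feature ranges", {
  cfg <- default_cfg()
  grid <- enumerate_states(cfg)
  expect_equal(nrow(grid), 13L * 6L * 10L * 18L)
  expect_equal(range(grid$ntk), c(0L, 12L))
  expect_equal(range(grid$tsco), c(1L, 6L))
  expect_equal(range(grid$te), c(1L, 10L))
  expect_equal(range(grid$nobs), c(1L, 18L))
  pruned <- enumerate_states(cfg, prune_infeasible = TRUE)
  expect_false(any(pruned$ntk == 8L & pruned$tsco == 1L))
  expect_true(all(pruned$ntk <= 2L * pruned$tsco))
  # maximum feasible token count at TSCO = 4 is 8
  expect_equal(max(pruned$ntk[pruned$tsco == 4L]), 8L)
})

test_that("outcome posterior reproduces worked examples and degeneracies", {
  # early learning: scaled means (0.17, 0.11, -0.01, -0.01), sigma 0.175
  p1 <- posterior_from_means(c(0.17, 0.11, -0.01, -0.01), 1, 0.175)
  expect_equal(unname(p1[1]), 0.2402822, tolerance = 1e-6)
  expect_equal(round(unname(p1[1]), 2), 0.24)
  # late learning: scaled means (0.66, 0.36, -0.03, -0.04), sigma 0.23
  p2 <- posterior_from_means(c(0.66, 0.36, -0.03, -0.04), 1, 0.23)
  expect_equal(unname(p2[1]), 0.5179620, tolerance = 1e-6)
  expect_equal(round(unname(p2[1]), 2), 0.52)
  # tied means: uniform posterior, no-change mass fixed
  pu <- posterior_from_means(rep(0.2, 4), 2, 0.3)
  expect_equal(unname(pu), c(rep(0.1875, 4), 0.25))
  # normalization and the exact 0.25 no-change mass, random cases
  set.seed(9)
  for (i in 1:20) {
    mu <- rnorm(4, 0, 0.5)
    p <- posterior_from_means(mu, sample(4, 1), runif(1, 0.05, 0.5))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(unname(p[5]), 0.25)
    expect_true(all(p[1:4] > 0 & p[1:4] < 0.75))
  }
  expect_error(posterior_from_means(c(0.3, 0.1, 0, 0), 1, 0),
               "degenerate")
})

test_that("sigma calibration inverts the posterior by root finding", {
  s1 <- calibrate_sigma(c(0.17, 0.11, -0.01, -0.01), 1, 0.24)
  expect_equal(s1, 0.175, tolerance = 0.01)
  p <- posterior_from_means(c(0.17, 0.11, -0.01, -0.01), 1, s1)
  expect_equal(unname(p[1]), 0.24, tolerance = 1e-7)
  s2 <- calibrate_sigma(c(0.66, 0.36, -0.03, -0.04), 1, 0.52)
  expect_equal(s2, 0.23, tolerance = 0.01)
  expect_error(calibrate_sigma(c(0.2, 0.1, 0, 0), 1, 0.1), "target")
})

test_that("transition model rows are stochastic with task-given pieces", {
  cfg <- default_cfg()
  model <- build_transition_model(fitted_curves(), k = 0.8, cfg)
  sums <- apply(model$outcome, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(model$p_cues, 1 / 6)
  expect_equal(model$outcome[, , , 5], array(0.25, dim = c(6, 2, 18)))
  # naive first presentation: uniform over the four token outcomes
  expect_equal(model$outcome[3, 1, 1, 1:4], rep(0.1875, 4))
  # hazard branch via explicit successor enumeration
  td <- transition_dist(model, ntk = 5L, tsco = 4L, te = 8L, nobs = 9L)
  p_cash <- td$next_states$prob[td$next_states$te == 9L]
  expect_equal(p_cash, 1 / 3)
  # fixation fans out to the six cue states at 1/6 each
  tf <- transition_dist(model, 2L, 2L, 1L, 5L)
  expect_equal(tf$next_states$prob, rep(1 / 6, 6))
  expect_equal(sort(tf$next_states$te), 2:7)
})

test_that("generic value iteration solves closed-form problems exactly", {
  # 2-state deterministic cycle A -> B -> A, r = (1, 0), gamma = 0.5
  P <- list(matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  sol <- value_iteration(P, gamma = 0.5, reward = c(1, 0), sweeps = 2000L,
                         tol = 1e-14)
  expect_equal(sol$u, c(4 / 3, 2 / 3), tolerance = 1e-12)
  # zero reward: utilities vanish
  sol0 <- value_iteration(P, 0.9, reward = c(0, 0), sweeps = 50L)
  expect_equal(sol0$u, c(0, 0))
  expect_error(value_iteration(list(matrix(c(0.5, 0.4, 1, 0), 2,
                                           byrow = TRUE)),
                               0.9, reward = c(1, 0)),
               "non-stochastic")
})

test_that("task solver degenerates correctly at gamma = 0 and zero reward", {
  vt <- value_iteration(mini_model(), gamma = 0, sweeps = 5L)
  ids <- epoch_ids(mini_cfg())
  # cash-out states carry their immediate juice; everything else is 0
  expect_equal(vt$u[4, 2, ids[["cashout"]], 2], 3)
  expect_equal(vt$u[1, 1, ids[["cashout"]], 1], 0)
  expect_true(all(vt$u[, , setdiff(seq_len(dim(vt$u)[3]), ids[["cashout"]]), ]
                  == 0))
  vtz <- value_iteration(mini_model(), gamma = 0.9, sweeps = 60L,
                         reward = function(n) 0 * n)
  expect_true(all(vtz$u == 0))
})

test_that("structured solver agrees with independent finite-horizon
           enumeration on the miniature task", {
  model <- mini_model()
  dense <- dense_mdp(model)
  u_oracle <- backward_induction(dense, gamma = 0.9, horizon = 30L)
  vt <- value_iteration(model, gamma = 0.9, sweeps = 30L, tol = 0)
  u_pkg <- vt_lookup_states(vt, dense$states)
  expect_lt(max(abs(u_pkg - u_oracle)), 1e-3)
})

test_that("structured solver matches Monte-Carlo returns under the
           greedy policy on the miniature task", {
  model <- mini_model()
  dense <- dense_mdp(model)
  gamma <- 0.9
  vt <- value_iteration(model, gamma, sweeps = 400L, tol = 1e-10)
  u_pkg <- vt_lookup_states(vt, dense$states)
  # greedy policy from the dense representation itself
  pol <- vapply(seq_len(nrow(dense$states)), function(s) {
    q <- vapply(dense$trans, function(tr)
      dense$reward[s] + gamma * sum(tr[[s]]$p * u_pkg[tr[[s]]$j]),
      numeric(1))
    which.max(q)
  }, integer(1))
  ids <- epoch_ids(mini_cfg())
  starts <- which(
    (dense$states$te == ids[["fixation"]] & dense$states$ntk == 2 &
       dense$states$tsco == 2 & dense$states$nobs == 2) |
    (dense$states$te == 3L & dense$states$ntk == 0 &
       dense$states$tsco == 1 & dense$states$nobs == 1))
  set.seed(21)
  for (s in starts) {
    mc <- mc_return(dense, pol, s, gamma, n_episodes = 500L, horizon = 120L)
    trunc_bound <- gamma^120 * max(dense$reward) / (1 - gamma)
    expect_lt(abs(mc$mean - u_pkg[s]), 3.5 * mc$se + trunc_bound + 1e-6)
  }
})

test_that("choice probabilities from action values behave as a softmax", {
  expect_equal(mdp_choice_prob(c(2.2, 2.2), 5), c(0.5, 0.5))
  expect_equal(mdp_choice_prob(c(9, 1), 0), c(0.5, 0.5))
  p <- mdp_choice_prob(c(1, 0), 1)
  expect_equal(p[1], 1 / (1 + exp(-1)))
  expect_error(mdp_choice_prob(c(1, 0), -2), "non-negative")
  # at NObs = 1 the two action values are identical in every condition
  vt <- default_vt()
  expect_equal(max(abs(vt$q[, , , 1, 1] - vt$q[, , , 1, 2])), 0)
  # after learning, the better cue is preferred in the five
  # gain-containing conditions
  cc <- model_choice_curves(vt, beta_mdp = 2)
  expect_true(all(cc[1:5, 18] > 0.5))
  expect_true(all(cc[, 1] == 0.5))
})

test_that("downstream regressions are invariant to affine value rescaling", {
  cfg <- default_cfg()
  vt <- default_vt()
  tr <- behavior_truth(seed = 14L)
  ses <- simulate_session(cfg, tr, vt, 3L)
  vt2 <- vt
  a <- 2.5; b <- -7
  vt2$u <- a * vt$u + b
  f1 <- fit_fixation_rt(ses, vt, cfg)
  f2 <- fit_fixation_rt(ses, vt2, cfg)
  expect_equal(unname(f2$coefficients[2]), unname(f1$coefficients[2]) / a,
               tolerance = 1e-10)
  g1 <- fit_abort_logistic(ses, vt, cfg)
  g2 <- fit_abort_logistic(ses, vt2, cfg)
  expect_equal(unname(g2$coefficients[2]), unname(g1$coefficients[2]) / a,
               tolerance = 1e-6)
})
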