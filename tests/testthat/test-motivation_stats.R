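test_that("Tukey fences remove outliers two-sidedly", {
  expect_equal(tukey_filter(c(0.2, 0.21, 0.22, 0.23)),
               c(0.2, 0.21, 0.22, 0.23))
  expect_equal(tukey_filter(c(0.2, 0.21, 0.22, 0.23, 5.0)),
               c(0.2, 0.21, 0.22, 0.23))
  # symmetric outliers are removed from both tails
  x <- c(-9, seq(0.1, 1, by = 0.1), 9)
  expect_equal(tukey_filter(x), seq(0.1, 1, by = 0.1))
  expect_warning(out <- tukey_filter(c(1, 2, 100)), "fewer than 4")
  expect_equal(out, c(1, 2, 100))
})

test_that("fixation-RT regression recovers the generative coupling sign", {
  cfg <- default_cfg()
  vt <- default_vt()
  tr <- behavior_truth(seed = 20L)
  signs <- vapply(1:6, function(i) {
    t2 <- tr
    t2$seed <- 900L + i
    ses <- simulate_session(cfg, t2, vt, 4L)
    unname(fit_fixation_rt(ses, vt, cfg)$coefficients[2])
  }, numeric(1))
  expect_gte(sum(signs < 0), 5L)
  # constant V_fix is a singular design
  vt_const <- vt
  vt_const$u[] <- 3
  ses <- simulate_session(cfg, tr, vt, 2L)
  expect_error(fit_fixation_rt(ses, vt_const, cfg), "singular")
})

test_that("choice-RT regression needs variation in the value change", {
  cfg <- default_cfg()
  vt <- default_vt()
  ses <- simulate_session(cfg, behavior_truth(seed = 21L), vt, 3L)
  res <- fit_choice_rt(ses, vt, cfg)
  expect_named(res$coefficients, c("(Intercept)", "v_cue", "dv"))
  # marginalizing the epoch feature forces V_cue == V_fix, so dV == 0
  vt_te <- marginalize_values(vt, "TE")
  expect_error(fit_choice_rt(ses, vt_te, cfg), "inestimable|constant")
})

test_that("abort regression flags separation and degenerate sessions", {
  cfg <- default_cfg()
  vt <- default_vt()
  tr0 <- behavior_truth(abort_coefs = c(-Inf, 0), seed = 22L)
  ses0 <- simulate_session(cfg, tr0, vt, 2L)
  expect_error(fit_abort_logistic(ses0, vt, cfg), "separation")
  # hand-built separation: aborts exactly when the cue value is high
  ses <- simulate_session(cfg, behavior_truth(seed = 23L), vt, 2L)
  df <- ses[ses$abort_code == "none", ]
  nobs <- nobs_of_trial(df$trial, cfg)
  vcue <- value_lookup(vt, df$tokens_before, df$tsco, 1L + df$condition,
                       nobs)
  df$abort_code <- ifelse(vcue > stats::median(vcue), "choice_abort",
                          "none")
  res <- fit_abort_logistic(df, vt, cfg)
  expect_true("separation_ridge_fallback" %in% res$flags)
  expect_true(all(is.finite(res$coefficients)))
  expect_gt(unname(res$coefficients["v_cue"]), 0)
})

test_that("marginalization averages over feasible feature levels only", {
  cfg <- default_cfg()
  vt <- default_vt()
  mg <- marginalize_values(vt, "NTk")
  # at TSCO = 4 the feasible token counts are 0..8
  expect_equal(mg$u[1, 4, 1, 12], mean(vt$u[1:9, 4, 1, 12]))
  expect_equal(mg$u[5, 4, 1, 12], mg$u[1, 4, 1, 12])
  # at TSCO = 6 all 13 token counts are feasible
  expect_equal(mg$u[1, 6, 3, 7], mean(vt$u[, 6, 3, 7]))
  # TSCO marginal at NTk = 8 averages TSCO 4..6
  mg_t <- marginalize_values(vt, "TSCO")
  expect_equal(mg_t$u[9, 1, 1, 10], mean(vt$u[9, 4:6, 1, 10]))
  # a table constant in the feature is unchanged by marginalization
  vt_c <- vt
  vt_c$u <- array(rep(vt$u[, , , 1], times = dim(vt$u)[4]), dim = dim(vt$u))
  mg_n <- marginalize_values(vt_c, "NObs")
  expect_equal(mg_n$u, vt_c$u)
  # toy: u(NTk = 0,1,2) = (1,2,3) at TSCO = 1 (feasible set 0..2)
  # marginalizes to their mean, 2
  toy <- vt
  toy$u[] <- 0
  toy$u[1:3, 1, 2, 1] <- c(1, 2, 3)
  expect_equal(marginalize_values(toy, "NTk")$u[1, 1, 2, 1], 2)
  expect_error(marginalize_values(vt, "juice"), "unknown feature")
})

test_that("marginalizing the coupled feature attenuates the fitted slope", {
  cfg <- default_cfg()
  vt <- default_vt()
  tr <- behavior_truth(rt_noise_sd = 0.1, seed = 24L)
  ses <- simulate_session(cfg, tr, vt, 6L)
  full <- abs(fit_fixation_rt(ses, vt, cfg)$coefficients[2])
  marg <- abs(fit_fixation_rt(ses, marginalize_values(vt, "NTk"),
                              cfg)$coefficients[2])
  expect_lt(unname(marg), unname(full))
})

test_that("feature-level regressions expose the generative structure", {
  cfg <- default_cfg()
  # a value table that IS the token count: behaviour couples only to NTk
  vt_ntk <- default_vt()
  vt_ntk$u[] <- as.numeric(slice.index(vt_ntk$u, 1) - 1L)
  tr <- behavior_truth(rt_fix_coefs = c(-0.4, -0.08),
                       rt_choice_coefs = c(-1.1, -0.05, 0),
                       abort_coefs = c(-2.2, -0.1),
                       rt_noise_sd = 0.15, seed = 25L)
  ses <- simulate_session(cfg, tr, vt_ntk, 6L)
  res <- multivariate_feature_regressions(ses, vt_ntk, rw_alpha = tr$alpha,
                                          config = cfg)
  fx <- res$fix_rt_features
  z <- fx$coefficients / fx$se
  expect_lt(z[["tokens_before"]], -4)
  expect_lt(abs(z[["tsco"]]), 3)
  expect_lt(abs(z[["nobs"]]), 3)
  # reference-level contract for the condition factor
  ch <- res$choice_rt_features
  cond_coefs <- grep("^condition_f", names(ch$coefficients), value = TRUE)
  expect_length(cond_coefs, 5L)
  expect_false("condition_f1" %in% names(ch$coefficients))
  # RW chosen-value regression exists and carries a slope
  expect_s3_class(res$choice_rt_rw_value, "regression_result")
  expect_true("rw_chosen" %in% names(res$choice_rt_rw_value$coefficients))
  expect_s3_class(res$abort_fix_features, "regression_result")
  expect_s3_class(res$abort_choice_features, "regression_result")
})

test_that("RW chosen-value RT regression recovers a negative slope from
           value-coupled reaction times", {
  cfg <- default_cfg()
  vt <- default_vt()
  tr <- behavior_truth(rt_noise_sd = 0, abort_coefs = c(-Inf, 0),
                       seed = 26L)
  ses <- simulate_session(cfg, tr, vt, 6L)
  res <- suppressWarnings(
    multivariate_feature_regressions(ses, vt, rw_alpha = tr$alpha,
                                     config = cfg))
  expect_lt(unname(res$choice_rt_rw_value$coefficients["rw_chosen"]), 0)
})

test_that("group statistics use exact small-sample signed-rank inference", {
  set.seed(31)
  mk <- function(animal, mu) data.frame(animal = animal, session = 1:6,
                                        value = mu + rnorm(6, 0, 0.01))
  coefs <- do.call(rbind, Map(mk, 1:5, c(-0.05, -0.04, -0.03, -0.06, -0.02)))
  g <- group_tests(coefs, direction = "less")
  expect_equal(g$group_p, 1 / 32)
  expect_equal(g$per_animal$dof, rep(5, 5))
  expect_true(all(g$per_animal$t < 0))
  # second-smallest attainable p for n = 5: 2/32
  coefs2 <- do.call(rbind, Map(mk, 1:5, c(-3, -2, -4, -5, 0.5)))
  g2 <- group_tests(coefs2, direction = "less")
  expect_equal(g2$group_p, 2 / 32)
  # brute-force null enumeration over the 32 sign patterns
  mags <- c(0.9, 1.7, 2.2, 3.1, 4.5)
  stat <- function(x) sum(rank(abs(x))[x > 0])
  null_stats <- apply(expand.grid(rep(list(c(-1, 1)), 5)), 1,
                      function(s) stat(s * mags))
  obs <- stat(-mags)
  p_enum <- mean(null_stats <= obs)
  expect_equal(p_enum, 1 / 32)
  expect_equal(wilcox.test(-mags, alternative = "less",
                           exact = TRUE)$p.value, p_enum)
  # guards
  expect_error(group_tests(data.frame(animal = 1, session = 1, value = 0)),
               ">= 2 sessions")
  g1 <- group_tests(mk(1, -0.1), direction = "less")
  expect_true(is.na(g1$group_p))
  expect_match(g1$note, "single animal")
})

test_that("Fisher z comparison of correlations is calibrated", {
  expect_equal(compare_correlations(0.7, 0.7, 40)$p, 1)
  out <- compare_correlations(0.9, 0.5, 50)
  expect_equal(out$statistic, 4.473988, tolerance = 1e-6)
  expect_equal(out$p, 7.677390e-06, tolerance = 1e-6)
  # p decreases as the correlation gap widens
  ps <- vapply(seq(0.5, 0.9, by = 0.1),
               function(r) compare_correlations(r, 0.4, 30)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(compare_correlations(1, 0.5, 30), "infinite")
  expect_error(compare_correlations(0.2, 0.5, 3), "exceed 3")
})

test_that("Gaussian kernel smoothing interpolates with the stated weights", {
  expect_equal(kernel_smooth(1:10, rep(2.5, 10)), rep(2.5, 10))
  expect_equal(kernel_smooth(3, 1.7, x_out = c(-5, 0, 9)), rep(1.7, 3))
  # two points at (0, 0) and (1, 1) evaluated at x = 0 with bandwidth 0.5
  w <- exp(-1 / (2 * 0.25))
  expect_equal(kernel_smooth(c(0, 1), c(0, 1), bandwidth = 0.5, x_out = 0),
               w / (1 + w))
  expect_equal(kernel_smooth(c(0, 1), c(0, 1), bandwidth = 0.5, x_out = 0),
               0.119202922, tolerance = 1e-8)
  expect_error(kernel_smooth(numeric(0), numeric(0)), "empty")
})
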