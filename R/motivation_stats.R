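#' Tukey fence outlier removal
#'
#' Removes reaction times outside the Tukey fences
#' `[q0.25 - 1.5 IQR, q0.75 + 1.5 IQR]`.  Inputs with fewer than four
#' values pass through unchanged with a warning.
#'
#' @param rts numeric vector (NAs are dropped).
#' @return Filtered numeric vector.
#' @export
tukey_filter <- function(rts) {
  rts <- rts[!is.na(rts)]
  if (length(rts) < 4L) {
    warning("fewer than 4 values; returning input unfiltered")
    return(rts)
  }
  q <- stats::quantile(rts, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  rts[rts >= q[1] - 1.5 * iqr & rts <= q[2] + 1.5 * iqr]
}

# Attach per-attempt latent state values (V_fix, V_cue, dV) and NObs to
# a session table.
session_state_values <- function(session, values, config) {
  nobs <- nobs_of_trial(session$trial, config)
  v_fix <- value_lookup(values, session$tokens_before, session$tsco, 1L, nobs)
  v_cue <- value_lookup(values, session$tokens_before, session$tsco,
                        1L + session$condition, nobs)
  cbind(session, nobs = nobs, v_fix = v_fix, v_cue = v_cue,
        dv = v_cue - v_fix)
}

new_regression_result <- function(model, fit, n, flags = character()) {
  cf <- summary(fit)$coefficients
  structure(list(model = model,
                 coefficients = stats::setNames(cf[, 1], rownames(cf)),
                 se = stats::setNames(cf[, 2], rownames(cf)),
                 n = n,
                 residual_var = stats::var(stats::residuals(fit)),
                 flags = flags),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("Regression (", x$model, "), n =", x$n, "\n")
  print(round(rbind(coef = x$coefficients, se = x$se), 4))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fixation-RT regression on the fixation-state value
#'
#' Per-session ordinary least squares of log fixation-acquisition RT on
#' the fixation-state value `V_fix`, after Tukey outlier removal.  Only
#' completed attempts contribute.
#'
#' @param session session data frame.
#' @param values an `mdp_value_table`.
#' @param config a [task_config()].
#' @return A `regression_result` with coefficients `(Intercept, v_fix)`.
#' @export
fit_fixation_rt <- function(session, values, config = task_config()) {
  df <- session_state_values(session, values, config)
  df <- df[df$abort_code == "none" & !is.na(df$rt_fix), ]
  keep <- tukey_filter(df$rt_fix)
  df <- df[df$rt_fix %in% keep, ]
  if (stats::var(df$v_fix) == 0)
    stop("singular design: V_fix is constant within the session")
  fit <- stats::lm(log(rt_fix) ~ v_fix, data = df)
  new_regression_result("fix_rt", fit, nrow(df))
}

#' Choice-RT regression on cue-state value and value change
#'
#' Per-session OLS of log choice RT on the cue-state value `V_cue` and
#' the within-trial value change `dV = V_cue - V_fix`, after Tukey
#' outlier removal of the choice RTs.
#'
#' @inheritParams fit_fixation_rt
#' @return A `regression_result` with coefficients
#'   `(Intercept, v_cue, dv)`.
#' @export
fit_choice_rt <- function(session, values, config = task_config()) {
  df <- session_state_values(session, values, config)
  df <- df[df$abort_code == "none" & !is.na(df$rt_choice), ]
  keep <- tukey_filter(df$rt_choice)
  df <- df[df$rt_choice %in% keep, ]
  if (stats::var(df$dv) == 0)
    stop("degenerate design: dV is constant, its coefficient is inestimable")
  flags <- character()
  if (abs(stats::cor(df$v_cue, df$dv)) > 0.999) {
    warning("V_cue and dV nearly collinear")
    flags <- "collinear"
  }
  fit <- stats::lm(log(rt_choice) ~ v_cue + dv, data = df)
  new_regression_result("choice_rt", fit, nrow(df), flags)
}

# Ridge-penalized logistic regression by Newton iterations; fallback
# when maximum likelihood separates.
logistic_ridge <- function(X, y, lambda = 1e-6, iters = 50L) {
  beta <- numeric(ncol(X))
  for (i in seq_len(iters)) {
    p <- stats::plogis(drop(X %*% beta))
    W <- p * (1 - p)
    g <- crossprod(X, y - p) - lambda * beta
    Hm <- crossprod(X * W, X) + lambda * diag(ncol(X))
    step <- solve(Hm, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  se <- sqrt(diag(solve(Hm)))
  list(beta = drop(beta), se = se)
}

#' Abort-probability logistic regression on state values
#'
#' Maximum-likelihood logistic regression of the abort indicator on the
#' cue-state value and the value change, over all attempts (completed
#' and aborted).  On complete separation the fit falls back to a
#' lightly ridge-penalized logistic regression and flags the result.
#'
#' @inheritParams fit_fixation_rt
#' @return A `regression_result` with coefficients
#'   `(Intercept, v_cue, dv)`.
#' @export
fit_abort_logistic <- function(session, values, config = task_config()) {
  df <- session_state_values(session, values, config)
  df$abort <- as.integer(df$abort_code != "none")
  if (length(unique(df$abort)) < 2L)
    stop("separation: session has no aborts (or only aborts)")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(abort ~ v_cue + dv, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged) {
    X <- cbind(1, df$v_cue, df$dv)
    rid <- logistic_ridge(X, df$abort)
    res <- structure(list(
      model = "abort",
      coefficients = stats::setNames(rid$beta, c("(Intercept)", "v_cue", "dv")),
      se = stats::setNames(rid$se, c("(Intercept)", "v_cue", "dv")),
      n = nrow(df), residual_var = NA_real_,
      flags = "separation_ridge_fallback"), class = "regression_result")
    return(res)
  }
  out <- new_regression_result("abort", fit, nrow(df))
  out$residual_var <- stats::var(df$abort - stats::fitted(fit))
  out
}

#' Marginalize a value table over one state feature
#'
#' Replaces `u(NTk, TSCO, TE, NObs)` by its average over all feasible
#' levels of one feature at each combination of the others, removing
#' that feature's contribution from downstream regressions.  Token
#' feasibility (`NTk <= max_gain * TSCO`) restricts the averaging sets:
#' marginalizing tokens at TSCO 4 averages NTk 0..8; marginalizing TSCO
#' at NTk 8 averages TSCO 4..6.  Marginalizing TE averages across every
#' epoch, which makes cue- and fixation-state lookups identical (so the
#' value change `dV` collapses to zero by construction).
#'
#' @param values an `mdp_value_table`.
#' @param feature one of `"NTk"`, `"TSCO"`, `"NObs"`, `"TE"`.
#' @return An `mdp_value_table` whose `u` is constant along the
#'   marginalized feature.
#' @export
marginalize_values <- function(values, feature) {
  u <- values$u
  gain <- max(values$config$cue_deltas)
  N <- dim(u)[1]; T_ <- dim(u)[2]
  out <- u
  if (feature == "NTk") {
    for (t in seq_len(T_)) {
      nmax <- min(gain * t, N - 1L)
      m <- apply(u[seq_len(nmax + 1L), t, , , drop = FALSE], c(3, 4), mean)
      for (n in seq_len(N)) out[n, t, , ] <- m
    }
  } else if (feature == "TSCO") {
    for (n in seq_len(N)) {
      tmin <- max(1L, ceiling((n - 1L) / gain))
      m <- apply(u[n, tmin:T_, , , drop = FALSE], c(3, 4), mean)
      for (t in seq_len(T_)) out[n, t, , ] <- m
    }
  } else if (feature == "NObs") {
    m <- apply(u, c(1, 2, 3), mean)
    for (o in seq_len(dim(u)[4])) out[, , , o] <- m
  } else if (feature == "TE") {
    m <- apply(u, c(1, 2, 4), mean)
    for (te in seq_len(dim(u)[3])) out[, , te, ] <- m
  } else stop("unknown feature: ", feature)
  values$u <- out
  values
}

#' Multivariate regressions on the raw state features
#'
#' The five feature-level specifications complementing the state-value
#' regressions: (1) log fixation RT on NTk, TSCO and NObs; (2) log
#' choice RT on NTk, TSCO, NObs and cue condition (categorical,
#' condition 1 as reference); (3) log choice RT on the chosen cue's
#' Rescorla-Wagner value; (4) fixation-stage aborts (logistic) on NTk,
#' TSCO and NObs; (5) choice-stage aborts (logistic) on NTk, TSCO,
#' NObs and cue condition.  Fixation-stage aborts exclude the condition
#' because the cues are not yet visible when the abort occurs.
#'
#' @param session session data frame.
#' @param values an `mdp_value_table`.
#' @param rw_alpha per-cue learning rates used to replay chosen values
#'   (fitted from the session with [fit_rw()] when `NULL`).
#' @param config a [task_config()].
#' @return Named list of `regression_result` objects (an element is
#'   `NULL`, with a message, when its subset is degenerate).
#' @export
multivariate_feature_regressions <- function(session, values,
                                             rw_alpha = NULL,
                                             config = task_config()) {
  df <- session_state_values(session, values, config)
  df$condition_f <- factor(df$condition,
                           levels = seq_len(config$n_conditions))
  comp <- df[df$abort_code == "none", ]
  out <- list()
  safe <- function(expr) tryCatch(expr, error = function(e) {
    message("multivariate regression skipped: ", conditionMessage(e))
    NULL
  })
  out$fix_rt_features <- safe({
    d <- comp[!is.na(comp$rt_fix), ]
    d <- d[d$rt_fix %in% tukey_filter(d$rt_fix), ]
    new_regression_result("fix_rt_features",
                          stats::lm(log(rt_fix) ~ tokens_before + tsco + nobs,
                                    data = d), nrow(d))
  })
  out$choice_rt_features <- safe({
    d <- comp[!is.na(comp$rt_choice), ]
    d <- d[d$rt_choice %in% tukey_filter(d$rt_choice), ]
    new_regression_result("choice_rt_features",
                          stats::lm(log(rt_choice) ~ tokens_before + tsco +
                                      nobs + condition_f, data = d), nrow(d))
  })
  out$choice_rt_rw_value <- safe({
    if (is.null(rw_alpha)) rw_alpha <- fit_rw(session, config)$alpha
    traj <- completed_choice_data(session, config)
    vals <- rw_replay_cpp(rw_alpha, traj$block, traj$cue1, traj$cue2,
                          traj$chosen_slot, traj$reward)
    chosen_idx <- ifelse(traj$chosen_slot == 1L, traj$cue1, traj$cue2)
    d <- comp
    d$rw_chosen <- vals[cbind(seq_len(nrow(vals)), chosen_idx)]
    d <- d[!is.na(d$rt_choice), ]
    d <- d[d$rt_choice %in% tukey_filter(d$rt_choice), ]
    new_regression_result("rw_chosen_value",
                          stats::lm(log(rt_choice) ~ rw_chosen, data = d),
                          nrow(d))
  })
  out$abort_fix_features <- safe({
    d <- df
    d$y <- as.integer(d$abort_code == "fixation_abort")
    if (length(unique(d$y)) < 2L) stop("no fixation aborts")
    new_regression_result("abort_fix_features",
                          stats::glm(y ~ tokens_before + tsco + nobs,
                                     family = stats::binomial(), data = d),
                          nrow(d))
  })
  out$abort_choice_features <- safe({
    d <- df[df$abort_code != "fixation_abort", ]
    d$y <- as.integer(d$abort_code == "choice_abort")
    if (length(unique(d$y)) < 2L) stop("no choice aborts")
    new_regression_result("abort_choice_features",
                          stats::glm(y ~ tokens_before + tsco + nobs +
                                       condition_f,
                                     family = stats::binomial(), data = d),
                          nrow(d))
  })
  out
}

#' Per-animal and group-level tests on regression coefficients
#'
#' For each animal, a one-sample t test of the session-level
#' coefficients against zero (dof = sessions - 1); across animals, an
#' exact one-sided Wilcoxon signed-rank test on the per-animal mean
#' coefficients.  With five animals the signed-rank null has 32
#' equiprobable sign patterns, so the smallest attainable one-sided p
#' is 1/32 = 0.03125.
#'
#' @param coefs data frame with columns `animal`, `session`, `value`
#'   (one coefficient estimate per session).
#' @param direction alternative for the group test (`"less"` tests
#'   coefficients below zero).
#' @return An object of class `group_stats`: per-animal statistics and
#'   the exact group-level signed-rank p value (`NA`, with a note, for
#'   a single animal).
#' @export
group_tests <- function(coefs, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  counts <- table(coefs$animal)
  if (any(counts < 2L)) stop("need >= 2 sessions per animal")
  animals <- names(counts)
  per <- do.call(rbind, lapply(animals, function(a) {
    v <- coefs$value[coefs$animal == a]
    tt <- stats::t.test(v)
    data.frame(animal = a, mean = mean(v), t = unname(tt$statistic),
               dof = unname(tt$parameter), p = tt$p.value)
  }))
  if (length(animals) < 2L) {
    group_p <- NA_real_
    note <- "single animal: group test skipped"
  } else {
    group_p <- stats::wilcox.test(per$mean, alternative = direction,
                                  exact = TRUE)$p.value
    note <- NULL
  }
  structure(list(per_animal = per, group_p = group_p,
                 direction = direction, n_animals = length(animals),
                 note = note),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  print(transform(x$per_animal, t = round(t, 2), p = signif(p, 3)))
  cat("group signed-rank p (", x$direction, "):", signif(x$group_p, 4), "\n")
  if (!is.null(x$note)) cat(x$note, "\n")
  invisible(x)
}

#' Compare two correlation coefficients by Fisher z
#'
#' Two-sided test of `r1 = r2` for correlations estimated on `n` paired
#' observations each: `z = atanh(r)`, statistic
#' `(z1 - z2) / sqrt(2 / (n - 3))`, normal reference.
#'
#' @param r1,r2 correlation coefficients with `|r| < 1`.
#' @param n number of observations per correlation (> 3).
#' @return List with `statistic` and two-sided `p`.
#' @export
compare_correlations <- function(r1, r2, n) {
  if (any(abs(c(r1, r2)) >= 1)) stop("|r| must be < 1 (Fisher z is infinite)")
  if (n <= 3) stop("n must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(2 / (n - 3))
  list(statistic = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Gaussian-kernel smoothing of a behavioural trend
#'
#' Nadaraya-Watson estimate with a Gaussian kernel of standard
#' deviation `bandwidth` (in the units of `x`, i.e. state-value units
#' for the motivation trends).
#'
#' @param x,y observed points.
#' @param bandwidth Gaussian kernel sd.
#' @param x_out evaluation points (defaults to `x`).
#' @return Numeric vector of smoothed values at `x_out`.
#' @export
kernel_smooth <- function(x, y, bandwidth = 0.5, x_out = x) {
  if (!length(x)) stop("empty input")
  vapply(x_out, function(x0) {
    w <- stats::dnorm(x0, mean = x, sd = bandwidth)
    sum(w * y) / sum(w)
  }, numeric(1))
}
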