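#' Empirical choice-probability curves
#'
#' Fraction of completed trials on which the objectively better cue of
#' each condition was chosen, per condition per learning stage (NObs),
#' averaged across blocks within sessions and then across sessions.
#'
#' @param sessions a session data frame or list of session data frames.
#' @param config a [task_config()].
#' @return `n_conditions x nobs_max` matrix of choice fractions; cells
#'   with no trials are `NA` and reported via the `"n_missing"`
#'   attribute.
#' @export
empirical_choice_curves <- function(sessions, config = task_config()) {
  if (is.data.frame(sessions)) sessions <- list(sessions)
  C <- config$n_conditions
  O <- config$nobs_max
  acc <- matrix(0, C, O)
  cnt <- matrix(0L, C, O)
  per_session <- list()
  for (ses in sessions) {
    df <- ses[ses$abort_code == "none" & !is.na(ses$choice), ]
    if (!nrow(df)) next
    nobs <- nobs_of_trial(df$trial, config)
    pair <- do.call(rbind, config$conditions)
    deltas <- config$cue_deltas
    better <- ifelse(deltas[pair[df$condition, 1L]] >=
                       deltas[pair[df$condition, 2L]],
                     pair[df$condition, 1L], pair[df$condition, 2L])
    hit <- as.numeric(df$choice == better)
    m <- matrix(NA_real_, C, O)
    for (cc in seq_len(C)) for (o in seq_len(O)) {
      sel <- df$condition == cc & nobs == o
      if (any(sel)) m[cc, o] <- mean(hit[sel])
    }
    per_session[[length(per_session) + 1L]] <- m
  }
  if (!length(per_session)) stop("no completed trials in any session")
  arr <- simplify2array(per_session)
  out <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  nmiss <- sum(is.nan(out))
  out[is.nan(out)] <- NA_real_
  attr(out, "n_missing") <- nmiss
  out
}

#' Fit the MDP's two free parameters to choice behaviour
#'
#' Jointly fits the value-scale parameter `k` and the choice softmax
#' inverse temperature `beta_mdp` by minimizing the root mean squared
#' error between the model's choice-probability curves and the
#' empirical 6 x 18 choice-fraction matrix, over all cells with data.
#' Optimization is bounded Nelder-Mead on log-parameters from a fixed
#' grid of restarts; the returned model is re-solved at the fitted `k`
#' with the full sweep budget so that state values and policy are
#' reconverged.
#'
#' @param curves a [cue_value_curves] object.
#' @param empirical empirical choice matrix from
#'   [empirical_choice_curves()].
#' @param gamma discount factor.
#' @param config a [task_config()].
#' @param sweeps_fit value-iteration sweeps per objective evaluation.
#' @param sweeps_final sweep budget for the reconverged model.
#' @param restarts number of Nelder-Mead restarts (fixed start grid).
#' @param reconverge_rounds maximum rebuild/re-solve alternations after
#'   fitting (early exit when the policy is unchanged).
#' @return An object of class `mdp_fit`: `k`, `beta_mdp`, `gamma`,
#'   `rmse`, `rmse_initial`, and the reconverged `value_table`.
#' @export
fit_k_beta <- function(curves, empirical, gamma = 0.999,
                       config = task_config(), sweeps_fit = 60L,
                       sweeps_final = 100L, restarts = 4L,
                       reconverge_rounds = 5L) {
  if (all(is.na(empirical))) stop("empirical choice matrix is all missing")
  memo <- new.env(parent = emptyenv())
  solve_k <- function(k, sweeps) {
    key <- sprintf("%.12g_%d", k, sweeps)
    if (!is.null(memo[[key]])) return(memo[[key]])
    vt <- value_iteration(build_transition_model(curves, k, config),
                          gamma, sweeps = sweeps)
    memo[[key]] <- vt
    vt
  }
  rmse_of <- function(k, beta, sweeps) {
    pred <- model_choice_curves(solve_k(k, sweeps), beta)
    sqrt(mean((pred - empirical)^2, na.rm = TRUE))
  }
  obj <- function(par) rmse_of(exp(par[1]), exp(par[2]), sweeps_fit)
  starts <- list(log(c(0.5, 1.5)), log(c(1.0, 2.5)),
                 log(c(0.8, 1.0)), log(c(1.3, 3.0)))
  starts <- starts[seq_len(min(restarts, length(starts)))]
  rmse_initial <- obj(starts[[1]])
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-6))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  k <- exp(best$par[1])
  beta <- exp(best$par[2])
  # refit transitions at the fitted k and iterate to reconvergence
  vt <- solve_k(k, sweeps_fit)
  for (r in seq_len(reconverge_rounds)) {
    vt_new <- value_iteration(build_transition_model(curves, k, config),
                              gamma, sweeps = sweeps_final)
    stable <- identical(vt_new$policy, vt$policy)
    vt <- vt_new
    if (stable) break
  }
  structure(list(k = k, beta_mdp = beta, gamma = gamma,
                 rmse = rmse_of_table(vt, beta, empirical),
                 rmse_search = best$value,
                 rmse_initial = rmse_initial,
                 value_table = vt),
            class = "mdp_fit")
}

rmse_of_table <- function(vt, beta, empirical) {
  pred <- model_choice_curves(vt, beta)
  sqrt(mean((pred - empirical)^2, na.rm = TRUE))
}

#' @export
print.mdp_fit <- function(x, ...) {
  cat(sprintf("MDP fit: k = %.3f, beta_mdp = %.3f (gamma = %g), RMSE = %.4f\n",
              x$k, x$beta_mdp, x$gamma, x$rmse))
  invisible(x)
}

#' Discount-factor sweep
#'
#' Fits an MDP at each candidate discount factor, runs the three
#' motivation regressions against the resulting state values on every
#' session, and selects the candidate minimizing the regression error
#' (mean residual variance across the three regressions, averaged over
#' sessions).
#'
#' @param candidates discount factors in (0, 1); the default is the
#'   canonical screening set.
#' @param sessions list of session data frames.
#' @param curves a [cue_value_curves] object.
#' @param config a [task_config()].
#' @param k,beta_mdp optional fixed values for the two free parameters;
#'   when `NULL` they are refit per candidate via [fit_k_beta()].
#' @param sweeps value-iteration sweep budget per candidate.
#' @return List with `best_gamma` and a `diagnostics` data frame (one
#'   row per candidate: regression error and fitted parameters).
#' @export
sweep_gamma <- function(candidates = c(0.8, 0.85, 0.9, 0.95, 0.99, 0.999),
                        sessions, curves, config = task_config(),
                        k = NULL, beta_mdp = NULL, sweeps = 100L) {
  if (!length(candidates)) stop("empty candidate list")
  if (any(candidates <= 0 | candidates >= 1))
    stop("candidates must lie in (0, 1)")
  if (is.data.frame(sessions)) sessions <- list(sessions)
  empirical <- if (is.null(k)) empirical_choice_curves(sessions, config)
  rows <- lapply(candidates, function(g) {
    if (is.null(k)) {
      fit <- fit_k_beta(curves, empirical, gamma = g, config = config,
                        sweeps_fit = max(20L, sweeps %/% 2L),
                        sweeps_final = sweeps)
      vt <- fit$value_table
      kk <- fit$k; bb <- fit$beta_mdp
    } else {
      vt <- value_iteration(build_transition_model(curves, k, config),
                            g, sweeps = sweeps)
      kk <- k; bb <- beta_mdp
    }
    errs <- vapply(sessions, function(ses) {
      rv <- c(fit_fixation_rt(ses, vt, config)$residual_var,
              fit_choice_rt(ses, vt, config)$residual_var,
              tryCatch(fit_abort_logistic(ses, vt, config)$residual_var,
                       error = function(e) NA_real_))
      mean(rv, na.rm = TRUE)
    }, numeric(1))
    data.frame(gamma = g, regression_error = mean(errs), k = kk,
               beta_mdp = bb)
  })
  diagnostics <- do.call(rbind, rows)
  list(best_gamma = diagnostics$gamma[which.min(diagnostics$regression_error)],
       diagnostics = diagnostics)
}
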