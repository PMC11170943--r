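#' Rescorla-Wagner value update
#'
#' One delta-rule update of the chosen cue's value estimate,
#' `v + alpha * (R - v)`, where `R` is the realized token change that
#' followed the choice (0 on the 25\% of trials where the outcome is not
#' delivered).  Only the chosen cue updates.
#'
#' @param v current value estimate.
#' @param R realized signed token change.
#' @param alpha learning rate in `[0, 1]`.
#' @return Updated value estimate.
#' @export
rw_update <- function(v, R, alpha) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha must be in [0, 1]")
  v + alpha * (R - v)
}

#' Softmax choice probability for a cue pair
#'
#' Fermi/softmax rule on the value difference:
#' `d_j = 1 / (1 + exp(beta * (v_i - v_j)))`, `d_i = 1 - d_j`.
#'
#' @param v_i,v_j value estimates of the two options.
#' @param beta inverse temperature (>= 0).
#' @return Named numeric vector `c(i = d_i, j = d_j)`.
#' @export
choice_prob <- function(v_i, v_j, beta) {
  if (beta < 0) stop("beta must be non-negative")
  d_j <- 1 / (1 + exp(beta * (v_i - v_j)))
  c(i = 1 - d_j, j = d_j)
}

# Extract the completed-choice arrays the likelihood kernel consumes.
completed_choice_data <- function(session, config) {
  df <- session[session$abort_code == "none", ]
  if (!nrow(df)) stop("session has no completed choice trials")
  pairs <- do.call(rbind, config$conditions)
  list(block = as.integer(df$block),
       cue1 = pairs[df$condition, 1L],
       cue2 = pairs[df$condition, 2L],
       chosen_slot = ifelse(df$choice == pairs[df$condition, 1L], 1L, 2L),
       reward = as.numeric(df$delta * df$delivered))
}

#' Fit the Rescorla-Wagner model to a session by maximum likelihood
#'
#' Maximizes the likelihood of the session's completed choices over one
#' learning rate per cue and a shared inverse temperature, with cue
#' values reset to zero at every block start (each block uses novel
#' images).  Optimization is bounded quasi-Newton (`L-BFGS-B`) from a
#' fixed grid of starting points, so fits are deterministic.
#'
#' @param session a session data frame (one row per attempt).
#' @param config a [task_config()].
#' @param n_starts number of multi-start points (>= 1; default 5).
#' @return A list with elements `alpha` (per-cue learning rates), `beta`
#'   (inverse temperature), `logLik`, `n_trials`, and `convergence`.
#' @export
fit_rw <- function(session, config = task_config(), n_starts = 5L) {
  dat <- completed_choice_data(session, config)
  ncue <- length(config$cue_deltas)
  nll <- function(par) {
    rw_nll_cpp(par[seq_len(ncue)], par[ncue + 1L], dat$block, dat$cue1,
               dat$cue2, dat$chosen_slot, dat$reward)
  }
  starts <- list(c(rep(0.1, ncue), 1), c(rep(0.3, ncue), 2),
                 c(rep(0.5, ncue), 5), c(rep(0.2, ncue), 10),
                 c(rep(0.4, ncue), 0.5))
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  lower <- c(rep(0, ncue), 0)
  upper <- c(rep(1, ncue), 50)
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, nll, method = "L-BFGS-B",
                        lower = lower, upper = upper)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(alpha = best$par[seq_len(ncue)], beta = best$par[ncue + 1L],
       logLik = -best$value, n_trials = length(dat$block),
       convergence = best$convergence)
}

#' Replayed cue-value trajectories for a session
#'
#' Replays a session's completed choices under fixed RW parameters and
#' returns, for each block, the value estimate each cue held at each of
#' its observations (1 to 54 for the default task: each cue appears in
#' three conditions shown 18 times each).  Values are the estimates held
#' *before* the observation's outcome, so all cues start at zero at
#' observation 1.
#'
#' @param session a session data frame.
#' @param alpha per-cue learning rates to replay with (typically from
#'   [fit_rw()]).
#' @param config a [task_config()].
#' @return A list with one `n_cues x n_raw` matrix per block.
#' @export
rw_value_trajectories <- function(session, alpha, config = task_config()) {
  dat <- completed_choice_data(session, config)
  vals <- rw_replay_cpp(alpha, dat$block, dat$cue1, dat$cue2,
                        dat$chosen_slot, dat$reward)
  ncue <- length(config$cue_deltas)
  appearances <- vapply(seq_len(ncue), function(k)
    sum(vapply(config$conditions, function(p) k %in% p, logical(1))),
    integer(1)) * config$presentations_per_condition
  out <- list()
  for (b in unique(dat$block)) {
    rows <- which(dat$block == b)
    m <- matrix(NA_real_, ncue, max(appearances))
    cnt <- integer(ncue)
    for (t in rows) {
      for (k in c(dat$cue1[t], dat$cue2[t])) {
        cnt[k] <- cnt[k] + 1L
        m[k, cnt[k]] <- vals[t, k]
      }
    }
    out[[length(out) + 1L]] <- m
  }
  out
}

#' Mean cue-value curves and their dispersion
#'
#' Averages per-block cue-value trajectories across blocks (and
#' sessions) to produce one learning curve per cue over raw observation
#' counts, then collapses each consecutive group of three observations
#' (one per condition containing the cue) into the per-cue-pair
#' observation index NObs 1..18.  The dispersion `sigma` at each
#' collapsed index is the across-block standard deviation of the
#' collapsed value, averaged over cues -- a single dispersion per trial
#' index, shared by all cues.
#'
#' @param trajectories list of `n_cues x n_raw` matrices, one per block
#'   (concatenated across sessions), as from [rw_value_trajectories()].
#' @param config a [task_config()].
#' @return An object of class `cue_value_curves`: list with `raw`
#'   (`n_cues x n_raw` mean curve), `collapsed` (`n_cues x nobs_max`),
#'   `sigma` (length `nobs_max`), and `n_blocks`.
#' @export
extract_mean_curves <- function(trajectories, config = task_config()) {
  if (!length(trajectories)) stop("no trajectories supplied")
  dims <- vapply(trajectories, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent trajectory dimensions across blocks")
  ncue <- dims[1, 1]
  n_raw <- dims[2, 1]
  f <- n_raw %/% config$nobs_max
  if (f * config$nobs_max != n_raw)
    stop("raw observation count not divisible by nobs_max")
  arr <- simplify2array(trajectories)            # ncue x n_raw x blocks
  raw <- apply(arr, c(1, 2), mean)
  collapse <- function(m)
    t(apply(m, 1, function(r) colMeans(matrix(r, nrow = f))))
  coll_blocks <- lapply(trajectories, collapse)  # per block ncue x nobs
  carr <- simplify2array(coll_blocks)
  collapsed <- apply(carr, c(1, 2), mean)
  sd_blocks <- apply(carr, c(1, 2), stats::sd)
  if (length(trajectories) == 1L) sd_blocks[] <- 0
  sigma <- colMeans(sd_blocks)
  structure(list(raw = raw, collapsed = collapsed, sigma = sigma,
                 n_blocks = length(trajectories)),
            class = "cue_value_curves")
}

#' Idealized saturating cue-value curves
#'
#' Noise-free stand-in for learned mean cue-value curves: each cue's
#' value saturates exponentially toward `deliver_prob * delta` (the
#' asymptote of delta-rule learning on 75\%-delivered outcomes) with
#' time constant `tau` observation groups, and the dispersion is a
#' constant `sigma`.  Useful for structural checks (monotonicity,
#' calibration self-consistency) where sampling wiggle in estimated
#' curves would obscure the model's own properties.
#'
#' @param config a [task_config()].
#' @param tau saturation time constant in NObs units.
#' @param sigma constant dispersion of the curves.
#' @return A `cue_value_curves` object.
#' @export
idealized_curves <- function(config = task_config(), tau = 4, sigma = 0.2) {
  O <- config$nobs_max
  sat <- 1 - exp(-(seq_len(O) - 1) / tau)
  collapsed <- outer(config$outcome_deliver_prob * config$cue_deltas, sat)
  structure(list(raw = NULL, collapsed = collapsed,
                 sigma = rep(sigma, O), n_blocks = 0L),
            class = "cue_value_curves")
}

#' @export
print.cue_value_curves <- function(x, ...) {
  cat("Cue-value curves:", nrow(x$collapsed), "cues x",
      ncol(x$collapsed), "observations (", x$n_blocks, "blocks )\n")
  cat("final collapsed values:",
      paste(sprintf("%.3f", x$collapsed[, ncol(x$collapsed)]),
            collapse = ", "), "\n")
  invisible(x)
}
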