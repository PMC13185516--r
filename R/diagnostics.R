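# Per-timepoint decoding-quality diagnostics: response probability P_t,
# temporal reliability rho_t (1 - total variation), Mahalanobis model
# discrepancy, and the frame/trial flagging rules.

#' Brain response probability P_t
#'
#' Instantaneous probability that the brain is actively responding to task
#' stimuli: `P_t = sum_c pi_{t,c} * a_{c,resp}`, where `a_{c,resp}` is the
#' state's responding-mixture weight. Bounded in `[0, 1]`.
#'
#' @param traj a [infer_posteriors()] trajectory.
#' @param params the `pcsm_hmm` supplying the mixture weights.
#' @return numeric vector of length K.
#' @export
response_probability <- function(traj, params) {
  stopifnot(inherits(traj, "pcsm_posterior"), inherits(params, "pcsm_hmm"))
  if (ncol(traj$pi) != params$C) stop("invalid-input: state count mismatch")
  as.numeric(traj$pi %*% params$mixture_weights[, params$responding])
}

#' Temporal reliability rho_t
#'
#' One minus the total variation distance between consecutive state
#' posteriors: `rho_t = 1 - 0.5 * sum_c |pi_{t,c} - pi_{t-1,c}|` for t >= 2,
#' with `rho_1 = 1` by convention (no predecessor). When `smooth` is set an
#' exponential moving average with half-life equal to the FIR bin count is
#' applied to the rho series only (the definition is unchanged).
#'
#' @param traj a [infer_posteriors()] trajectory.
#' @param smooth apply the adaptive EMA smoother (off by default).
#' @param halflife EMA half-life in timepoints (defaults to the delay count).
#' @return numeric vector of length K in `[0, 1]`.
#' @export
temporal_reliability <- function(traj, smooth = FALSE, halflife = NULL) {
  stopifnot(inherits(traj, "pcsm_posterior"))
  K <- nrow(traj$pi)
  rho <- c(1, 1 - 0.5 * rowSums(abs(traj$pi[-1, , drop = FALSE] -
                                      traj$pi[-K, , drop = FALSE])))
  if (smooth && K > 1) {
    if (is.null(halflife)) halflife <- max(traj$delay)
    lambda <- 1 - 2^(-1 / halflife)
    sm <- numeric(K); sm[1] <- rho[1]
    for (t in 2:K) sm[t] <- (1 - lambda) * sm[t - 1] + lambda * rho[t]
    rho <- sm
  }
  pmin(pmax(rho, 0), 1)
}

#' Mahalanobis model discrepancy
#'
#' Quantifies the deviation between observed and model-predicted BOLD:
#' `D_t = (y_t - yhat_t)' Sigma^-1 (y_t - yhat_t)` with
#' `yhat_t = sum_c pi_{t,c} mu_bar_c` (mixture-weighted state means) and
#' `Sigma` the global spatial covariance. The quadratic form is evaluated via
#' a Cholesky solve of the (jittered, if needed) covariance, never an
#' explicit inverse. The raw series is unbounded; the normalized series is
#' the per-subject empirical-CDF rank transform `(rank - 0.5) / K`, giving
#' support `[0, 1]`.
#'
#' @param fir the subject's [fir_series()].
#' @param params a `pcsm_hmm` carrying `spatial_cov`.
#' @param traj the matching [infer_posteriors()] trajectory.
#' @return list with `raw` (non-negative) and `normalized` (in `[0, 1]`)
#'   vectors of length K.
#' @export
model_discrepancy <- function(fir, params, traj) {
  stopifnot(inherits(params, "pcsm_hmm"), inherits(traj, "pcsm_posterior"))
  if (is.null(params$spatial_cov)) stop("invalid-input: spatial covariance unavailable")
  Y <- fir$values
  yhat <- traj$pi %*% weighted_state_means(params)
  Res <- Y - yhat
  Sigma <- params$spatial_cov
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    jitter <- 1e-8 * mean(diag(Sigma))
    ch <- chol(Sigma + diag(jitter, ncol(Sigma)))
    message("spatial covariance jittered for a stable solve")
  }
  # raw_t = || L^-T res_t ||^2 where Sigma = L'L
  Z <- backsolve(ch, t(Res), transpose = TRUE)
  raw <- colSums(Z^2)
  K <- length(raw)
  normalized <- (rank(raw, ties.method = "average") - 0.5) / K
  list(raw = raw, normalized = normalized)
}

#' Frame and trial flagging
#'
#' A timepoint gets the Mahalanobis flag when its normalized discrepancy is
#' at or above `tau_maha`; it is flagged for removal when additionally both
#' the response probability and the temporal reliability are weak
#' (`P < tau_p` and `rho < tau_rho`). A trial is recommended for removal when
#' at least half of its FIR bins (3 or more of 5) carry the removal flag;
#' with fewer flagged bins the trial is kept (a strong transition that
#' stabilizes within trial).
#'
#' @param p_t,rho_t,d_maha_norm diagnostic series of equal length.
#' @param trial trial index per timepoint.
#' @param thresholds named list or vector with `tau_maha`, `tau_p`, `tau_rho`.
#' @return an object of class `pcsm_diagnostics`: per-timepoint data frame
#'   `frames` (flags), per-trial data frame `trials` (flagged-bin counts and
#'   keep/remove recommendation).
#' @export
flag_frames <- function(p_t, rho_t, d_maha_norm, trial, thresholds) {
  th <- as.list(thresholds)
  for (nm in c("tau_maha", "tau_p", "tau_rho"))
    if (is.null(th[[nm]]) || is.na(th[[nm]]))
      stop("invalid-input: missing threshold ", nm)
  stopifnot(length(p_t) == length(rho_t),
            length(p_t) == length(d_maha_norm),
            length(p_t) == length(trial))
  maha_flag <- d_maha_norm >= th$tau_maha
  weak_p <- p_t < th$tau_p
  weak_rho <- rho_t < th$tau_rho
  removal_flag <- maha_flag & weak_p & weak_rho
  frames <- data.frame(trial = trial, p_t = p_t, rho_t = rho_t,
                       d_maha_norm = d_maha_norm, maha_flag = maha_flag,
                       weak_p = weak_p, weak_rho = weak_rho,
                       removal_flag = removal_flag)
  n_flagged <- tapply(removal_flag, trial, sum)
  n_bins <- tapply(removal_flag, trial, length)
  decision <- ifelse(n_flagged >= ceiling(n_bins / 2 + 1e-9), "remove", "keep")
  trials <- data.frame(trial = as.integer(names(n_flagged)),
                       n_bins = as.integer(n_bins),
                       n_flagged = as.integer(n_flagged),
                       decision = decision, row.names = NULL)
  structure(list(frames = frames, trials = trials, thresholds = th),
            class = "pcsm_diagnostics")
}

#' @export
print.pcsm_diagnostics <- function(x, ...) {
  cat("PCSM diagnostics:", nrow(x$frames), "timepoints,",
      sum(x$frames$removal_flag), "flagged for removal;",
      sum(x$trials$decision == "remove"), "of", nrow(x$trials),
      "trials recommended for removal\n")
  invisible(x)
}
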