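# End-to-end study orchestration: simulate (or ingest) a cohort, fit the
# global model, fit + align + decode each subject, derive diagnostics and
# emergent metrics, estimate all data-driven thresholds, and evaluate
# ground-truth recovery.

# Default KDE search windows per metric (support regions around the expected
# density dips; all configurable through run_pcsm_study()).
default_kde_windows <- function() {
  list(p_t = c(0.02, 0.60),
       dsp_low = c(0.45, 0.58),
       dsp_high = c(0.55, 0.70),
       bottleneck_tail = list(c(0.05, 0.60), c(0.60, 0.99)))
}

#' Run a full simulated PCSM study
#'
#' Simulates a cohort balanced over the three transition regimes and four
#' noise levels, fits the global GMM-HMM on the concatenated FIR series,
#' refits each subject with frozen covariances, aligns subjects to the global
#' template, decodes filtered posteriors and Viterbi paths, computes
#' diagnostics (P, rho, Mahalanobis discrepancy), emergent metrics (node
#' response posterior, D^SP, demand, resource, bottleneck), estimates every
#' data-driven threshold from the pooled cohort distributions, and evaluates
#' latent-state and transition recovery against the simulator's ground truth.
#'
#' @param n_subjects cohort size (balanced round-robin over regime x noise).
#' @param seed study seed; all randomness derives from it.
#' @param n_nodes,n_trials simulator dimensions.
#' @param C,M model order.
#' @param n_init,max_iter,tol EM controls for the global fit.
#' @param subject_max_iter EM iterations per subject refit.
#' @param fdr_alphas grid of FDR levels summarized for node selection.
#' @param pe_delta post-exit window for the bottleneck.
#' @param n_boot bootstrap resamples for quartile thresholds.
#' @param kde_windows per-metric KDE valley search windows (see
#'   `pcsm:::default_kde_windows`).
#' @param verbose print stage progress.
#' @return an object of class `pcsm_study` with elements `global`,
#'   `subjects` (per-subject metric lists), `thresholds`, `fdr` (per-alpha
#'   summary), `recovery_states`, `recovery_transitions`, `flags`, and
#'   `meta`.
#' @export
run_pcsm_study <- function(n_subjects = 120L, seed = 1L, n_nodes = 200L,
                           n_trials = 132L, C = 3L, M = 2L, n_init = 5L,
                           max_iter = 100L, tol = 1e-4,
                           subject_max_iter = 50L,
                           fdr_alphas = c(0.10, 0.15, 0.20, 0.25, 0.30),
                           pe_delta = 3L, n_boot = 2000L,
                           kde_windows = default_kde_windows(),
                           verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()
  say("stage simulate: ", n_subjects, " subjects x ", n_trials, " trials x ",
      n_nodes, " nodes")
  cohort <- simulate_cohort(n_subjects, seed = seed, n_nodes = n_nodes,
                            n_trials = n_trials)
  fir_stack <- lapply(cohort, function(s) s$fir)

  say("stage fit-global: C=", C, " M=", M)
  global <- fit_global(fir_stack, C = C, M = M, n_init = n_init,
                       max_iter = max_iter, tol = tol, seed = seed)

  say("stage subjects: fit + align + decode + metrics")
  subjects <- vector("list", n_subjects)
  fdr_acc <- matrix(0, length(fdr_alphas), 3)  # sums of tau, nodes, fdr
  fdr_n <- 0L
  for (i in seq_len(n_subjects)) {
    s <- cohort[[i]]
    fit <- fit_subject(s$fir, global, max_iter = subject_max_iter, tol = tol)
    al <- align_to_template(fit, global)
    traj <- infer_posteriors(al$aligned, s$fir)
    p_t <- response_probability(traj, al$aligned)
    rho_t <- temporal_reliability(traj)
    dm <- model_discrepancy(s$fir, al$aligned, traj)
    B <- node_response_posterior(s$fir, al$aligned, traj)
    d_sp <- serial_parallel_deviation(B)
    dem <- cognitive_demand(d_sp, traj)
    # adaptive-FDR summaries per timepoint (B is then released)
    Bs <- t(apply(B, 1, sort, decreasing = TRUE))
    err <- t(apply(1 - Bs, 1, cumsum)) /
      matrix(seq_len(ncol(Bs)), nrow(Bs), ncol(Bs), byrow = TRUE)
    for (ai in seq_along(fdr_alphas)) {
      k <- apply(err <= fdr_alphas[ai], 1, function(z) {
        w <- which(z); if (length(w)) max(w) else 0L })
      tau <- ifelse(k > 0, Bs[cbind(seq_len(nrow(Bs)), pmax(k, 1L))], NA_real_)
      fdr_t <- ifelse(k > 0, err[cbind(seq_len(nrow(Bs)), pmax(k, 1L))], 0)
      fdr_acc[ai, ] <- fdr_acc[ai, ] +
        c(sum(tau, na.rm = TRUE), sum(k), sum(fdr_t))
      if (ai == 1) fdr_n <- fdr_n + nrow(Bs)
    }
    subjects[[i]] <- list(
      regime = s$truth$regime, noise = s$truth$noise,
      truth_states = s$truth$state_seq, truth = s$truth,
      viterbi = traj$viterbi, trial = s$fir$trial, delay = s$fir$delay,
      p_t = p_t, rho_t = rho_t,
      d_maha_raw = dm$raw, d_maha_norm = dm$normalized,
      d_sp = d_sp, demand_raw = dem$raw, demand = dem$squashed,
      loglik = traj$loglik, state_perm = al$state_perm)
  }

  say("stage thresholds: pooled distributions")
  pool <- function(field) unlist(lapply(subjects, `[[`, field), use.names = FALSE)
  thresholds <- list()
  thresholds$rho <- gmm_intersection_threshold(
    pool("rho_t"), support = c(0, 1), G = 2L, tail_ok = TRUE, seed = seed)
  thresholds$p <- gmm_intersection_threshold(
    pool("p_t"), support = c(0, 1), G = 2L, tail_ok = FALSE,
    kde_windows = list(kde_windows$p_t), seed = seed)
  thresholds$d_maha <- gmm_intersection_threshold(
    pool("d_maha_norm"), support = c(0, 1), G = 2L, tail_ok = TRUE, seed = seed)
  thresholds$d_sp <- gmm_intersection_threshold(
    pool("d_sp"), support = c(0, 1), G = 3L, tail_ok = TRUE,
    kde_windows = list(kde_windows$dsp_low, kde_windows$dsp_high), seed = seed)
  tau_low <- thresholds$d_sp$taus[1]
  tau_high <- thresholds$d_sp$taus[2]
  if (is.na(tau_low) || is.na(tau_high) || !(tau_low < tau_high)) {
    warning("degenerate D^SP thresholds; falling back to pooled terciles")
    qq <- stats::quantile(pool("d_sp"), c(1 / 3, 2 / 3), names = FALSE)
    tau_low <- qq[1]; tau_high <- qq[2]
  }

  say("stage modes: classification, resource, bottleneck")
  for (i in seq_len(n_subjects)) {
    sb <- subjects[[i]]
    mode <- classify_mode(sb$d_sp, tau_low, tau_high)
    res <- resource_level(sb$demand_raw, mode)
    bott <- serial_bottleneck(mode, sb$demand_raw, pe_delta = pe_delta)
    subjects[[i]]$mode <- mode
    subjects[[i]]$serial_fraction <- mean(mode == "serial")
    subjects[[i]]$resource_raw <- res$raw
    subjects[[i]]$resource <- res$squashed
    subjects[[i]]$resource_params <- res[c("lambda", "h", "dwell_med", "alpha")]
    subjects[[i]]$bottleneck_raw <- bott$raw
    subjects[[i]]$bottleneck_detail <- bott
  }
  bott_raw <- vapply(subjects, `[[`, numeric(1), "bottleneck_raw")
  bott_sq <- squash_bottleneck_cohort(bott_raw)
  for (i in seq_len(n_subjects)) subjects[[i]]$bottleneck <- bott_sq[i]

  thresholds$demand <- quartile_bootstrap_thresholds(
    lapply(subjects, `[[`, "demand"), n_boot = n_boot, seed = seed)
  thresholds$resource <- quartile_bootstrap_thresholds(
    lapply(subjects, `[[`, "resource"), n_boot = n_boot, seed = seed)
  bneg <- mean(bott_sq < 0)
  bott_tail <- tryCatch(
    kde_valley_threshold(bott_sq, support = c(-1, 1),
                         windows = kde_windows$bottleneck_tail,
                         sensitivity = FALSE),
    error = function(e) NULL)
  thresholds$bottleneck <- list(negative_mass = bneg, tail_valleys = bott_tail,
                                values = bott_sq)

  say("stage flags: frame/trial quality control")
  flag_summary <- NULL
  if (!is.na(thresholds$d_maha$taus[1]) && !is.na(thresholds$p$taus[1]) &&
      !is.na(thresholds$rho$taus[1])) {
    th <- list(tau_maha = thresholds$d_maha$taus[1],
               tau_p = thresholds$p$taus[1],
               tau_rho = thresholds$rho$taus[1])
    fl <- lapply(subjects, function(sb)
      flag_frames(sb$p_t, sb$rho_t, sb$d_maha_norm, sb$trial, th))
    flag_summary <- list(
      thresholds = th,
      mean_flagged_timepoints = mean(vapply(fl, function(f)
        sum(f$frames$removal_flag), numeric(1))),
      mean_removed_trials = mean(vapply(fl, function(f)
        sum(f$trials$decision == "remove"), numeric(1))))
  }

  say("stage evaluate: ground-truth recovery")
  strata <- list(
    regime = lapply(subjects, function(sb) rep(sb$regime, length(sb$viterbi))),
    noise = lapply(subjects, function(sb) rep(sb$noise, length(sb$viterbi))))
  # one global correspondence between template and generative state labels
  label_map <- match_template_to_truth(
    lapply(subjects, `[[`, "viterbi"),
    lapply(subjects, `[[`, "truth_states"), C = C)
  recovery_states <- evaluate_state_recovery(
    lapply(subjects, `[[`, "viterbi"),
    lapply(subjects, function(sb) label_map[sb$truth_states]),
    strata = strata, C = C)
  recovery_transitions <- evaluate_transition_recovery(
    lapply(subjects, `[[`, "viterbi"),
    lapply(subjects, `[[`, "truth"), strata = strata)

  fdr_tab <- data.frame(alpha = fdr_alphas,
                        mean_tau = fdr_acc[, 1] / fdr_n,
                        mean_nodes = fdr_acc[, 2] / fdr_n,
                        mean_fdr = fdr_acc[, 3] / fdr_n)

  serial_by_regime <- tapply(
    vapply(subjects, `[[`, numeric(1), "serial_fraction"),
    vapply(subjects, `[[`, character(1), "regime"), mean)

  structure(list(
    global = global, subjects = subjects, label_map = label_map,
    thresholds = thresholds,
    fdr = fdr_tab, recovery_states = recovery_states,
    recovery_transitions = recovery_transitions, flags = flag_summary,
    serial_fraction_by_regime = serial_by_regime,
    meta = list(n_subjects = n_subjects, seed = seed, n_nodes = n_nodes,
                n_trials = n_trials, C = C, M = M, pe_delta = pe_delta,
                n_boot = n_boot,
                elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    class = "pcsm_study")
}

#' @export
print.pcsm_study <- function(x, ...) {
  cat("PCSM study:", x$meta$n_subjects, "subjects,", x$meta$n_nodes,
      "nodes, seed", x$meta$seed, "\n")
  cat("  state recovery accuracy:",
      format(x$recovery_states$overall$accuracy, digits = 4), "\n")
  cat("  thresholds: rho", round(x$thresholds$rho$taus[1], 3),
      "| P", round(x$thresholds$p$taus[1], 3),
      "| D_maha", round(x$thresholds$d_maha$taus[1], 3),
      "| D_SP (", round(x$thresholds$d_sp$taus[1], 3), ",",
      round(x$thresholds$d_sp$taus[2], 3), ")\n")
  cat("  demand high tau:", round(x$thresholds$demand$taus["high"], 3),
      "| resource high tau:", round(x$thresholds$resource$taus["high"], 3),
      "| bottleneck negative mass:",
      round(100 * x$thresholds$bottleneck$negative_mass, 1), "%\n")
  invisible(x)
}
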