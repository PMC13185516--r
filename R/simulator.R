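# Generative stop-signal-task simulator: behavior, ground-truth latent state
# sequences, and state-conditioned FIR-domain BOLD with known ground truth.

#' Simulation configuration
#'
#' Builds the configuration object driving the stop-signal-task (SST)
#' simulator. Defaults encode the study design: 132 trials with 60% go / 40%
#' stop, 5 FIR delay bins (0-8 s at TR = 2 s), 200 spatial nodes, three
#' within-trial transition regimes and four noise levels. Reaction times and
#' stop-signal delays (SSD) are drawn uniformly from realistic ranges; a stop
#' trial succeeds when the (latent) go reaction time exceeds SSD plus the
#' stop-signal reaction time (SSRT).
#'
#' State-conditioned node amplitudes reflect the three latent states: state 1
#' high positive, state 2 low positive, state 3 mixed positive/negative.
#' Noise standard deviations are multiples of the half-width of the state-1
#' amplitude range.
#'
#' @param n_trials number of trials per subject.
#' @param stop_proportion proportion of stop trials in `[0, 1]`.
#' @param n_delays number of FIR delay bins per trial.
#' @param tr_s repetition time in seconds.
#' @param n_nodes number of spatial nodes.
#' @param isi_range_s inter-stimulus-interval range (seconds).
#' @param rt_range_s go reaction-time range (seconds).
#' @param ssd_range_s stop-signal-delay range (seconds).
#' @param ssrt_s stop-signal reaction time (seconds).
#' @param transition_regime one of `"low"`, `"medium"`, `"high"` (frequency of
#'   within-trial state transitions; low transition = high stay probability).
#' @param stay_prob_by_regime named stay probabilities per regime, strictly
#'   decreasing from `low` to `high`.
#' @param noise_level one of `"low"`, `"medium"`, `"high"`, `"very_high"`.
#' @param noise_sd_by_level named noise standard deviations per level.
#' @param state_amplitude_ranges list of length-2 amplitude ranges, one per
#'   latent state.
#' @param init_probs_go,init_probs_stop initial state distributions for go and
#'   stop trials (go trials favor state 2, stop trials favor state 1).
#' @param seed integer seed; all simulator randomness flows from it.
#' @return an object of class `pcsm_sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_nodes = 20, seed = 1)
#' cfg$n_trials
sim_config <- function(n_trials = 132L,
                       stop_proportion = 0.40,
                       n_delays = 5L,
                       tr_s = 2.0,
                       n_nodes = 200L,
                       isi_range_s = c(3, 7),
                       rt_range_s = c(0.35, 0.65),
                       ssd_range_s = c(0.10, 0.40),
                       ssrt_s = 0.25,
                       transition_regime = c("low", "medium", "high"),
                       stay_prob_by_regime = c(low = 0.90, medium = 0.70, high = 0.50),
                       noise_level = c("low", "medium", "high", "very_high"),
                       noise_sd_by_level = NULL,
                       state_amplitude_ranges = list(c(0.8, 1.2), c(0.2, 0.5), c(-0.8, 0.8)),
                       init_probs_go = c(0.2, 0.6, 0.2),
                       init_probs_stop = c(0.6, 0.2, 0.2),
                       seed = 1L) {
  transition_regime <- match.arg(transition_regime)
  noise_level <- match.arg(noise_level)
  if (length(n_trials) != 1L || is.na(n_trials) || n_trials <= 0)
    stop("invalid-config: n_trials must be a positive integer")
  if (stop_proportion < 0 || stop_proportion > 1)
    stop("invalid-config: stop_proportion must lie in [0, 1]")
  if (n_delays <= 0 || n_nodes <= 0 || tr_s <= 0)
    stop("invalid-config: n_delays, n_nodes and tr_s must be positive")
  for (r in list(isi_range_s, rt_range_s, ssd_range_s)) {
    if (length(r) != 2L || r[1] > r[2]) stop("invalid-config: range low must be <= high")
  }
  if (is.null(noise_sd_by_level)) {
    # multiples of the state-1 (high positive) amplitude midpoint, so the
    # between-state mean distance exceeds the within-state spread at low
    # noise (per-node effect size ~1.3 between adjacent states) while
    # decoding remains probabilistic rather than degenerate
    mid <- mean(state_amplitude_ranges[[1]])
    noise_sd_by_level <- c(low = 0.5, medium = 1.0, high = 1.5, very_high = 2.0) * mid
  }
  if (any(noise_sd_by_level <= 0)) stop("invalid-config: noise sds must be positive")
  sp <- stay_prob_by_regime[c("low", "medium", "high")]
  if (any(is.na(sp)) || any(diff(sp) >= 0))
    stop("invalid-config: stay probabilities must strictly decrease from regime low to high")
  if (any(sp <= 0 | sp > 1)) stop("invalid-config: stay probabilities must lie in (0, 1]")
  stopifnot(length(state_amplitude_ranges) == 3L,
            length(init_probs_go) == 3L, length(init_probs_stop) == 3L)
  cfg <- list(
    n_trials = as.integer(n_trials), stop_proportion = stop_proportion,
    n_delays = as.integer(n_delays), tr_s = tr_s, n_nodes = as.integer(n_nodes),
    isi_range_s = isi_range_s, rt_range_s = rt_range_s,
    ssd_range_s = ssd_range_s, ssrt_s = ssrt_s,
    transition_regime = transition_regime,
    stay_prob_by_regime = stay_prob_by_regime,
    noise_level = noise_level, noise_sd_by_level = noise_sd_by_level,
    state_amplitude_ranges = state_amplitude_ranges,
    init_probs_go = init_probs_go / sum(init_probs_go),
    init_probs_stop = init_probs_stop / sum(init_probs_stop),
    seed = as.integer(seed))
  class(cfg) <- "pcsm_sim_config"
  cfg
}

#' @export
print.pcsm_sim_config <- function(x, ...) {
  cat("PCSM simulation config:", x$n_trials, "trials (",
      round(100 * x$stop_proportion), "% stop ),", x$n_delays, "delay bins,",
      x$n_nodes, "nodes\n")
  cat("  regime:", x$transition_regime,
      "( stay =", x$stay_prob_by_regime[[x$transition_regime]], ")",
      " noise:", x$noise_level,
      "( sd =", x$noise_sd_by_level[[x$noise_level]], ")\n")
  invisible(x)
}

#' Simulate stop-signal-task behavior
#'
#' Generates a trial table with `round(n_trials * stop_proportion)` stop
#' trials in random order. ISIs are sampled uniformly within `isi_range_s`
#' and rescaled so the total duration matches the nominal run length
#' (`n_trials * mean(isi_range_s)`). Go reaction times and SSDs are uniform
#' within their ranges; a stop trial is a successful stop iff
#' `rt > ssd + ssrt`.
#'
#' @param config a [sim_config()] object.
#' @return a `data.frame` of class `pcsm_trials` with columns `trial_id`,
#'   `onset_s`, `isi_s`, `trial_type`, `rt_s`, `ssd_s`, `outcome`.
#' @export
simulate_behavior <- function(config) {
  stopifnot(inherits(config, "pcsm_sim_config"))
  n <- config$n_trials
  n_stop <- round(n * config$stop_proportion)
  type <- rep("go", n)
  if (n_stop > 0) type[sample.int(n, n_stop)] <- "stop"
  isi <- stats::runif(n, config$isi_range_s[1], config$isi_range_s[2])
  target <- n * mean(config$isi_range_s)
  isi <- isi * target / sum(isi)               # rescale to nominal run length
  onset <- cumsum(isi) - isi[1]                # first trial starts at 0
  rt <- stats::runif(n, config$rt_range_s[1], config$rt_range_s[2])
  ssd <- ifelse(type == "stop",
                stats::runif(n, config$ssd_range_s[1], config$ssd_range_s[2]),
                NA_real_)
  outcome <- ifelse(type == "go", "go_response",
                    ifelse(rt > ssd + config$ssrt_s, "stop_success", "stop_fail"))
  out <- data.frame(trial_id = seq_len(n), onset_s = onset, isi_s = isi,
                    trial_type = type, rt_s = rt, ssd_s = ssd,
                    outcome = outcome, stringsAsFactors = FALSE)
  class(out) <- c("pcsm_trials", "data.frame")
  out
}

regime_transition_matrix <- function(stay, C = 3L) {
  P <- matrix((1 - stay) / (C - 1), C, C)
  diag(P) <- stay
  P
}

#' Simulate ground-truth latent state sequences
#'
#' Per trial, a first-order Markov chain of length `n_delays` over states
#' 1..3. The initial state distribution is conditioned on trial type (stop
#' trials favor the high-salience state 1, go trials favor state 2); the
#' per-step stay probability is set by the transition regime, with the
#' off-diagonal mass split equally.
#'
#' @param trials a `pcsm_trials` table from [simulate_behavior()].
#' @param config a [sim_config()] object.
#' @return an object of class `pcsm_truth`: list with `state_seq` (integer
#'   vector of length `n_trials * n_delays`, states in 1..3), `transition_seq`
#'   (0 = stay, 1 = change; `NA` at the first bin of each trial), `trial`,
#'   `delay` indices, `regime` and `noise` labels.
#' @export
simulate_state_sequence <- function(trials, config) {
  stopifnot(inherits(config, "pcsm_sim_config"), nrow(trials) > 0L)
  D <- config$n_delays
  stay <- config$stay_prob_by_regime[[config$transition_regime]]
  if (is.null(stay) || is.na(stay)) stop("invalid-config: unknown transition regime")
  P <- regime_transition_matrix(stay)
  R <- nrow(trials)
  states <- integer(R * D)
  for (r in seq_len(R)) {
    p0 <- if (trials$trial_type[r] == "stop") config$init_probs_stop else config$init_probs_go
    s <- integer(D)
    s[1] <- sample.int(3L, 1L, prob = p0)
    if (D > 1) for (d in 2:D) s[d] <- sample.int(3L, 1L, prob = P[s[d - 1], ])
    states[((r - 1) * D + 1):(r * D)] <- s
  }
  trial <- rep(seq_len(R), each = D)
  delay <- rep(seq_len(D), times = R)
  trans <- c(NA_integer_, as.integer(states[-1] != states[-length(states)]))
  trans[delay == 1L] <- NA_integer_   # undefined across trial boundaries
  out <- list(state_seq = states, transition_seq = trans,
              trial = trial, delay = delay,
              regime = config$transition_regime, noise = config$noise_level)
  class(out) <- "pcsm_truth"
  out
}

#' Simulate state-conditioned FIR-domain BOLD
#'
#' For each node and latent state a fixed amplitude is drawn once per subject
#' from the state's amplitude range; each observation is that amplitude plus
#' Gaussian noise at the configured level. Columns are z-scored per node
#' across all `K = n_trials * n_delays` timepoints.
#'
#' @param truth a `pcsm_truth` object from [simulate_state_sequence()].
#' @param config a [sim_config()] object.
#' @return a [fir_series()] object (K x N matrix view with trial/delay row
#'   index); the per-subject amplitude matrix (3 x N) is attached as
#'   `attr(, "amplitudes")`.
#' @export
simulate_fir_bold <- function(truth, config) {
  stopifnot(inherits(truth, "pcsm_truth"), inherits(config, "pcsm_sim_config"))
  K <- length(truth$state_seq)
  if (K != max(truth$trial) * config$n_delays)
    stop("invalid-input: truth dimensions inconsistent with config")
  N <- config$n_nodes
  amp <- matrix(0, 3L, N)
  for (c in 1:3) {
    rg <- config$state_amplitude_ranges[[c]]
    amp[c, ] <- stats::runif(N, rg[1], rg[2])
  }
  sd <- config$noise_sd_by_level[[config$noise_level]]
  Y <- amp[truth$state_seq, , drop = FALSE] +
    matrix(stats::rnorm(K * N, 0, sd), K, N)
  Y <- scale(Y)   # z-score per node across all timepoints
  attr(Y, "scaled:center") <- NULL
  attr(Y, "scaled:scale") <- NULL
  fs <- fir_series(Y, trial = truth$trial, delay = truth$delay, zscored = TRUE)
  attr(fs, "amplitudes") <- amp
  fs
}

#' Simulate one subject (behavior, ground truth, FIR-BOLD)
#'
#' Convenience wrapper seeding the RNG from `config$seed` and running
#' [simulate_behavior()], [simulate_state_sequence()] and
#' [simulate_fir_bold()] in sequence. Identical configs (including seed)
#' produce bit-identical outputs.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `trials`, `truth`, `fir`, `config`.
#' @export
simulate_subject <- function(config) {
  set.seed(config$seed)
  trials <- simulate_behavior(config)
  truth <- simulate_state_sequence(trials, config)
  fir <- simulate_fir_bold(truth, config)
  list(trials = trials, truth = truth, fir = fir, config = config)
}

#' Simulate a cohort balanced over transition regimes and noise levels
#'
#' Assigns subjects round-robin to the regime x noise grid and derives
#' per-subject seeds from `seed`, so the cohort is reproducible as a whole.
#'
#' @param n_subjects number of subjects.
#' @param seed cohort seed.
#' @param regimes,noise_levels factor levels to balance over.
#' @param ... further arguments passed to [sim_config()].
#' @return list of [simulate_subject()] results.
#' @export
simulate_cohort <- function(n_subjects, seed = 1L,
                            regimes = c("low", "medium", "high"),
                            noise_levels = c("low", "medium", "high", "very_high"),
                            ...) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  grid <- expand.grid(regime = regimes, noise = noise_levels,
                      stringsAsFactors = FALSE)
  lapply(seq_len(n_subjects), function(i) {
    g <- grid[((i - 1L) %% nrow(grid)) + 1L, ]
    cfg <- sim_config(transition_regime = g$regime, noise_level = g$noise,
                      seed = seeds[i], ...)
    simulate_subject(cfg)
  })
}
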