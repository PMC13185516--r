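# Shared fixtures. Small objects are rebuilt per file; the expensive cohort
# study used by the acceptance checks is computed once per session and
# memoized.

.pcsm_cache <- new.env(parent = emptyenv())

# Scaled study under the default generative conditions (full node count and
# trial count; reduced cohort size). Used by the acceptance checks and the
# regime-ordering property.
acceptance_study <- function() {
  if (is.null(.pcsm_cache$study)) {
    .pcsm_cache$study <- suppressMessages(run_pcsm_study(
      n_subjects = 108L, seed = 20260922L, verbose = FALSE))
  }
  .pcsm_cache$study
}

# A tiny cohort for wiring tests.
tiny_cohort <- function(n = 6L, seed = 11L, nodes = 24L, trials = 24L) {
  simulate_cohort(n, seed = seed, n_nodes = nodes, n_trials = trials)
}

# Deterministic small GMM-HMM parameter set (C states, M mixtures, N nodes)
# with well-separated state means; responding mixture last.
toy_hmm <- function(C = 3L, M = 2L, N = 6L, seed = 5L, sep = 3) {
  set.seed(seed)
  means <- array(0, c(C, M, N))
  vars <- array(0.25, c(C, M, N))
  for (c in seq_len(C)) {
    base <- stats::rnorm(N, 0, 0.3)
    means[c, M, ] <- base + sep * c / C
    if (M > 1) for (m in seq_len(M - 1)) means[c, m, ] <- base - 0.5 * m
  }
  trans <- matrix(0.15 / max(C - 1, 1), C, C)
  diag(trans) <- 0.85
  if (C == 1) trans <- matrix(1, 1, 1)
  w <- matrix(1 / M, C, M)
  p <- list(C = C, M = M, start = rep(1 / C, C), trans = trans,
            weights = w, means = pcsm:::flat_means_arr(means),
            vars = pcsm:::flat_means_arr(vars))
  hmm <- pcsm:::as_pcsm_hmm(p, N = N)
  hmm$spatial_cov <- diag(N)
  hmm
}

# Sample observations from a pcsm_hmm with per-trial segments of length D.
sample_gmmhmm <- function(hmm, n_trials = 40L, D = 5L, seed = 2L) {
  set.seed(seed)
  K <- n_trials * D
  states <- integer(K)
  Y <- matrix(0, K, hmm$N)
  t <- 1L
  for (r in seq_len(n_trials)) {
    for (d in seq_len(D)) {
      states[t] <- if (d == 1) sample.int(hmm$C, 1, prob = hmm$start_probs)
      else sample.int(hmm$C, 1, prob = hmm$transition[states[t - 1L], ])
      m <- sample.int(hmm$M, 1, prob = hmm$mixture_weights[states[t], ])
      Y[t, ] <- stats::rnorm(hmm$N, hmm$means[states[t], m, ],
                             sqrt(hmm$vars[states[t], m, ]))
      t <- t + 1L
    }
  }
  list(fir = fir_series(Y, trial = rep(seq_len(n_trials), each = D),
                        delay = rep(seq_len(D), n_trials)),
       states = states)
}

# Brute-force Poisson-binomial PMF over all 2^N outcomes.
pb_enumerate <- function(q) {
  N <- length(q)
  pmf <- numeric(N + 1)
  for (mask in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(mask))[1:N]
    pmf[sum(bits) + 1] <- pmf[sum(bits) + 1] +
      prod(ifelse(bits == 1, q, 1 - q))
  }
  pmf
}

# Direct (oracle) GMM-HMM emission density of one observation in one state.
oracle_state_density <- function(hmm, y, c) {
  total <- 0
  for (m in seq_len(hmm$M)) {
    total <- total + hmm$mixture_weights[c, m] *
      prod(stats::dnorm(y, hmm$means[c, m, ], sqrt(hmm$vars[c, m, ])))
  }
  total
}
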