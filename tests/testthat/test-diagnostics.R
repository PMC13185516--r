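# Decoding-quality diagnostics: P_t, rho_t, Mahalanobis discrepancy, flags.

fake_traj <- function(pi, trial = NULL, delay = NULL) {
  K <- nrow(pi)
  if (is.null(trial)) trial <- rep(1L, K)
  if (is.null(delay)) delay <- seq_len(K)
  structure(list(pi = pi, viterbi = max.col(pi), loglik = 0,
                 seq_lengths = as.integer(rle(trial)$lengths),
                 trial = trial, delay = delay, smoothing = "filtered"),
            class = "pcsm_posterior")
}

test_that("response probability is the posterior-weighted responding mass", {
  hmm <- toy_hmm()
  hmm$mixture_weights <- rbind(c(0.3, 0.7), c(0.5, 0.5), c(0.9, 0.1))
  tr <- fake_traj(rbind(c(1, 0, 0), rep(1 / 3, 3)))
  p <- response_probability(tr, hmm)
  expect_equal(p[1], 0.7)
  expect_equal(p[2], mean(c(0.7, 0.5, 0.1)))  # = 0.4333...
  # random posteriors against a direct dot-product oracle
  set.seed(1)
  Pi <- t(apply(matrix(rexp(15), 5), 1, function(x) x / sum(x)))
  pr <- response_probability(fake_traj(Pi), hmm)
  oracle <- sapply(1:5, function(t) sum(Pi[t, ] * hmm$mixture_weights[, 2]))
  expect_equal(pr, oracle, tolerance = 1e-12)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("temporal reliability is one minus total variation distance", {
  Pi <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.2, 0.5, 0.3))
  rho <- temporal_reliability(fake_traj(Pi))
  expect_equal(rho[1], 1)            # convention at the first timepoint
  expect_equal(rho[2], 1)            # identical posteriors
  expect_equal(rho[3], 0)            # maximal total variation
  expect_equal(rho[4], 1 - 0.5 * sum(abs(Pi[4, ] - Pi[3, ])))
  # random pairs against an independent half-L1 oracle
  set.seed(2)
  Q <- t(apply(matrix(rexp(30), 10), 1, function(x) x / sum(x)))
  r <- temporal_reliability(fake_traj(Q))
  for (t in 2:10)
    expect_equal(r[t], 1 - 0.5 * sum(abs(Q[t, ] - Q[t - 1, ])),
                 tolerance = 1e-12)
  sm <- temporal_reliability(fake_traj(Q), smooth = TRUE, halflife = 5)
  expect_true(all(sm >= 0 & sm <= 1))
})

test_that("Mahalanobis discrepancy matches a solve-based quadratic form", {
  hmm <- toy_hmm(N = 5L)
  set.seed(3)
  A <- matrix(rnorm(25), 5)
  hmm$spatial_cov <- crossprod(A) + diag(5) * 0.5
  Pi <- t(apply(matrix(rexp(12), 4), 1, function(x) x / sum(x)))
  Y <- matrix(rnorm(20), 4, 5)
  fir <- fir_series(Y, trial = rep(1L, 4), delay = 1:4)
  dm <- model_discrepancy(fir, hmm, fake_traj(Pi))
  mu_bar <- pcsm:::weighted_state_means(hmm)
  for (t in 1:4) {
    r <- Y[t, ] - as.numeric(Pi[t, ] %*% mu_bar)
    expect_equal(dm$raw[t], sum(r * solve(hmm$spatial_cov, r)),
                 tolerance = 1e-8)
  }
  expect_true(all(dm$raw >= 0))
  expect_true(all(dm$normalized > 0 & dm$normalized < 1))
})

test_that("zero residuals give zero discrepancy; identity covariance gives squared norm", {
  hmm <- toy_hmm(N = 4L)
  hmm$spatial_cov <- diag(4)
  mu_bar <- pcsm:::weighted_state_means(hmm)
  Pi <- rbind(c(1, 0, 0), c(0, 0, 1))
  Y <- rbind(mu_bar[1, ], mu_bar[3, ] + c(1, -1, 0.5, 0))
  fir <- fir_series(Y, trial = c(1L, 1L), delay = 1:2)
  dm <- model_discrepancy(fir, hmm, fake_traj(Pi))
  expect_equal(dm$raw[1], 0, tolerance = 1e-12)
  expect_equal(dm$raw[2], sum(c(1, -1, 0.5, 0)^2), tolerance = 1e-12)
})

test_that("scaling residuals by k multiplies raw discrepancy by k^2", {
  hmm <- toy_hmm(N = 4L)
  hmm$spatial_cov <- diag(4)
  mu_bar <- pcsm:::weighted_state_means(hmm)
  Pi <- matrix(rep(c(1, 0, 0), 3), 3, byrow = TRUE)
  R <- matrix(rnorm(12), 3, 4)
  f1 <- fir_series(sweep(R, 2, mu_bar[1, ], "+"), trial = rep(1L, 3), delay = 1:3)
  f2 <- fir_series(sweep(3 * R, 2, mu_bar[1, ], "+"), trial = rep(1L, 3), delay = 1:3)
  d1 <- model_discrepancy(f1, hmm, fake_traj(Pi))
  d2 <- model_discrepancy(f2, hmm, fake_traj(Pi))
  expect_equal(d2$raw, 9 * d1$raw, tolerance = 1e-10)
})

test_that("rank-normalized discrepancy is near-uniform on [0, 1]", {
  hmm <- toy_hmm(N = 4L)
  hmm$spatial_cov <- diag(4)
  set.seed(4)
  K <- 660
  Pi <- matrix(rep(c(1, 0, 0), K), K, byrow = TRUE)
  Y <- matrix(rnorm(K * 4), K, 4)
  fir <- fir_series(Y, trial = rep(1:132, each = 5), delay = rep(1:5, 132))
  dm <- model_discrepancy(fir, hmm, fake_traj(Pi))
  ks <- suppressWarnings(stats::ks.test(dm$normalized, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("frame and trial flagging follows the majority-of-bins rule", {
  th <- list(tau_maha = 0.8, tau_p = 0.2, tau_rho = 0.5)
  D <- 5L
  trial <- rep(1:3, each = D)
  p <- rep(0.9, 15); rho <- rep(0.9, 15); dm <- rep(0.1, 15)
  # trial 1: 3 of 5 bins fully flagged -> remove
  idx <- 1:3
  p[idx] <- 0.05; rho[idx] <- 0.1; dm[idx] <- 0.95
  # trial 2: 2 of 5 bins flagged -> keep
  idx <- D + (1:2)
  p[idx] <- 0.05; rho[idx] <- 0.1; dm[idx] <- 0.95
  # trial 3: high discrepancy but strong P and rho -> no removal flag
  dm[2 * D + (1:4)] <- 0.95
  fl <- flag_frames(p, rho, dm, trial, th)
  expect_equal(fl$trials$decision, c("remove", "keep", "keep"))
  expect_equal(sum(fl$frames$removal_flag), 5L)
  expect_true(all(fl$frames$removal_flag ==
                    (fl$frames$maha_flag & fl$frames$weak_p & fl$frames$weak_rho)))
  # no flags anywhere -> no removals
  fl0 <- flag_frames(rep(1, 15), rep(1, 15), rep(0, 15), trial, th)
  expect_equal(sum(fl0$frames$removal_flag), 0L)
  expect_true(all(fl0$trials$decision == "keep"))
  expect_error(flag_frames(p, rho, dm, trial, list(tau_maha = 0.8)),
               "invalid-input")
})
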