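# Emergent metrics: node posterior, Poisson-binomial D^SP, demand, resource,
# bottleneck, robust scaling.

fake_traj <- function(pi) {
  K <- nrow(pi)
  structure(list(pi = pi, viterbi = max.col(pi), loglik = 0,
                 seq_lengths = K, trial = rep(1L, K), delay = seq_len(K),
                 smoothing = "filtered"),
            class = "pcsm_posterior")
}

test_that("Poisson-binomial DP equals the closed forms and sums to one", {
  expect_equal(poisson_binomial_pmf(c(0.5, 0.5)), c(0.25, 0.5, 0.25))
  expect_equal(poisson_binomial_pmf(rep(1, 4)), c(0, 0, 0, 0, 1))
  expect_error(poisson_binomial_pmf(c(0.5, 1.2)), "invalid-input")
  set.seed(1)
  for (rep in 1:5) {
    q <- runif(10)
    pmf <- poisson_binomial_pmf(q)
    expect_equal(sum(pmf), 1, tolerance = 1e-10)
    expect_equal(pmf, pb_enumerate(q), tolerance = 1e-9)
  }
})

test_that("D^SP matches enumeration, stays in [0,1] and is reflection-symmetric", {
  expect_equal(serial_parallel_deviation(matrix(1, 1, 4)), 1.0)
  expect_equal(serial_parallel_deviation(matrix(0.5, 1, 2)), 0.5)
  set.seed(2)
  for (rep in 1:5) {
    q <- runif(12)
    d <- serial_parallel_deviation(matrix(q, 1))
    pmf <- pb_enumerate(q)
    oracle <- (2 / 12) * sum(abs(0:12 - 6) * pmf)
    expect_equal(d, oracle, tolerance = 1e-9)
    expect_true(d >= 0 && d <= 1)
    # q -> 1 - q reflects the count distribution about N/2
    expect_equal(serial_parallel_deviation(matrix(1 - q, 1)), d,
                 tolerance = 1e-9)
  }
  # row-parallel DP agrees with per-row evaluation
  Q <- matrix(runif(30), 5, 6)
  d_rows <- serial_parallel_deviation(Q)
  for (t in 1:5)
    expect_equal(d_rows[t], serial_parallel_deviation(Q[t, , drop = FALSE]),
                 tolerance = 1e-12)
})

test_that("node response posterior reduces to its degenerate closed forms", {
  hmm <- toy_hmm(N = 4L)
  K <- 3L
  set.seed(3)
  Pi <- t(apply(matrix(rexp(K * 3), K), 1, function(x) x / sum(x)))
  Y <- matrix(rnorm(K * 4), K, 4)
  fir <- fir_series(Y, trial = rep(1L, K), delay = 1:K)

  # responding weight 1 and equal densities: B = sum_c pi = 1
  h1 <- hmm
  h1$mixture_weights <- matrix(rep(c(0, 1), each = 3), 3, 2)
  for (c in 1:3) h1$means[c, 1, ] <- h1$means[c, 2, ]
  B1 <- node_response_posterior(fir, h1, fake_traj(Pi))
  expect_equal(B1, matrix(1, K, 4), tolerance = 1e-12, ignore_attr = TRUE)

  # equal densities at y: responsibilities equal the mixture weights
  h2 <- hmm
  h2$mixture_weights <- rbind(c(0.4, 0.6), c(0.8, 0.2), c(0.5, 0.5))
  for (c in 1:3) h2$means[c, 1, ] <- h2$means[c, 2, ]
  B2 <- node_response_posterior(fir, h2, fake_traj(Pi))
  expect_equal(B2, matrix(as.numeric(Pi %*% h2$mixture_weights[, 2]), K, 4),
               tolerance = 1e-12, ignore_attr = TRUE)

  # random instance against a per-node Bayes-rule oracle
  B3 <- node_response_posterior(fir, hmm, fake_traj(Pi))
  for (t in 1:K) for (n in 1:4) {
    g <- sapply(1:3, function(c) {
      num <- hmm$mixture_weights[c, 2] *
        dnorm(Y[t, n], hmm$means[c, 2, n], sqrt(hmm$vars[c, 2, n]))
      den <- sum(sapply(1:2, function(m) hmm$mixture_weights[c, m] *
                          dnorm(Y[t, n], hmm$means[c, m, n],
                                sqrt(hmm$vars[c, m, n]))))
      num / den
    })
    expect_equal(unname(B3[t, n]), sum(Pi[t, ] * g), tolerance = 1e-10)
  }
  expect_true(all(B3 >= 0 & B3 <= 1))
})

test_that("processing modes follow the two thresholds", {
  d <- c(0.50, 0.55, 0.70)
  expect_equal(classify_mode(d, 0.522, 0.612), c("parallel", "mixed", "serial"))
  expect_equal(classify_mode(0.522, 0.522, 0.612), "parallel")  # boundary
  expect_equal(classify_mode(0.612, 0.522, 0.612), "serial")
  expect_error(classify_mode(d, 0.7, 0.5), "invalid-input")
})

test_that("cognitive demand components match a hand computation", {
  # three timepoints, hand-constructed posteriors and d_sp
  Pi <- rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(0.5, 0.5, 0))
  d_sp <- c(0.2, 0.8, 0.8)
  out <- cognitive_demand(d_sp, fake_traj(Pi))
  U <- c(0, 1, 1)
  H <- c(0, -2 * 0.5 * log(0.5) / log(3), -2 * 0.5 * log(0.5) / log(3))
  kl <- function(p, q) sum(ifelse(p > 0, p * log(p / q), 0))
  Mid <- (Pi[1, ] + Pi[2, ]) / 2
  J2 <- (0.5 * kl(Pi[1, ], Mid) + 0.5 * kl(Pi[2, ], Mid)) / log(2)
  Jsteps <- c(J2, 0)                     # step 3 has identical posteriors
  dJ <- c(0, Jsteps - median(Jsteps))    # median over steps
  dU <- c(0, diff(U)); dH <- c(0, diff(H))
  syn <- abs(dU) * abs(dJ)
  S <- syn - median(syn)
  base <- -(dU + dH + dJ) / 3
  L <- base - mean(abs(base)) * S
  expect_equal(out$components$U, U)
  expect_equal(out$components$dH, dH, tolerance = 1e-12)
  expect_equal(out$components$dJ, dJ, tolerance = 1e-12)
  expect_equal(out$components$unscaled, L, tolerance = 1e-12)
  expect_equal(out$raw, robust_scale(L), tolerance = 1e-12)
  expect_true(all(out$squashed > -1 & out$squashed < 1))
})

test_that("constant trajectories yield zero unweighted demand", {
  Pi <- matrix(rep(c(0.6, 0.3, 0.1), 5), 5, byrow = TRUE)
  out <- cognitive_demand(rep(0.4, 5), fake_traj(Pi))
  expect_equal(out$components$unscaled, rep(0, 5))
  expect_equal(out$raw, rep(0, 5))  # degenerate scale convention
})

test_that("resource integrator matches its closed forms", {
  # dwell-derived leak: Dwell_med = 3 -> h = 6
  mode <- rep(c("serial", "parallel"), each = 3, times = 4)
  set.seed(4)
  L <- rnorm(24)
  res <- resource_level(L, mode)
  expect_equal(res$dwell_med, 3)
  expect_equal(res$h, 6)
  expect_equal(res$lambda, 1 - 2^(-1 / 6))
  expect_equal(res$alpha, sqrt((1 - (1 - res$lambda)^2) / var(L)))
  # recursion R_t = (1-lambda) R_{t-1} + alpha L_t with R_0 = 0
  R <- numeric(24); prev <- 0
  for (t in 1:24) { R[t] <- (1 - res$lambda) * prev + res$alpha * L[t]; prev <- R[t] }
  expect_equal(res$raw, R, tolerance = 1e-12)
  # zero input stays at zero
  expect_equal(resource_level(rep(0, 10), rep("mixed", 10))$raw, rep(0, 10))
})

test_that("integrator stationary variance is matched to unit scale", {
  set.seed(5)
  mode <- rep(c("serial", "mixed"), each = 3, times = 1000)
  L <- rnorm(6000)
  res <- resource_level(L, mode)
  expect_equal(var(res$raw), 1, tolerance = 0.1)
  # impulse response decays geometrically at rate (1 - lambda)
  imp <- resource_level(c(1, rep(0, 19)), rep("mixed", 20))
  expect_equal(imp$raw, imp$raw[1] * (1 - imp$lambda)^(0:19), tolerance = 1e-12)
})

test_that("serial bottleneck reproduces the worked example and edge cases", {
  # one serial episode of length 4, post-exit demand (-0.5, -0.5, -0.5)
  mode <- c(rep("serial", 4), rep("parallel", 3))
  L <- c(rnorm(4), -0.5, -0.5, -0.5)
  out <- serial_bottleneck(mode, L, pe_delta = 3L)
  expect_equal(out$persistence, 4)
  expect_equal(out$exit, 0.5)
  expect_equal(out$raw, 2.0)
  expect_equal(out$squashed, tanh(2.0))

  # episode ending within pe_delta of the series end is excluded from exits
  mode2 <- c(rep("serial", 2), "parallel", rep("serial", 3), "parallel")
  L2 <- rep(-1, 7)
  out2 <- serial_bottleneck(mode2, L2, pe_delta = 3L)
  expect_equal(out2$s_tot, 2L)
  expect_equal(out2$s_exit, 1L)          # only the first episode has 3 post bins
  expect_equal(out2$persistence, 2.5)

  # recovery after exit (positive demand) contributes zero exit cost
  out3 <- serial_bottleneck(c("serial", rep("mixed", 3)), c(0, 1, 1, 1))
  expect_equal(out3$raw, 0)

  # no serial episodes at all
  out0 <- serial_bottleneck(rep("parallel", 5), rnorm(5))
  expect_equal(out0$raw, 0)
  expect_true(out0$no_serial_episodes)
})

test_that("robust scaling uses the Gaussian consistency constant", {
  z <- robust_scale(c(-1, 0, 1))
  expect_equal(z, c(-0.6745, 0, 0.6745), tolerance = 1e-3)
  expect_equal(robust_scale(rep(3, 7)), rep(0, 7))  # degenerate scale
  set.seed(6)
  x <- rnorm(50)
  expect_equal(robust_scale(x),
               (x - median(x)) / (1.4826 * median(abs(x - median(x)))),
               tolerance = 1e-12)
  expect_true(all(abs(tanh_squash(robust_scale(x))) < 1))
})
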