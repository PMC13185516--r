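# GMM-HMM fitting, decoding, alignment and model-order selection.

test_that("emission density matches a direct weighted-sum-of-Gaussians oracle", {
  hmm <- toy_hmm(N = 5L)
  set.seed(1)
  Y <- matrix(rnorm(4 * 5), 4, 5)
  flat <- pcsm:::hmm_to_flat(hmm)
  logB <- pcsm:::state_loglik(
    pcsm:::component_logdens(Y, flat$means, flat$vars),
    log(flat$weights), hmm$C, hmm$M)
  for (t in 1:4) for (c in 1:hmm$C) {
    expect_equal(exp(logB[t, c]), oracle_state_density(hmm, Y[t, ], c),
                 tolerance = 1e-10)
  }
})

test_that("EM log-likelihood is non-decreasing and posteriors are normalized", {
  hmm <- toy_hmm()
  sam <- sample_gmmhmm(hmm, n_trials = 30L, seed = 3L)
  g <- fit_global(sam$fir, C = 3L, M = 2L, n_init = 2L, max_iter = 200L,
                  seed = 1L)
  st <- pcsm:::stack_fir(sam$fir)
  fit <- pcsm:::em_gmmhmm(st$Y, st$seq_lengths,
                          pcsm:::random_init_params(st$Y, 3L, 2L),
                          max_iter = 25L, tol = 0)
  expect_true(all(diff(fit$ll_trace) > -1e-8))
  traj <- infer_posteriors(g, sam$fir)
  expect_equal(rowSums(traj$pi), rep(1, nrow(traj$pi)), tolerance = 1e-8)
  smooth <- infer_posteriors(g, sam$fir, smoothing = "smoothed")
  expect_equal(rowSums(smooth$pi), rep(1, nrow(smooth$pi)), tolerance = 1e-8)
})

test_that("stochasticity is conserved by EM and alignment", {
  hmm <- toy_hmm()
  sam <- sample_gmmhmm(hmm, n_trials = 25L, seed = 9L)
  g <- fit_global(sam$fir, n_init = 2L, max_iter = 200L, seed = 2L)
  expect_equal(sum(g$start_probs), 1, tolerance = 1e-12)
  expect_equal(rowSums(g$transition), rep(1, 3), tolerance = 1e-12)
  expect_equal(rowSums(g$mixture_weights), rep(1, 3), tolerance = 1e-12)
  expect_true(all(g$vars > 0))
  al <- align_to_template(g, hmm)$aligned
  expect_equal(sum(al$start_probs), 1, tolerance = 1e-12)
  expect_equal(rowSums(al$transition), rep(1, 3), tolerance = 1e-12)
  expect_equal(rowSums(al$mixture_weights), rep(1, 3), tolerance = 1e-12)
})

test_that("parameters generating the data are recovered at low noise", {
  # fully identified generator: every (state, mixture) component has its own
  # well-separated mean level
  hmm <- toy_hmm(N = 8L)
  set.seed(21)
  for (c in 1:3) {
    base <- rnorm(8, 4 * c, 0.2)
    hmm$means[c, 1, ] <- base - 0.8   # non-responding level
    hmm$means[c, 2, ] <- base + 0.8   # responding level
  }
  hmm$vars[] <- 0.09
  sam <- sample_gmmhmm(hmm, n_trials = 300L, D = 5L, seed = 4L)
  g <- fit_global(sam$fir, C = 3L, M = 2L, n_init = 3L, max_iter = 150L,
                  seed = 3L)
  al <- align_to_template(g, hmm)$aligned
  # mixture-weighted state means recovered within 0.05 after alignment
  expect_equal(pcsm:::weighted_state_means(al),
               pcsm:::weighted_state_means(hmm), tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("subject fits keep the template variances bit-identical", {
  hmm <- toy_hmm()
  sam <- sample_gmmhmm(hmm, n_trials = 40L, seed = 5L)
  g <- fit_global(sam$fir, n_init = 2L, max_iter = 200L, seed = 5L)
  sam2 <- sample_gmmhmm(hmm, n_trials = 40L, seed = 6L)
  f <- fit_subject(sam2$fir, g, max_iter = 25L)
  expect_identical(f$vars, g$vars)
  expect_false(identical(f$transition, g$transition))
  # EM monotonicity: final log-likelihood at least the initialization's
  st <- pcsm:::stack_fir(sam2$fir)
  ll0 <- pcsm:::gmmhmm_data_loglik(pcsm:::hmm_to_flat_full(g), st$Y,
                                   st$seq_lengths)
  expect_gte(f$loglik, ll0 - 1e-6)
})

test_that("subject transition matrix self-recovers from template data", {
  hmm <- toy_hmm(N = 10L, sep = 4)
  sam <- sample_gmmhmm(hmm, n_trials = 120L, seed = 7L)
  f <- fit_subject(sam$fir, hmm, max_iter = 40L)
  al <- align_to_template(f, hmm)$aligned
  expect_lt(max(abs(al$transition - hmm$transition)), 0.1)
})

test_that("alignment is a likelihood-preserving relabeling for all 6 permutations", {
  hmm <- toy_hmm(N = 6L)
  sam <- sample_gmmhmm(hmm, n_trials = 15L, seed = 8L)
  st <- pcsm:::stack_fir(sam$fir)
  ll_ref <- pcsm:::gmmhmm_data_loglik(pcsm:::hmm_to_flat_full(hmm), st$Y,
                                      st$seq_lengths)
  perms <- pcsm:::all_permutations(3L)
  for (i in seq_len(nrow(perms))) {
    shuffled <- pcsm:::permute_hmm(hmm, perms[i, ])
    al <- align_to_template(shuffled, hmm)
    # round trip: alignment recovers the inverse permutation
    expect_equal(al$aligned$means, hmm$means, tolerance = 1e-12)
    # relabeling leaves the data likelihood untouched
    ll_s <- pcsm:::gmmhmm_data_loglik(pcsm:::hmm_to_flat_full(shuffled),
                                      st$Y, st$seq_lengths)
    ll_a <- pcsm:::gmmhmm_data_loglik(pcsm:::hmm_to_flat_full(al$aligned),
                                      st$Y, st$seq_lengths)
    expect_equal(ll_s, ll_ref, tolerance = 1e-8)
    expect_equal(ll_a, ll_ref, tolerance = 1e-8)
  }
  # aligning the template to itself is the identity
  self <- align_to_template(hmm, hmm)
  expect_equal(self$state_perm, 1:3)
})

test_that("decoding after alignment equals relabeled decoding (equivariance)", {
  hmm <- toy_hmm(N = 6L)
  sam <- sample_gmmhmm(hmm, n_trials = 20L, seed = 10L)
  perm <- c(3L, 1L, 2L)
  shuffled <- pcsm:::permute_hmm(hmm, perm)
  v_ref <- infer_posteriors(hmm, sam$fir)$viterbi
  v_shuf <- infer_posteriors(shuffled, sam$fir)$viterbi
  # relabel: state s in the shuffled model is perm[s] in the original
  expect_equal(perm[v_shuf], v_ref)
})

test_that("Viterbi matches exhaustive path search for short sequences", {
  hmm <- toy_hmm(N = 4L, sep = 1.5)
  set.seed(11)
  for (rep in 1:5) {
    K <- sample(4:8, 1)
    Y <- matrix(rnorm(K * 4, sample(-1:1, 1)), K, 4)
    fir <- fir_series(Y, trial = rep(1L, K), delay = seq_len(K))
    traj <- infer_posteriors(hmm, fir)
    flat <- pcsm:::hmm_to_flat(hmm)
    logB <- pcsm:::state_loglik(
      pcsm:::component_logdens(Y, flat$means, flat$vars),
      log(flat$weights), 3L, 2L)
    paths <- as.matrix(expand.grid(rep(list(1:3), K)))
    score <- apply(paths, 1, function(p) {
      lp <- log(hmm$start_probs[p[1]]) + logB[1, p[1]]
      if (K > 1) for (t in 2:K)
        lp <- lp + log(hmm$transition[p[t - 1], p[t]]) + logB[t, p[t]]
      lp
    })
    expect_equal(traj$viterbi_logp, max(score), tolerance = 1e-8)
    expect_equal(unname(traj$viterbi), unname(paths[which.max(score), ]))
  }
})

test_that("model order selection recovers the generating (C, M) and the null model", {
  # generating model: 3 states, 2 well-separated mixtures per state
  hmm <- toy_hmm(N = 10L)
  set.seed(31)
  for (c in 1:3) {
    base <- rnorm(10, 4 * c, 0.2)
    hmm$means[c, 1, ] <- base - 0.8
    hmm$means[c, 2, ] <- base + 0.8
  }
  hmm$vars[] <- 0.09
  subs <- lapply(1:10, function(i)
    sample_gmmhmm(hmm, n_trials = 40L, seed = 100 + i)$fir)
  sel <- select_model_order(subs, C_range = 2:4, M_range = 1:2, k_folds = 5L,
                            n_init = 2L, max_iter = 120L, seed = 1L)
  expect_equal(unname(sel$selected["C"]), 3)
  expect_equal(unname(sel$selected["M"]), 2)

  # single-Gaussian data: no higher order passes the gain criteria
  set.seed(2)
  null_subs <- lapply(1:6, function(i) {
    Y <- matrix(rnorm(150 * 6), 150, 6)
    fir_series(Y, trial = rep(1:30, each = 5), delay = rep(1:5, 30))
  })
  # higher-order fits on pure noise may legitimately stop at max_iter
  sel0 <- suppressWarnings(
    select_model_order(null_subs, C_range = 1:3, M_range = 1:2,
                       k_folds = 3L, n_init = 2L, max_iter = 60L,
                       seed = 2L))
  expect_equal(unname(sel0$selected["C"]), 1)
  expect_equal(unname(sel0$selected["M"]), 1)
})
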