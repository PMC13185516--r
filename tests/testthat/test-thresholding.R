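# Data-driven thresholds: mixture intersections, KDE valleys, quartile
# bootstrap, adaptive FDR.

test_that("separation d follows its closed form", {
  expect_equal(separation_d(0, 1, 2, 1), 2.0)
  expect_equal(separation_d(0, 1, 1, 1), 1.0)
  expect_equal(separation_d(5, 2, 5, 3), 0.0)
  expect_error(separation_d(0, 0, 1, 1), "invalid-input")
})

test_that("gaussian intersection solves the log-density equality", {
  # symmetric equal-variance case: midpoint
  expect_equal(pcsm:::gaussian_intersection(0.5, 0, 1, 0.5, 2, 1), 1.0)
  # unequal variances and weights against a fine-grid oracle
  set.seed(1)
  for (rep in 1:5) {
    m1 <- runif(1, -1, 0); m2 <- runif(1, 1, 2)
    s1 <- runif(1, 0.2, 0.8); s2 <- runif(1, 0.2, 0.8)
    w1 <- runif(1, 0.2, 0.8); w2 <- 1 - w1
    tau <- pcsm:::gaussian_intersection(w1, m1, s1, w2, m2, s2)
    grid <- seq(m1, m2, length.out = 200001)
    diffs <- abs(w1 * dnorm(grid, m1, s1) - w2 * dnorm(grid, m2, s2))
    expect_equal(tau, grid[which.min(diffs)], tolerance = 1e-4)
    # density equality at the returned intersection
    expect_lt(abs(w1 * dnorm(tau, m1, s1) - w2 * dnorm(tau, m2, s2)),
              1e-6 * w1 * dnorm(tau, m1, s1) + 1e-12)
  }
})

test_that("mixture threshold recovers the boundary of a bimodal sample", {
  set.seed(2)
  x <- c(rnorm(3000, 0.3, 0.05), rnorm(5000, 0.7, 0.06))
  th <- gmm_intersection_threshold(x, support = c(0, 1), seed = 1)
  expect_equal(th$method[1], "gmm_intersection")
  expect_equal(th$notes[1], "balanced")
  expect_gt(th$separation_d[1], 1.5)
  # population crossing point 0.4794 located by an independent grid oracle
  expect_equal(th$taus[1], 0.4794, tolerance = 0.03)
  expect_error(gmm_intersection_threshold(rnorm(50)), "invalid-input")
})

test_that("weight-gated fits fall back to the KDE valley when tails are disallowed", {
  set.seed(3)
  x <- c(rnorm(400, 0.15, 0.04), rnorm(7600, 0.75, 0.10))  # 5% minor mode
  th_tail <- gmm_intersection_threshold(x, support = c(0, 1), tail_ok = TRUE,
                                        seed = 1)
  th_kde <- gmm_intersection_threshold(x, support = c(0, 1), tail_ok = FALSE,
                                       kde_windows = list(c(0.2, 0.6)),
                                       seed = 1)
  expect_equal(th_tail$notes[1], "tail")
  expect_equal(th_tail$method[1], "gmm_intersection")
  expect_equal(th_kde$method[1], "kde_valley")
  expect_true(th_kde$taus[1] > 0.2 && th_kde$taus[1] < 0.6)
})

test_that("KDE valley finds the density minimum of a bimodal sample", {
  set.seed(4)
  x <- c(rnorm(4000, 0.25, 0.07), rnorm(4000, 0.75, 0.07))
  th <- kde_valley_threshold(x, support = c(0, 1), windows = list(c(0.3, 0.7)))
  # grid oracle on the same reflected-histogram density
  k <- pcsm:::reflected_kde(x, c(0, 1), n_bins = 512L)
  sel <- which(k$x >= 0.3 & k$x <= 0.7)
  expect_equal(th$taus[1], k$x[sel[which.min(k$y[sel])]], tolerance = 0.01)
  expect_lt(abs(th$taus[1] - 0.5), 0.05)
  expect_true(is.finite(th$drift[1]))
  # mirrored sample gives the mirrored valley
  th_m <- kde_valley_threshold(1 - x, support = c(0, 1),
                               windows = list(c(0.3, 0.7)))
  expect_equal(th_m$taus[1], 1 - th$taus[1], tolerance = 0.01)
})

test_that("KDE valley transforms affinely under affine rescaling", {
  set.seed(5)
  x <- c(rnorm(3000, 0.3, 0.05), rnorm(3000, 0.8, 0.05))
  t1 <- kde_valley_threshold(x, support = c(0, 1), windows = list(c(0.4, 0.7)),
                             sensitivity = FALSE)
  y <- 10 * x + 5
  t2 <- kde_valley_threshold(y, support = c(5, 15),
                             windows = list(c(9, 12)), sensitivity = FALSE)
  expect_equal(t2$taus[1], 10 * t1$taus[1] + 5, tolerance = 0.05)
  expect_error(
    kde_valley_threshold(x, support = c(0, 1), windows = list(c(0.95, 1))),
    "not-found")
})

test_that("quartile bootstrap reproduces normal quantiles and is deterministic", {
  set.seed(6)
  subj <- lapply(1:40, function(i) rnorm(500))
  th <- quartile_bootstrap_thresholds(subj, n_boot = 200L, seed = 9L)
  expect_equal(unname(th$taus["low"]), -0.6745, tolerance = 0.03)
  expect_equal(unname(th$taus["high"]), 0.6745, tolerance = 0.03)
  expect_true(th$accepted)
  th2 <- quartile_bootstrap_thresholds(subj, n_boot = 200L, seed = 9L)
  expect_identical(th$ci, th2$ci)
  expect_error(quartile_bootstrap_thresholds(subj[1:5]), "invalid-input")
})

test_that("adaptive FDR retains the largest admissible prefix", {
  r <- adaptive_fdr_select(c(0.99, 0.95, 0.90, 0.50), alpha = 0.10)
  expect_equal(sort(r$selected), 1:3)
  expect_equal(r$fdr_estimate, mean(1 - c(0.99, 0.95, 0.90)))
  expect_equal(r$realized_tau, 0.90)
  # perfect posteriors retain everything with zero error
  r1 <- adaptive_fdr_select(rep(1, 6), alpha = 0.05)
  expect_equal(length(r1$selected), 6L)
  expect_equal(r1$fdr_estimate, 0)
  # empty selection allowed
  r0 <- adaptive_fdr_select(rep(0.1, 4), alpha = 0.05)
  expect_equal(length(r0$selected), 0L)
  expect_equal(r0$fdr_estimate, 0)
  # stopping rule: realized error never exceeds alpha; monotone in alpha
  set.seed(7)
  for (rep in 1:10) {
    b <- runif(30)
    sizes <- sapply(c(0.05, 0.1, 0.2, 0.3), function(a) {
      r <- adaptive_fdr_select(b, a)
      expect_lte(r$fdr_estimate, a)
      length(r$selected)
    })
    expect_true(all(diff(sizes) >= 0))
  }
  expect_error(adaptive_fdr_select(runif(5), alpha = 0), "invalid-input")
})

test_that("BH mode agrees with p.adjust on 1 - B", {
  set.seed(8)
  b <- runif(20)
  r <- adaptive_fdr_select(b, 0.2, method = "bh")
  keep <- which(p.adjust(1 - b, "BH") <= 0.2)
  expect_setequal(r$selected, keep)
})
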