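# Data-driven decision boundaries: Gaussian-mixture density intersections
# with separation gating, boundary-corrected KDE valley selection, quartile
# bootstrap for unimodal metrics, and adaptive posterior-FDR node selection.

#' Cohen's-d-like component separation
#'
#' `d = |m2 - m1| / sqrt((s1^2 + s2^2) / 2)`; below 1 is weak, around 1
#' moderate, above 1.5 strong separation.
#'
#' @param m1,s1,m2,s2 means and standard deviations of the two components.
#' @return non-negative scalar.
#' @export
separation_d <- function(m1, s1, m2, s2) {
  if (s1 <= 0 || s2 <= 0) stop("invalid-input: standard deviations must be positive")
  abs(m2 - m1) / sqrt((s2^2 + s1^2) / 2)
}

# Intersection of two weighted Gaussian densities: the root of the quadratic
# obtained by equating log densities, restricted to (m1, m2).
gaussian_intersection <- function(w1, m1, s1, w2, m2, s2) {
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log((w1 * s2) / (w2 * s1))
  if (abs(a) < 1e-14) {
    if (abs(b) < 1e-14) return(NA_real_)
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(NA_real_)
    roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
  }
  lo <- min(m1, m2); hi <- max(m1, m2)
  inside <- roots[roots > lo & roots < hi]
  if (length(inside) == 0) return(NA_real_)
  inside[1]
}

# Univariate Gaussian-mixture fit with components sorted by mean. A
# maximum-likelihood fit is tried first; spike-heavy samples (many tied
# values) that defeat it are refit under mclust's default conjugate prior,
# which regularizes the component variances.
#' @importFrom mclust Mclust mclustBIC priorControl
fit_univariate_gmm <- function(samples, G) {
  fit <- tryCatch(
    mclust::Mclust(samples, G = G, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- mclust::Mclust(samples, G = G, modelNames = "V", verbose = FALSE,
                          prior = mclust::priorControl())
  if (is.null(fit)) return(NULL)
  mu <- as.numeric(fit$parameters$mean)
  sg <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sg) == 1) sg <- rep(sg, G)
  w <- as.numeric(fit$parameters$pro)
  o <- order(mu)
  list(w = w[o], m = mu[o], s = sg[o])
}

#' Gaussian-mixture intersection threshold
#'
#' Fits a `G`-component univariate Gaussian mixture to the pooled samples and
#' takes the density intersections between adjacent components (sorted by
#' mean) as candidate decision boundaries. Each intersection is gated on the
#' component separation (`d >= sep_gate`); an intersection whose components
#' pass separation but where one carries at most `weight_gate` of the density
#' is a tail threshold, retained when `tail_ok` and otherwise refined by
#' boundary-corrected KDE valley selection, as is any intersection failing
#' separation or lacking a real root between the means.
#'
#' @param samples numeric vector (>= 100 values).
#' @param support metric support `(lo, hi)` for the KDE fallback.
#' @param G number of mixture components (2 for single boundaries, 3 for a
#'   low/high pair).
#' @param weight_gate minimum component weight for a balanced split.
#' @param sep_gate minimum separation d.
#' @param tail_ok retain low-weight (tail) intersections instead of falling
#'   back to the KDE valley.
#' @param kde_windows list of `(lo, hi)` search windows for the KDE fallback,
#'   one per adjacent-component boundary (defaults to a window around the
#'   failing intersection or the midpoint of the component means).
#' @param seed seed for the mixture initialization subsample.
#' @return an object of class `pcsm_threshold`: list with `taus`, `method`
#'   per boundary, `separation_d`, `mixture_summary`, and any KDE details.
#' @export
gmm_intersection_threshold <- function(samples, support = range(samples),
                                       G = 2L, weight_gate = 0.20,
                                       sep_gate = 1.0, tail_ok = TRUE,
                                       kde_windows = NULL, seed = 1L) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 100) stop("invalid-input: need at least 100 samples")
  set.seed(seed)
  mix <- tryCatch(fit_univariate_gmm(samples, G), error = function(e) NULL)
  n_bound <- G - 1L
  taus <- rep(NA_real_, n_bound)
  method <- rep("gmm_intersection", n_bound)
  seps <- rep(NA_real_, n_bound)
  notes <- character(n_bound)
  kde_detail <- vector("list", n_bound)
  for (b in seq_len(n_bound)) {
    ok <- FALSE
    tau <- NA_real_
    if (!is.null(mix)) {
      w1 <- mix$w[b]; m1 <- mix$m[b]; s1 <- mix$s[b]
      w2 <- mix$w[b + 1]; m2 <- mix$m[b + 1]; s2 <- mix$s[b + 1]
      seps[b] <- separation_d(m1, s1, m2, s2)
      tau <- gaussian_intersection(w1, m1, s1, w2, m2, s2)
      balanced <- min(w1, w2) > weight_gate
      if (!is.na(tau) && seps[b] >= sep_gate && (balanced || tail_ok)) {
        taus[b] <- tau
        notes[b] <- if (balanced) "balanced" else "tail"
        ok <- TRUE
      }
    }
    if (!ok) {
      win <- if (!is.null(kde_windows) && length(kde_windows) >= b &&
                 !is.null(kde_windows[[b]])) kde_windows[[b]]
      else if (!is.null(mix)) {
        mid <- if (!is.na(tau)) tau else mean(mix$m[b:(b + 1)])
        c(max(support[1], mid - 0.1 * diff(support)),
          min(support[2], mid + 0.1 * diff(support)))
      } else support
      kv <- tryCatch(kde_valley_threshold(samples, support, windows = list(win)),
                     error = function(e) NULL)
      if (is.null(kv))   # no valley inside the window: search the full support
        kv <- tryCatch(kde_valley_threshold(samples, support,
                                            windows = list(support)),
                       error = function(e) NULL)
      if (is.null(kv)) {
        method[b] <- "kde_valley"
        notes[b] <- "not-found"
      } else {
        taus[b] <- kv$taus[1]
        method[b] <- "kde_valley"
        notes[b] <- "fallback"
        kde_detail[[b]] <- kv
      }
    }
  }
  structure(list(taus = taus, method = method, separation_d = seps,
                 notes = notes,
                 mixture_summary = mix, kde_detail = kde_detail,
                 support = support, n = length(samples)),
            class = "pcsm_threshold")
}

#' @export
print.pcsm_threshold <- function(x, ...) {
  cat("PCSM threshold(s):",
      paste(sprintf("%.4f [%s]", x$taus, x$method), collapse = ", "), "\n")
  if (!is.null(x$separation_d) && any(is.finite(x$separation_d)))
    cat("  separation d:", paste(round(x$separation_d, 3), collapse = ", "), "\n")
  invisible(x)
}

# Histogram smoothed by a Gaussian kernel with reflection at both support
# boundaries; returns bin centers and density heights.
reflected_kde <- function(samples, support, n_bins = 512L, bandwidth = NULL) {
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(samples)
  breaks <- seq(support[1], support[2], length.out = n_bins + 1L)
  width <- breaks[2] - breaks[1]
  h <- graphics::hist(pmin(pmax(samples, support[1]), support[2]),
                      breaks = breaks, plot = FALSE)
  dens <- h$density
  pad <- min(n_bins, max(1L, ceiling(4 * bandwidth / width)))
  padded <- c(rev(dens[seq_len(pad)]), dens, rev(dens)[seq_len(pad)])
  kx <- seq(-pad, pad) * width
  kern <- stats::dnorm(kx, 0, bandwidth)
  kern <- kern / sum(kern)
  sm <- stats::filter(padded, kern, sides = 2)
  sm <- as.numeric(sm)[(pad + 1L):(pad + n_bins)]
  list(x = h$mids, y = sm, bandwidth = bandwidth, n_bins = n_bins)
}

#' Boundary-corrected KDE valley threshold
#'
#' Builds an `n_bins` histogram on the support, reflects mass at both
#' boundaries before Gaussian smoothing, and returns the local density
#' minima restricted to the supplied windows. A sensitivity sweep over
#' `{0.5x, 1x, 2x}` bandwidth and `{256, 512, 1024}` bins reports the
#' maximum drift of each valley.
#'
#' @param samples numeric vector within the support.
#' @param support `(lo, hi)` support of the metric.
#' @param windows list of `(lo, hi)` windows, one valley each.
#' @param bandwidth Gaussian kernel bandwidth (default `bw.nrd0`).
#' @param n_bins histogram resolution.
#' @param sensitivity run the bandwidth/bin sweep.
#' @return a `pcsm_threshold` with `taus`, per-valley `drift`, and the
#'   smoothed density.
#' @export
kde_valley_threshold <- function(samples, support = range(samples),
                                 windows = list(support), bandwidth = NULL,
                                 n_bins = 512L, sensitivity = TRUE) {
  samples <- samples[is.finite(samples)]
  locate <- function(bw_mult, bins) {
    k <- reflected_kde(samples, support, n_bins = bins,
                       bandwidth = if (is.null(bandwidth))
                         stats::bw.nrd0(samples) * bw_mult
                       else bandwidth * bw_mult)
    vapply(windows, function(win) {
      sel <- which(k$x >= win[1] & k$x <= win[2])
      if (length(sel) < 3) return(NA_real_)
      y <- k$y[sel]
      # interior local minima within the window; a monotone or flat window
      # has no valley
      locmin <- sel[which(diff(sign(diff(y))) > 0) + 1L]
      if (length(locmin) == 0) return(NA_real_)
      k$x[locmin[which.min(k$y[locmin])]]
    }, numeric(1))
  }
  taus <- locate(1, n_bins)
  if (all(is.na(taus)))
    stop("not-found: no local density minimum inside the supplied window(s)")
  drift <- rep(NA_real_, length(taus))
  sweep_tab <- NULL
  if (sensitivity) {
    grid <- expand.grid(bw_mult = c(0.5, 1, 2), bins = c(256L, 512L, 1024L))
    vals <- t(apply(grid, 1, function(g) locate(g[["bw_mult"]], as.integer(g[["bins"]]))))
    if (length(taus) == 1) vals <- matrix(vals, ncol = 1)
    drift <- vapply(seq_along(taus), function(i)
      max(abs(vals[, i] - taus[i]), na.rm = TRUE), numeric(1))
    sweep_tab <- cbind(grid, vals)
  }
  k <- reflected_kde(samples, support, n_bins = n_bins, bandwidth = bandwidth)
  structure(list(taus = taus, method = rep("kde_valley", length(taus)),
                 drift = drift, sensitivity = sweep_tab, density = k,
                 support = support, windows = windows, n = length(samples)),
            class = "pcsm_threshold")
}

#' Quartile-bootstrap thresholds for unimodal metrics
#'
#' Robust-standardizes the pooled values (median/MAD with the 1.4826
#' consistency factor) and takes the 25th/75th percentiles as the low/high
#' thresholds. A nonparametric bootstrap across subjects (default 2000
#' resamples) yields 95% confidence intervals; the thresholds are accepted
#' when the CI of the high-low difference excludes 0 and the separation
#' between the below-low and above-high subsets exceeds `d = 1`.
#'
#' @param subject_values list of per-subject numeric vectors (>= 10 subjects).
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @return a `pcsm_threshold` with `taus` (low, high), `ci` (2 x 2 matrix),
#'   `separation_d` and `accepted`.
#' @export
quartile_bootstrap_thresholds <- function(subject_values, n_boot = 2000L,
                                          seed = 1L) {
  if (length(subject_values) < 10) stop("invalid-input: need at least 10 subjects")
  pooled <- unlist(subject_values, use.names = FALSE)
  z_list <- {
    ctr <- stats::median(pooled)
    scl <- 1.4826 * stats::median(abs(pooled - ctr))
    if (!is.finite(scl) || scl == 0) scl <- 1
    lapply(subject_values, function(v) (v - ctr) / scl)
  }
  z <- unlist(z_list, use.names = FALSE)
  taus <- stats::quantile(z, c(0.25, 0.75), names = FALSE, type = 7)
  set.seed(seed)
  n_sub <- length(z_list)
  boot <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    zi <- unlist(z_list[sample.int(n_sub, n_sub, replace = TRUE)],
                 use.names = FALSE)
    boot[b, ] <- stats::quantile(zi, c(0.25, 0.75), names = FALSE, type = 7)
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
  colnames(ci) <- c("low", "high")
  diff_ci <- stats::quantile(boot[, 2] - boot[, 1], c(0.025, 0.975))
  lo_set <- z[z < taus[1]]; hi_set <- z[z > taus[2]]
  sep <- if (length(lo_set) > 1 && length(hi_set) > 1)
    separation_d(mean(lo_set), stats::sd(lo_set),
                 mean(hi_set), stats::sd(hi_set)) else NA_real_
  accepted <- isTRUE(diff_ci[1] > 0) && isTRUE(sep > 1)
  structure(list(taus = c(low = taus[1], high = taus[2]),
                 method = "quartile_bootstrap", ci = ci,
                 diff_ci = diff_ci, separation_d = sep, accepted = accepted,
                 n = length(z), n_subjects = n_sub),
            class = "pcsm_threshold")
}

#' Adaptive posterior-FDR node selection
#'
#' Treats `1 - B` as the local false-discovery estimate of calling a node
#' responding, sorts nodes by descending posterior and retains the largest
#' prefix whose mean posterior error stays at or below `alpha`. The realized
#' error is therefore conservative (never above `alpha`) by construction.
#'
#' @param b_row vector of node response posteriors in `[0, 1]`.
#' @param alpha target false-discovery level in `(0, 1)`.
#' @param method `"posterior_prefix"` (default) or `"bh"`
#'   (Benjamini-Hochberg on `1 - B` as an alternate mode).
#' @return list with `selected` (node indices), `realized_tau` (smallest
#'   retained posterior; `NA` when empty), and `fdr_estimate` (mean prefix
#'   error; 0 when empty).
#' @export
adaptive_fdr_select <- function(b_row, alpha,
                                method = c("posterior_prefix", "bh")) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop("invalid-input: alpha must be in (0, 1)")
  o <- order(b_row, decreasing = TRUE)
  if (method == "bh") {
    p <- 1 - b_row
    keep <- which(stats::p.adjust(p, method = "BH") <= alpha)
    sel <- o[o %in% keep]
  } else {
    err <- cumsum(1 - b_row[o]) / seq_along(o)
    k <- max(c(0L, which(err <= alpha)))
    sel <- if (k > 0) o[seq_len(k)] else integer(0)
  }
  fdr <- if (length(sel) > 0) mean(1 - b_row[sel]) else 0
  tau <- if (length(sel) > 0) min(b_row[sel]) else NA_real_
  list(selected = sel, realized_tau = tau, fdr_estimate = fdr)
}
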