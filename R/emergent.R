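# Emergent cognitive metrics derived from posterior structure: node response
# posteriors, Poisson-binomial serial-parallel deviation, cognitive demand,
# leaky-integrator resource level, and the serial-bottleneck scalar.

#' Robust scaling and tanh squashing
#'
#' `robust_scale` standardizes by the median and the MAD with the Gaussian
#' consistency constant: `z = (x - median(x)) / (1.4826 * MAD(x))` (MAD here
#' is the raw median absolute deviation). A degenerate scale (MAD = 0) yields
#' the zero vector. `tanh_squash` maps any real vector into `(-1, 1)`.
#'
#' @param x numeric vector.
#' @param center optional pre-computed center (e.g. a cohort value).
#' @param scale optional pre-computed scale (1.4826 * MAD equivalent).
#' @return numeric vector of the same length.
#' @export
robust_scale <- function(x, center = NULL, scale = NULL) {
  if (length(x) == 0) stop("invalid-input: empty vector")
  if (is.null(center)) center <- stats::median(x)
  if (is.null(scale)) scale <- 1.4826 * stats::median(abs(x - stats::median(x)))
  if (!is.finite(scale) || scale == 0) return(rep(0, length(x)))
  (x - center) / scale
}

#' @rdname robust_scale
#' @param z numeric vector of standardized values.
#' @export
tanh_squash <- function(z) tanh(z)

#' Node response posterior B_{t,n}
#'
#' State-marginalized posterior probability that node `n` is responding at
#' time `t`: per node, the responding-mixture responsibility
#' `gamma_{t,c,m}(n)` is computed from univariate Gaussian densities weighted
#' by the mixture weights, then `B_{t,n} = sum_c pi_{t,c} gamma_{t,c,resp}(n)`.
#' Nodes with vanishing total density fall back to the mixture weights.
#'
#' @param fir the subject's [fir_series()].
#' @param params a `pcsm_hmm`.
#' @param traj the matching [infer_posteriors()] trajectory.
#' @return a K x N matrix with entries in `[0, 1]`.
#' @export
node_response_posterior <- function(fir, params, traj) {
  stopifnot(inherits(params, "pcsm_hmm"), inherits(traj, "pcsm_posterior"))
  Y <- fir$values
  K <- nrow(Y); N <- ncol(Y)
  C <- params$C; M <- params$M; resp <- params$responding
  B <- matrix(0, K, N)
  for (c in seq_len(C)) {
    # per-node log densities for each mixture of this state
    lognum <- NULL
    logall <- vector("list", M)
    for (m in seq_len(M)) {
      mu <- matrix(params$means[c, m, ], K, N, byrow = TRUE)
      sd <- matrix(sqrt(params$vars[c, m, ]), K, N, byrow = TRUE)
      logall[[m]] <- log(pmax(params$mixture_weights[c, m],
                              .Machine$double.xmin)) +
        stats::dnorm(Y, mu, sd, log = TRUE)
    }
    mx <- Reduce(pmax, logall)
    denom <- Reduce(`+`, lapply(logall, function(L) exp(L - mx)))
    g_resp <- exp(logall[[resp]] - mx) / denom
    bad <- !is.finite(g_resp)
    if (any(bad)) g_resp[bad] <- params$mixture_weights[c, resp]
    B <- B + traj$pi[, c] * g_resp
  }
  pmin(pmax(B, 0), 1)   # floating-point guard only
  }

#' Exact Poisson-binomial probability mass function
#'
#' PMF of the number of successes among independent Bernoulli trials with
#' probabilities `q`, computed by iterative convolution (dynamic programming,
#' O(N^2)); exact up to floating point, sums to 1 within 1e-10.
#'
#' @param q vector of success probabilities in `[0, 1]`.
#' @return numeric vector of length `length(q) + 1` giving `P(K = 0..N)`.
#' @export
poisson_binomial_pmf <- function(q) {
  if (any(q < 0 | q > 1)) stop("invalid-input: probabilities must lie in [0, 1]")
  pmf <- 1
  for (p in q) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  pmf
}

# D^SP for every row of a K x N matrix of responding probabilities, sharing
# one DP sweep across timepoints (row-parallel convolution).
pb_absdev_rows <- function(Q) {
  K <- nrow(Q); N <- ncol(Q)
  P <- matrix(0, K, N + 1)
  P[, 1] <- 1
  for (n in seq_len(N)) {
    q <- Q[, n]
    P <- P * (1 - q) + cbind(0, P[, -(N + 1), drop = FALSE] * q)
  }
  w <- abs(0:N - N / 2)
  as.numeric((2 / N) * (P %*% w))
}

#' Serial-parallel deviation D^SP
#'
#' Normalized expected deviation of the responding-node count from half the
#' nodes: `D_t = (2/N) * E|K_t - N/2|` where `K_t` follows the
#' Poisson-binomial distribution with per-node probabilities `B_{t,n}`.
#' High values indicate serial (polarized) processing, low values parallel
#' (distributed) processing; the `2/N` factor normalizes across node counts.
#'
#' @param B a K x N matrix from [node_response_posterior()] (or one row).
#' @return numeric vector of length K with values in `[0, 1]`.
#' @export
serial_parallel_deviation <- function(B) {
  if (is.null(dim(B))) B <- matrix(B, 1)
  if (ncol(B) == 0) stop("invalid-input: N must be positive")
  if (any(B < -1e-12 | B > 1 + 1e-12)) stop("invalid-input: B outside [0, 1]")
  pb_absdev_rows(pmin(pmax(B, 0), 1))
}

#' Classify processing mode from D^SP
#'
#' @param d_sp vector of serial-parallel deviations.
#' @param tau_low,tau_high decision boundaries with `tau_low < tau_high`:
#'   `parallel` when `d_sp <= tau_low`, `serial` when `d_sp >= tau_high`,
#'   otherwise `mixed`.
#' @return character vector of labels.
#' @export
classify_mode <- function(d_sp, tau_low, tau_high) {
  if (!(tau_low < tau_high)) stop("invalid-input: tau_low must be < tau_high")
  ifelse(d_sp <= tau_low, "parallel", ifelse(d_sp >= tau_high, "serial", "mixed"))
}

# Jensen-Shannon divergence between consecutive rows of a probability
# matrix (natural log, normalized by ln 2 so the result lies in [0, 1]).
js_divergence_steps <- function(P) {
  K <- nrow(P)
  if (K < 2) return(numeric(0))
  A <- P[-K, , drop = FALSE]; B <- P[-1, , drop = FALSE]
  Mid <- (A + B) / 2
  kl <- function(X, Y) rowSums(ifelse(X > 0, X * (log(X) - log(Y)), 0))
  (0.5 * kl(A, Mid) + 0.5 * kl(B, Mid)) / log(2)
}

#' Cognitive demand L^demand
#'
#' Signed moment-to-moment flow between processing strain and recovery.
#' Components: `U` = min-max normalized D^SP (processing mode potential);
#' `H` = normalized posterior entropy; `J` = Jensen-Shannon divergence
#' between successive posteriors, centered at its median; the synergy term
#' `S_t = |dU_t| * |dJ_t| - median(|dU| * |dJ|)` upweights steps with
#' concurrent mode and state changes, weighted by `omega_syn`, the mean
#' absolute magnitude of the unweighted demand. The instantaneous demand is
#' `L_t = -(dU_t + dH_t + dJ_t)/3 - omega_syn * S_t`; all deltas at the first
#' timepoint are 0. Negative values indicate increased demand, positive
#' values recovery. The raw series is median/MAD-standardized and the
#' squashed series is its tanh, bounded in `(-1, 1)`.
#'
#' @param d_sp serial-parallel deviation series.
#' @param traj the matching [infer_posteriors()] trajectory.
#' @return list with `raw` (robust-standardized series used downstream),
#'   `squashed` (tanh), and `components` (U, H, J, deltas, S, omega_syn).
#' @export
cognitive_demand <- function(d_sp, traj) {
  stopifnot(inherits(traj, "pcsm_posterior"))
  K <- length(d_sp)
  if (K < 2) stop("invalid-input: need at least two timepoints")
  if (K != nrow(traj$pi)) stop("invalid-input: series lengths differ")
  rngU <- range(d_sp)
  U <- if (diff(rngU) > 0) (d_sp - rngU[1]) / diff(rngU) else rep(0, K)
  Pi <- pmax(traj$pi, 0)
  H <- -rowSums(ifelse(Pi > 0, Pi * log(Pi), 0)) / log(ncol(Pi))
  Jsteps <- js_divergence_steps(traj$pi)
  dU <- c(0, diff(U))
  dH <- c(0, diff(H))
  dJ <- c(0, Jsteps - stats::median(Jsteps))
  syn_prod <- abs(dU) * abs(dJ)
  S <- syn_prod - stats::median(syn_prod)
  base <- -(dU + dH + dJ) / 3
  omega_syn <- mean(abs(base))
  L <- base - omega_syn * S
  raw <- robust_scale(L)
  list(raw = raw, squashed = tanh_squash(raw),
       components = list(U = U, H = H, J = c(0, Jsteps), dU = dU, dH = dH,
                         dJ = dJ, S = S, omega_syn = omega_syn,
                         unscaled = L))
}

#' Resource level R^level
#'
#' Cumulative availability of control resources as a discrete-time leaky
#' integrator over the demand series: `R_t = (1 - lambda) R_{t-1} + alpha L_t`
#' with `R_0 = 0`. The leak rate derives from an individual data-driven
#' half-life `h = max(3, 2 * Dwell_med)` (Dwell_med = median dwell time in
#' processing modes), `lambda = 1 - 2^(-1/h)`; the input gain
#' `alpha = sqrt((1 - (1 - lambda)^2) / Var(L))` matches the integrator's
#' stationary variance to unit-scaled demand. The squashed series is the tanh
#' of the robust-standardized integrator output.
#'
#' @param l_demand_raw robust-standardized demand series (from
#'   [cognitive_demand()]`$raw`).
#' @param mode processing-mode labels (for the dwell computation).
#' @return list with `raw`, `squashed`, and parameters `lambda`, `h`,
#'   `dwell_med`, `alpha`.
#' @export
resource_level <- function(l_demand_raw, mode) {
  stopifnot(length(l_demand_raw) == length(mode))
  dwell_med <- stats::median(rle(as.character(mode))$lengths)
  h <- max(3, 2 * dwell_med)
  lambda <- 1 - 2^(-1 / h)
  v <- stats::var(l_demand_raw)
  if (!is.finite(v) || v == 0) {
    alpha <- 0
    message("constant demand series: resource gain alpha set to 0")
  } else {
    alpha <- sqrt((1 - (1 - lambda)^2) / v)
  }
  R <- as.numeric(stats::filter(alpha * l_demand_raw, 1 - lambda,
                                method = "recursive"))
  list(raw = R, squashed = tanh_squash(robust_scale(R)),
       lambda = lambda, h = h, dwell_med = dwell_med, alpha = alpha)
}

#' Serial bottleneck S^bottleneck
#'
#' Scalar integrating the persistence of serial processing and the effort
#' required to disengage. Serial episodes are maximal contiguous runs labeled
#' `serial`; the persistence factor is the mean episode length. For episodes
#' whose final timepoint has at least `pe_delta` subsequent timepoints, the
#' exit cost is `max(0, -(1/pe_delta) * sum of the next pe_delta demand
#' values)` (demand is negative under strain, so a positive cost means
#' post-exit strain); the exit factor is their mean. The raw bottleneck is
#' persistence x exit; with no serial episodes it is 0 (flagged).
#'
#' @param mode processing-mode labels.
#' @param l_demand_raw robust-standardized demand series.
#' @param pe_delta post-exit window length in timepoints.
#' @return list with `raw`, `squashed` (tanh of raw; cohort-level scaling is
#'   applied by the study pipeline), `persistence`, `exit`, episode counts
#'   `s_tot`, `s_exit`, and flags.
#' @export
serial_bottleneck <- function(mode, l_demand_raw, pe_delta = 3L) {
  stopifnot(length(mode) == length(l_demand_raw))
  K <- length(mode)
  r <- rle(as.character(mode) == "serial")
  ends <- cumsum(r$lengths)
  serial_runs <- which(r$values)
  s_tot <- length(serial_runs)
  if (s_tot == 0) {
    return(list(raw = 0, squashed = tanh(0), persistence = 0, exit = 0,
                s_tot = 0L, s_exit = 0L, no_serial_episodes = TRUE,
                no_exit_data = TRUE))
  }
  lengths <- r$lengths[serial_runs]
  persistence <- mean(lengths)
  t_e <- ends[serial_runs]
  usable <- t_e + pe_delta <= K
  s_exit <- sum(usable)
  if (s_exit == 0) {
    exit_factor <- 0
  } else {
    exit_factor <- mean(vapply(t_e[usable], function(te) {
      max(0, -mean(l_demand_raw[(te + 1):(te + pe_delta)]))
    }, numeric(1)))
  }
  raw <- persistence * exit_factor
  list(raw = raw, squashed = tanh(raw), persistence = persistence,
       exit = exit_factor, s_tot = as.integer(s_tot),
       s_exit = as.integer(s_exit), no_serial_episodes = FALSE,
       no_exit_data = s_exit == 0L)
}

#' Cohort-level squashing of subject bottleneck values
#'
#' Centers the cohort's raw bottleneck scalars at their mean with a robust
#' (MAD-based) spread before the tanh. The raw persistence-times-exit product
#' is non-negative and strongly right-skewed, so mean-centering places the
#' bulk of ordinary subjects below zero and isolates the long upper tail of
#' persistent bottlenecks; a median-centered transform would instead pin half
#' the cohort below zero by construction.
#'
#' @param raw vector of per-subject raw bottleneck values.
#' @return vector of squashed values in `(-1, 1)`.
#' @export
squash_bottleneck_cohort <- function(raw) {
  scale <- 1.4826 * stats::median(abs(raw - stats::median(raw)))
  if (!is.finite(scale) || scale == 0) return(tanh(raw - mean(raw)))
  tanh((raw - mean(raw)) / scale)
}
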