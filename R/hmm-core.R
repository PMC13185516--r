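# Internal GMM-HMM machinery: diagonal-covariance Gaussian-mixture emissions,
# scaled forward-backward over trial-segmented sequences, Viterbi, and EM
# (Baum-Welch) updates. Sequences are grouped by length so the recursions
# vectorize across segments (all trials share the FIR bin count D).

logsumexp_rows <- function(M) {
  mx <- do.call(pmax, c(as.data.frame(M), list(-Inf)))
  mx + log(rowSums(exp(M - mx)))
}

# K x (C*M) per-component log densities under diagonal Gaussians.
# means/vars: (C*M) x N matrices, component index cm = (c-1)*M + m.
component_logdens <- function(Y, means, vars) {
  IV <- 1 / vars
  const <- -0.5 * rowSums(log(2 * pi * vars)) - 0.5 * rowSums(means^2 * IV)
  A1 <- (Y * Y) %*% t(IV)
  A2 <- Y %*% t(means * IV)
  sweep(A2 - 0.5 * A1, 2, const, "+")
}

# State emission log-likelihoods: logsumexp over mixture components.
state_loglik <- function(logdens, logw, C, M) {
  K <- nrow(logdens)
  logB <- matrix(-Inf, K, C)
  for (c in seq_len(C)) {
    cols <- ((c - 1) * M + 1):(c * M)
    Lm <- sweep(logdens[, cols, drop = FALSE], 2, logw[c, ], "+")
    logB[, c] <- logsumexp_rows(Lm)
  }
  logB
}

# Row index matrix [segment, step] for all segments of a given length.
segment_groups <- function(seq_lengths) {
  ends <- cumsum(seq_lengths)
  starts <- ends - seq_lengths + 1L
  out <- list()
  for (L in sort(unique(seq_lengths))) {
    sel <- which(seq_lengths == L)
    idx <- matrix(0L, length(sel), L)
    for (d in seq_len(L)) idx[, d] <- starts[sel] + d - 1L
    out[[as.character(L)]] <- idx
  }
  out
}

# Scaled forward(-backward) pass over segmented sequences.
# Returns filtered posteriors, smoothed posteriors, transition/start
# accumulators for EM, and the total log-likelihood.
forward_backward <- function(logB, seq_lengths, start, trans,
                             backward = TRUE) {
  K <- nrow(logB); C <- ncol(logB)
  rmax <- do.call(pmax, c(as.data.frame(logB), list(-Inf)))
  rmax[!is.finite(rmax)] <- 0   # all -Inf row: renormalized below
  Bsh <- exp(logB - rmax)
  filt <- matrix(0, K, C)
  gamma <- if (backward) matrix(0, K, C) else NULL
  trans_num <- matrix(0, C, C)
  start_num <- numeric(C)
  loglik <- sum(rmax)
  groups <- segment_groups(seq_lengths)
  for (idx in groups) {
    S <- nrow(idx); L <- ncol(idx)
    alphas <- vector("list", L)
    cs <- matrix(0, S, L)
    A <- matrix(start, S, C, byrow = TRUE) * Bsh[idx[, 1], , drop = FALSE]
    r <- rowSums(A); r[r <= 0] <- .Machine$double.xmin
    A <- A / r; cs[, 1] <- r; alphas[[1]] <- A
    if (L > 1) for (d in 2:L) {
      A <- (A %*% trans) * Bsh[idx[, d], , drop = FALSE]
      r <- rowSums(A); r[r <= 0] <- .Machine$double.xmin
      A <- A / r; cs[, d] <- r; alphas[[d]] <- A
    }
    for (d in seq_len(L)) filt[idx[, d], ] <- alphas[[d]]
    loglik <- loglik + sum(log(cs))
    if (!backward) next
    beta <- matrix(1, S, C)
    gamma[idx[, L], ] <- alphas[[L]]
    if (L > 1) for (d in (L - 1):1) {
      W <- Bsh[idx[, d + 1], , drop = FALSE] * beta / cs[, d + 1]
      trans_num <- trans_num + trans * crossprod(alphas[[d]], W)
      beta <- W %*% t(trans)
      g <- alphas[[d]] * beta
      g <- g / pmax(rowSums(g), .Machine$double.xmin)
      gamma[idx[, d], ] <- g
    }
    start_num <- start_num + colSums(gamma[idx[, 1], , drop = FALSE])
  }
  list(filtered = filt, gamma = gamma, trans_num = trans_num,
       start_num = start_num, loglik = loglik)
}

# Most probable state path per segment (log-space max-product).
viterbi_decode <- function(logB, seq_lengths, start, trans) {
  K <- nrow(logB); C <- ncol(logB)
  lstart <- log(pmax(start, .Machine$double.xmin))
  ltrans <- log(pmax(trans, .Machine$double.xmin))
  path <- integer(K)
  logp <- 0
  for (idx in segment_groups(seq_lengths)) {
    S <- nrow(idx); L <- ncol(idx)
    delta <- matrix(lstart, S, C, byrow = TRUE) + logB[idx[, 1], , drop = FALSE]
    psi <- array(0L, c(S, C, L))
    if (L > 1) for (d in 2:L) {
      newdelta <- matrix(0, S, C)
      for (j in seq_len(C)) {
        tmp <- delta + matrix(ltrans[, j], S, C, byrow = TRUE)
        arg <- max.col(tmp, ties.method = "first")
        psi[, j, d] <- arg
        newdelta[, j] <- tmp[cbind(seq_len(S), arg)]
      }
      delta <- newdelta + logB[idx[, d], , drop = FALSE]
    }
    p <- max.col(delta, ties.method = "first")
    logp <- logp + sum(delta[cbind(seq_len(S), p)])
    path[idx[, L]] <- p
    if (L > 1) for (d in (L - 1):1) {
      p <- psi[cbind(seq_len(S), p, d + 1L)]
      path[idx[, d]] <- p
    }
  }
  list(path = path, logp = logp)
}

# Per-timepoint mixture responsibilities gamma_{t,c,m}, K x (C*M).
# Rows where a state's total density underflows fall back to the mixture
# weights (logged via attribute).
mixture_responsibilities <- function(logdens, logB, gamma, logw, C, M) {
  K <- nrow(logdens)
  GCM <- matrix(0, K, C * M)
  fallback <- FALSE
  for (c in seq_len(C)) {
    cols <- ((c - 1) * M + 1):(c * M)
    Lm <- sweep(logdens[, cols, drop = FALSE], 2, logw[c, ], "+")
    r <- exp(Lm - logB[, c])
    bad <- !is.finite(logB[, c])
    if (any(bad)) {
      r[bad, ] <- matrix(exp(logw[c, ]), sum(bad), M, byrow = TRUE)
      fallback <- TRUE
    }
    GCM[, cols] <- r * gamma[, c]
  }
  attr(GCM, "weight_fallback") <- fallback
  GCM
}

# One full Baum-Welch run from given parameters.
# params: list(C, M, start, trans, weights (CxM), means ((C*M)xN),
#              vars ((C*M)xN))
em_gmmhmm <- function(Y, seq_lengths, params, max_iter = 100L, tol = 1e-4,
                      freeze_var = FALSE, var_floor = 1e-6) {
  K <- nrow(Y)
  C <- params$C; M <- params$M
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  floored <- FALSE
  for (iter in seq_len(max_iter)) {
    logw <- log(pmax(params$weights, .Machine$double.xmin))
    logdens <- component_logdens(Y, params$means, params$vars)
    logB <- state_loglik(logdens, logw, C, M)
    fb <- forward_backward(logB, seq_lengths, params$start, params$trans)
    ll <- fb$loglik / K
    ll_trace <- c(ll_trace, ll)
    GCM <- mixture_responsibilities(logdens, logB, fb$gamma, logw, C, M)
    # M-step
    start <- fb$start_num / sum(fb$start_num)
    trans <- fb$trans_num
    rs <- rowSums(trans)
    trans <- ifelse(rs > 0, 1, 0) * trans / ifelse(rs > 0, rs, 1)
    trans[rs == 0, ] <- params$trans[rs == 0, ]   # state never left: keep row
    csum <- colSums(GCM)
    gsum <- colSums(fb$gamma)
    W <- matrix(csum, C, M, byrow = TRUE) / pmax(gsum, .Machine$double.xmin)
    W <- W / rowSums(W)
    ok <- csum > 1e-10
    MU <- params$means
    VA <- params$vars
    if (any(ok)) {
      MU_new <- crossprod(GCM[, ok, drop = FALSE], Y) / csum[ok]
      MU[ok, ] <- MU_new
      if (!freeze_var) {
        EY2 <- crossprod(GCM[, ok, drop = FALSE], Y * Y) / csum[ok]
        V_new <- EY2 - MU_new^2
        if (any(V_new < var_floor)) floored <- TRUE
        VA[ok, ] <- pmax(V_new, var_floor)
      }
    }
    params$start <- start
    params$trans <- trans
    params$weights <- W
    params$means <- MU
    params$vars <- VA
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  # log-likelihood under the final parameters
  logw <- log(pmax(params$weights, .Machine$double.xmin))
  logB <- state_loglik(component_logdens(Y, params$means, params$vars), logw, C, M)
  fb <- forward_backward(logB, seq_lengths, params$start, params$trans,
                         backward = FALSE)
  params$loglik <- fb$loglik
  params$loglik_per_obs <- fb$loglik / K
  params$n_iter <- length(ll_trace)
  params$converged <- converged
  params$variance_floored <- floored
  params$ll_trace <- ll_trace
  params
}

# Level-based initialization: cluster timepoints by their mean amplitude
# across nodes (1-D k-means). Trial-evoked states differ foremost in overall
# intensity, and averaging over nodes suppresses node-level noise by
# sqrt(N), so the level partition recovers the state structure even when
# spatial patterns are subject-specific and full-pattern clustering fails.
level_init_params <- function(Y, C, M) {
  lv <- rowMeans(Y)
  km <- tryCatch(stats::kmeans(lv, centers = C, nstart = 5, iter.max = 20),
                 error = function(e) NULL)
  if (is.null(km) || min(tabulate(km$cluster, C)) < 2)
    return(kmeans_init_params(Y, C, M))
  N <- ncol(Y)
  means <- matrix(0, C * M, N)
  vars <- matrix(1, C * M, N)
  for (c in seq_len(C)) {
    sel <- km$cluster == c
    mu <- colMeans(Y[sel, , drop = FALSE])
    v <- apply(Y[sel, , drop = FALSE], 2, stats::var)
    v[!is.finite(v) | v <= 0] <- 1
    for (m in seq_len(M))
      means[(c - 1) * M + m, ] <- mu + stats::rnorm(N, 0, 0.02 * sqrt(mean(v)))
    vars[((c - 1) * M + 1):(c * M), ] <- matrix(v, M, N, byrow = TRUE)
  }
  trans <- matrix(0.4 / max(C - 1, 1), C, C); diag(trans) <- 0.6
  if (C == 1) trans <- matrix(1, 1, 1)
  list(C = C, M = M, start = rep(1 / C, C), trans = trans,
       weights = matrix(1 / M, C, M), means = means, vars = vars)
}

# K-means initialization: state means from a C-cluster solution, mixture
# means jittered copies of their state center, variances from within-cluster
# spread. Gives EM a state structure to refine rather than discover.
kmeans_init_params <- function(Y, C, M) {
  km <- tryCatch(
    stats::kmeans(Y, centers = C, nstart = 1, iter.max = 20),
    error = function(e) NULL)
  if (is.null(km)) return(random_init_params(Y, C, M))
  N <- ncol(Y)
  J <- C * M
  cv <- numeric(N)
  for (c in seq_len(C)) {
    sel <- km$cluster == c
    if (sum(sel) > 1)
      cv <- cv + apply(Y[sel, , drop = FALSE], 2, stats::var) * sum(sel)
  }
  cv <- cv / nrow(Y)
  cv[!is.finite(cv) | cv <= 0] <- 1
  means <- matrix(0, J, N)
  for (c in seq_len(C)) for (m in seq_len(M))
    means[(c - 1) * M + m, ] <- km$centers[c, ] +
      stats::rnorm(N, 0, 0.05 * sqrt(mean(cv)))
  vars <- matrix(cv, J, N, byrow = TRUE)
  trans <- matrix(0.4 / max(C - 1, 1), C, C); diag(trans) <- 0.6
  if (C == 1) trans <- matrix(1, 1, 1)
  list(C = C, M = M, start = rep(1 / C, C), trans = trans,
       weights = matrix(1 / M, C, M), means = means, vars = vars)
}

# Random EM initialization: component means are perturbed data rows.
random_init_params <- function(Y, C, M) {
  K <- nrow(Y); N <- ncol(Y)
  J <- C * M
  rows <- sample.int(K, J, replace = K < J)
  cv <- apply(Y, 2, stats::var)
  cv[cv <= 0] <- 1
  means <- Y[rows, , drop = FALSE] +
    matrix(stats::rnorm(J * N, 0, 0.1 * sqrt(mean(cv))), J, N)
  vars <- matrix(cv, J, N, byrow = TRUE)
  trans <- matrix(0.4 / (C - 1), C, C); diag(trans) <- 0.6
  if (C == 1) trans <- matrix(1, 1, 1)
  list(C = C, M = M, start = rep(1 / C, C), trans = trans,
       weights = matrix(1 / M, C, M), means = means, vars = vars)
}

# Forward-only log-likelihood of data under fixed parameters.
gmmhmm_data_loglik <- function(params, Y, seq_lengths) {
  logw <- log(pmax(params$weights, .Machine$double.xmin))
  logB <- state_loglik(component_logdens(Y, flat_means(params), flat_vars(params)),
                       logw, params$C, params$M)
  forward_backward(logB, seq_lengths, params$start, params$trans,
                   backward = FALSE)$loglik
}

# means/vars of a pcsm_hmm object as flat (C*M) x N matrices.
flat_means <- function(p) {
  if (is.matrix(p$means)) return(p$means)
  matrix(aperm(p$means, c(2, 1, 3)), p$C * p$M, dim(p$means)[3], byrow = FALSE)
}
flat_vars <- function(p) {
  if (is.matrix(p$vars)) return(p$vars)
  matrix(aperm(p$vars, c(2, 1, 3)), p$C * p$M, dim(p$vars)[3], byrow = FALSE)
}

# Ledoit-Wolf-style shrinkage of the N x N spatial covariance toward a scaled
# identity; exact plug-in intensity computed from the data.
shrinkage_spatial_cov <- function(Y) {
  K <- nrow(Y); N <- ncol(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- crossprod(Yc) / K
  m <- sum(diag(S)) / N
  d2 <- sum((S - diag(m, N))^2) / N
  q <- rowSums(Yc^2)                    # y_t' y_t
  ySy <- rowSums((Yc %*% S) * Yc)       # y_t' S y_t
  b2bar <- (sum(q^2) - 2 * sum(ySy) + K * sum(S^2)) / (K^2 * N)
  b2 <- min(b2bar, d2)
  rho <- if (d2 > 0) b2 / d2 else 1
  Sigma <- rho * diag(m, N) + (1 - rho) * S
  attr(Sigma, "shrinkage") <- rho
  Sigma
}
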