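# Constrained GMM-HMM fitting and decoding: global concatenated fit,
# subject-level refits with frozen covariances, salience-based template
# alignment, filtered/smoothed posterior inference and Viterbi decoding.

# Assemble a pcsm_hmm object from flat EM parameters.
as_pcsm_hmm <- function(params, N, node_labels = NULL, Sigma = NULL) {
  C <- params$C; M <- params$M
  means <- array(0, c(C, M, N))
  vars <- array(0, c(C, M, N))
  fm <- params$means; fv <- params$vars
  for (c in seq_len(C)) for (m in seq_len(M)) {
    means[c, m, ] <- fm[(c - 1) * M + m, ]
    vars[c, m, ] <- fv[(c - 1) * M + m, ]
  }
  structure(list(
    C = C, M = M, N = N,
    start_probs = as.numeric(params$start),
    transition = params$trans,
    mixture_weights = params$weights,
    means = means, vars = vars,
    spatial_cov = Sigma,
    responding = M,      # responding mixture stored last after alignment
    node_labels = node_labels,
    loglik = params$loglik, loglik_per_obs = params$loglik_per_obs,
    n_iter = params$n_iter, converged = params$converged,
    variance_floored = isTRUE(params$variance_floored)),
    class = "pcsm_hmm")
}

hmm_to_flat <- function(p) {
  list(C = p$C, M = p$M, start = p$start_probs, trans = p$transition,
       weights = p$mixture_weights, means = flat_means_arr(p$means),
       vars = flat_means_arr(p$vars))
}

flat_means_arr <- function(arr) {
  C <- dim(arr)[1]; M <- dim(arr)[2]; N <- dim(arr)[3]
  out <- matrix(0, C * M, N)
  for (c in seq_len(C)) for (m in seq_len(M))
    out[(c - 1) * M + m, ] <- arr[c, m, ]
  out
}

#' @export
print.pcsm_hmm <- function(x, ...) {
  cat("PCSM GMM-HMM:", x$C, "states x", x$M, "mixtures over", x$N, "nodes\n")
  cat("  log-likelihood/obs:", format(x$loglik_per_obs, digits = 6),
      if (isTRUE(x$converged)) "(converged)" else "(max iterations)", "\n")
  cat("  transition matrix:\n")
  print(round(x$transition, 3))
  invisible(x)
}

stack_fir <- function(fir_stack) {
  if (inherits(fir_stack, "pcsm_fir")) fir_stack <- list(fir_stack)
  Ns <- vapply(fir_stack, function(f) ncol(f$values), 1L)
  if (length(unique(Ns)) != 1L)
    stop("invalid-input: all FIR series must share the node count")
  Y <- do.call(rbind, lapply(fir_stack, function(f) f$values))
  seq_lengths <- unlist(lapply(fir_stack, function(f) {
    as.integer(rle(f$trial)$lengths)
  }))
  list(Y = Y, seq_lengths = seq_lengths,
       node_labels = fir_stack[[1]]$node_labels)
}

#' Fit the global GMM-HMM on concatenated subjects
#'
#' Baum-Welch (EM) over the concatenation of all subjects' FIR series, with
#' per-trial sequence segmentation: each trial's delay-bin run is treated as
#' an independent sequence re-initialized from the start distribution, so
#' transitions never bridge inter-trial gaps.
#'
#' Initialization is structured: timepoints are clustered by their mean
#' amplitude level across nodes (trial-evoked states differ foremost in
#' overall intensity, and the node average suppresses node-level noise by
#' sqrt(N)) and EM refines from the cluster-conditional moments. This
#' solution is kept whenever it is sound; up to `n_init - 1` alternative
#' starts (full-pattern k-means, then random restarts) are consulted, by
#' final log-likelihood, only when it degenerates (an unvisited state or a
#' non-finite likelihood). On concatenated multi-subject data a free
#' likelihood race is deliberately avoided: with subject-specific spatial
#' patterns the pooled likelihood can favor solutions whose states absorb
#' between-subject heterogeneity instead of the shared trial-evoked
#' structure. The result is internally aligned so state order
#' follows descending salience and the responding mixture is last. The global
#' N x N spatial covariance (used for Mahalanobis discrepancy scoring) is
#' estimated from the concatenated data with shrinkage regularization.
#'
#' @param fir_stack list of [fir_series()] objects (>= 2 subjects), or a
#'   single series.
#' @param C number of latent states (default 3).
#' @param M number of mixtures per state (default 2: non-responding,
#'   responding).
#' @param n_init maximum number of initializations (structured first, then
#'   fallback restarts; see Details).
#' @param max_iter maximum EM iterations per run.
#' @param tol convergence tolerance on per-observation log-likelihood.
#' @param var_floor lower bound applied to emission variances.
#' @param seed RNG seed for initializations.
#' @return an object of class `pcsm_hmm`.
#' @export
fit_global <- function(fir_stack, C = 3L, M = 2L, n_init = 5L,
                       max_iter = 100L, tol = 1e-4, var_floor = 1e-6,
                       seed = 1L) {
  st <- stack_fir(fir_stack)
  set.seed(seed)
  fit <- NULL
  for (i in seq_len(n_init)) {
    p0 <- if (i == 1) level_init_params(st$Y, C, M)
    else if (i == 2) kmeans_init_params(st$Y, C, M)
    else random_init_params(st$Y, C, M)
    cand <- em_gmmhmm(st$Y, st$seq_lengths, p0, max_iter = max_iter,
                      tol = tol, var_floor = var_floor)
    # the structured (level) solution is kept whenever it is sound; restarts
    # only replace it when it degenerates (see the initialization note above)
    if (i == 1 && !gmmhmm_degenerate(cand, st)) { fit <- cand; break }
    if (is.null(fit) || cand$loglik > fit$loglik) fit <- cand
  }
  if (!fit$converged)
    warning("EM did not converge within max_iter; returning best iterate")
  Sigma <- shrinkage_spatial_cov(st$Y)
  hmm <- as_pcsm_hmm(fit, N = ncol(st$Y), node_labels = st$node_labels,
                     Sigma = Sigma)
  canonicalize_hmm(hmm)
}

#' Fit a subject-level GMM-HMM with frozen covariances
#'
#' EM updates the subject's start probabilities, transition matrix, mixture
#' weights and means, while the emission variances remain bit-identical to
#' the global template's (fixing covariances for numerical stability).
#' Initialization is at the global values, which anchors the state labels to
#' the template.
#'
#' @param fir a [fir_series()] object.
#' @param global_params the template `pcsm_hmm` from [fit_global()].
#' @param max_iter,tol EM controls.
#' @return a `pcsm_hmm` carrying the global spatial covariance.
#' @export
fit_subject <- function(fir, global_params, max_iter = 50L, tol = 1e-4) {
  stopifnot(inherits(global_params, "pcsm_hmm"))
  st <- stack_fir(fir)
  if (ncol(st$Y) != global_params$N)
    stop("invalid-input: node count differs from the global model")
  p0 <- hmm_to_flat(global_params)
  fit <- em_gmmhmm(st$Y, st$seq_lengths, p0, max_iter = max_iter, tol = tol,
                   freeze_var = TRUE)
  as_pcsm_hmm(fit, N = global_params$N, node_labels = global_params$node_labels,
              Sigma = global_params$spatial_cov)
}

# A fit is degenerate when its likelihood is non-finite or some state is
# essentially never occupied under the filtered posteriors.
gmmhmm_degenerate <- function(fit, st, min_occupancy = 0.02) {
  if (!is.finite(fit$loglik)) return(TRUE)
  logw <- log(pmax(fit$weights, .Machine$double.xmin))
  logB <- state_loglik(component_logdens(st$Y, fit$means, fit$vars),
                       logw, fit$C, fit$M)
  fb <- forward_backward(logB, st$seq_lengths, fit$start, fit$trans,
                         backward = FALSE)
  any(colMeans(fb$filtered) < min_occupancy)
}

# Salience score per state: standardized mean amplitude (over mixtures and
# nodes) plus standardized responding-mixture weight.
state_salience <- function(params, effective_weights = NULL) {
  mu_term <- apply(params$means, 1, mean)
  a_term <- if (is.null(effective_weights))
    params$mixture_weights[, params$responding] else effective_weights
  zs <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  zs(mu_term) + zs(a_term)
}

# Within-state mixture order: responding (largest mean |mu|) last; ties
# broken by mixture weight.
mixture_order <- function(params, c) {
  mag <- apply(abs(params$means[c, , , drop = FALSE]), 2, mean)
  order(mag, params$mixture_weights[c, ])
}

# Apply a state permutation (perm[k] = old index moving to slot k) and
# per-state mixture permutations.
permute_hmm <- function(params, state_perm, mixture_perms = NULL) {
  p <- params
  p$start_probs <- params$start_probs[state_perm]
  p$transition <- params$transition[state_perm, state_perm, drop = FALSE]
  p$mixture_weights <- params$mixture_weights[state_perm, , drop = FALSE]
  p$means <- params$means[state_perm, , , drop = FALSE]
  p$vars <- params$vars[state_perm, , , drop = FALSE]
  if (!is.null(mixture_perms)) {
    for (k in seq_len(p$C)) {
      mp <- mixture_perms[[k]]
      p$mixture_weights[k, ] <- p$mixture_weights[k, mp]
      p$means[k, , ] <- p$means[k, mp, , drop = FALSE]
      p$vars[k, , ] <- p$vars[k, mp, , drop = FALSE]
    }
  }
  p
}

# Sort states by descending salience and mixtures so responding is last.
canonicalize_hmm <- function(params) {
  mixture_perms <- lapply(seq_len(params$C), function(c) mixture_order(params, c))
  p <- permute_hmm(params, seq_len(params$C), mixture_perms)
  sal <- state_salience(p)
  perm <- order(sal, decreasing = TRUE)
  p <- permute_hmm(p, perm)
  p$salience <- sal[perm]
  p
}

#' Align a subject model to the global template
#'
#' Within each state the mixture with the larger mean absolute amplitude is
#' labeled responding and moved to the last index. States are then matched to
#' the template by the exact-search permutation minimizing the total squared
#' distance between the subject's and the template's mixture-weighted
#' state-mean vectors; this captures both the state's average intensity and
#' its spatial pattern, and reduces to sorting by salience when states are
#' separated in intensity. Salience scores (standardized mean amplitude +
#' standardized responding weight, the sorting key of the template itself)
#' are computed and reported, and break exact distance ties. Start
#' probabilities, transition rows and columns, mixture weights, means and
#' variances are permuted consistently, so the data likelihood is unchanged
#' (relabeling invariance).
#'
#' @param subject a subject `pcsm_hmm`.
#' @param template the global `pcsm_hmm`.
#' @param use_effective_weights replace the fixed responding weight in the
#'   salience by the subject's empirical responding-responsibility mass
#'   (requires `fir`).
#' @param fir the subject's [fir_series()], needed only for effective weights.
#' @return an object of class `pcsm_alignment`: list with `state_perm`,
#'   `mixture_perms`, `salience_scores` and the `aligned` model.
#' @export
align_to_template <- function(subject, template, use_effective_weights = FALSE,
                              fir = NULL) {
  stopifnot(inherits(subject, "pcsm_hmm"), inherits(template, "pcsm_hmm"))
  if (subject$C != template$C || subject$M != template$M ||
      subject$N != template$N)
    stop("invalid-input: subject and template dimensions differ")
  C <- subject$C
  mixture_perms <- lapply(seq_len(C), function(c) mixture_order(subject, c))
  p <- permute_hmm(subject, seq_len(C), mixture_perms)
  eff <- NULL
  if (use_effective_weights) {
    if (is.null(fir)) stop("invalid-input: effective weights require the subject FIR data")
    eff <- responding_mass(p, fir)
  }
  sal_s <- state_salience(p, eff)
  sal_t <- if (!is.null(template$salience)) template$salience else state_salience(template)
  ms <- weighted_state_means(p)
  mt <- weighted_state_means(template)
  perms <- all_permutations(C)
  cost <- vapply(seq_len(nrow(perms)), function(i)
    sum((ms[perms[i, ], , drop = FALSE] - mt)^2), numeric(1))
  best <- which(cost <= min(cost) + 1e-12)
  if (length(best) > 1) {
    # distance tie: prefer the permutation matching salience ranks
    rank_t <- rank(-sal_t, ties.method = "first")
    agree <- vapply(best, function(i)
      sum(rank(-sal_s[perms[i, ]], ties.method = "first") == rank_t),
      numeric(1))
    best <- best[which.max(agree)]
  }
  perm <- perms[best[1], ]
  aligned <- permute_hmm(p, perm)
  aligned$salience <- sal_s[perm]
  structure(list(state_perm = perm, mixture_perms = mixture_perms,
                 salience_scores = sal_s, aligned = aligned),
            class = "pcsm_alignment")
}

# Mixture-weighted mean vector per state, C x N.
weighted_state_means <- function(params) {
  C <- params$C; M <- params$M; N <- params$N
  out <- matrix(0, C, N)
  for (c in seq_len(C)) {
    mu_c <- matrix(params$means[c, , ], M, N)
    out[c, ] <- colSums(mu_c * params$mixture_weights[c, ])
  }
  out
}

# Empirical responding-responsibility mass per state under subject params.
responding_mass <- function(params, fir) {
  st <- stack_fir(fir)
  flat <- hmm_to_flat(params)
  logw <- log(pmax(flat$weights, .Machine$double.xmin))
  logdens <- component_logdens(st$Y, flat$means, flat$vars)
  logB <- state_loglik(logdens, logw, params$C, params$M)
  fb <- forward_backward(logB, st$seq_lengths, flat$start, flat$trans)
  GCM <- mixture_responsibilities(logdens, logB, fb$gamma, logw,
                                  params$C, params$M)
  resp_cols <- (seq_len(params$C) - 1) * params$M + params$responding
  colSums(GCM[, resp_cols, drop = FALSE]) / pmax(colSums(fb$gamma), 1e-300)
}

#' Infer state posteriors and the Viterbi path
#'
#' Runs the forward pass per trial segment to obtain filtered posteriors
#' `P(C_t = c | y_0:t)` (the default convention), optionally the
#' forward-backward smoothed posteriors, and the per-segment Viterbi path in
#' log space. Zero-probability observations are handled by log-space scaling
#' and renormalization, never producing NaN.
#'
#' @param params a `pcsm_hmm`.
#' @param fir a [fir_series()] with matching node count.
#' @param smoothing `"filtered"` (default) or `"smoothed"`.
#' @return an object of class `pcsm_posterior`: list with `pi` (K x C rows
#'   summing to 1), `viterbi` (states 1..C), `loglik`, `seq_lengths`,
#'   `trial`, `delay`.
#' @export
infer_posteriors <- function(params, fir, smoothing = c("filtered", "smoothed")) {
  smoothing <- match.arg(smoothing)
  stopifnot(inherits(params, "pcsm_hmm"))
  st <- stack_fir(fir)
  if (ncol(st$Y) != params$N) stop("invalid-input: node count mismatch")
  flat <- hmm_to_flat(params)
  logw <- log(pmax(flat$weights, .Machine$double.xmin))
  logB <- state_loglik(component_logdens(st$Y, flat$means, flat$vars),
                       logw, params$C, params$M)
  fb <- forward_backward(logB, st$seq_lengths, flat$start, flat$trans,
                         backward = (smoothing == "smoothed"))
  pi <- if (smoothing == "smoothed") fb$gamma else fb$filtered
  vit <- viterbi_decode(logB, st$seq_lengths, flat$start, flat$trans)
  structure(list(pi = pi, viterbi = vit$path, viterbi_logp = vit$logp,
                 loglik = fb$loglik, seq_lengths = st$seq_lengths,
                 trial = fir$trial, delay = fir$delay, smoothing = smoothing),
            class = "pcsm_posterior")
}

#' @export
print.pcsm_posterior <- function(x, ...) {
  cat("PCSM posterior trajectory:", nrow(x$pi), "timepoints x", ncol(x$pi),
      "states (", x$smoothing, ")\n")
  cat("  log-likelihood:", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' Cross-validated model-order selection
#'
#' Subject-level k-fold cross-validation of held-out log-likelihood per
#' observation over a grid of state counts `C` and mixture counts `M`.
#' Mixtures are selected per state count in ascending order, retaining a
#' larger `M` only when its gain is practically meaningful
#' (`dLL >= max(5, 2 * SE)` per observation). State counts are then compared
#' consecutively; `C + 1` replaces `C` only when `dLL > 2`, `dLL > 2 * SE`,
#' the higher order wins in at least 70% of folds, and (when a previous gain
#' exists) the new gain exceeds 10% of it.
#'
#' @param fir_stack list of [fir_series()] objects, one per subject.
#' @param C_range,M_range integer grids to evaluate.
#' @param k_folds number of subject-level folds.
#' @param n_init,max_iter,tol EM controls passed to [fit_global()].
#' @param seed RNG seed (fold assignment and initializations).
#' @return an object of class `pcsm_order_selection`: list with `selected`
#'   (named vector C, M), per-cell mean/SE tables `ll`, `se`, fold details,
#'   and the applied decisions.
#' @export
select_model_order <- function(fir_stack, C_range = 2:5, M_range = 1:3,
                               k_folds = 5L, n_init = 2L,
                               max_iter = 50L, tol = 1e-4, seed = 1L) {
  n_sub <- length(fir_stack)
  if (n_sub < k_folds) stop("invalid-input: fewer subjects than folds")
  set.seed(seed)
  fold <- sample(rep(seq_len(k_folds), length.out = n_sub))
  cells <- expand.grid(C = C_range, M = M_range)
  ll_fold <- array(NA_real_, c(length(C_range), length(M_range), k_folds),
                   dimnames = list(paste0("C", C_range), paste0("M", M_range), NULL))
  for (i in seq_len(nrow(cells))) {
    C <- cells$C[i]; M <- cells$M[i]
    for (f in seq_len(k_folds)) {
      train <- fir_stack[fold != f]
      test <- fir_stack[fold == f]
      g <- fit_global(train, C = C, M = M, n_init = n_init,
                      max_iter = max_iter, tol = tol, seed = seed + f)
      st <- stack_fir(test)
      ll_fold[paste0("C", C), paste0("M", M), f] <-
        gmmhmm_data_loglik(hmm_to_flat_full(g), st$Y, st$seq_lengths) / nrow(st$Y)
    }
  }
  ll <- apply(ll_fold, c(1, 2), mean)
  se <- apply(ll_fold, c(1, 2), function(x) stats::sd(x) / sqrt(length(x)))
  # mixture selection per C (ascending, meaningful-gain rule)
  best_M <- setNames(integer(length(C_range)), paste0("C", C_range))
  for (ci in seq_along(C_range)) {
    chosen <- 1L
    for (mi in seq_along(M_range)[-1]) {
      gain <- ll[ci, mi] - ll[ci, which(M_range == M_range[chosen])]
      if (is.finite(gain) && gain >= max(5, 2 * se[ci, mi])) chosen <- mi
    }
    best_M[ci] <- M_range[chosen]
  }
  # state selection (consecutive comparison with consistency criterion)
  chosen_ci <- 1L
  prev_gain <- NA_real_
  for (ci in seq_along(C_range)[-1]) {
    mi_new <- which(M_range == best_M[ci])
    mi_old <- which(M_range == best_M[chosen_ci])
    gain <- ll[ci, mi_new] - ll[chosen_ci, mi_old]
    fold_wins <- mean(ll_fold[ci, mi_new, ] > ll_fold[chosen_ci, mi_old, ])
    pass <- is.finite(gain) && gain > 2 && gain > 2 * se[ci, mi_new] &&
      fold_wins >= 0.70 &&
      (is.na(prev_gain) || gain > 0.10 * prev_gain)
    if (pass) { prev_gain <- gain; chosen_ci <- ci } else break
  }
  selected <- c(C = C_range[chosen_ci], M = unname(best_M[chosen_ci]))
  structure(list(selected = selected, ll = ll, se = se, ll_fold = ll_fold,
                 best_M_per_C = best_M, fold = fold),
            class = "pcsm_order_selection")
}

# flat params carrying C/M from a pcsm_hmm (for likelihood evaluation)
hmm_to_flat_full <- function(p) {
  f <- hmm_to_flat(p)
  f$C <- p$C; f$M <- p$M
  f
}

#' @export
print.pcsm_order_selection <- function(x, ...) {
  cat("PCSM model-order selection: C =", x$selected["C"],
      ", M =", x$selected["M"], "\n")
  cat("  held-out log-likelihood per observation:\n")
  print(round(x$ll, 3))
  invisible(x)
}
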