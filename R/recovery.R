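# Ground-truth recovery evaluation: state and transition classification
# reports, Dice spatial-pattern similarity, cross-validated global-model
# stability.

classification_report <- function(pred, truth, levels) {
  pred <- factor(pred, levels = levels)
  truth <- factor(truth, levels = levels)
  cm <- table(truth = truth, pred = pred)
  tp <- diag(cm)
  precision <- ifelse(colSums(cm) > 0, tp / colSums(cm), NA_real_)
  recall <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  list(confusion = cm,
       accuracy = sum(tp) / sum(cm),
       precision = precision, recall = recall, f1 = f1,
       macro_precision = mean(precision, na.rm = TRUE),
       macro_recall = mean(recall, na.rm = TRUE),
       macro_f1 = mean(f1, na.rm = TRUE))
}

#' Match template state labels to ground-truth labels
#'
#' The fitted template defines an arbitrary (salience-sorted) state
#' numbering, while the simulator numbers its generative states by
#' construction. For recovery evaluation the two label spaces are matched
#' once, globally: over all `C!` permutations of the truth labels, the one
#' maximizing pooled prediction-truth agreement is selected. Per-subject
#' re-matching is deliberately not performed (all subjects share the
#' template's label space).
#'
#' @param pred pooled decoded states (vector or list).
#' @param truth pooled true states (vector or list).
#' @param C number of states.
#' @return integer permutation `p` such that `p[truth]` lives in the
#'   template's label space.
#' @export
match_template_to_truth <- function(pred, truth, C = 3L) {
  pred <- unlist(pred, use.names = FALSE)
  truth <- unlist(truth, use.names = FALSE)
  cm <- table(factor(truth, levels = seq_len(C)),
              factor(pred, levels = seq_len(C)))
  perms <- all_permutations(C)
  agree <- vapply(seq_len(nrow(perms)), function(i)
    sum(cm[cbind(seq_len(C), perms[i, ])]), numeric(1))
  perms[which.max(agree), ]
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out <- rbind(out, block)
  }
  dimnames(out) <- NULL
  out
}

#' Evaluate latent-state recovery against ground truth
#'
#' Compares template-aligned decoded state sequences with the simulator's
#' ground truth: per-state precision/recall/F1, overall accuracy and the 3x3
#' confusion matrix, overall and per stratum (e.g. transition regime, noise
#' level).
#'
#' @param pred integer vector (or list per subject) of decoded states 1..C.
#' @param truth matching vector/list of true states.
#' @param strata optional data.frame-like list of per-timepoint stratum
#'   labels (each element a vector matching `pred`).
#' @param C number of states.
#' @return an object of class `pcsm_recovery`: `overall` report and a named
#'   list `by_stratum`.
#' @export
evaluate_state_recovery <- function(pred, truth, strata = NULL, C = 3L) {
  pred <- unlist(pred, use.names = FALSE)
  truth <- unlist(truth, use.names = FALSE)
  if (length(pred) != length(truth)) stop("invalid-input: length mismatch")
  levels <- seq_len(C)
  out <- list(overall = classification_report(pred, truth, levels),
              by_stratum = list())
  if (!is.null(strata)) {
    for (nm in names(strata)) {
      lab <- unlist(strata[[nm]], use.names = FALSE)
      if (length(lab) != length(pred)) stop("invalid-input: stratum length mismatch")
      out$by_stratum[[nm]] <- lapply(split(seq_along(pred), lab), function(idx)
        classification_report(pred[idx], truth[idx], levels))
    }
  }
  class(out) <- "pcsm_recovery"
  out
}

#' Evaluate stay/change transition recovery
#'
#' Binary stay (0) / change (1) classification of within-trial steps; the
#' first bin of each trial is excluded (transitions are undefined across
#' trial boundaries; `NA` entries in the truth are dropped). Single-class
#' cells report `NA` metrics rather than NaN.
#'
#' @param pred_states decoded state vector (or list per subject).
#' @param truth a `pcsm_truth` (or list of them) supplying `transition_seq`
#'   and `delay`.
#' @param strata optional per-timepoint stratum labels as in
#'   [evaluate_state_recovery()].
#' @return a `pcsm_recovery` with 2x2 stay/change confusion matrices.
#' @export
evaluate_transition_recovery <- function(pred_states, truth, strata = NULL) {
  if (inherits(truth, "pcsm_truth")) truth <- list(truth)
  if (!is.list(pred_states)) pred_states <- list(pred_states)
  pred_tr <- c(); true_tr <- c(); keep_all <- c()
  for (i in seq_along(truth)) {
    p <- pred_states[[i]]
    tr <- truth[[i]]
    pt <- c(NA_integer_, as.integer(p[-1] != p[-length(p)]))
    keep <- !is.na(tr$transition_seq)
    pred_tr <- c(pred_tr, pt[keep])
    true_tr <- c(true_tr, tr$transition_seq[keep])
    keep_all <- c(keep_all, which(keep) + (i - 1L) * length(p))
  }
  out <- list(overall = classification_report(pred_tr, true_tr, 0:1),
              by_stratum = list())
  if (!is.null(strata)) {
    for (nm in names(strata)) {
      lab <- unlist(strata[[nm]], use.names = FALSE)[keep_all]
      out$by_stratum[[nm]] <- lapply(split(seq_along(pred_tr), lab), function(idx)
        classification_report(pred_tr[idx], true_tr[idx], 0:1))
    }
  }
  class(out) <- "pcsm_recovery"
  out
}

#' @export
print.pcsm_recovery <- function(x, ...) {
  cat("PCSM recovery report: accuracy",
      format(x$overall$accuracy, digits = 4),
      "| macro F1", format(x$overall$macro_f1, digits = 4), "\n")
  print(x$overall$confusion)
  invisible(x)
}

#' Dice spatial-pattern similarity
#'
#' Binarizes both pattern vectors (default: top-quartile magnitude) and
#' returns `2|A n B| / (|A| + |B|)`. Two empty binarized sets count as
#' identical (Dice 1).
#'
#' @param a,b numeric pattern vectors of equal length, or logical masks.
#' @param binarize `"top_quartile"` (magnitude above the 75th percentile) or
#'   `"nonzero"`; logical inputs are used as-is.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_similarity <- function(a, b, binarize = c("top_quartile", "nonzero")) {
  binarize <- match.arg(binarize)
  if (length(a) != length(b)) stop("invalid-input: pattern lengths differ")
  bin <- function(x) {
    if (is.logical(x)) return(x)
    if (binarize == "nonzero") return(x != 0)
    abs(x) > stats::quantile(abs(x), 0.75, names = FALSE)
  }
  A <- bin(a); B <- bin(b)
  if (sum(A) + sum(B) == 0) return(1)
  2 * sum(A & B) / (sum(A) + sum(B))
}

#' Cross-validated stability of the global model
#'
#' Refits the global GMM-HMM on k subject folds (leave-fold-out), reporting
#' the per-fold held-out log-likelihood per observation, whether all folds
#' lie within 2 SDs of the fold mean, and the Dice similarity between
#' fold-specific and full-model state patterns (mixture-weighted means and
#' variances, binarized at the top quartile).
#'
#' @param fir_stack list of [fir_series()] objects.
#' @param global_params optional pre-fit full model (refit when `NULL`).
#' @param k number of folds.
#' @param seed RNG seed.
#' @param ... passed to [fit_global()].
#' @return list with `fold_ll`, `stable` (2-SD verdict), `dice_means`,
#'   `dice_vars` (per fold x state matrices).
#' @export
crossval_global_stability <- function(fir_stack, global_params = NULL, k = 5L,
                                      seed = 1L, ...) {
  n_sub <- length(fir_stack)
  if (n_sub < k) stop("invalid-input: fewer subjects than folds")
  if (is.null(global_params))
    global_params <- fit_global(fir_stack, seed = seed, ...)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n_sub))
  C <- global_params$C
  fold_ll <- numeric(k)
  dice_means <- matrix(NA_real_, k, C)
  dice_vars <- matrix(NA_real_, k, C)
  gm <- weighted_state_means(global_params)
  gv <- t(vapply(seq_len(C), function(c)
    colSums(matrix(global_params$vars[c, , ], global_params$M) *
              global_params$mixture_weights[c, ]), numeric(global_params$N)))
  for (f in seq_len(k)) {
    train <- fir_stack[fold != f]
    test <- fir_stack[fold == f]
    gfit <- fit_global(train, C = C, M = global_params$M, seed = seed + f, ...)
    al <- align_to_template(gfit, global_params)$aligned
    st <- stack_fir(test)
    fold_ll[f] <- gmmhmm_data_loglik(hmm_to_flat_full(al), st$Y,
                                     st$seq_lengths) / nrow(st$Y)
    fm <- weighted_state_means(al)
    fv <- t(vapply(seq_len(C), function(c)
      colSums(matrix(al$vars[c, , ], al$M) * al$mixture_weights[c, ]),
      numeric(al$N)))
    for (c in seq_len(C)) {
      dice_means[f, c] <- dice_similarity(fm[c, ], gm[c, ])
      dice_vars[f, c] <- dice_similarity(fv[c, ], gv[c, ])
    }
  }
  mu <- mean(fold_ll); sdv <- stats::sd(fold_ll)
  stable <- all(abs(fold_ll - mu) <= 2 * sdv) || sdv == 0
  list(fold_ll = fold_ll, mean_ll = mu, sd_ll = sdv, stable = stable,
       dice_means = dice_means, dice_vars = dice_vars, fold = fold)
}
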