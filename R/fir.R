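# FIR deconvolution: trial-and-delay stick design matrices and OLS amplitude
# estimation, beta = (X'X)^-1 X'Y via a rank-tolerant pseudo-inverse.

#' FIR amplitude series
#'
#' Container for the K x N matrix of per-trial, per-delay FIR amplitudes that
#' forms the observation sequence of the state model (K = trials x delays,
#' rows trial-major then delay).
#'
#' @param values numeric K x N matrix.
#' @param trial,delay integer row index vectors of length K.
#' @param node_labels optional node identifiers (defaults to colnames or
#'   `node_1..node_N`).
#' @param zscored logical flag: have columns been z-scored?
#' @return an object of class `pcsm_fir`.
#' @export
fir_series <- function(values, trial, delay, node_labels = NULL, zscored = FALSE) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(trial), length(trial) == length(delay))
  if (any(!is.finite(values))) stop("invalid-input: FIR values must be finite")
  if (is.null(node_labels)) {
    node_labels <- colnames(values)
    if (is.null(node_labels)) node_labels <- paste0("node_", seq_len(ncol(values)))
  }
  colnames(values) <- node_labels
  structure(list(values = values, trial = as.integer(trial),
                 delay = as.integer(delay), node_labels = node_labels,
                 zscored = isTRUE(zscored)),
            class = "pcsm_fir")
}

#' @export
print.pcsm_fir <- function(x, ...) {
  cat("PCSM FIR series:", nrow(x$values), "timepoints (",
      max(x$trial), "trials x", max(x$delay), "delays ) x",
      ncol(x$values), "nodes;", if (x$zscored) "z-scored" else "raw", "\n")
  invisible(x)
}

#' Build an FIR stick design matrix
#'
#' One indicator column per (trial, delay) pair: trial `r` with onset volume
#' `v = round(onset_s / tr_s)` contributes a 1 at row `v + d` for delay
#' `d = 0..n_delays-1` when that row lies inside the run; delayed sticks
#' falling beyond the run yield all-zero columns (with a warning when a whole
#' trial is lost). Columns are ordered trial-major then delay.
#'
#' @param trials a trial table with `onset_s` (e.g. from
#'   [simulate_behavior()] or [read_events()]).
#' @param n_volumes number of BOLD volumes T.
#' @param tr_s repetition time in seconds.
#' @param n_delays number of FIR delay bins.
#' @return an object of class `pcsm_fir_design`: list with binary matrix `X`
#'   (T x K), `trial`/`delay` column index, and dimensions.
#' @export
build_fir_design <- function(trials, n_volumes, tr_s = 2.0, n_delays = 5L) {
  stopifnot(n_volumes > 0, tr_s > 0, n_delays > 0)
  onset <- trials$onset_s
  if (any(onset < 0)) stop("invalid-input: onsets must be non-negative")
  R <- length(onset)
  K <- R * n_delays
  X <- matrix(0, n_volumes, K)
  vol <- round(onset / tr_s)   # nearest-volume onset mapping
  lost <- 0L
  for (r in seq_len(R)) {
    for (d in seq_len(n_delays) - 1L) {
      row <- vol[r] + d + 1L
      if (row <= n_volumes) X[row, (r - 1L) * n_delays + d + 1L] <- 1
    }
    if (vol[r] + 1L > n_volumes) lost <- lost + 1L
  }
  if (lost > 0L)
    warning(sprintf("%d trial(s) with onset beyond run end: all-zero columns", lost))
  structure(list(X = X, trial = rep(seq_len(R), each = n_delays),
                 delay = rep(seq_len(n_delays), times = R),
                 n_volumes = as.integer(n_volumes), n_trials = R,
                 n_delays = as.integer(n_delays), K = as.integer(K),
                 tr_s = tr_s),
            class = "pcsm_fir_design")
}

# Moore-Penrose pseudo-inverse via SVD; singular values below
# tol * max(singular value) are treated as zero.
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Estimate FIR amplitudes by ordinary least squares
#'
#' Solves `beta = (X'X)^-1 X'Y` with a rank-tolerant pseudo-inverse. An
#' intercept column per run is added during estimation and discarded from the
#' result, so baseline offsets do not leak into FIR amplitudes. Overlapping
#' trials are solved jointly; all-zero design columns yield amplitude 0 and
#' are flagged in `attr(, "zero_columns")`.
#'
#' @param design a [build_fir_design()] object.
#' @param bold numeric T x N BOLD matrix (timepoints x nodes).
#' @return a [fir_series()] object (K x N).
#' @export
estimate_fir <- function(design, bold) {
  stopifnot(inherits(design, "pcsm_fir_design"))
  bold <- as.matrix(bold)
  if (nrow(bold) != design$n_volumes)
    stop("invalid-input: BOLD rows must equal design rows")
  X <- cbind(design$X, 1)   # run intercept, discarded below
  XtX <- crossprod(X)
  beta <- pinv(XtX) %*% crossprod(X, bold)
  beta <- beta[seq_len(design$K), , drop = FALSE]
  zero_cols <- colSums(design$X != 0) == 0L
  beta[zero_cols, ] <- 0
  fs <- fir_series(beta, trial = design$trial, delay = design$delay,
                   node_labels = colnames(bold), zscored = FALSE)
  attr(fs, "zero_columns") <- which(zero_cols)
  fs
}

#' Z-score an FIR series per node
#'
#' @param fir a [fir_series()] object.
#' @return the series with each node column standardized to mean 0, sd 1.
#' @export
zscore_fir <- function(fir) {
  stopifnot(inherits(fir, "pcsm_fir"))
  v <- scale(fir$values)
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  fir_series(v, fir$trial, fir$delay, fir$node_labels, zscored = TRUE)
}

#' Tensor view of an FIR series
#'
#' @param fir a [fir_series()] object.
#' @return a trials x delays x nodes array.
#' @export
fir_tensor <- function(fir) {
  stopifnot(inherits(fir, "pcsm_fir"))
  R <- max(fir$trial); D <- max(fir$delay); N <- ncol(fir$values)
  arr <- array(NA_real_, c(R, D, N),
               dimnames = list(NULL, NULL, fir$node_labels))
  for (i in seq_len(nrow(fir$values)))
    arr[fir$trial[i], fir$delay[i], ] <- fir$values[i, ]
  arr
}
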