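# Plain-text I/O: BIDS-style events.tsv, tab-separated BOLD / FIR matrices,
# JSON model parameters and threshold manifests.

#' Read and write BIDS-style event tables
#'
#' `write_events` emits `onset`, `duration`, `trial_type`, `response_time`,
#' `ssd`, `outcome` columns (seconds; `n/a` for missing values, e.g. the
#' response time of a successful stop). `read_events` returns a
#' `pcsm_trials` table usable by [build_fir_design()].
#'
#' @param trials a `pcsm_trials` table.
#' @param path file path of the events.tsv.
#' @param duration event duration in seconds written to the file.
#' @return `read_events` returns a `pcsm_trials` data.frame.
#' @export
write_events <- function(trials, path, duration = 1.0) {
  rt <- ifelse(trials$outcome == "stop_success", NA_real_, trials$rt_s)
  df <- data.frame(onset = trials$onset_s, duration = duration,
                   trial_type = trials$trial_type, response_time = rt,
                   ssd = trials$ssd_s, outcome = trials$outcome)
  utils::write.table(format_na(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

format_na <- function(df) {
  for (j in seq_along(df)) df[[j]][is.na(df[[j]])] <- "n/a"
  df
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, na.strings = c("n/a", "NA"),
                          stringsAsFactors = FALSE)
  out <- data.frame(trial_id = seq_len(nrow(df)), onset_s = df$onset,
                    trial_type = df$trial_type,
                    rt_s = if ("response_time" %in% names(df))
                      df$response_time else NA_real_,
                    ssd_s = if ("ssd" %in% names(df)) df$ssd else NA_real_,
                    outcome = if ("outcome" %in% names(df)) df$outcome
                    else NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("pcsm_trials", "data.frame")
  out
}

#' Read a node-wise BOLD matrix
#'
#' Tab-separated timepoints x nodes with a header row of node labels.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_bold <- function(path) {
  as.matrix(utils::read.delim(path, check.names = FALSE))
}

#' Read and write FIR series tables
#'
#' Tab-separated with `trial` and `delay` index columns followed by one
#' column per node.
#'
#' @param fir a [fir_series()] object.
#' @param path file path.
#' @return `read_fir` returns a [fir_series()].
#' @export
write_fir <- function(fir, path) {
  df <- data.frame(trial = fir$trial, delay = fir$delay,
                   fir$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fir
#' @export
read_fir <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  fir_series(as.matrix(df[, -(1:2), drop = FALSE]), trial = df$trial,
             delay = df$delay)
}

#' Serialize and restore GMM-HMM parameters as JSON
#'
#' Arrays are written row-major with an explicit C/M/N header, so files are
#' portable across sessions and tools.
#'
#' @param params a `pcsm_hmm`.
#' @param path file path.
#' @return `read_hmm_json` returns a `pcsm_hmm`.
#' @export
write_hmm_json <- function(params, path) {
  obj <- list(C = params$C, M = params$M, N = params$N,
              start_probs = params$start_probs,
              transition = params$transition,
              mixture_weights = params$mixture_weights,
              means = flat_means_arr(params$means),
              vars = flat_means_arr(params$vars),
              spatial_cov = params$spatial_cov,
              responding = params$responding,
              salience = params$salience,
              node_labels = params$node_labels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  C <- obj$C; M <- obj$M; N <- obj$N
  flat <- list(C = C, M = M, start = obj$start_probs,
               trans = matrix(unlist(obj$transition), C, C, byrow = FALSE),
               weights = matrix(unlist(obj$mixture_weights), C, M),
               means = matrix(unlist(obj$means), C * M, N),
               vars = matrix(unlist(obj$vars), C * M, N))
  Sigma <- if (!is.null(obj$spatial_cov)) matrix(unlist(obj$spatial_cov), N, N)
  p <- as_pcsm_hmm(flat, N = N, node_labels = obj$node_labels, Sigma = Sigma)
  p$salience <- obj$salience
  p
}

#' Write a study threshold manifest as JSON
#'
#' @param study a [run_pcsm_study()] result.
#' @param path file path.
#' @export
write_threshold_manifest <- function(study, path) {
  th <- study$thresholds
  obj <- list(
    rho = list(tau = th$rho$taus[1], method = th$rho$method[1],
               separation_d = th$rho$separation_d[1]),
    p = list(tau = th$p$taus[1], method = th$p$method[1]),
    d_maha = list(tau = th$d_maha$taus[1], method = th$d_maha$method[1]),
    d_sp = list(tau_low = th$d_sp$taus[1], tau_high = th$d_sp$taus[2],
                method = th$d_sp$method),
    demand = list(tau_low = th$demand$taus[["low"]],
                  tau_high = th$demand$taus[["high"]],
                  ci = th$demand$ci, accepted = th$demand$accepted),
    resource = list(tau_low = th$resource$taus[["low"]],
                    tau_high = th$resource$taus[["high"]],
                    ci = th$resource$ci, accepted = th$resource$accepted),
    bottleneck = list(negative_mass = th$bottleneck$negative_mass,
                      tail_valleys = if (!is.null(th$bottleneck$tail_valleys))
                        th$bottleneck$tail_valleys$taus),
    seed = study$meta$seed, n_subjects = study$meta$n_subjects)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
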