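#' Benchmark estimators on repeated simulations
#'
#' Runs a seeded simulator \code{n_trials} times, applies every requested
#' estimator to each trial, scores it against the ground truth carried by
#' the simulated series, and returns a tidy trial x estimator x metric
#' table.  A failure in one cell is recorded in the \code{message} column
#' and the run continues.
#'
#' @param simulator function taking a seed and returning a
#'   \code{\link{ddc_timeseries}} whose \code{"truth"} attribute holds the
#'   generating \code{\link{ddc_network}}.
#' @param estimators character vector of estimator names (see
#'   \code{\link{ar_bootstrap_significance}} for the recognized set) or a
#'   named list of functions \code{ts -> estimate}.
#' @param n_trials number of simulation trials.
#' @param seed master seed; trial k uses \code{seed + k - 1}.
#' @param metrics subset of \code{c("error", "auc")}.
#' @return data.frame with columns \code{trial}, \code{estimator},
#'   \code{metric}, \code{value}, \code{message}.
#' @export
run_benchmark <- function(simulator, estimators = c("Cov", "P", "Dc", "Dp", "DDC_L"),
                          n_trials = 10L, seed = 1L, metrics = "error") {
  metrics <- match.arg(metrics, c("error", "auc"), several.ok = TRUE)
  if (is.character(estimators)) {
    fns <- lapply(estimators, .resolve_estimator)
    names(fns) <- estimators
  } else {
    fns <- estimators
    if (is.null(names(fns))) stop("estimator list must be named")
  }
  rows <- list()
  for (k in seq_len(n_trials)) {
    ts <- simulator(seed + k - 1L)
    truth <- attr(ts, "truth")
    if (is.null(truth)) stop("simulator output carries no `truth` attribute")
    for (nm in names(fns)) {
      est <- tryCatch(.mat_of(fns[[nm]](ts)), error = function(e) e)
      for (met in metrics) {
        if (inherits(est, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            trial = k, estimator = nm, metric = met, value = NA_real_,
            message = conditionMessage(est))
          next
        }
        val <- tryCatch(
          switch(met,
                 error = error_bias_variance(list(est), truth)$error,
                 auc = roc_auc(est, truth)$auc),
          error = function(e) e)
        rows[[length(rows) + 1L]] <- if (inherits(val, "error"))
          data.frame(trial = k, estimator = nm, metric = met,
                     value = NA_real_, message = conditionMessage(val))
        else
          data.frame(trial = k, estimator = nm, metric = met, value = val,
                     message = "")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
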