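.mat_of <- function(x) {
  if (inherits(x, "ddc_estimate")) x$matrix
  else if (inherits(x, "ddc_network")) x$W
  else as.matrix(x)
}

#' Normalize matrices for comparison
#'
#' Estimates and ground truth usually differ by an overall scale, so both
#' are divided by their own maximum absolute entry before comparison; the
#' diagonal is always excluded (set to zero before scaling and dropped from
#' vectorized output).  Optionally only the strictly lower triangle is
#' compared, the fair restriction when undirected estimators are in the mix
#' and all true edges sit in the lower triangle.
#'
#' @param est,truth square matrices (or \code{ddc_estimate} /
#'   \code{ddc_network}) of equal shape.
#' @param lower_triangle_only compare only strictly-lower-triangle entries.
#' @return list with \code{est} and \code{truth}: numeric vectors of the
#'   compared entries (length \code{n(n-1)/2} or \code{n(n-1)}).
#' @export
normalize_for_comparison <- function(est, truth, lower_triangle_only = TRUE) {
  E <- .mat_of(est); W <- .mat_of(truth)
  if (!all(dim(E) == dim(W))) stop("matrices differ in shape")
  pick <- function(M) {
    diag(M) <- 0
    mx <- max(abs(M))
    if (mx == 0) stop("all-zero matrix cannot be normalized")
    M <- M / mx
    if (lower_triangle_only) M[lower.tri(M)] else M[row(M) != col(M)]
  }
  list(est = pick(E), truth = pick(W))
}

#' Error, bias and variance of repeated estimates
#'
#' Decomposes the normalized estimation error across trials.  With
#' \code{W} the (normalized) ground truth, \code{W_k} the normalized
#' per-trial estimates and \code{Wbar} their mean:
#' \deqn{Error^2 = mean_k ||W - W_k||^2 / ||W||^2, \quad
#'       Bias = ||W - Wbar|| / ||W||, \quad
#'       Variance = sqrt(mean_k ||W_k - Wbar||^2) / ||W||,}
#' so that \code{Error^2 = Bias^2 + Variance^2} holds exactly (the bias and
#' variance components are orthogonal).  The bias angle
#' \code{theta_b = atan(Bias/Variance)} measures their relative
#' contribution; by convention it is \code{pi/2} when the variance
#' vanishes and 0 when both components vanish.
#'
#' @param estimates list of square matrices (or \code{ddc_estimate}s), one
#'   per trial.
#' @param truth ground-truth matrix or \code{\link{ddc_network}}.
#' @param lower_triangle_only restrict to the strictly lower triangle
#'   (default, matching the evaluation convention for mixed
#'   directed/undirected estimator comparisons).
#' @return An object of class \code{ddc_errdecomp}: list with \code{error},
#'   \code{bias}, \code{variance}, \code{theta_b}, \code{n_trials} and the
#'   \code{per_trial} error vector.
#' @export
error_bias_variance <- function(estimates, truth, lower_triangle_only = TRUE) {
  if (inherits(estimates, "ddc_estimate") || is.matrix(estimates))
    estimates <- list(estimates)
  if (!length(estimates)) stop("`estimates` must contain at least one trial")
  vecs <- lapply(estimates, function(e)
    normalize_for_comparison(e, truth, lower_triangle_only))
  wt <- vecs[[1]]$truth
  wn <- sqrt(sum(wt^2))
  V <- vapply(vecs, function(v) v$est, numeric(length(wt)))
  V <- matrix(V, nrow = length(wt))
  vbar <- rowMeans(V)
  per_trial <- apply(V, 2, function(v) sqrt(sum((wt - v)^2)) / wn)
  error <- sqrt(mean(per_trial^2))
  bias <- sqrt(sum((wt - vbar)^2)) / wn
  variance <- sqrt(mean(colSums((V - vbar)^2))) / wn
  theta_b <- if (variance > 0) atan(bias / variance)
             else if (bias > 0) pi / 2 else 0
  structure(list(error = error, bias = bias, variance = variance,
                 theta_b = theta_b, n_trials = length(estimates),
                 per_trial = per_trial),
            class = "ddc_errdecomp")
}

#' @export
print.ddc_errdecomp <- function(x, ...) {
  cat(sprintf("<ddc_errdecomp> %d trial(s): error %.4f = sqrt(bias %.4f^2 + var %.4f^2), theta_b %.3f rad\n",
              x$n_trials, x$error, x$bias, x$variance, x$theta_b))
  invisible(x)
}

#' ROC curve and AUC for edge classification
#'
#' Binarizes \code{|est|} at every observed magnitude, compares against the
#' binary ground truth (diagonal ignored), and integrates sensitivity
#' against 1 - specificity by the trapezoidal rule.  Equivalent to the
#' Mann-Whitney pair-ranking probability with ties counted half.
#'
#' @param est square estimate matrix (or \code{ddc_estimate}).
#' @param truth_binary logical/0-1 matrix of true edges, or a
#'   \code{\link{ddc_network}} (nonzero off-diagonal entries are edges).
#' @return An object of class \code{ddc_roc}: list with \code{thresholds},
#'   \code{sensitivity}, \code{specificity}, \code{auc}.
#' @export
roc_auc <- function(est, truth_binary) {
  E <- .mat_of(est)
  B <- if (inherits(truth_binary, "ddc_network")) edge_mask(truth_binary)
       else .mat_of(truth_binary) != 0
  if (!all(dim(E) == dim(B))) stop("matrices differ in shape")
  off <- row(E) != col(E)
  scores <- abs(E[off])
  labels <- B[off]
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L)
    stop("ROC undefined: ground truth has ", if (np == 0L) "no" else "only",
         " edges")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(th, function(t) sum(scores >= t & labels) / np, 0)
  spec <- vapply(th, function(t) sum(scores < t & !labels) / nn, 0)
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(list(thresholds = th, sensitivity = sens, specificity = spec,
                 auc = auc), class = "ddc_roc")
}

#' @export
print.ddc_roc <- function(x, ...) {
  cat(sprintf("<ddc_roc> AUC = %.4f over %d thresholds\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' c-sensitivity
#'
#' The fraction of true-edge estimate magnitudes exceeding the 95th
#' percentile of the non-edge (false positive candidate) magnitudes; 1 when
#' the true positives are completely separated from the rest.  Invariant to
#' positive rescaling of the estimate.
#'
#' @inheritParams roc_auc
#' @return A number in \code{[0, 1]}.
#' @export
c_sensitivity <- function(est, truth_binary) {
  E <- .mat_of(est)
  B <- if (inherits(truth_binary, "ddc_network")) edge_mask(truth_binary)
       else .mat_of(truth_binary) != 0
  if (!all(dim(E) == dim(B))) stop("matrices differ in shape")
  off <- row(E) != col(E)
  pos <- abs(E[off & B])
  neg <- abs(E[off & !B])
  if (!length(pos)) stop("ground truth has no true edges")
  if (length(neg) < 20L)
    warning("fewer than 20 non-edges; the 95th percentile is unstable")
  mean(pos > stats::quantile(neg, 0.95))
}

#' Subject identification from matrix collections
#'
#' For every target matrix, database matrices are ranked by Pearson
#' correlation of their vectorized off-diagonal entries; identification
#' succeeds when the true label sits in the top-\code{m} candidate pool.
#' Accuracy is the fraction of successful targets and is nondecreasing in
#' \code{m}.
#'
#' @param database named list of square matrices, one per subject.
#' @param targets named list of square matrices, labels drawn from the same
#'   set.
#' @param m candidate pool size.
#' @return Identification accuracy in \code{[0, 1]}.
#' @export
subject_identification <- function(database, targets, m = 1L) {
  if (is.null(names(database)) || is.null(names(targets)))
    stop("`database` and `targets` must be named by subject")
  if (!all(names(targets) %in% names(database)))
    stop("target label(s) missing from the database: ",
         paste(setdiff(names(targets), names(database)), collapse = ", "))
  vecize <- function(M) { M <- .mat_of(M); M[row(M) != col(M)] }
  dbv <- vapply(database, vecize, numeric(length(vecize(database[[1]]))))
  hits <- vapply(names(targets), function(lab) {
    r <- as.vector(stats::cor(vecize(targets[[lab]]), dbv))
    pool <- colnames(dbv)[order(r, decreasing = TRUE)[seq_len(min(m, ncol(dbv)))]]
    lab %in% pool
  }, logical(1))
  mean(hits)
}
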