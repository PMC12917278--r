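# Risk estimates from error and weight vectors, and the three comparison
# metrics (MAPE, RMSE, RMSPE) used to score estimators against the
# ground-truth risk across repetitions.

risk_estimate <- function(value, method, n_used, metadata = list()) {
  if (!is.finite(value) || value < 0)
    stop("risk_estimate: value must be finite and nonnegative", call. = FALSE)
  structure(list(value = value, method = method, n_used = n_used,
                 metadata = metadata), class = "risk_estimate")
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("risk estimate [%s]: %.6g (n = %d)\n", x$method, x$value, x$n_used))
  invisible(x)
}

#' Ground-truth Monte Carlo risk from target-test errors
#'
#' The arithmetic mean of the errors on the labeled target test sample: an
#' unbiased Monte Carlo estimate of the true risk, used only as the benchmark
#' the other estimators are compared against.
#'
#' @param target_test_errors Nonempty `error_vector` (or numeric vector).
#' @return A `risk_estimate` with `method = "gt"`.
#' @export
ground_truth_risk <- function(target_test_errors) {
  e <- as.numeric(target_test_errors)
  if (length(e) == 0L) stop("ground_truth_risk: empty error vector", call. = FALSE)
  risk_estimate(mean(e), "gt", length(e))
}

#' Weighted risk estimate from source-test errors
#'
#' (1/n) sum_i w_i e_i. With all-ones weights this is the no-weighting (NW)
#' estimator; otherwise the method tag is inherited from the weight vector
#' (iw, classifier, kmm).
#'
#' @param source_test_errors `error_vector` (or numeric vector).
#' @param weights A `weight_vector` of equal length, or `NULL` for NW.
#' @return A `risk_estimate`.
#' @export
weighted_risk <- function(source_test_errors, weights = NULL) {
  e <- as.numeric(source_test_errors)
  if (is.null(weights)) weights <- weight_vector(rep(1, length(e)), "nw")
  w <- as.numeric(weights)
  if (length(w) != length(e))
    stop("weighted_risk: errors and weights differ in length", call. = FALSE)
  risk_estimate(mean(w * e), attr(weights, "method") %||% "nw", length(e),
                metadata = attr(weights, "diagnostics") %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' MAPE, RMSE and RMSPE between ground-truth and estimated risks
#'
#' Across n repetitions: MAPE = 100 * mean(|gt - est| / gt), RMSE =
#' sqrt(mean((gt - est)^2)) on the raw risk scale, RMSPE = 100 *
#' sqrt(mean(((gt - est)/gt)^2)). Percentage metrics are reported x100 to
#' match the conventional tabulation. Ground-truth values at or below the
#' guard are rejected, since percentage metrics are undefined for an
#' error-free model.
#'
#' @param gt,est Equal-length numeric vectors of ground-truth and estimated
#'   risks (one entry per repetition).
#' @param guard Positive lower guard on `gt` (default 1e-12).
#' @return Named numeric vector `c(mape, rmse, rmspe)`.
#' @export
risk_metrics <- function(gt, est, guard = 1e-12) {
  gt <- as.numeric(gt); est <- as.numeric(est)
  if (length(gt) != length(est) || length(gt) < 1L)
    stop("risk_metrics: need equal nonempty vectors", call. = FALSE)
  if (any(gt <= guard))
    stop("risk_metrics: degenerate ground truth (value <= guard); ",
         "percentage metrics undefined", call. = FALSE)
  pe <- (gt - est) / gt
  c(mape = 100 * mean(abs(pe)),
    rmse = sqrt(mean((gt - est)^2)),
    rmspe = 100 * sqrt(mean(pe^2)))
}
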