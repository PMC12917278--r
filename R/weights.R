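# Importance weights by the density-ratio (KDE) and classifier routes, plus
# the bandwidth rules they rely on. The kernel mean matching route lives in
# kmm.R.

#' Scott's-rule bandwidth matrix
#'
#' H = Sigma_hat * n^(-2/(d+4)), with Sigma_hat the sample covariance of the
#' training points. Data-driven: the bandwidth adapts to the scale and sample
#' size, shrinking entrywise by 2^(-2/(d+4)) when n doubles.
#'
#' @param train A `point_set` with n >= 2 and nonsingular sample covariance.
#' @return A `bandwidth_matrix` (symmetric positive-definite d x d matrix).
#' @export
scott_bandwidth <- function(train) {
  stopifnot(inherits(train, "point_set"))
  if (train$n < 2L) stop("scott_bandwidth: need n >= 2", call. = FALSE)
  sigma <- stats::cov(train$coords)
  H <- sigma * train$n^(-2 / (train$d + 4))
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev), 1))
    stop("scott_bandwidth: degenerate data (singular sample covariance)",
         call. = FALSE)
  structure(H, class = "bandwidth_matrix")
}

#' Fit a multivariate Gaussian kernel density estimate
#'
#' ghat(x) = (1/n) sum_i |H|^(-1/2) K(H^(-1/2)(x - x_i)) with K the standard
#' multivariate Gaussian kernel. Evaluation uses a Cholesky whitening of H.
#'
#' @param train A `point_set` of support points.
#' @param H Bandwidth matrix; default [scott_bandwidth()] of `train`.
#' @return A `density_model`; evaluate with [kde_eval()].
#' @export
kde_fit <- function(train, H = NULL) {
  stopifnot(inherits(train, "point_set"))
  if (is.null(H)) H <- scott_bandwidth(train)
  H <- unclass(H)
  if (nrow(H) != train$d) stop("kde_fit: bandwidth dimension mismatch", call. = FALSE)
  if (max(abs(H - t(H))) > 1e-10) stop("kde_fit: H must be symmetric", call. = FALSE)
  L <- t(chol(H))                       # H = L L'
  white <- t(forwardsolve(L, t(train$coords)))
  structure(list(train = train, H = H, L = L, white = white,
                 log_det_half = sum(log(diag(L))), d = train$d, n = train$n),
            class = "density_model")
}

#' Evaluate a fitted kernel density estimate
#'
#' @param model A `density_model` from [kde_fit()].
#' @param x Coordinate matrix or `point_set`.
#' @param block Evaluation block size (memory control).
#' @return Nonnegative density values, one per row of `x`.
#' @export
kde_eval <- function(model, x, block = 2048L) {
  stopifnot(inherits(model, "density_model"))
  if (inherits(x, "point_set")) x <- x$coords
  if (is.vector(x)) x <- matrix(x, ncol = model$d)
  if (ncol(x) != model$d) stop("kde_eval: dimension mismatch", call. = FALSE)
  xw <- t(forwardsolve(model$L, t(x)))
  const <- exp(-model$log_det_half) * (2 * pi)^(-model$d / 2) / model$n
  tr2 <- rowSums(model$white^2)
  out <- numeric(nrow(xw))
  for (s in seq(1L, nrow(xw), by = block)) {
    idx <- s:min(s + block - 1L, nrow(xw))
    d2 <- outer(rowSums(xw[idx, , drop = FALSE]^2), tr2, "+") -
      2 * xw[idx, , drop = FALSE] %*% t(model$white)
    d2[d2 < 0] <- 0
    out[idx] <- const * rowSums(exp(-d2 / 2))
  }
  out
}

# Constructor for weight vectors: nonnegative, finite, tagged with the method
# that produced them. Diagnostics (floored counts, solver status) ride along
# as attributes.
weight_vector <- function(values, method, diagnostics = list()) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < -1e-9))
    stop("weight_vector: weights must be finite and nonnegative", call. = FALSE)
  values[values < 0] <- 0
  structure(values, method = method, diagnostics = diagnostics,
            class = "weight_vector")
}

#' Export a weight vector as CSV
#'
#' Columns `index`, `weight`, `method` — the format used for
#' weight-distribution audits.
#'
#' @param weights A `weight_vector`.
#' @param path Output CSV path.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "weight_vector"))
  utils::write.csv(data.frame(index = seq_along(weights),
                              weight = as.numeric(weights),
                              method = attr(weights, "method")),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Importance weights from a KDE density ratio
#'
#' w_i = phat(x_i) / max(ghat(x_i), floor). The floor absorbs vanishing source
#' densities so weights stay finite; when the source density is tiny where the
#' target density is not, the resulting weights can still be enormous -- the
#' weight-explosion pathology this estimator is known for. A warning reports
#' how many denominators were floored.
#'
#' @param dens_p Target-density `density_model` (fitted on target train).
#' @param dens_g Source-density `density_model` (fitted on source train).
#' @param eval_points `point_set` at which the ratio is taken (source test).
#' @param floor Denominator floor (default 1e-12).
#' @return A `weight_vector` with `method = "iw"` and a `floored` diagnostic.
#' @export
iw_weights <- function(dens_p, dens_g, eval_points, floor = 1e-12) {
  p <- kde_eval(dens_p, eval_points)
  g <- kde_eval(dens_g, eval_points)
  n_floored <- sum(g < floor)
  if (n_floored > 0L)
    warning(sprintf("iw_weights: %d of %d source densities floored at %g",
                    n_floored, length(g), floor), call. = FALSE)
  weight_vector(p / pmax(g, floor), "iw", list(floored = n_floored))
}

#' Fit a source-vs-target domain classifier
#'
#' Pools the source training points (class 0) and target training points
#' (class 1) and fits a gradient-boosted probabilistic classifier. The
#' empirical class priors n_g/(n_g+n_p) and n_p/(n_g+n_p) are recorded for the
#' probability-ratio weight formula.
#'
#' @param source_train,target_train `point_set`s of equal dimensionality.
#' @param seed Integer seed.
#' @param posterior Optional function `coords -> P(target | x)` overriding the
#'   boosted classifier (used to plug in an analytic Bayes posterior).
#' @return A `domain_classifier`.
#' @export
fit_domain_classifier <- function(source_train, target_train, seed = 1L,
                                  posterior = NULL) {
  stopifnot(inherits(source_train, "point_set"), inherits(target_train, "point_set"))
  if (source_train$d != target_train$d)
    stop("fit_domain_classifier: dimension mismatch", call. = FALSE)
  n_g <- source_train$n; n_p <- target_train$n
  if (n_g < 1L || n_p < 1L)
    stop("fit_domain_classifier: empty domain sample", call. = FALSE)
  if (is.null(posterior)) {
    pooled <- point_set(rbind(source_train$coords, target_train$coords),
                        labels = c(rep(0, n_g), rep(1, n_p)))
    clf <- fit_black_box(pooled, "gb_classifier", seed = seed)
    posterior <- function(coords) predict_black_box(clf, coords)
  }
  structure(list(posterior = posterior,
                 prior_g = n_g / (n_g + n_p), prior_p = n_p / (n_g + n_p),
                 n_g_train = n_g, n_p_train = n_p, d = source_train$d),
            class = "domain_classifier")
}

#' Probability-ratio importance weights from a domain classifier
#'
#' w_i = (n_g_train / n_p_train) * (1 / P(g | x_i) - 1), clipped to
#' \[0, clip_max\]. With a perfectly calibrated posterior this equals the true
#' density ratio p(x)/g(x).
#'
#' @param clf A `domain_classifier`.
#' @param eval_points `point_set` (source test).
#' @param clip_max Upper clip, default 1000 for comparability with the KMM
#'   weight bound.
#' @return A `weight_vector` with `method = "classifier"` and a `clipped`
#'   diagnostic count.
#' @export
classifier_weights <- function(clf, eval_points, clip_max = 1000) {
  stopifnot(inherits(clf, "domain_classifier"))
  p_target <- clf$posterior(if (inherits(eval_points, "point_set"))
    eval_points$coords else eval_points)
  p_g <- 1 - p_target
  ratio <- ifelse(p_g <= 0, Inf, 1 / p_g - 1)
  w <- (clf$n_g_train / clf$n_p_train) * ratio
  n_clipped <- sum(w > clip_max | !is.finite(w))
  if (n_clipped > 0L)
    warning(sprintf("classifier_weights: %d of %d weights clipped at %g",
                    n_clipped, length(w), clip_max), call. = FALSE)
  weight_vector(pmin(pmax(w, 0), clip_max), "classifier",
                list(clipped = n_clipped))
}
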