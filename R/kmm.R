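# Kernel mean matching: RBF kernel with the median heuristic, the Gram/kappa
# problem construction, and the box- and sum-constrained quadratic program
# whose solution reweights the source test sample to match the target test
# sample in RKHS mean embedding.
#
# The quadratic program is derived directly from the mean-embedding objective
#   || (1/n_p) sum_j phi(x'_j) - (1/n_g) sum_i w_i phi(x_i) ||^2
# which expands (dropping the constant) to
#   (1/n_g^2) w' K w - (2/(n_g n_p)) sum_i w_i sum_j K(x_i, x'_j)
# subject to 0 <= w_i <= B and sum_i w_i = n_g. After rescaling by n_g^2/2 the
# solver sees 0.5 w'Kw - n_g kappa'w with kappa_i the mean target similarity.

#' Median-heuristic RBF bandwidth
#'
#' sigma^2 = median of the squared pairwise distances over unordered distinct
#' pairs (self-pairs excluded, since including the diagonal's zeros is a
#' degenerate reading of the median heuristic), divided by log n (natural
#' logarithm).
#'
#' @param points A `point_set` with n >= 2.
#' @return Positive scalar sigma^2 (squared domain units). Falls back to 1
#'   with a warning when all points coincide.
#' @export
median_sigma <- function(points) {
  stopifnot(inherits(points, "point_set"))
  if (points$n < 2L) stop("median_sigma: need n >= 2", call. = FALSE)
  d2 <- stats::dist(points$coords)^2
  med <- stats::median(d2)
  if (med <= 0) {
    warning("median_sigma: degenerate geometry (median pairwise distance 0); ",
            "falling back to sigma^2 = 1", call. = FALSE)
    return(1)
  }
  med / log(points$n)
}

#' RBF (Gaussian) kernel Gram matrix
#'
#' K_ij = exp(-||x_i - z_j||^2 / (2 sigma^2)); entries in (0, 1\].
#'
#' @param X,Z `point_set`s or coordinate matrices of equal dimensionality.
#' @param sigma2 Positive bandwidth (squared units).
#' @return Numeric matrix nrow(X) x nrow(Z).
#' @export
rbf_gram <- function(X, Z, sigma2) {
  if (inherits(X, "point_set")) X <- X$coords
  if (inherits(Z, "point_set")) Z <- Z$coords
  if (!is.numeric(sigma2) || sigma2 <= 0)
    stop("rbf_gram: sigma2 must be positive", call. = FALSE)
  if (ncol(X) != ncol(Z)) stop("rbf_gram: dimension mismatch", call. = FALSE)
  d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * X %*% t(Z)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma2))
}

#' Kernel configuration for KMM
#'
#' @param sigma2 RBF bandwidth; `NULL` selects the median heuristic on the
#'   source test points at problem-build time.
#' @param B Upper weight bound (default 1000, large enough that weights are
#'   effectively unclipped in the benchmark runs).
#' @return A `kernel_config`.
#' @export
kernel_config <- function(sigma2 = NULL, B = 1000) {
  if (!is.null(sigma2) && sigma2 <= 0)
    stop("kernel_config: sigma2 must be positive", call. = FALSE)
  if (B < 1) stop("kernel_config: B must be >= 1", call. = FALSE)
  structure(list(sigma2 = sigma2, B = B), class = "kernel_config")
}

#' Assemble the KMM quadratic program
#'
#' Builds the Gram matrix K over the source test points and the
#' target-similarity vector kappa_i = (1/n_p) sum_j K(x_i, x'_j). The feature
#' map is never materialized; K and kappa represent it.
#'
#' @param source_test,target_test Nonempty `point_set`s.
#' @param config A [kernel_config()].
#' @return A `kmm_problem` with `K`, `kappa`, `n_source`, `n_target`,
#'   `sigma2`, `B`.
#' @export
build_kmm_problem <- function(source_test, target_test,
                              config = kernel_config()) {
  stopifnot(inherits(config, "kernel_config"))
  if (inherits(source_test, "point_set") && is.null(config$sigma2))
    config$sigma2 <- median_sigma(source_test)
  s2 <- config$sigma2
  if (is.null(s2)) stop("build_kmm_problem: sigma2 unset", call. = FALSE)
  K <- rbf_gram(source_test, source_test, s2)
  kappa <- rowMeans(rbf_gram(source_test, target_test, s2))
  structure(list(K = K, kappa = kappa, n_source = nrow(K),
                 n_target = if (inherits(target_test, "point_set"))
                   target_test$n else nrow(target_test),
                 sigma2 = s2, B = config$B),
            class = "kmm_problem")
}

# Scaled QP objective 0.5 w'Kw - n_g kappa'w (the mean-embedding objective
# times n_g^2/2, constant dropped).
kmm_objective <- function(problem, w) {
  0.5 * drop(crossprod(w, problem$K %*% w)) -
    problem$n_source * sum(problem$kappa * w)
}

# Euclidean projection onto {w : sum(w) = s, 0 <= w <= B} by bisection on the
# shift parameter of w = clamp(v - tau, 0, B).
project_polytope <- function(v, s, B, tol = 1e-12) {
  f <- function(tau) sum(pmin(pmax(v - tau, 0), B)) - s
  lo <- min(v) - B - 1; hi <- max(v) + 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  w <- pmin(pmax(v - (lo + hi) / 2, 0), B)
  # exact equality on the sum: distribute the residual over interior entries
  free <- which(w > 0 & w < B)
  if (length(free) > 0L) w[free] <- w[free] + (s - sum(w)) / length(free)
  pmin(pmax(w, 0), B)
}

#' Solve the KMM quadratic program
#'
#' Minimizes the mean-embedding objective subject to 0 <= w_i <= B and
#' sum(w) = n_source (the equality enforced exactly, not as a tolerance band).
#' An interior-point solve (kernlab's ipop, with a +1e-8 diagonal jitter on the
#' Gram matrix for strict positive definiteness) is followed by a monotone
#' projected-gradient polish, so the returned weights are exactly feasible and
#' their objective never exceeds that of the always-feasible all-ones vector.
#'
#' @param problem A `kmm_problem` from [build_kmm_problem()].
#' @param maxiter Interior-point iteration cap.
#' @param polish_iter Projected-gradient polish iterations.
#' @return A `weight_vector` with `method = "kmm"`; diagnostics carry the
#'   solver status, final objective and the all-ones objective.
#' @export
solve_kmm <- function(problem, maxiter = 200L, polish_iter = 300L) {
  stopifnot(inherits(problem, "kmm_problem"))
  n <- problem$n_source; B <- problem$B
  Kj <- problem$K + diag(1e-8, n)
  prob <- list(K = Kj, kappa = problem$kappa, n_source = n)
  ones <- rep(1, n)
  status <- "converged"
  w0 <- tryCatch({
    sol <- kernlab::ipop(c = -n * problem$kappa, H = Kj,
                         A = matrix(1, 1L, n), b = n,
                         l = rep(0, n), u = rep(B, n), r = 0,
                         sigf = 9, maxiter = maxiter)
    status <- kernlab::how(sol)
    kernlab::primal(sol)
  }, error = function(e) {
    status <<- paste("ipop failed:", conditionMessage(e))
    ones
  })
  w0 <- project_polytope(w0, n, B)
  # start the monotone polish from the better of the solver point and all-ones
  start <- if (kmm_objective(prob, w0) <= kmm_objective(prob, ones)) w0 else ones
  L <- n  # ||K||_2 <= n for an RBF Gram matrix with unit diagonal
  w <- start; fw <- kmm_objective(prob, w)
  for (i in seq_len(polish_iter)) {
    g <- Kj %*% w - n * problem$kappa
    w_new <- project_polytope(w - drop(g) / L, n, B)
    f_new <- kmm_objective(prob, w_new)
    if (f_new > fw) break
    improved <- fw - f_new
    w <- w_new; fw <- f_new
    if (improved < 1e-12 * max(1, abs(fw))) break
  }
  weight_vector(w, "kmm",
                list(solver_status = status, objective = fw,
                     objective_ones = kmm_objective(prob, ones),
                     max_weight = max(w)))
}

#' Empirical squared maximum mean discrepancy between weighted source and target
#'
#' MMD^2 = (1/n_g^2) w'K_ss w - (2/(n_g n_p)) w'K_st 1 + (1/n_p^2) 1'K_tt 1,
#' with unit weights by default. KMM weights minimize this quantity over the
#' feasible polytope.
#'
#' @param source,target `point_set`s or coordinate matrices.
#' @param sigma2 RBF bandwidth; default median heuristic on the source points.
#' @param weights Source weights (default all ones).
#' @return Nonnegative scalar (up to numerical roundoff).
#' @export
mmd2 <- function(source, target, sigma2 = NULL, weights = NULL) {
  if (!inherits(source, "point_set")) source <- point_set(source)
  if (!inherits(target, "point_set")) target <- point_set(target)
  if (is.null(sigma2)) sigma2 <- median_sigma(source)
  ng <- source$n; np <- target$n
  w <- if (is.null(weights)) rep(1, ng) else as.numeric(weights)
  Kss <- rbf_gram(source, source, sigma2)
  Kst <- rbf_gram(source, target, sigma2)
  Ktt <- rbf_gram(target, target, sigma2)
  drop(crossprod(w, Kss %*% w)) / ng^2 - 2 * sum(w * rowSums(Kst)) / (ng * np) +
    sum(Ktt) / np^2
}
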