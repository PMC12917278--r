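# Synthetic data generation: Gaussian-mixture and uniform samplers on
# [0,100]^d, the ten bidirectional shift scenarios, the smooth ground-truth
# function, and train/test splitting.
#
# Mixture components are centered uniformly in the bounds. Each component
# covariance is SPD with largest eigenvalue at most sigma_max: eigenvalues are
# drawn i.i.d. U(0.2*sigma_max, sigma_max) and rotated by a seeded random
# orthogonal matrix (QR of a Gaussian matrix), except where a scenario demands
# an axis-aligned (diagonal) covariance. Points falling outside the bounds (or
# outside a scenario's truncation region) are replaced by rejection
# re-sampling, so the requested sample size is exact and no boundary atoms are
# created.

random_orthogonal <- function(d) {
  qr_ <- qr(matrix(stats::rnorm(d * d), d))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_)) + (diag(qr.R(qr_)) == 0)), d)
}

# Draw one component covariance. cov_type: "random" (rotated, generic),
# "diagonal" (axis-aligned), "rotated" (same eigenvalues as the diagonal
# counterpart but rotated so that a genuine correlation appears; the rotation
# is redrawn until the induced correlation is non-negligible, which isolates
# the correlation change as the only shift).
draw_cov <- function(d, sigma_max, cov_type = "random", eigenvalues = NULL) {
  ev <- if (is.null(eigenvalues)) stats::runif(d, 0.2 * sigma_max, sigma_max)
        else eigenvalues
  if (cov_type == "diagonal") return(list(cov = diag(ev, d), eigenvalues = ev))
  if (cov_type == "rotated") {
    best <- NULL; best_corr <- -1
    for (i in 1:500) {
      q <- random_orthogonal(d)
      cv <- q %*% diag(ev, d) %*% t(q)
      corr <- max(abs(stats::cov2cor(cv)[upper.tri(cv)]))
      if (corr > best_corr) { best <- cv; best_corr <- corr }
      if (corr >= 0.2) break
    }
    return(list(cov = best, eigenvalues = ev))
  }
  q <- random_orthogonal(d)
  list(cov = q %*% diag(ev, d) %*% t(q), eigenvalues = ev)
}

# Eigenvalues spread across [0.2, 1] * sigma_max (with multiplicative jitter)
# for the correlation scenarios: i.i.d. draws can be nearly equal, making the
# component almost isotropic, in which case no rotation induces a correlation
# -- the spread guarantees the anisotropy the scenario is about.
spread_eigenvalues <- function(d, sigma_max) {
  base <- if (d == 1L) 1 else seq(0.2, 1, length.out = d)
  pmin(base * stats::runif(d, 0.9, 1.1), 1) * sigma_max
}

# Mixture specification: list of centers (m x d), covariances (list of d x d),
# equal mixing weights 1/m.
gmm_spec <- function(d, n_components, sigma_max, bounds, seed,
                     centers = NULL, cov_type = "random", eigenvalues = NULL) {
  b <- expand_bounds(bounds, d)
  centers <- if (is.null(centers)) {
    with_seed(derive_seed(seed, "centers"), {
      matrix(stats::runif(n_components * d, rep(b[, 1L], each = n_components),
                          rep(b[, 2L], each = n_components)), n_components, d)
    })
  } else matrix(centers, ncol = d)
  m <- nrow(centers)
  covs <- with_seed(derive_seed(seed, "covariances"), {
    lapply(seq_len(m), function(i)
      draw_cov(d, sigma_max, cov_type,
               eigenvalues = if (is.null(eigenvalues)) NULL else eigenvalues[[i]])$cov)
  })
  list(d = d, centers = centers, covs = covs, bounds = b)
}

# Cholesky-based multivariate normal draw.
rmvnorm_chol <- function(n, mean, cov) {
  d <- length(mean)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% chol(cov), 2L, mean, "+")
}

# Sample n points from a mixture spec by rejection: points outside the bounds
# or failing `region` (a predicate on the coordinate matrix) are redrawn.
sample_from_spec <- function(spec, n, seed, region = NULL) {
  d <- spec$d; b <- spec$bounds; m <- nrow(spec$centers)
  with_seed(derive_seed(seed, "points"), {
    out <- matrix(NA_real_, 0L, d)
    guard <- 0L
    while (nrow(out) < n) {
      need <- n - nrow(out)
      batch <- max(need * 2L, 64L)
      comp <- sample.int(m, batch, replace = TRUE)
      x <- matrix(NA_real_, batch, d)
      for (k in unique(comp)) {
        idx <- which(comp == k)
        x[idx, ] <- rmvnorm_chol(length(idx), spec$centers[k, ], spec$covs[[k]])
      }
      keep <- rowSums(sweep(x, 2L, b[, 1L], "<") | sweep(x, 2L, b[, 2L], ">")) == 0L
      if (!is.null(region)) keep <- keep & region(x)
      out <- rbind(out, x[keep, , drop = FALSE])
      guard <- guard + 1L
      if (guard > 10000L)
        stop("sample_from_spec: rejection sampling failed to accept points; ",
             "the mixture places negligible mass in the admissible region",
             call. = FALSE)
    }
    out[seq_len(n), , drop = FALSE]
  })
}

#' Sample from a random Gaussian mixture on a bounded domain
#'
#' Components are centered uniformly in `bounds`; each covariance is SPD with
#' largest eigenvalue at most `sigma_max` (eigenvalues U(0.2*sigma_max,
#' sigma_max), random rotation). Mixing weights are uniform. Points outside the
#' bounds are rejection re-sampled, so all n points lie strictly inside.
#'
#' @param d Dimensionality (>= 1).
#' @param n Number of points (>= 1).
#' @param sigma_max Positive upper bound on component covariance eigenvalues
#'   (squared domain units). Small values give tight, distinct clusters; large
#'   values a diffuse cloud.
#' @param n_components Number of mixture components (default 30).
#' @param bounds Domain, either `c(lo, hi)` per axis or a d x 2 matrix
#'   (default `c(0, 100)`).
#' @param seed Integer seed; the draw is a pure function of the arguments.
#' @return A `point_set`.
#' @export
sample_gmm <- function(d, n, sigma_max, n_components = 30L, bounds = c(0, 100),
                       seed = 1L) {
  if (!is.numeric(sigma_max) || sigma_max <= 0)
    stop("sample_gmm: sigma_max must be positive", call. = FALSE)
  if (n < 1L) stop("sample_gmm: n must be >= 1", call. = FALSE)
  spec <- gmm_spec(d, n_components, sigma_max, bounds, seed)
  point_set(sample_from_spec(spec, n, seed))
}

#' Sample uniformly on a bounded domain (CSR)
#'
#' @inheritParams sample_gmm
#' @return A `point_set` of i.i.d. uniform points.
#' @export
sample_uniform <- function(d, n, bounds = c(0, 100), seed = 1L) {
  if (n < 1L) stop("sample_uniform: n must be >= 1", call. = FALSE)
  b <- expand_bounds(bounds, d)
  coords <- with_seed(derive_seed(seed, "points"), {
    matrix(stats::runif(n * d, rep(b[, 1L], each = n), rep(b[, 2L], each = n)), n, d)
  })
  point_set(coords)
}

#' The ten bidirectional shift scenarios
#'
#' @return Character vector of scenario identifiers.
#' @export
scenario_ids <- function() c(
  "domain_truncation_cropped_to_full", "domain_truncation_full_to_cropped",
  "mode_expansion", "mode_contraction",
  "correlation_shift", "correlation_restoration",
  "variance_focusing", "variance_extrapolation",
  "support_mismatch_uniform_to_gmm", "support_mismatch_gmm_to_uniform")

#' Scenario configuration
#'
#' Bundles the parameters of one synthetic source/target generation recipe.
#'
#' @param scenario_id One of [scenario_ids()].
#' @param d Dimensionality, 2 to 4 in the benchmark runs.
#' @param n_points Points per domain (default 10000).
#' @param n_components Mixture components for multi-modal recipes (default 30).
#' @param bounds Domain bounds (default `c(0, 100)`).
#' @param seed Integer master seed for the scenario draw.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario_id, d = 2L, n_points = 10000L,
                            n_components = 30L, bounds = c(0, 100), seed = 1L) {
  if (!scenario_id %in% scenario_ids())
    stop(sprintf("unknown scenario '%s'; see scenario_ids()", scenario_id),
         call. = FALSE)
  if (n_points < 10L) stop("scenario_config: n_points must be >= 10", call. = FALSE)
  structure(list(scenario_id = scenario_id, d = as.integer(d),
                 n_points = as.integer(n_points),
                 n_components = as.integer(n_components),
                 bounds = bounds, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate the source/target pair of a named shift scenario
#'
#' Implements the ten bidirectional recipes: domain truncation (cropped vs.
#' full, the cropped side restricted to the lower half `x2 < 50` by rejection),
#' mode expansion/contraction (single centered component vs. a 30-component
#' mixture), correlation shift/restoration (a single centered component with
#' diagonal vs. rotated covariance sharing the same eigenvalues), variance
#' focusing/extrapolation (sigma_max 400 vs. 50), and support mismatch
#' (uniform vs. clustered mixture with sigma_max 50).
#'
#' @param config A [scenario_config()].
#' @return List with `source` and `target` point sets, each of
#'   `config$n_points` points.
#' @export
make_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  d <- config$d; n <- config$n_points; b <- config$bounds
  m <- config$n_components; seed <- config$seed
  s_seed <- derive_seed(seed, "source"); t_seed <- derive_seed(seed, "target")
  bm <- expand_bounds(b, d)
  center <- (bm[, 1L] + bm[, 2L]) / 2
  lower_half <- function(x) x[, 2L] < (bm[2L, 1L] + bm[2L, 2L]) / 2

  gmm_side <- function(side_seed, sigma_max, n_comp = m, centers = NULL,
                       cov_type = "random", eigenvalues = NULL, region = NULL) {
    spec <- gmm_spec(d, n_comp, sigma_max, b, side_seed, centers = centers,
                     cov_type = cov_type, eigenvalues = eigenvalues)
    point_set(sample_from_spec(spec, n, side_seed, region = region))
  }

  out <- switch(config$scenario_id,
    domain_truncation_cropped_to_full = list(
      source = gmm_side(s_seed, 50, region = lower_half),
      target = gmm_side(t_seed, 400)),
    domain_truncation_full_to_cropped = list(
      source = gmm_side(s_seed, 400),
      target = gmm_side(t_seed, 50, region = lower_half)),
    mode_expansion = list(
      source = gmm_side(s_seed, 50, n_comp = 1L, centers = center),
      target = gmm_side(t_seed, 10)),
    mode_contraction = list(
      source = gmm_side(s_seed, 10),
      target = gmm_side(t_seed, 50, n_comp = 1L, centers = center)),
    correlation_shift = {
      # shared eigenvalues so the rotation is the only change
      ev <- with_seed(derive_seed(seed, "shared_eigenvalues"),
                      list(spread_eigenvalues(d, 150)))
      list(source = gmm_side(s_seed, 150, n_comp = 1L, centers = center,
                             cov_type = "diagonal", eigenvalues = ev),
           target = gmm_side(t_seed, 150, n_comp = 1L, centers = center,
                             cov_type = "rotated", eigenvalues = ev))
    },
    correlation_restoration = {
      ev <- with_seed(derive_seed(seed, "shared_eigenvalues"),
                      list(spread_eigenvalues(d, 150)))
      list(source = gmm_side(s_seed, 150, n_comp = 1L, centers = center,
                             cov_type = "rotated", eigenvalues = ev),
           target = gmm_side(t_seed, 150, n_comp = 1L, centers = center,
                             cov_type = "diagonal", eigenvalues = ev))
    },
    variance_focusing = list(
      source = gmm_side(s_seed, 400),
      target = gmm_side(t_seed, 50)),
    variance_extrapolation = list(
      source = gmm_side(s_seed, 50),
      target = gmm_side(t_seed, 400)),
    support_mismatch_uniform_to_gmm = list(
      source = sample_uniform(d, n, b, s_seed),
      target = gmm_side(t_seed, 50)),
    support_mismatch_gmm_to_uniform = list(
      source = gmm_side(s_seed, 50),
      target = sample_uniform(d, n, b, t_seed)),
    stop(sprintf("unknown scenario '%s'", config$scenario_id), call. = FALSE))
  out$source$domain_tag <- "source"; out$target$domain_tag <- "target"
  out
}

#' Smooth synthetic ground-truth function
#'
#' A mixture of Gaussian bumps f(x) = sum_k a_k exp(-||x - c_k||^2 / (2 s_k^2))
#' with m bumps, amplitudes a_k ~ U(-1, 1), widths s_k ~ U(5, 25) domain units
#' and centers uniform in the bounds. The multiscale structure makes the fitted
#' model's error vary spatially, which is what the risk estimators must track.
#'
#' @param d Dimensionality.
#' @param seed Integer seed; the function is deterministic given the seed.
#' @param m Number of bumps (default 10).
#' @param amplitude_range,width_range Ranges for a_k and s_k.
#' @param bounds Domain bounds for the centers.
#' @return A `true_function` object; evaluate with [eval_true_function()].
#' @export
make_true_function <- function(d, seed = 1L, m = 10L,
                               amplitude_range = c(-1, 1),
                               width_range = c(5, 25), bounds = c(0, 100)) {
  if (d < 1L) stop("make_true_function: d must be >= 1", call. = FALSE)
  b <- expand_bounds(bounds, d)
  with_seed(derive_seed(seed, "true_function"), {
    centers <- matrix(stats::runif(m * d, rep(b[, 1L], each = m),
                                   rep(b[, 2L], each = m)), m, d)
    amplitudes <- stats::runif(m, amplitude_range[1L], amplitude_range[2L])
    widths <- stats::runif(m, width_range[1L], width_range[2L])
    structure(list(centers = centers, amplitudes = amplitudes, widths = widths,
                   d = d, seed = seed), class = "true_function")
  })
}

#' Evaluate a true function at a coordinate matrix
#'
#' @param fn A `true_function`.
#' @param x Numeric matrix (n x d) or vector (one point).
#' @return Numeric vector of length n, bounded by `sum(abs(fn$amplitudes))`.
#' @export
eval_true_function <- function(fn, x) {
  stopifnot(inherits(fn, "true_function"))
  if (is.vector(x)) x <- matrix(x, ncol = fn$d)
  if (ncol(x) != fn$d) stop("eval_true_function: dimension mismatch", call. = FALSE)
  d2 <- outer(rowSums(x^2), rowSums(fn$centers^2), "+") - 2 * x %*% t(fn$centers)
  d2[d2 < 0] <- 0
  drop(exp(-sweep(d2, 2L, 2 * fn$widths^2, "/")) %*% fn$amplitudes)
}

#' Random train/test split of a point set
#'
#' Disjoint, exhaustive partition with `floor(train_frac * n)` training points.
#'
#' @param points A `point_set` with n >= 2.
#' @param train_frac Training fraction in (0, 1); default 0.7 as in the
#'   benchmark protocol.
#' @param seed Integer seed.
#' @return List with `train` and `test` point sets.
#' @export
split_points <- function(points, train_frac = 0.7, seed = 1L) {
  stopifnot(inherits(points, "point_set"))
  if (points$n < 2L) stop("split_points: need at least 2 points", call. = FALSE)
  if (train_frac <= 0 || train_frac >= 1)
    stop("split_points: train_frac must be in (0, 1)", call. = FALSE)
  n_train <- floor(train_frac * points$n)
  if (n_train < 1L || n_train >= points$n)
    stop("split_points: split leaves an empty partition", call. = FALSE)
  idx <- with_seed(derive_seed(seed, "split"), sample.int(points$n, n_train))
  list(train = subset_points(points, sort(idx), split_tag = "train"),
       test = subset_points(points, setdiff(seq_len(points$n), idx),
                            split_tag = "test"))
}
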