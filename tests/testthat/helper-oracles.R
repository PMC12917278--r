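# Shared fixtures and independent oracles used across the suite. Everything is
# generated in code at test time.

# Data with an exactly prescribed sample mean and covariance: whiten a random
# draw by its own sample statistics, then color with the target.
exact_cov_data <- function(n, sigma, mean = rep(0, nrow(sigma)), seed = 1) {
  d <- nrow(sigma)
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d)
  x <- sweep(x, 2L, colMeans(x))
  x <- x %*% solve(chol(cov(x)))
  sweep(x %*% chol(sigma), 2L, mean, "+")
}

# Truncated normal on [0, 100]: density and inverse-CDF sampler.
dtrunc100 <- function(x, mu, s)
  dnorm(x, mu, s) / (pnorm(100, mu, s) - pnorm(0, mu, s))
rtrunc100 <- function(n, mu, s) {
  u <- runif(n, pnorm(0, mu, s), pnorm(100, mu, s))
  qnorm(u, mu, s)
}

# Exhaustive coarse-to-fine grid minimizer of the KMM objective over the
# feasible polytope {sum w = n, 0 <= w <= B}, for n_source <= 3. Independent
# of the package's solver: works directly on K and kappa.
kmm_grid_oracle <- function(K, kappa, B) {
  n <- nrow(K)
  obj_many <- function(W) 0.5 * colSums(W * (K %*% W)) - n * colSums(kappa * W)
  if (n == 1L) return(1)
  if (n == 2L) {
    lo <- max(0, n - B); hi <- min(B, n)
    best <- n / 2
    for (step in c(0.02, 2e-4)) {
      g <- seq(max(lo, best - 0.04), min(hi, best + 0.04), by = step)
      if (step == 0.02) g <- seq(lo, hi, by = step)
      W <- rbind(g, n - g)
      best <- g[which.min(obj_many(W))]
    }
    return(c(best, n - best))
  }
  lo <- max(0, n - 2 * B); hi <- min(B, n)
  best <- c(1, 1)
  for (step in c(0.02, 1e-3, 1e-4)) {
    if (step == 0.02) {
      g1 <- seq(lo, hi, by = step); g2 <- g1
    } else {
      g1 <- seq(max(lo, best[1] - 2 * 0.02), min(hi, best[1] + 2 * 0.02), by = step)
      g2 <- seq(max(lo, best[2] - 2 * 0.02), min(hi, best[2] + 2 * 0.02), by = step)
    }
    grid <- expand.grid(w1 = g1, w2 = g2)
    w3 <- n - grid$w1 - grid$w2
    ok <- w3 >= 0 & w3 <= B
    grid <- grid[ok, ]; w3 <- w3[ok]
    W <- rbind(grid$w1, grid$w2, w3)
    i <- which.min(obj_many(W))
    best <- c(grid$w1[i], grid$w2[i])
  }
  c(best, n - sum(best))
}

kmm_objective_raw <- function(K, kappa, w) {
  n <- nrow(K)
  0.5 * drop(crossprod(w, K %*% w)) - n * sum(kappa * w)
}

# A random small KMM problem with well-separated source points (minimum
# pairwise spacing 1 in [0, 10]^d), so the optimum is well localized.
random_small_kmm <- function(seed) {
  set.seed(seed)
  n_s <- sample(1:3, 1)
  n_t <- sample(1:5, 1)
  d <- sample(1:2, 1)
  repeat {
    xs <- matrix(runif(n_s * d, 0, 10), n_s, d)
    if (n_s == 1L || min(dist(xs)) > 1) break
  }
  xt <- matrix(runif(n_t * d, 0, 10), n_t, d)
  sigma2 <- runif(1, 0.3, 3)
  B <- sample(c(1.5, 2, 5, 1000), 1)
  build_kmm_problem(point_set(xs), point_set(xt),
                    kernel_config(sigma2 = sigma2, B = B))
}

# Labeled source/target pair for classification runs: clustered mixture source,
# dispersed target, class membership determined by the sign of the smooth
# ground-truth surface (spatially coherent classes, as in presence/absence or
# cell-type regions, so candidate models differ genuinely in target risk).
labeled_classification_pair <- function(n = 500, d = 2, seed = 1,
                                        source_sigma = 30, target = "uniform") {
  src <- sample_gmm(d, n, source_sigma, seed = derive_seed(seed, "src"))
  tgt <- if (identical(target, "uniform"))
    sample_uniform(d, n, seed = derive_seed(seed, "tgt"))
  else sample_gmm(d, n, target, seed = derive_seed(seed, "tgt"))
  # redraw the class surface until both domains carry a usable class mix
  for (attempt in 1:50) {
    fn <- make_true_function(d, seed = derive_seed(seed, paste0("surface", attempt)))
    ys <- as.numeric(eval_true_function(fn, src$coords) > 0)
    yt <- as.numeric(eval_true_function(fn, tgt$coords) > 0)
    if (min(mean(ys), 1 - mean(ys), mean(yt), 1 - mean(yt)) >= 0.15) break
  }
  src$labels <- ys; tgt$labels <- yt
  list(source = src, target = tgt, fn = fn)
}
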