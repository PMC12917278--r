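test_that("Scott's rule reproduces hand values and its scaling law", {
  x <- exact_cov_data(64, diag(c(4, 9)), seed = 1)
  H <- scott_bandwidth(point_set(x))
  expect_equal(unclass(H), diag(c(1, 2.25)), tolerance = 1e-9)
  # doubling n multiplies H entrywise by 2^(-2/(d+4))
  for (d in 2:4) {
    sigma <- crossprod(matrix(rnorm(d * d), d)) + diag(d)
    h1 <- unclass(scott_bandwidth(point_set(exact_cov_data(200, sigma, seed = d))))
    h2 <- unclass(scott_bandwidth(point_set(exact_cov_data(400, sigma, seed = d))))
    expect_equal(h2 / h1, matrix(2^(-2 / (d + 4)), d, d), tolerance = 1e-9)
  }
  expect_error(scott_bandwidth(point_set(matrix(1, 10, 2))), "degenerate")
})

test_that("the Gaussian KDE is exact at a single support point and integrates to 1", {
  m <- kde_fit(point_set(matrix(0, 1, 2)), H = diag(2))
  expect_equal(kde_eval(m, c(0, 0)), 1 / (2 * pi), tolerance = 1e-12)
  expect_true(all(kde_eval(m, sample_uniform(2, 100, seed = 1)) >= 0))
  # 1-D toy: quadrature of the density over +-10 bandwidths
  pts <- point_set(c(0, 1, 3))
  model <- kde_fit(pts)
  h <- sqrt(model$H[1, 1])
  grid <- seq(-10 * h, 3 + 10 * h, length.out = 20001)
  dens <- kde_eval(model, matrix(grid, ncol = 1))
  integral <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid))
  expect_equal(integral, 1, tolerance = 1e-3)
  expect_error(kde_eval(m, matrix(0, 1, 3)), "dimension mismatch")
})

test_that("density-ratio weights follow the ratio and floor degenerate denominators", {
  pts <- sample_gmm(2, 200, 100, seed = 1)
  same <- kde_fit(pts)
  w <- iw_weights(same, same, pts)
  expect_equal(as.numeric(w), rep(1, 200), tolerance = 1e-9)
  expect_identical(attr(w, "method"), "iw")

  # ratio = exp((dg^2 - dp^2)/2) with unit bandwidths: place the eval point so
  # the true ratio is exactly 2
  dens_p <- kde_fit(point_set(matrix(0, 1, 1)), H = diag(1))
  dens_g <- kde_fit(point_set(matrix(sqrt(2 * log(2)), 1, 1)), H = diag(1))
  w2 <- iw_weights(dens_p, dens_g, point_set(matrix(0, 1, 1)))
  expect_equal(as.numeric(w2), 2, tolerance = 1e-12)

  # a source density below the floor triggers the warning and the capped ratio
  far_g <- kde_fit(point_set(matrix(100, 1, 1)), H = diag(1))
  expect_warning(w3 <- iw_weights(dens_p, far_g, point_set(matrix(0, 1, 1))),
                 "floored")
  expect_equal(attr(w3, "diagnostics")$floored, 1L)
  expect_equal(as.numeric(w3), kde_eval(dens_p, matrix(0, 1, 1)) / 1e-12)
})

test_that("weight vectors export to the audit CSV format", {
  w <- spatrisk:::weight_vector(c(0.5, 2, 1), "iw")
  path <- tempfile(fileext = ".csv")
  write_weights(w, path)
  back <- read.csv(path)
  expect_equal(back$weight, c(0.5, 2, 1))
  expect_true(all(back$method == "iw"))
  expect_equal(back$index, 1:3)
})

test_that("median-heuristic bandwidth matches hand computations and scales", {
  expect_equal(median_sigma(point_set(c(0, 1, 3))), 4 / log(3), tolerance = 1e-12)
  expect_equal(median_sigma(point_set(c(0, 1))), 1 / log(2), tolerance = 1e-12)
  pts <- sample_uniform(2, 50, seed = 1)
  scaled <- point_set(pts$coords * 3)
  expect_equal(median_sigma(scaled), 9 * median_sigma(pts), tolerance = 1e-9)
  expect_warning(s <- median_sigma(point_set(matrix(1, 5, 2))), "degenerate")
  expect_equal(s, 1)
})

test_that("the RBF Gram matrix has the closed form and symmetry", {
  X <- point_set(matrix(c(0, 1), 2, 1))
  expect_equal(rbf_gram(X, X, 5)[1, 1], 1)
  x <- matrix(0, 1, 1); z <- matrix(sqrt(2 * 5), 1, 1)
  expect_equal(rbf_gram(point_set(x), point_set(z), 5)[1, 1], exp(-1),
               tolerance = 1e-12)
  A <- sample_uniform(2, 10, seed = 1); B <- sample_uniform(2, 7, seed = 2)
  expect_equal(rbf_gram(A, B, 50), t(rbf_gram(B, A, 50)))
  expect_error(rbf_gram(A, B, -1), "positive")
})

test_that("classifier weights reproduce the probability-ratio formula", {
  src <- sample_uniform(2, 100, seed = 1)
  tgt <- sample_uniform(2, 50, seed = 2)
  # fixed posterior P(target|x) = 0.2, so P(g|x) = 0.8
  clf <- fit_domain_classifier(src, tgt, posterior = function(x) rep(0.2, nrow(x)))
  expect_equal(clf$prior_g, 100 / 150)
  expect_equal(clf$prior_p, 50 / 150)
  w <- classifier_weights(clf, sample_uniform(2, 5, seed = 3))
  expect_equal(as.numeric(w), rep(2 * (1 / 0.8 - 1), 5), tolerance = 1e-12)
  # P(g|x) = 1 drives the weight to zero; P(g|x) = 0 hits the clip
  clf1 <- fit_domain_classifier(src, src, posterior = function(x) rep(0, nrow(x)))
  expect_equal(as.numeric(classifier_weights(clf1, src)), rep(0, 100))
  clf0 <- fit_domain_classifier(src, src, posterior = function(x) rep(1, nrow(x)))
  expect_warning(w0 <- classifier_weights(clf0, src, clip_max = 1000), "clipped")
  expect_equal(as.numeric(w0), rep(1000, 100))
})

test_that("an analytic Bayes posterior recovers the exact density ratio", {
  # two known 1-D Gaussians with equal priors: the Bayes posterior plugged into
  # the probability-ratio formula must return p(x)/g(x) exactly
  mu_g <- 40; mu_p <- 60; s <- 12
  set.seed(1)
  src <- point_set(rnorm(300, mu_g, s)); tgt <- point_set(rnorm(300, mu_p, s))
  bayes <- function(x) {
    p <- dnorm(x[, 1], mu_p, s); g <- dnorm(x[, 1], mu_g, s)
    p / (p + g)  # equal empirical priors (n_g = n_p)
  }
  clf <- fit_domain_classifier(src, tgt, posterior = bayes)
  eval_pts <- point_set(seq(20, 80, by = 5))
  w <- classifier_weights(clf, eval_pts, clip_max = 1e12)
  truth <- dnorm(eval_pts$coords[, 1], mu_p, s) / dnorm(eval_pts$coords[, 1], mu_g, s)
  expect_equal(as.numeric(w), truth, tolerance = 1e-9)
})

test_that("the boosted domain classifier is calibrated near 0.5 on identical domains", {
  pts <- sample_gmm(2, 400, 100, seed = 1)
  clf <- fit_domain_classifier(pts, pts, seed = 1)
  probes <- sample_uniform(2, 100, seed = 2)
  expect_lt(max(abs(clf$posterior(probes$coords) - 0.5)), 0.15)
  # fully separated domains are told apart almost perfectly
  a <- point_set(matrix(runif(400, 0, 30), 200, 2))
  b <- point_set(matrix(runif(400, 70, 100), 200, 2))
  clf2 <- fit_domain_classifier(a, b, seed = 1)
  held_a <- point_set(matrix(runif(100, 0, 30), 50, 2))
  held_b <- point_set(matrix(runif(100, 70, 100), 50, 2))
  scores <- clf2$posterior(rbind(held_a$coords, held_b$coords))
  expect_gt(roc_auc(scores, rep(c(0, 1), each = 50)), 0.99)
})
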