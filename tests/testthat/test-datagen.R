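test_that("gmm sampler respects bounds, determinism and vanishing covariance", {
  ps <- sample_gmm(2, 1000, 50, seed = 1)
  expect_equal(ps$n, 1000L)
  expect_true(all(ps$coords >= 0 & ps$coords <= 100))
  expect_identical(ps$coords, sample_gmm(2, 1000, 50, seed = 1)$coords)

  # with vanishing covariance every point collapses onto a component center
  tiny <- sample_gmm(2, 5, 1e-9, n_components = 5, seed = 7)
  centers <- spatrisk:::gmm_spec(2, 5, 1e-9, c(0, 100), 7)$centers
  d2 <- outer(rowSums(tiny$coords^2), rowSums(centers^2), "+") -
    2 * tiny$coords %*% t(centers)
  expect_lt(max(sqrt(pmax(apply(d2, 1, min), 0))), 1e-3)

  expect_error(sample_gmm(2, 10, -1), "sigma_max")
  expect_error(sample_gmm(2, 0, 10), "n must be")
})

test_that("uniform sampler has the right support and moments", {
  ps <- sample_uniform(2, 10000, seed = 3)
  # CLT bound for U(0,100): 3 * (100/sqrt(12)) / sqrt(n)
  expect_true(all(abs(colMeans(ps$coords) - 50) <= 3 * (100 / sqrt(12)) / 100))
  expect_true(all(ps$coords >= 0 & ps$coords <= 100))
  one <- sample_uniform(4, 1, seed = 0)
  expect_equal(dim(one$coords), c(1L, 4L))
  expect_error(sample_uniform(2, 0), "n must be")
})

test_that("scenario recipes honor their geometric constraints", {
  cfg <- scenario_config("domain_truncation_cropped_to_full", d = 2,
                         n_points = 1500, seed = 11)
  pair <- make_scenario(cfg)
  expect_lt(max(pair$source$coords[, 2]), 50)
  expect_gt(max(pair$target$coords[, 2]), 80)
  expect_lt(min(pair$target$coords[, 2]), 20)
  expect_equal(pair$source$n, 1500L)
  expect_identical(pair$source$domain_tag, "source")

  mis <- make_scenario(scenario_config("support_mismatch_gmm_to_uniform",
                                       d = 4, n_points = 500, seed = 2))
  expect_equal(ncol(mis$target$coords), 4L)
  expect_true(all(mis$target$coords >= 0 & mis$target$coords <= 100))

  expect_error(scenario_config("no_such_scenario"), "unknown scenario")
})

test_that("scenario generation is a pure function of its config", {
  cfg <- scenario_config("variance_extrapolation", d = 2, n_points = 300, seed = 5)
  a <- make_scenario(cfg); b <- make_scenario(cfg)
  expect_identical(a$source$coords, b$source$coords)
  expect_identical(a$target$coords, b$target$coords)
})

test_that("correlation scenarios shift only the covariance orientation", {
  cfg <- scenario_config("correlation_shift", d = 2, n_points = 6000, seed = 9)
  pair <- make_scenario(cfg)
  cor_s <- cor(pair$source$coords)[1, 2]
  cor_t <- cor(pair$target$coords)[1, 2]
  expect_lt(abs(cor_s), 0.08)          # axis-aligned source
  expect_gt(abs(cor_t), 0.12)          # genuinely rotated target
  # same marginal spread: shared eigenvalues
  expect_equal(sum(diag(cov(pair$source$coords))),
               sum(diag(cov(pair$target$coords))), tolerance = 0.15)
})

test_that("mode contraction moves from scattered modes to a single one", {
  cfg <- scenario_config("mode_contraction", d = 2, n_points = 2000, seed = 4)
  pair <- make_scenario(cfg)
  # multi-modal source spreads over the domain; single-mode target is tight
  expect_gt(mean(diag(cov(pair$source$coords))), 4 * mean(diag(cov(pair$target$coords))))
  km_s <- kmeans(pair$source$coords, 2, nstart = 5)
  km_t <- kmeans(pair$target$coords, 2, nstart = 5)
  expect_gt(dist(km_s$centers)[1], 30)  # well-separated source modes
  expect_lt(dist(km_t$centers)[1], 30)  # one target mode
})

test_that("the true function is bounded, seed-determined and peaked at its centers", {
  fn <- make_true_function(2, seed = 1)
  x <- sample_uniform(2, 500, seed = 2)$coords
  expect_true(all(abs(eval_true_function(fn, x)) <= sum(abs(fn$amplitudes))))
  # single-bump peak: removing the other bumps leaves exactly a1 at center 1
  solo <- fn; solo$amplitudes[-1] <- 0
  expect_equal(eval_true_function(solo, fn$centers[1, ]), fn$amplitudes[1])
  # distinct seeds give distinct center sets
  collisions <- sum(vapply(1:100, function(s)
    isTRUE(all.equal(make_true_function(2, seed = s)$centers,
                     make_true_function(2, seed = s + 100)$centers)),
    logical(1)))
  expect_equal(collisions, 0L)
  expect_identical(make_true_function(3, seed = 5)$centers,
                   make_true_function(3, seed = 5)$centers)
})

test_that("train/test split is a disjoint exhaustive reproducible partition", {
  ps <- sample_uniform(2, 10, seed = 1)
  sp <- split_points(ps, 0.7, seed = 2)
  expect_equal(sp$train$n, 7L)
  expect_equal(sp$test$n, 3L)
  all_rows <- rbind(sp$train$coords, sp$test$coords)
  expect_equal(nrow(unique(all_rows)), 10L)
  expect_equal(all_rows[order(all_rows[, 1]), ],
               ps$coords[order(ps$coords[, 1]), ])
  sp2 <- split_points(ps, 0.7, seed = 2)
  expect_identical(sp$train$coords, sp2$train$coords)
  expect_error(split_points(point_set(matrix(1, 1, 1)), 0.7), "at least 2")
})

test_that("point sets round-trip through CSV", {
  ps <- sample_gmm(3, 50, 20, seed = 6)
  ps$labels <- rnorm(50)
  ps$domain_tag <- "source"
  path <- tempfile(fileext = ".csv")
  write_point_set(ps, path)
  back <- read_point_set(path)
  expect_equal(back$coords, ps$coords, ignore_attr = TRUE)
  expect_equal(back$labels, ps$labels)
  expect_identical(back$domain_tag, "source")
})
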