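test_that("a trial returns exactly the requested estimates, reproducibly", {
  cfg <- scenario_config("support_mismatch_gmm_to_uniform", d = 2,
                         n_points = 300, seed = 1)
  tr <- run_trial(cfg, methods = "nw", seed = 1)
  expect_named(tr$estimates, c("gt", "nw"))
  tr2 <- run_trial(cfg, methods = "nw", seed = 1)
  expect_identical(vapply(tr$estimates, function(x) x$value, numeric(1)),
                   vapply(tr2$estimates, function(x) x$value, numeric(1)))
})

test_that("an error-free model drives every estimator to zero and trips the metrics guard", {
  src <- sample_uniform(2, 200, seed = 1)
  src$labels <- rep(2, 200)                 # constant surface
  tgt <- sample_uniform(2, 200, seed = 2)
  tgt$labels <- rep(2, 200)                 # model will predict it exactly
  res <- suppressWarnings(estimate_risks(src, tgt, seed = 1))
  vals <- vapply(res$estimates, function(x) x$value, numeric(1))
  expect_true(all(vals < 1e-10))
  expect_error(risk_metrics(res$estimates$gt$value, res$estimates$nw$value),
               "degenerate ground truth")
})

test_that("no estimator except the ground truth reads target labels", {
  pair <- labeled_classification_pair(n = 300, seed = 5)
  res1 <- estimate_risks(pair$source, pair$target, seed = 2,
                         model_kind = "gb_classifier", error_kind = "log_loss")
  perturbed <- pair$target
  perturbed$labels <- 1 - perturbed$labels
  res2 <- estimate_risks(pair$source, perturbed, seed = 2,
                         model_kind = "gb_classifier", error_kind = "log_loss")
  for (m in c("nw", "iw", "classifier", "kmm"))
    expect_identical(res1$estimates[[m]]$value, res2$estimates[[m]]$value)
  expect_false(res1$estimates$gt$value == res2$estimates$gt$value)
})

test_that("experiments aggregate finite metrics and flag single-repetition runs", {
  cfg <- scenario_config("variance_extrapolation", d = 2, n_points = 300, seed = 3)
  tab <- suppressWarnings(run_experiment(cfg, methods = c("nw", "kmm"),
                                         n_reps = 2, master_seed = 3))
  df <- as.data.frame(tab)
  expect_setequal(unique(df$method), c("nw", "kmm"))
  expect_setequal(unique(df$metric), c("mape", "rmse", "rmspe"))
  expect_true(all(is.finite(df$value)))
  one <- suppressWarnings(run_experiment(cfg, methods = "nw", n_reps = 1,
                                         master_seed = 3))
  expect_true(all(as.data.frame(one)$sd == 0))
})

test_that("the model pool honors its size, ranges and AUC filter", {
  pair <- labeled_classification_pair(n = 300, seed = 7)
  pool <- suppressWarnings(generate_model_pool(
    pair$source, pair$target, n_models = 10, auc_threshold = 0, seed = 1))
  expect_equal(nrow(pool), 10L)
  expect_setequal(unique(pool$kind), c("gb_classifier", "random_forest"))
  expect_true(all(pool$n_estimators >= 5 & pool$n_estimators <= 20))
  expect_true(all(pool$max_depth >= 1 & pool$max_depth <= 4))
  expect_true(all(pool$learning_rate >= 0.01 & pool$learning_rate <= 0.3))
  expect_true(all(pool$roc_auc_target > 0))
  filtered <- suppressWarnings(generate_model_pool(
    pair$source, pair$target, n_models = 10, auc_threshold = 0.55, seed = 1))
  expect_true(all(filtered$roc_auc_target > 0.55))
  expect_error(suppressWarnings(generate_model_pool(
    pair$source, pair$target, n_models = 10, auc_threshold = 1.01, seed = 1)),
    "no model survived")
  expect_error(generate_model_pool(pair$source, pair$target, n_models = 9),
               "even")
})

test_that("model selection averages the true risk of the K lowest estimates", {
  pool <- structure(data.frame(
    model_id = 1:6, true_risk = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
    est_perfect = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
    est_reversed = c(0.6, 0.5, 0.4, 0.3, 0.2, 0.1)),
    class = c("model_pool", "data.frame"))
  expect_equal(as.numeric(model_selection(pool, "perfect", 2)), 0.15)
  expect_equal(as.numeric(model_selection(pool, "perfect", 6)), mean(pool$true_risk))
  # an exactly reversed estimate picks the K largest true risks
  expect_equal(as.numeric(model_selection(pool, "reversed", 2)), 0.55)
  expect_error(model_selection(pool, "perfect", 7), "exceeds")
  # ties break by model id
  pool$est_tied <- rep(1, 6)
  expect_equal(attr(model_selection(pool, "tied", 3), "selected"), 1:3)
})
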