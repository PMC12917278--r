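# Benchmark orchestration: one trial runs generate -> split (70/30) -> fit the
# black box on source train -> per-point errors -> weights per method on the
# test partitions -> risk estimates. Experiments repeat trials with derived
# seeds and aggregate MAPE/RMSE/RMSPE; the model-selection experiment scores
# how well each estimator picks low-true-risk models from a hyperparameter
# pool.

all_methods <- function() c("nw", "iw", "classifier", "kmm")

#' Estimate target-domain risks of a fixed model from labeled source data
#'
#' The core estimation pipeline on already-generated domains. Source and
#' target are split 70/30; the black box is fitted on source train; per-point
#' errors are computed on the source test partition (all estimators) and on
#' the target test partition (ground truth only). Weights are computed on the
#' test partitions: KDE density ratio fitted on the train partitions (IW),
#' domain classifier fitted on the train partitions, and KMM solved on the
#' test partitions. No estimator other than the ground truth ever reads
#' target labels.
#'
#' @param source,target Labeled source and (for ground truth) target
#'   `point_set`s. Target labels are used only for the ground-truth benchmark.
#' @param methods Subset of `c("nw", "iw", "classifier", "kmm")`.
#' @param seed Integer seed for split, model and weight stages.
#' @param model_kind Black-box kind (default `"gb_regressor"`).
#' @param error_kind `"squared"` (regression labels) or `"log_loss"` (0/1
#'   labels).
#' @param train_frac Train fraction (default 0.7).
#' @param B Weight bound for KMM and the classifier clip (default 1000).
#' @param floor KDE denominator floor (default 1e-12).
#' @param model Optional pre-fitted `black_box`; when supplied the fitting
#'   stage is skipped (used by the model-pool experiment).
#' @return A `trial_result`: list with `estimates` (named list of
#'   `risk_estimate`, including `gt`), `model`, `diagnostics` per method and
#'   the split sizes.
#' @export
estimate_risks <- function(source, target, methods = all_methods(), seed = 1L,
                           model_kind = "gb_regressor",
                           error_kind = c("squared", "log_loss"),
                           train_frac = 0.7, B = 1000, floor = 1e-12,
                           model = NULL) {
  error_kind <- match.arg(error_kind)
  methods <- match.arg(methods, all_methods(), several.ok = TRUE)
  if (is.null(source$labels) || is.null(target$labels))
    stop("estimate_risks: both domains need labels (target labels feed only ",
         "the ground-truth benchmark)", call. = FALSE)
  sp_s <- split_points(source, train_frac, derive_seed(seed, "split_source"))
  sp_t <- split_points(target, train_frac, derive_seed(seed, "split_target"))
  if (is.null(model))
    model <- fit_black_box(sp_s$train, model_kind, seed = derive_seed(seed, "model"))

  errors_of <- function(ps) {
    if (error_kind == "squared") squared_error(model, ps)
    else log_loss_error(ps$labels, predict_black_box(model, ps))
  }
  e_src <- errors_of(sp_s$test)
  e_tgt <- errors_of(sp_t$test)

  estimates <- list(gt = ground_truth_risk(e_tgt))
  diagnostics <- list()
  floored <- 0L
  for (m in methods) {
    w <- switch(m,
      nw = weight_vector(rep(1, sp_s$test$n), "nw"),
      iw = withCallingHandlers(
        iw_weights(kde_fit(sp_t$train), kde_fit(sp_s$train), sp_s$test,
                   floor = floor),
        warning = function(c) invokeRestart("muffleWarning")),
      classifier = {
        clf <- fit_domain_classifier(sp_s$train, sp_t$train,
                                     seed = derive_seed(seed, "domain_classifier"))
        withCallingHandlers(classifier_weights(clf, sp_s$test, clip_max = B),
                            warning = function(c) invokeRestart("muffleWarning"))
      },
      kmm = solve_kmm(build_kmm_problem(sp_s$test, sp_t$test,
                                        kernel_config(B = B))))
    estimates[[m]] <- weighted_risk(e_src, w)
    diagnostics[[m]] <- utils::modifyList(list(max_weight = max(w)),
                                          attr(w, "diagnostics"))
  }
  structure(list(estimates = estimates, model = model,
                 diagnostics = diagnostics, seed = seed,
                 n_source_test = sp_s$test$n, n_target_test = sp_t$test$n,
                 splits = list(source = sp_s, target = sp_t)),
            class = "trial_result")
}

#' Run one synthetic benchmark trial
#'
#' Generates the scenario's source/target pair, labels both domains with the
#' synthetic ground-truth function, and runs the estimation pipeline.
#'
#' @param config A [scenario_config()].
#' @param methods Estimators to run.
#' @param seed Integer master seed; named substreams drive generation, the
#'   true function, the split and the model.
#' @param ... Passed to [estimate_risks()].
#' @return A `trial_result` with the scenario id and seed attached.
#' @export
run_trial <- function(config, methods = all_methods(), seed = 1L, ...) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config; cfg$seed <- derive_seed(seed, "scenario")
  pair <- make_scenario(cfg)
  fn <- make_true_function(config$d, seed = derive_seed(seed, "true_function"))
  pair$source$labels <- eval_true_function(fn, pair$source$coords)
  pair$target$labels <- eval_true_function(fn, pair$target$coords)
  res <- estimate_risks(pair$source, pair$target, methods = methods,
                        seed = seed, ...)
  res$scenario_id <- config$scenario_id; res$d <- config$d
  res$true_function <- fn
  res
}

#' Repeat a scenario and aggregate estimator metrics
#'
#' Runs `n_reps` independent trials with seeds derived from `master_seed`,
#' then scores each estimator against the per-trial ground truth with MAPE,
#' RMSE and RMSPE. Dispersion is reported as both the standard deviation and
#' the standard error over repetitions of the per-repetition deviations
#' (absolute percentage error for MAPE/RMSPE, absolute error for RMSE).
#' Failed trials are excluded with a count rather than aborting the
#' experiment.
#'
#' @param config A [scenario_config()].
#' @param methods Estimators to run.
#' @param n_reps Number of repetitions (the full-scale protocol uses 100).
#' @param master_seed Integer seed from which the per-trial seeds derive.
#' @param ... Passed to [run_trial()].
#' @return A `metrics_table` data frame: scenario, d, method, metric, value,
#'   sd, sem, n_reps; the per-trial estimates ride along as
#'   `attr(, "estimates")` and the failure count as `attr(, "n_failed")`.
#' @export
run_experiment <- function(config, methods = all_methods(), n_reps = 100L,
                           master_seed = 1L, ...) {
  stopifnot(n_reps >= 1L)
  rows <- vector("list", n_reps)
  n_failed <- 0L
  for (i in seq_len(n_reps)) {
    rows[[i]] <- tryCatch(
      run_trial(config, methods, seed = derive_seed(master_seed, paste0("trial", i)), ...),
      error = function(e) {
        n_failed <<- n_failed + 1L
        warning(sprintf("trial %d failed (%s): %s", i, config$scenario_id,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
  }
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L)
    stop("run_experiment: all trials failed", call. = FALSE)
  est <- vapply(rows, function(r)
    vapply(r$estimates, function(x) x$value, numeric(1L)),
    numeric(length(methods) + 1L))
  est <- matrix(est, nrow = length(methods) + 1L,
                dimnames = list(c("gt", methods), NULL))
  gt <- est["gt", ]
  tab <- do.call(rbind, lapply(methods, function(m) {
    v <- risk_metrics(gt, est[m, ])
    ape <- 100 * abs((gt - est[m, ]) / gt)
    ae <- abs(gt - est[m, ])
    disp_sd <- c(mape = stats::sd(ape), rmse = stats::sd(ae),
                 rmspe = stats::sd(ape))
    if (length(gt) == 1L) disp_sd[] <- 0
    data.frame(scenario = config$scenario_id, d = config$d, method = m,
               metric = names(v), value = as.numeric(v),
               sd = as.numeric(disp_sd),
               sem = as.numeric(disp_sd) / sqrt(length(gt)),
               n_reps = length(gt), row.names = NULL)
  }))
  structure(tab, estimates = est, n_failed = n_failed,
            class = c("metrics_table", "data.frame"))
}

default_pool_ranges <- function() list(
  n_estimators = c(5L, 20L), max_depth = c(1L, 4L), learning_rate = c(0.01, 0.3))

#' Generate a pool of candidate classifiers with randomized hyperparameters
#'
#' Trains `n_models` binary classifiers (half gradient boosting, half random
#' forest) on the source training partition, with hyperparameters sampled
#' uniformly from the given ranges, and retains those whose ROC AUC on the
#' target test partition exceeds the threshold. Each retained entry carries
#' its true target risk (mean log-loss on target test) and the estimated risk
#' under every requested method; the method weights are computed once per
#' source/target pair since they do not depend on the model.
#'
#' @param source,target Labeled (0/1) `point_set`s.
#' @param n_models Pool size, even (half per family; default 200).
#' @param hyperparam_ranges Named list of `c(lo, hi)` ranges for
#'   `n_estimators`, `max_depth`, `learning_rate`.
#' @param auc_threshold Retention threshold on target-test ROC AUC
#'   (default 0.7).
#' @param methods Estimators to attach.
#' @param seed Integer seed.
#' @param B,floor Weight parameters as in [estimate_risks()].
#' @return A `model_pool` data frame: model_id, kind, hyperparameters,
#'   roc_auc_target, true_risk, and `est_<method>` columns.
#' @export
generate_model_pool <- function(source, target, n_models = 200L,
                                hyperparam_ranges = default_pool_ranges(),
                                auc_threshold = 0.7,
                                methods = all_methods(), seed = 1L,
                                B = 1000, floor = 1e-12) {
  if (n_models %% 2L != 0L)
    stop("generate_model_pool: n_models must be even (half per family)",
         call. = FALSE)
  rng <- utils::modifyList(default_pool_ranges(), hyperparam_ranges)
  sp_s <- split_points(source, 0.7, derive_seed(seed, "split_source"))
  sp_t <- split_points(target, 0.7, derive_seed(seed, "split_target"))

  weights <- list()
  for (m in setdiff(methods, "nw")) {
    weights[[m]] <- switch(m,
      iw = withCallingHandlers(
        iw_weights(kde_fit(sp_t$train), kde_fit(sp_s$train), sp_s$test,
                   floor = floor),
        warning = function(c) invokeRestart("muffleWarning")),
      classifier = {
        clf <- fit_domain_classifier(sp_s$train, sp_t$train,
                                     seed = derive_seed(seed, "domain_classifier"))
        withCallingHandlers(classifier_weights(clf, sp_s$test, clip_max = B),
                            warning = function(c) invokeRestart("muffleWarning"))
      },
      kmm = solve_kmm(build_kmm_problem(sp_s$test, sp_t$test, kernel_config(B = B))))
  }
  if ("nw" %in% methods) weights$nw <- weight_vector(rep(1, sp_s$test$n), "nw")

  kinds <- rep(c("gb_classifier", "random_forest"), each = n_models %/% 2L)
  entries <- vector("list", n_models)
  for (i in seq_len(n_models)) {
    hp <- with_seed(derive_seed(seed, paste0("hyper", i)), list(
      n_estimators = sample(rng$n_estimators[1L]:rng$n_estimators[2L], 1L),
      max_depth = sample(rng$max_depth[1L]:rng$max_depth[2L], 1L),
      learning_rate = stats::runif(1L, rng$learning_rate[1L], rng$learning_rate[2L])))
    mdl <- fit_black_box(sp_s$train, kinds[i], hyperparams = hp,
                         seed = derive_seed(seed, paste0("model", i)))
    auc <- tryCatch(roc_auc(mdl, sp_t$test), error = function(e) NA_real_)
    if (is.na(auc) || auc <= auc_threshold) next
    e_tgt <- log_loss_error(sp_t$test$labels, predict_black_box(mdl, sp_t$test))
    e_src <- log_loss_error(sp_s$test$labels, predict_black_box(mdl, sp_s$test))
    row <- data.frame(model_id = i, kind = kinds[i],
                      n_estimators = hp$n_estimators, max_depth = hp$max_depth,
                      learning_rate = hp$learning_rate,
                      roc_auc_target = auc,
                      true_risk = ground_truth_risk(e_tgt)$value)
    for (m in methods)
      row[[paste0("est_", m)]] <- weighted_risk(e_src, weights[[m]])$value
    entries[[i]] <- row
  }
  entries <- Filter(Negate(is.null), entries)
  if (length(entries) == 0L)
    stop("generate_model_pool: no model survived the AUC filter", call. = FALSE)
  structure(do.call(rbind, entries), class = c("model_pool", "data.frame"))
}

#' Average true risk of the K models an estimator would select
#'
#' Selects the K pool entries with the lowest estimated risk under `method`
#' (ties broken by model_id) and returns the mean of their true target risks:
#' the deployed performance of a selection guided by that estimator.
#'
#' @param pool A `model_pool`.
#' @param method Estimator name (`"nw"`, `"iw"`, `"classifier"`, `"kmm"`).
#' @param K Number of models to select (default 5).
#' @return Scalar mean true risk; selected model ids as attribute
#'   `selected`.
#' @export
model_selection <- function(pool, method, K = 5L) {
  col <- paste0("est_", method)
  if (!col %in% names(pool))
    stop(sprintf("model_selection: no estimates for method '%s'", method),
         call. = FALSE)
  if (K > nrow(pool))
    stop("model_selection: K exceeds the pool size", call. = FALSE)
  ord <- order(pool[[col]], pool$model_id)
  sel <- ord[seq_len(K)]
  structure(mean(pool$true_risk[sel]), selected = pool$model_id[sel])
}
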