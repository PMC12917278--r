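# Black-box models whose risk is being estimated, and their per-point errors.
# The estimators treat these models as fixed: nothing here ever reads target
# labels. Gradient boosting is backed by xgboost, random forests by
# randomForest, logistic regression by glm, and the MLP by nnet. Default
# boosting hyperparameters (100 rounds, learning rate 0.1, depth 3) follow the
# common library defaults for gradient boosting.

default_hyperparams <- function(kind) {
  switch(kind,
    gb_regressor  = list(n_estimators = 100L, learning_rate = 0.1, max_depth = 3L),
    gb_classifier = list(n_estimators = 100L, learning_rate = 0.1, max_depth = 3L),
    random_forest = list(n_estimators = 100L, max_depth = 0L),
    logistic      = list(),
    mlp           = list(size = 8L, decay = 1e-4, maxit = 200L),
    stop(sprintf("unknown model kind '%s'", kind), call. = FALSE))
}

#' Fit a black-box model on a labeled point set
#'
#' @param train A labeled `point_set` (regression labels for `gb_regressor`,
#'   0/1 labels for the classifier kinds).
#' @param kind One of `"gb_regressor"`, `"gb_classifier"`, `"logistic"`,
#'   `"random_forest"`, `"mlp"`.
#' @param hyperparams Named list overriding the kind's defaults
#'   (`n_estimators`, `learning_rate`, `max_depth`, ...).
#' @param seed Integer seed for the stochastic fitters.
#' @return A `black_box` model; predictions via [predict_black_box()].
#'   Classifier kinds predict the probability of class 1.
#' @export
fit_black_box <- function(train, kind, hyperparams = list(), seed = 1L) {
  stopifnot(inherits(train, "point_set"))
  if (is.null(train$labels))
    stop("fit_black_box: training data has no labels", call. = FALSE)
  hp <- utils::modifyList(default_hyperparams(kind), hyperparams)
  x <- train$coords; y <- train$labels
  is_classifier <- kind %in% c("gb_classifier", "logistic", "random_forest", "mlp")
  if (is_classifier && !all(y %in% c(0, 1)))
    stop("fit_black_box: classifier kinds need 0/1 labels", call. = FALSE)
  xgb_fit <- function(objective) xgboost::xgb.train(
    params = list(objective = objective, eta = hp$learning_rate,
                  max_depth = hp$max_depth, nthread = 1L),
    data = xgboost::xgb.DMatrix(x, label = y), nrounds = hp$n_estimators,
    verbose = 0)
  fit <- with_seed(derive_seed(seed, "model"), switch(kind,
    gb_regressor = xgb_fit("reg:squarederror"),
    gb_classifier = xgb_fit("binary:logistic"),
    logistic = {
      xx <- x; colnames(xx) <- paste0("V", seq_len(ncol(xx)))
      df <- data.frame(y = y, xx)
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    },
    random_forest = randomForest::randomForest(
      x = x, y = factor(y, levels = c(0, 1)), ntree = hp$n_estimators,
      maxnodes = if (hp$max_depth > 0L) 2L^hp$max_depth else NULL),
    mlp = {
      capture <- utils::capture.output(
        m <- nnet::nnet(x, y, size = hp$size, decay = hp$decay,
                        maxit = hp$maxit, entropy = TRUE, trace = FALSE))
      m
    },
    stop(sprintf("unknown model kind '%s'", kind), call. = FALSE)))
  structure(list(kind = kind, hyperparams = hp, seed = seed, fit = fit,
                 is_classifier = is_classifier),
            class = "black_box")
}

#' Predict with a black-box model
#'
#' @param model A `black_box`.
#' @param coords Coordinate matrix or `point_set`.
#' @return Numeric predictions; probabilities in \[0, 1\] for classifiers.
#' @export
predict_black_box <- function(model, coords) {
  stopifnot(inherits(model, "black_box"))
  if (inherits(coords, "point_set")) coords <- coords$coords
  if (is.vector(coords)) coords <- matrix(coords, nrow = 1L)
  p <- switch(model$kind,
    gb_regressor  = stats::predict(model$fit, xgboost::xgb.DMatrix(coords)),
    gb_classifier = stats::predict(model$fit, xgboost::xgb.DMatrix(coords)),
    logistic = {
      df <- as.data.frame(coords)
      names(df) <- paste0("V", seq_len(ncol(coords)))
      as.numeric(stats::predict(model$fit, newdata = df, type = "response"))
    },
    random_forest = as.numeric(
      stats::predict(model$fit, coords, type = "prob")[, "1"]),
    mlp = as.numeric(stats::predict(model$fit, coords)))
  p <- as.numeric(p)
  if (model$is_classifier) p <- pmin(pmax(p, 0), 1)
  p
}

#' @export
predict.black_box <- function(object, newdata, ...) predict_black_box(object, newdata)

#' Per-point squared error of a model against the true function
#'
#' e(x_i) = (f(x_i) - fhat(x_i))^2, the regression error used throughout the
#' synthetic benchmark.
#'
#' @param model A `black_box`.
#' @param points A `point_set`.
#' @param true_fn A `true_function`, or `NULL` to use `points$labels` as f(x).
#' @return An `error_vector` (nonnegative numeric, `error_kind = "squared"`).
#' @export
squared_error <- function(model, points, true_fn = NULL) {
  f <- if (is.null(true_fn)) {
    if (is.null(points$labels))
      stop("squared_error: no true function and no labels", call. = FALSE)
    points$labels
  } else eval_true_function(true_fn, points$coords)
  e <- (f - predict_black_box(model, points))^2
  structure(e, error_kind = "squared", class = "error_vector")
}

#' Per-point log-loss of predicted probabilities
#'
#' e = -(y log p + (1 - y) log(1 - p)) with p clamped to \[eps, 1 - eps\] so
#' the loss is finite at degenerate predictions.
#'
#' @param labels 0/1 vector.
#' @param probs Predicted probabilities in \[0, 1\].
#' @param eps Clamp (default 1e-15).
#' @return An `error_vector` with `error_kind = "log_loss"`.
#' @export
log_loss_error <- function(labels, probs, eps = 1e-15) {
  if (length(labels) != length(probs))
    stop("log_loss_error: length mismatch", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("log_loss_error: labels must be 0/1", call. = FALSE)
  p <- pmin(pmax(probs, eps), 1 - eps)
  e <- -(labels * log(p) + (1 - labels) * log(1 - p))
  structure(e, error_kind = "log_loss", class = "error_vector")
}

#' Rank-based ROC AUC of a classifier on a labeled test set
#'
#' @param model A `black_box` classifier, or a numeric vector of scores.
#' @param test A labeled `point_set` with both classes present, or (when
#'   `model` is a score vector) the 0/1 label vector.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(model, test) {
  if (inherits(model, "black_box")) {
    labels <- test$labels
    scores <- predict_black_box(model, test)
  } else {
    scores <- model; labels <- test
  }
  if (is.null(labels) || length(unique(labels[labels %in% c(0, 1)])) < 2L ||
      !all(labels %in% c(0, 1)))
    stop("roc_auc: need 0/1 labels with both classes present", call. = FALSE)
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}
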