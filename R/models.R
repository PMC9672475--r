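# Model registry. The learners come from established backends, configured
# with the fixed hyperparameters of the study design; the package's own
# contribution is the protocol around them (scaling, selection, CV,
# metrics), never the training algorithms.
#
# Registry keys and fixed settings:
#   XGB  gradient boosting: 500 rounds, depth 3, eta 0.1, logloss,
#        per-tree column subsample log2(p)/p
#   RF   random forest: 500 trees, mtry = 0.25 p
#   ET   extremely randomized trees: 1000 trees, mtry = log2(p)
#   PSVC polynomial-kernel SVC: C = 0.01, gamma = 0.1, degree 3, coef0 = 10
#   LSVC linear SVC: max_iter 1e5 (scores are decision values)
#   LRCV cross-validated ridge logistic regression (lambda path chosen by
#        internal CV), max iterations 1e4
# Both forest backends split on the Gini criterion (no entropy criterion is
# exposed by the R backends); documented in the methods vignette.

MODEL_KEYS <- c("XGB", "RF", "ET", "PSVC", "LSVC", "LRCV")

#' Model specification
#'
#' @param key one of `"XGB"`, `"RF"`, `"ET"`, `"PSVC"`, `"LSVC"`, `"LRCV"`.
#' @param class_weight `"none"` or `"balanced"` (reweights classes inversely
#'   to their frequencies; used for the imbalanced TLM-discovery task).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(key, class_weight = c("none", "balanced")) {
  key <- match.arg(key, MODEL_KEYS)
  class_weight <- match.arg(class_weight)
  structure(list(key = key, class_weight = class_weight), class = "model_spec")
}

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("model backend requires package '", pkg, "'")
}

class_weights <- function(y01, mode) {
  if (mode == "none") return(rep(1, length(y01)))
  n <- length(y01); tab <- table(factor(y01, levels = c(0, 1)))
  w <- n / (2 * pmax(tab, 1))
  as.numeric(w[as.character(y01)])
}

#' Fit a registered model
#'
#' @param spec a [model_spec()].
#' @param X numeric matrix (samples x features), already standardized.
#' @param y01 0/1 integer vector (1 = positive class).
#' @param seed integer seed controlling any backend randomness.
#' @return object of class `tlm_model` with elements `spec`,
#'   `feature_names`, `predict_prob(newX)` and optionally `coef` (named
#'   coefficient vector, linear models only).
#' @export
fit_model <- function(spec, X, y01, seed = 1) {
  stopifnot(is.matrix(X), length(y01) == nrow(X), all(y01 %in% c(0, 1)))
  if (length(unique(y01)) < 2) stop("training fold contains a single class")
  p <- ncol(X)
  w <- class_weights(y01, spec$class_weight)
  fit <- NULL; predict_prob <- NULL; cf <- NULL
  withr::with_seed(as.integer(seed), {
    if (spec$key == "LRCV") {
      if (p >= 2) {
        # suppressed: cv.glmnet nags when the minority class is below 8 per
        # internal fold, routine on the imbalanced discovery task
        fit <- suppressWarnings(
          glmnet::cv.glmnet(X, y01, family = "binomial", alpha = 0,
                            weights = w, maxit = 10000, nfolds = 5,
                            standardize = FALSE))
        predict_prob <- function(newX)
          as.numeric(stats::predict(fit, newx = newX, s = "lambda.min",
                                    type = "response"))
        b <- as.matrix(stats::coef(fit, s = "lambda.min"))[, 1]
        cf <- b[setdiff(names(b), "(Intercept)")]
      } else {
        df <- data.frame(y = y01, x = X[, 1])
        fit <- suppressWarnings(stats::glm(y ~ x, df, family = stats::binomial(),
                                           weights = w))
        predict_prob <- function(newX)
          as.numeric(stats::predict(fit, data.frame(x = newX[, 1]),
                                    type = "response"))
        cf <- setNames(stats::coef(fit)["x"], colnames(X))
      }
    } else if (spec$key == "XGB") {
      need_pkg("xgboost")
      dtrain <- xgboost::xgb.DMatrix(X, label = y01, weight = w, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(max_depth = 3, eta = 0.1, objective = "binary:logistic",
                      eval_metric = "logloss", nthread = 1,
                      colsample_bytree = max(log2(p) / p, 1 / p)),
        data = dtrain, nrounds = 500, verbose = 0)
      predict_prob <- function(newX)
        as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(newX, nthread = 1)))
    } else if (spec$key == "RF") {
      need_pkg("randomForest")
      fit <- randomForest::randomForest(
        x = X, y = factor(y01, levels = c(0, 1)), ntree = 500,
        mtry = max(1, floor(0.25 * p)), classwt = if (spec$class_weight ==
          "balanced") c("0" = 1 / max(1, sum(y01 == 0)),
                        "1" = 1 / max(1, sum(y01 == 1))) else NULL)
      predict_prob <- function(newX)
        stats::predict(fit, newX, type = "prob")[, "1"]
    } else if (spec$key == "ET") {
      need_pkg("ranger")
      fit <- ranger::ranger(
        x = X, y = factor(y01, levels = c(0, 1)), num.trees = 1000,
        splitrule = "extratrees", mtry = max(1, floor(log2(p))),
        probability = TRUE, num.threads = 1, case.weights = w)
      predict_prob <- function(newX)
        stats::predict(fit, data = newX, num.threads = 1)$predictions[, "1"]
    } else if (spec$key %in% c("PSVC", "LSVC")) {
      need_pkg("e1071")
      args <- list(x = X, y = factor(y01, levels = c(0, 1)), scale = FALSE,
                   class.weights = if (spec$class_weight == "balanced")
                     c("0" = length(y01) / (2 * max(1, sum(y01 == 0))),
                       "1" = length(y01) / (2 * max(1, sum(y01 == 1)))) else NULL)
      if (spec$key == "PSVC")
        args <- c(args, list(kernel = "polynomial", cost = 0.01, gamma = 0.1,
                             degree = 3, coef0 = 10))
      else
        args <- c(args, list(kernel = "linear", cost = 1))
      fit <- do.call(e1071::svm, args)
      # decision values are monotone scores; a sigmoid maps them to (0,1) so
      # the 0.5 threshold coincides with the decision boundary
      predict_prob <- function(newX) {
        dvm <- attr(stats::predict(fit, newX, decision.values = TRUE),
                    "decision.values")
        dv <- dvm[, 1]
        if (colnames(dvm)[1] == "0/1") dv <- -dv  # orient towards class "1"
        stats::plogis(dv)
      }
      if (spec$key == "LSVC") {
        sv <- fit$coefs; cf <- setNames(as.numeric(t(sv) %*% fit$SV), colnames(X))
        if (fit$labels[1] == 2) cf <- -cf
      }
    }
  })
  structure(list(spec = spec, feature_names = colnames(X), fit = fit,
                 predict_prob = predict_prob, coef = cf),
            class = "tlm_model")
}

#' Predict positive-class probabilities
#'
#' @param object a fitted [fit_model()] object.
#' @param newX numeric matrix with the model's feature columns.
#' @param ... unused.
#' @return numeric vector of probabilities (or sigmoid-mapped margins for
#'   the SVC models).
#' @export
predict.tlm_model <- function(object, newX, ...) {
  if (!identical(colnames(newX), object$feature_names))
    stop("feature mismatch between training and prediction data")
  object$predict_prob(newX)
}
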