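# Evaluation protocol: MCC and ROC AUC, repeated stratified k-fold
# cross-validation with in-fold scaling and feature selection, median
# aggregation, distribution comparison, permutation importance and
# coefficient summaries.

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`, the Pearson
#' correlation between predicted and true binary labels. When any factor of
#' the denominator is zero the coefficient is undefined; the documented
#' convention here is to return 0.
#'
#' @param tp,tn,fp,fn non-negative confusion counts.
#' @return numeric in `[-1, 1]`.
#' @export
mcc <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  den <- prod(sqrt(c(tp + fn, tp + fp, tn + fp, tn + fn)))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

confusion_counts <- function(truth01, pred01) {
  c(tp = sum(truth01 == 1 & pred01 == 1), tn = sum(truth01 == 0 & pred01 == 0),
    fp = sum(truth01 == 0 & pred01 == 1), fn = sum(truth01 == 1 & pred01 == 0))
}

#' ROC area under the curve
#'
#' Rank-based (Mann-Whitney) formulation: the probability that a random
#' positive scores above a random negative, counting ties as 1/2 —
#' equivalent to the trapezoidal area under the ROC curve.
#'
#' @param scores numeric scores, larger = more positive.
#' @param y01 0/1 truth vector.
#' @return numeric in `[0, 1]`.
#' @export
roc_auc <- function(scores, y01) {
  stopifnot(length(scores) == length(y01))
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  if (n1 == 0 || n0 == 0) stop("roc_auc requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    if (length(idx) < folds)
      stop("class '", cls, "' has fewer members than folds")
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' The full study protocol: for each repeat a fresh stratified shuffle, for
#' each fold a pipeline fitted strictly on the training split —
#' standardization, Bernoulli-NB feature selection capped at the number of
#' training samples, then the model — and scored on the held-out split with
#' MCC (0.5 probability threshold) and ROC AUC. Per-repeat seeds derive
#' deterministically from the master seed.
#'
#' @param X a [feature_table()] (raw, unstandardized values).
#' @param y named labels over (a superset of) the samples of `X`.
#' @param model a [model_spec()].
#' @param repeats,folds protocol size (defaults 5 and 10).
#' @param seed master seed.
#' @param positive label treated as the positive class (default: `"long"`
#'   or `"tlm"` when present).
#' @param feature_set_id tag recorded with every record.
#' @param threshold probability cut for the confusion counts.
#' @return object of class `cv_result`: `records` (one row per repeat x
#'   fold x metric), `predictions` (pooled held-out probabilities),
#'   `coefficients` (per-run named vectors, linear models), `folds`
#'   (samples x repeats fold assignment) and `scaler_means` (per-run fitted
#'   means, for leakage auditing).
#' @export
repeated_stratified_cv <- function(X, y, model, repeats = 5, folds = 10,
                                   seed = 1, positive = NULL,
                                   feature_set_id = "features",
                                   threshold = 0.5) {
  y <- y[X$samples]
  if (anyNA(y)) stop("labels missing for some samples")
  if (is.null(positive)) positive <- positive_class(y)
  y01 <- as.integer(y == positive)
  records <- list(); predictions <- list(); coefs <- list(); scaler_means <- list()
  fold_mat <- matrix(NA_integer_, nrow = length(y), ncol = repeats,
                     dimnames = list(X$samples, NULL))
  for (r in seq_len(repeats)) {
    fold <- withr::with_seed(as.integer(seed + r), stratified_folds(y, folds))
    fold_mat[, r] <- fold
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      run_seed <- as.integer(seed + 1000L * r + f)
      Xtr <- subset_features(X, X$features$id)  # shallow copy
      Xtr$values <- X$values[tr, , drop = FALSE]; Xtr$samples <- X$samples[tr]
      std <- standardize(Xtr)
      scaler_means[[sprintf("r%df%d", r, f)]] <- std$scaler$mean
      sel <- if (ncol(X$values) > sum(tr))
        select_top_features(std$table, y, k = sum(tr), positive = positive)
      else X$features$id
      Xtr_s <- subset_features(std$table, sel)
      Xte <- subset_features(X, X$features$id)
      Xte$values <- X$values[te, , drop = FALSE]; Xte$samples <- X$samples[te]
      Xte_s <- subset_features(apply_scaler(std$scaler, Xte), sel)
      m <- fit_model(model, Xtr_s$values, y01[tr], seed = run_seed)
      prob <- predict(m, Xte_s$values)
      cc <- confusion_counts(y01[te], as.integer(prob >= threshold))
      records[[length(records) + 1L]] <- data.frame(
        rep = r, fold = f, model_key = model$key,
        feature_set_id = feature_set_id,
        metric = c("MCC", "AUC"),
        value = c(mcc(cc["tp"], cc["tn"], cc["fp"], cc["fn"]),
                  roc_auc(prob, y01[te])),
        seed = run_seed)
      predictions[[length(predictions) + 1L]] <- data.frame(
        rep = r, fold = f, gene = X$samples[te], prob = prob,
        truth = y[te], stringsAsFactors = FALSE)
      if (!is.null(m$coef)) coefs[[sprintf("r%df%d", r, f)]] <- m$coef
    }
  }
  structure(list(records = do.call(rbind, records),
                 predictions = do.call(rbind, predictions),
                 coefficients = coefs, folds = fold_mat,
                 scaler_means = scaler_means,
                 model = model, positive = positive, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  med <- aggregate_records(x$records, by = "metric", stat = "median")
  cat(sprintf("cv_result [%s]: %d records; median %s\n", x$model$key,
              nrow(x$records),
              paste(sprintf("%s=%.3f", med$metric, med$value), collapse = ", ")))
  invisible(x)
}

#' Aggregate cross-validation records
#'
#' @param records the `records` data.frame of a [repeated_stratified_cv()]
#'   result.
#' @param by grouping column names (default `c("model_key", "metric")`).
#' @param stat `"median"` (the study's reporting statistic), `"mean"` or
#'   `"sd"`.
#' @return data.frame of group keys plus `value`.
#' @export
aggregate_records <- function(records, by = c("model_key", "metric"),
                              stat = c("median", "mean", "sd")) {
  stat <- match.arg(stat)
  if (nrow(records) == 0) stop("no records to aggregate")
  f <- switch(stat, median = median, mean = mean, sd = sd)
  out <- aggregate(records["value"], records[, by, drop = FALSE], f)
  out[order(do.call(paste, out[by])), , drop = FALSE]
}

#' Mann-Whitney U comparison of two score distributions
#'
#' Two-sided test with normal approximation, tie correction and continuity
#' correction (the convention used for the feature-set comparisons).
#'
#' @param x,y numeric vectors.
#' @return list with `U` (the Mann-Whitney statistic for `x` vs `y`) and
#'   `p_value`.
#' @export
compare_distributions <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Permutation feature importance
#'
#' Importance of feature i = baseline held-out accuracy minus the mean
#' accuracy over `n_repeats` shuffles of column i. A feature the model
#' ignores scores ~0; constant columns score exactly 0 (shuffling is the
#' identity).
#'
#' @param model fitted [fit_model()] object.
#' @param X held-out matrix (standardized like training).
#' @param y01 0/1 truth.
#' @param n_repeats shuffles per feature (default 5).
#' @param seed RNG seed.
#' @param threshold probability cut for accuracy.
#' @return named numeric of importances.
#' @export
permutation_importance <- function(model, X, y01, n_repeats = 5, seed = 1,
                                   threshold = 0.5) {
  if (!identical(colnames(X), model$feature_names))
    stop("feature mismatch between model and data")
  acc <- function(M) mean(as.integer(predict(model, M) >= threshold) == y01)
  base <- acc(X)
  withr::with_seed(as.integer(seed), {
    imp <- vapply(seq_len(ncol(X)), function(j) {
      if (length(unique(X[, j])) == 1) return(0)   # shuffle is the identity
      drops <- vapply(seq_len(n_repeats), function(k) {
        Xp <- X; Xp[, j] <- sample(Xp[, j]); acc(Xp)
      }, numeric(1))
      base - mean(drops)
    }, numeric(1))
  })
  setNames(imp, colnames(X))
}

#' Top features by mean absolute coefficient
#'
#' Ranks features by the mean absolute coefficient the linear model learned
#' across runs, restricted to features that were selected in every run, and
#' returns the top `k` (all eligible features when fewer).
#'
#' @param per_run_coefficients list of named coefficient vectors, one per
#'   run (each covering that run's selected features).
#' @param k number of features to report (default 15).
#' @return data.frame with `feature`, `mean_abs_coef`, ranked descending.
#' @export
top_mean_abs_coefficients <- function(per_run_coefficients, k = 15) {
  if (k <= 0) stop("k must be positive")
  if (!length(per_run_coefficients)) stop("no coefficient vectors supplied")
  eligible <- Reduce(intersect, lapply(per_run_coefficients, names))
  if (!length(eligible)) return(data.frame(feature = character(0),
                                           mean_abs_coef = numeric(0)))
  m <- sapply(per_run_coefficients, function(v) abs(v[eligible]))
  m <- matrix(m, nrow = length(eligible), dimnames = list(eligible, NULL))
  sc <- rowMeans(m)
  ord <- order(-sc, eligible)
  top <- head(ord, k)
  data.frame(feature = eligible[top], mean_abs_coef = unname(sc[top]))
}

#' Held-out probability summary by phenotype subtype
#'
#' Pools the held-out positive-class probabilities of a [repeated_stratified_cv()]
#' run and summarizes the classifier's confidence per raw phenotype subtype
#' (e.g. `very short` vs `short` vs `slightly short`), the meta-analysis of
#' whether severe phenotypes are predicted with higher confidence.
#'
#' @param cv a `cv_result`.
#' @param raw_labels named list of raw category vectors per gene (attribute
#'   `raw_labels` of [reduce_phenotypes()] output).
#' @return data.frame with `subtype`, `n`, `median_prob`. For `short`
#'   subtypes the probability of the *short* call is reported
#'   (1 - P(positive) when the positive class is `long`), so that larger =
#'   more confident in the gene's own phenotype.
#' @export
subtype_probabilities <- function(cv, raw_labels) {
  pr <- cv$predictions
  sub <- vapply(raw_labels[pr$gene], function(v) v[1], character(1))
  conf <- ifelse(sub %in% SHORT_VARIANTS,
                 ifelse(cv$positive == "long", 1 - pr$prob, pr$prob),
                 ifelse(cv$positive == "long", pr$prob, 1 - pr$prob))
  out <- aggregate(conf, list(subtype = sub), median)
  n <- aggregate(conf, list(subtype = sub), length)
  data.frame(subtype = out$subtype, n = n$x, median_prob = out$x)
}
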