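# Metrics, the repeated stratified CV protocol, aggregation, distribution
# comparison, permutation importance and coefficient summaries.

test_that("MCC matches its formula, conventions and the Pearson-encoding identity", {
  expect_equal(mcc(5, 5, 0, 0), 1)
  expect_equal(mcc(5, 5, 5, 5), 0)
  expect_equal(mcc(3, 4, 1, 2), 10 / sqrt(600))
  expect_equal(mcc(0, 10, 0, 5), 0)   # zero-factor convention
  expect_error(mcc(-1, 0, 0, 0), "non-negative")
  withr::local_seed(2)
  for (i in 1:20) {
    cc <- rpois(4, 5) + 1
    truth <- rep(c(1, 1, 0, 0), cc)   # tp, fn, fp, tn blocks
    pred <- rep(c(1, 0, 1, 0), cc)
    expect_equal(mcc(cc[1], cc[4], cc[3], cc[2]),
                 suppressWarnings(stats::cor(pred, truth)))
  }
})

test_that("ROC AUC equals the exhaustive pairwise oracle and honours its conventions", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  withr::local_seed(6)
  for (i in 1:15) {
    n <- sample(6:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, 0.1), n, TRUE)   # coarse grid forces ties
    expect_equal(roc_auc(s, y), pairwise_auc(s, y))
    # invariance under a strictly monotone transform
    expect_equal(roc_auc(exp(3 * s), y), roc_auc(s, y))
  }
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("repeated stratified CV produces the full record grid with disjoint stratified folds", {
  w <- small_world()
  ds <- phenotype_dataset(w, "cerevisiae")
  cv <- repeated_stratified_cv(ds$X, ds$y, model_spec("LRCV"),
                               repeats = 2, folds = 5, seed = 3)
  # 2 repeats x 5 folds per metric
  for (m in c("MCC", "AUC"))
    expect_equal(sum(cv$records$metric == m), 10)
  n <- length(ds$y)
  glob <- mean(ds$y == "long")
  for (r in 1:2) {
    fold <- cv$folds[, r]
    expect_setequal(unique(fold), 1:5)
    # held-out folds partition the samples
    expect_equal(sum(table(fold)), n)
    for (f in 1:5) {
      te <- names(fold)[fold == f]
      prop <- mean(ds$y[te] == "long")
      expect_lt(abs(prop - glob), 1 / length(te) + 1e-9)
    }
  }
  # each sample predicted exactly once per repeat
  per_rep <- table(cv$predictions$rep, cv$predictions$gene)
  expect_true(all(per_rep == 1))
})

test_that("CV is reproducible under the same seed and differs across seeds", {
  w <- small_world()
  ds <- phenotype_dataset(w, "cerevisiae")
  cv1 <- repeated_stratified_cv(ds$X, ds$y, model_spec("LRCV"), 1, 5, seed = 9)
  cv2 <- repeated_stratified_cv(ds$X, ds$y, model_spec("LRCV"), 1, 5, seed = 9)
  cv3 <- repeated_stratified_cv(ds$X, ds$y, model_spec("LRCV"), 1, 5, seed = 10)
  expect_identical(cv1$records, cv2$records)
  expect_false(identical(cv1$folds, cv3$folds))
})

test_that("scalers and selection see only training rows (no leakage)", {
  w <- small_world()
  ds <- phenotype_dataset(w, "cerevisiae")
  cv <- repeated_stratified_cv(ds$X, ds$y, model_spec("LRCV"), 1, 5, seed = 4)
  fold <- cv$folds[, 1]
  for (f in 1:5) {
    tr <- names(fold)[fold != f]
    recomputed <- colMeans(ds$X$values[tr, , drop = FALSE])
    expect_equal(cv$scaler_means[[sprintf("r1f%d", f)]], recomputed)
  }
})

test_that("every registered learner runs through the protocol on a small task", {
  w <- small_world()
  ds <- phenotype_dataset(w, "cerevisiae")
  for (key in c("XGB", "RF", "ET", "PSVC", "LSVC", "LRCV")) {
    cv <- repeated_stratified_cv(ds$X, ds$y, model_spec(key),
                                 repeats = 1, folds = 3, seed = 7)
    expect_equal(nrow(cv$records), 6, label = key)
    auc <- cv$records$value[cv$records$metric == "AUC"]
    expect_true(all(auc >= 0 & auc <= 1), label = key)
    # planted signal: every learner beats chance on the strong-signal world
    expect_gt(median(auc), 0.6, label = key)
  }
})

test_that("aggregation computes grouped medians, means and sds", {
  rec <- data.frame(model_key = "LRCV", metric = rep(c("MCC", "AUC"), c(3, 1)),
                    value = c(0.2, 0.4, 0.9, 0.7))
  med <- aggregate_records(rec, stat = "median")
  expect_equal(med$value[med$metric == "MCC"], 0.4)
  expect_equal(med$value[med$metric == "AUC"], 0.7)   # single record -> itself
  mn <- aggregate_records(rec, stat = "mean")
  expect_equal(mn$value[mn$metric == "MCC"], 0.5)
  sdv <- aggregate_records(rec, stat = "sd")
  expect_equal(sdv$value[sdv$metric == "MCC"], sd(c(0.2, 0.4, 0.9)))
  expect_error(aggregate_records(rec[0, ]), "no records")
})

test_that("Mann-Whitney comparison matches U enumeration and is order-invariant", {
  x <- c(1.2, 3.4, 5.6); y <- c(0.1, 0.2, 0.3)   # fully separated
  res <- compare_distributions(x, y)
  ora <- exact_mw(x, y)
  expect_equal(res$U, ora$U)          # U = 9 for full separation
  expect_equal(res$U, 9)
  # approximate p in the same regime as the exact enumeration (0.1)
  expect_lt(res$p_value, 0.15)
  expect_gt(res$p_value, 0.02)
  res_swap <- compare_distributions(rev(x), rev(y))
  expect_equal(res_swap, res)
  # identical samples: U = n*m/2
  same <- compare_distributions(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$U, 8)
  expect_error(compare_distributions(numeric(0), y), "non-empty")
})

test_that("permutation importance flags informative columns and zeroes constant ones", {
  withr::local_seed(30)
  n <- 120
  informative <- rnorm(n)
  X <- cbind(signal = informative, noise = rnorm(n), flat = rep(1, n))
  y01 <- as.integer(informative + rnorm(n, sd = 0.4) > 0)
  m <- fit_model(model_spec("LRCV"), X, y01, seed = 1)
  Xh <- cbind(signal = rnorm(n), noise = rnorm(n), flat = rep(1, n))
  yh <- as.integer(Xh[, "signal"] + rnorm(n, sd = 0.4) > 0)
  imp <- permutation_importance(m, Xh, yh, n_repeats = 5, seed = 2)
  expect_gt(imp["signal"], 0.1)
  expect_equal(unname(imp["flat"]), 0)       # shuffle is the identity
  expect_lt(abs(imp["noise"]), 0.08)         # ~0 within noise
  expect_error(permutation_importance(m, Xh[, 1:2], yh), "feature mismatch")
})

test_that("top mean-|coefficient| ranking restricts to features present in all runs", {
  runs <- list(c(a = 1.0, b = -0.2, c = 0.5),
               c(a = -0.8, b = 0.4, c = 0.1),
               c(a = 0.6, c = 0.9, b = 0.0))
  top <- top_mean_abs_coefficients(runs, k = 2)
  expect_identical(top$feature, c("a", "c"))
  expect_equal(top$mean_abs_coef, c(0.8, 0.5))
  # a feature missing from one run is ineligible
  runs2 <- c(runs, list(c(a = 1, c = 1)))
  expect_false("b" %in% top_mean_abs_coefficients(runs2, k = 10)$feature)
  expect_equal(nrow(top_mean_abs_coefficients(runs, k = 10)), 3)
  expect_error(top_mean_abs_coefficients(runs, k = 0), "positive")
})

test_that("held-out subtype probabilities are higher for severe planted phenotypes", {
  w <- small_world()
  ds <- phenotype_dataset(w, "cerevisiae")
  cv <- repeated_stratified_cv(ds$X, ds$y, model_spec("LRCV"), 2, 5, seed = 8)
  tab <- subtype_probabilities(cv, ds$raw_labels)
  expect_true(all(tab$median_prob >= 0 & tab$median_prob <= 1))
  expect_true(all(c("n", "median_prob") %in% names(tab)))
})
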