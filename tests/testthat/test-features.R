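# Feature construction: set filtering, GI-proportion and membership
# features, merging, scaling, naive-Bayes selection.

test_that("gene-set size filter intersects with the background and applies 3-30 bounds", {
  bg <- sprintf("g%02d", 1:40)
  sets <- list(
    too_big = sprintf("g%02d", 1:31),        # 31 background members
    too_small = c("g01", "g02"),             # 2
    at_min = c("g01", "g02", "g03"),         # exactly 3
    at_max = sprintf("g%02d", 1:30),         # exactly 30
    shrunk = c(sprintf("g%02d", 1:4), "x1", "x2"))  # 4 after intersection
  coll <- gene_set_collection(sets, source = "GO_BP")
  filt <- filter_gene_sets(coll, bg)
  expect_setequal(names(filt$sets), c("at_min", "at_max", "shrunk"))
  expect_setequal(filt$sets$shrunk, sprintf("g%02d", 1:4))
  expect_error(filter_gene_sets(coll, character(0)), "non-empty")
})

test_that("GI proportion equals the fraction of the set with a non-zero score", {
  m <- Matrix::sparseMatrix(i = c(1, 1), j = c(1, 3), x = c(0.5, -0.2),
                            dims = c(2, 4),
                            dimnames = list(c("g", "g2"),
                                            c("h1", "h2", "h3", "h4")))
  gi <- gi_matrix(m, "scored")
  coll <- gene_set_collection(list(S = c("h1", "h2", "h3", "h4")), "KEGG")
  ft <- gi_proportion_features(gi, coll)
  expect_equal(ft$values["g", "KEGG:S"], 0.5)   # interacts with h1, h3 of 4
  expect_equal(ft$values["g2", "KEGG:S"], 0)    # no non-zero GI at all
})

test_that("GI proportion matches a brute-force count/size oracle on a random toy", {
  withr::local_seed(9)
  genes <- sprintf("t%02d", 1:20)
  edges <- expand.grid(gene_a = genes, gene_b = genes, stringsAsFactors = FALSE)
  edges <- edges[runif(nrow(edges)) < 0.2 & edges$gene_a != edges$gene_b, ]
  edges$score <- rnorm(nrow(edges)); edges$p_value <- runif(nrow(edges), 0, 0.04)
  gi <- assemble_gi_edges(edges, "scored")
  sets <- lapply(1:5, function(i) sample(genes, sample(3:8, 1)))
  names(sets) <- paste0("s", 1:5)
  coll <- gene_set_collection(sets, "KEGG")
  ft <- gi_proportion_features(gi, coll, samples = genes)
  for (g in genes) for (s in names(sets)) {
    manual <- sum(vapply(sets[[s]], function(h) {
      g %in% rownames(gi$scores) && h %in% colnames(gi$scores) &&
        gi$scores[g, h] != 0
    }, logical(1))) / length(sets[[s]])
    expect_equal(ft$values[g, paste0("KEGG:", s)], manual)
  }
})

test_that("GI proportion is invariant to member order and sample order", {
  w <- small_world()
  coll <- w$sets$cerevisiae$kegg
  shuffled <- coll
  shuffled$sets <- lapply(coll$sets, rev)
  f1 <- gi_proportion_features(w$gi$cerevisiae, coll)
  f2 <- gi_proportion_features(w$gi$cerevisiae, shuffled)
  expect_equal(f1$values, f2$values)
})

test_that("membership features are exact indicators and restrict to covered genes", {
  coll <- gene_set_collection(list(C1 = c("a", "b"), C2 = c("b", "c")),
                              "COMPLEX")
  ft <- membership_features(coll, c("a", "b", "c", "d"))
  expect_setequal(ft$samples, c("a", "b", "c"))   # d is in no complex
  for (g in ft$samples) for (s in c("C1", "C2"))
    expect_equal(ft$values[g, paste0("COMPLEX:", s)],
                 as.numeric(g %in% coll$sets[[s]]))
  full <- membership_features(coll, c("a", "b", "c", "d"), restrict = FALSE)
  expect_equal(full$values["d", ], c("COMPLEX:C1" = 0, "COMPLEX:C2" = 0))
})

test_that("merging intersects samples, concatenates features, and reproduces published widths", {
  mk <- function(samples, ids) {
    toy_feature_table(matrix(0, length(samples), length(ids),
                             dimnames = list(samples, ids)))
  }
  a <- mk(c("x", "y", "z"), paste0("a", 1:3))
  b <- mk(c("y", "z", "w"), paste0("b", 1:2))
  m <- merge_feature_tables(a, b)
  expect_identical(m$samples, c("y", "z"))
  expect_identical(m$features$id, c(paste0("a", 1:3), paste0("b", 1:2)))
  # combined widths as published for the pathway/complex configurations
  expect_equal(ncol(merge_feature_tables(mk("x", paste0("gobp", 1:1559)),
                                         mk("x", paste0("kegg", 1:109)))$values),
               1668)
  expect_equal(ncol(merge_feature_tables(mk("x", paste0("kegg", 1:109)),
                                         mk("x", paste0("cyc", 1:146)))$values),
               255)
  expect_error(merge_feature_tables(mk("x", "a1"), mk("y", "b1")),
               "empty sample intersection")
})

test_that("merging is associative over the sample intersection", {
  withr::local_seed(4)
  mk <- function(samples, pre, k) {
    toy_feature_table(matrix(runif(length(samples) * k), length(samples), k,
                             dimnames = list(samples, paste0(pre, 1:k))))
  }
  a <- mk(sprintf("g%d", 1:8), "a", 3)
  b <- mk(sprintf("g%d", 3:10), "b", 2)
  c_ <- mk(sprintf("g%d", c(1, 3, 5, 7, 9)), "c", 4)
  lhs <- merge_feature_tables(merge_feature_tables(a, b), c_)
  rhs <- merge_feature_tables(a, merge_feature_tables(b, c_))
  expect_setequal(lhs$samples, rhs$samples)
  expect_setequal(lhs$features$id, rhs$features$id)
  expect_equal(lhs$values[rhs$samples, rhs$features$id], rhs$values)
})

test_that("standardization uses training statistics only", {
  train <- toy_feature_table(matrix(c(1, 2, 3, 5, 5, 5), 3,
                                    dimnames = list(c("a", "b", "c"),
                                                    c("f1", "f2"))),
                             family = "propagation")
  std <- standardize(train)
  expect_equal(mean(std$table$values[, "f1"]), 0)
  expect_equal(sd(std$table$values[, "f1"]), 1)
  expect_equal(std$table$values[, "f2"], c(a = 0, b = 0, c = 0))  # constant
  heldout <- toy_feature_table(matrix(c(4, 5), 1,
                                      dimnames = list("h", c("f1", "f2"))),
                               family = "propagation")
  tr <- standardize(train, heldout)$table
  expect_equal(tr$values["h", "f1"], (4 - 2) / 1)  # hand arithmetic
  expect_equal(tr$values["h", "f2"], 0)
  expect_error(standardize(train, toy_feature_table(
    matrix(0, 1, 1, dimnames = list("h", "zz")), family = "propagation")),
    "feature mismatch")
})

test_that("naive-Bayes selection ranks by smoothed positive-class log-probability", {
  # 6 samples, positive class "long" (3 samples); binarized at > 0
  vals <- cbind(
    always_pos = c(1, 1, 1, -1, -1, -1),   # in all positives, no negatives
    never = c(-1, -1, -1, -1, -1, -1),     # in neither class
    half = c(1, -1, 1, 1, -1, -1))
  rownames(vals) <- sprintf("g%d", 1:6)
  tab <- toy_feature_table(vals, family = "propagation")
  y <- setNames(rep(c("long", "short"), each = 3), rownames(vals))
  # hand-computed smoothed log-probs: log(4/5), log(1/5), log(3/5)
  expect_identical(select_top_features(tab, y, k = 1), "always_pos")
  expect_identical(select_top_features(tab, y, k = 2),
                   c("always_pos", "half"))
  # k >= n_features returns everything
  expect_identical(select_top_features(tab, y, k = 10), colnames(vals))
  expect_error(select_top_features(tab, setNames(rep("long", 6), rownames(vals)),
                                   k = 2), "both classes")
})

test_that("selection is monotone in k and capped at the number of samples in CV", {
  withr::local_seed(11)
  vals <- matrix(rnorm(20 * 40), 20, dimnames = list(sprintf("g%d", 1:20),
                                                     sprintf("f%d", 1:40)))
  tab <- toy_feature_table(vals, family = "propagation")
  y <- setNames(rep(c("long", "short"), 10), rownames(vals))
  prev <- character(0)
  for (k in 1:10) {
    cur <- select_top_features(tab, y, k = k)
    expect_length(cur, k)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  # within the CV pipeline, a learner never sees more features than samples
  cv <- repeated_stratified_cv(tab, y, model_spec("LRCV"), repeats = 1,
                               folds = 2, seed = 5)
  for (m in cv$coefficients)
    expect_lte(length(m), 10)   # 10 training samples per 2-fold split
})
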