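# Feature engineering: GI-proportion features over pathway/GO-term sets,
# complex membership indicators, table merging, scaling and naive-Bayes
# feature selection.

#' Feature table
#'
#' A dense samples-by-features matrix with per-feature provenance.
#'
#' @param values numeric matrix, rows = samples, columns = features.
#' @param features data.frame with columns `id`, `source`, `set_id`,
#'   `family` (`gi_proportion`, `membership` or `propagation`).
#' @param species species tag.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(values, features, species = "cerevisiae") {
  check_species(species)
  stopifnot(is.matrix(values), nrow(features) == ncol(values))
  if (anyDuplicated(features$id)) stop("duplicate feature descriptors")
  if (is.null(rownames(values))) stop("feature_table values need sample rownames")
  colnames(values) <- features$id
  fam <- features$family
  bad <- setdiff(unique(fam), c("gi_proportion", "membership", "propagation"))
  if (length(bad)) stop("unknown feature family: ", bad[1])
  if (any(fam == "gi_proportion")) {
    v <- values[, fam == "gi_proportion", drop = FALSE]
    if (any(v < 0 | v > 1)) stop("gi_proportion values must lie in [0,1]")
  }
  if (any(fam == "membership")) {
    v <- values[, fam == "membership", drop = FALSE]
    if (!all(v %in% c(0, 1))) stop("membership values must be 0/1")
  }
  structure(list(samples = rownames(values), features = features,
                 values = values, species = species),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table [%s]: %d samples x %d features (%s)\n",
              x$species, length(x$samples), nrow(x$features),
              paste(unique(x$features$family), collapse = "+")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

feature_desc <- function(source, set_id, family) {
  data.frame(id = paste(source, set_id, sep = ":"), source = source,
             set_id = set_id, family = family, stringsAsFactors = FALSE)
}

#' Filter gene sets by background-restricted size
#'
#' Each set is first intersected with the background (the genes for which
#' prior data exist, e.g. those appearing in the GI dataset), then retained
#' iff its restricted size lies in `[min_size, max_size]`. Applied to GO
#' BP/CC term collections; broad terms (> 30 genes) carry little signal and
#' tiny ones (< 3) are unstable.
#'
#' @param sets a [gene_set_collection()].
#' @param background non-empty character vector of genes.
#' @param min_size,max_size inclusive size bounds (defaults 3 and 30).
#' @return filtered [gene_set_collection()] with members restricted to the
#'   background.
#' @export
filter_gene_sets <- function(sets, background, min_size = 3, max_size = 30) {
  if (length(background) == 0) stop("background must be non-empty")
  kept <- list()
  for (id in names(sets$sets)) {
    m <- intersect(sets$sets[[id]], background)
    if (length(m) >= min_size && length(m) <= max_size) kept[[id]] <- m
  }
  if (!length(kept))
    stop("no gene sets survive size filtering")
  gene_set_collection(kept, source = sets$source,
                      descriptions = sets$descriptions[names(kept)],
                      external_id = sets$external_id[names(kept)],
                      species = sets$species)
}

#' Genetic-interaction proportion features
#'
#' For each sample gene g and each gene set S, the feature value is the
#' proportion of S that has a non-zero GI score with g:
#' `|{h in S : score(g,h) != 0}| / |S|`. Genes of S absent from the GI
#' matrix columns count as zero-score partners.
#'
#' @param gi a [gi_matrix()]; its rows are the sample genes.
#' @param sets a (filtered) [gene_set_collection()].
#' @param samples optional sample universe; defaults to the GI matrix rows.
#'   Genes without a GI profile get all-zero rows.
#' @return a [feature_table()] with family `gi_proportion`.
#' @export
gi_proportion_features <- function(gi, sets, samples = NULL) {
  if (any(lengths(sets$sets) == 0)) stop("empty set in collection")
  nz <- gi$scores
  nz@x <- as.numeric(nz@x != 0)
  if (is.null(samples)) samples <- rownames(nz)
  profiled <- samples[samples %in% rownames(nz)]
  vals <- matrix(0, nrow = length(samples), ncol = length(sets$sets),
                 dimnames = list(samples, names(sets$sets)))
  for (id in names(sets$sets)) {
    S <- sets$sets[[id]]
    present <- intersect(S, colnames(nz))
    if (length(present) && length(profiled))
      vals[profiled, id] <-
        Matrix::rowSums(nz[profiled, present, drop = FALSE]) / length(S)
  }
  feature_table(vals, feature_desc(sets$source, names(sets$sets), "gi_proportion"),
                species = gi$species)
}

#' Protein-complex membership features
#'
#' Binary indicators: value(g, C) = 1 iff gene g is a member of complex C.
#' With `restrict = TRUE` (the default) the sample list is reduced to genes
#' belonging to at least one set, which is why complex feature tables cover
#' fewer samples than pathway tables. `restrict = FALSE` keeps the full
#' sample universe with all-zero rows for uncovered genes (used for the
#' genome-wide discovery datasets).
#'
#' @param sets a [gene_set_collection()] of complexes (or GO CC terms).
#' @param samples candidate sample genes.
#' @param restrict drop samples in no set (default `TRUE`).
#' @return a [feature_table()] with family `membership`.
#' @export
membership_features <- function(sets, samples, restrict = TRUE) {
  vals <- sapply(sets$sets, function(S) as.numeric(samples %in% S))
  vals <- matrix(vals, nrow = length(samples),
                 dimnames = list(samples, names(sets$sets)))
  if (restrict) {
    covered <- rowSums(vals) > 0
    vals <- vals[covered, , drop = FALSE]
  }
  feature_table(vals, feature_desc(sets$source, names(sets$sets), "membership"),
                species = sets$species)
}

#' Merge two feature tables on their shared samples
#'
#' Samples are intersected (keeping the first table's order); features are
#' concatenated, first table's columns first.
#'
#' @param a,b [feature_table()]s of the same species.
#' @return merged [feature_table()].
#' @export
merge_feature_tables <- function(a, b) {
  if (a$species != b$species) stop("cannot merge feature tables across species")
  common <- intersect(a$samples, b$samples)
  if (!length(common)) stop("empty sample intersection when merging")
  if (any(a$features$id %in% b$features$id))
    stop("duplicate feature descriptors between tables")
  vals <- cbind(a$values[common, , drop = FALSE], b$values[common, , drop = FALSE])
  feature_table(vals, rbind(a$features, b$features), species = a$species)
}

#' Add a single propagation feature column
#'
#' @param tab a [feature_table()].
#' @param scores named numeric of per-gene propagation values; samples of
#'   `tab` absent from `scores` are dropped (they are outside the network).
#' @param id feature id (default `"ANCHOR:propagation"`).
#' @return extended [feature_table()].
#' @export
add_propagation_feature <- function(tab, scores, id = "ANCHOR:propagation") {
  keep <- tab$samples[tab$samples %in% names(scores)]
  if (!length(keep)) stop("no samples covered by propagation scores")
  vals <- cbind(tab$values[keep, , drop = FALSE],
                matrix(scores[keep], ncol = 1, dimnames = list(keep, id)))
  feats <- rbind(tab$features,
                 data.frame(id = id, source = "ANCHOR", set_id = "propagation",
                            family = "propagation", stringsAsFactors = FALSE))
  feature_table(vals, feats, species = tab$species)
}

#' Fit standardization on training rows and apply
#'
#' Per-feature z-scaling with mean/sd learned from the training table only;
#' constant training features (sd below `eps`) map to 0.
#'
#' @param train training [feature_table()].
#' @param apply_to table to transform (same features; defaults to `train`).
#' @param eps sd threshold below which a feature counts as constant.
#' @return list with `scaler` (means/sds) and `table` (transformed copy of
#'   `apply_to`, values no longer family-constrained).
#' @export
standardize <- function(train, apply_to = train, eps = 1e-12) {
  if (!identical(train$features$id, apply_to$features$id))
    stop("feature mismatch between train and apply_to")
  mu <- colMeans(train$values)
  sdv <- apply(train$values, 2, sd)
  sdv[!is.finite(sdv) | sdv < eps] <- 1
  vals <- sweep(sweep(apply_to$values, 2, mu, "-"), 2, sdv, "/")
  out <- apply_to
  out$values <- vals
  class(out) <- "feature_table"   # keep structure; values now standardized
  list(scaler = list(mean = mu, sd = sdv), table = out)
}

apply_scaler <- function(scaler, tab) {
  out <- tab
  out$values <- sweep(sweep(tab$values, 2, scaler$mean, "-"), 2, scaler$sd, "/")
  out
}

#' Select top features by Bernoulli naive-Bayes importance
#'
#' Feature values are binarized at 0 (after standardization, a positive
#' value means above the training average). Importance of feature i is the
#' add-one-smoothed log probability of observing the feature in the positive
#' class, `log((n_pos_i + 1) / (n_pos + 2))`. The `k` highest-importance
#' features are returned (all features when the table has at most `k`); ties
#' break by feature order in the table.
#'
#' @param train standardized training [feature_table()].
#' @param y named binary labels over the training samples.
#' @param k number of features to keep (typically the number of training
#'   samples, so the learner never sees more features than samples).
#' @param positive label value treated as the positive class.
#' @return character vector of selected feature ids, in table order.
#' @export
select_top_features <- function(train, y, k, positive = NULL) {
  if (k < 1) stop("k must be >= 1")
  y <- y[train$samples]
  if (length(unique(y)) < 2) stop("feature selection needs both classes")
  if (is.null(positive)) positive <- positive_class(y)
  pos <- train$values[y == positive, , drop = FALSE] > 0
  npos <- nrow(pos)
  imp <- log((colSums(pos) + 1) / (npos + 2))
  if (ncol(train$values) <= k) return(train$features$id)
  ord <- order(-imp, seq_along(imp))
  sel <- sort(ord[seq_len(k)])
  train$features$id[sel]
}

positive_class <- function(y) {
  u <- unique(y)
  if ("long" %in% u) "long" else if ("tlm" %in% u) "tlm" else sort(u)[1]
}

#' Restrict a feature table to a sample subset
#'
#' @param tab a [feature_table()].
#' @param samples genes to keep (order preserved; must all be present).
#' @return a [feature_table()] over `samples`.
#' @export
subset_samples <- function(tab, samples) {
  missing <- setdiff(samples, tab$samples)
  if (length(missing)) stop("samples not in table: ", missing[1])
  out <- tab
  out$values <- tab$values[samples, , drop = FALSE]
  out$samples <- samples
  out
}

# Column subset without re-validating family ranges (used on standardized
# tables whose values are no longer in the raw family domain).
subset_features <- function(tab, ids) {
  keep <- tab$features$id %in% ids
  out <- tab
  out$values <- tab$values[, keep, drop = FALSE]
  out$features <- tab$features[keep, , drop = FALSE]
  out
}
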