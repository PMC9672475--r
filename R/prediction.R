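# Cross-species feature mapping, the five TLM-discovery dataset
# constructions, leave-one-out candidate ranking, and gene-set
# overrepresentation analysis.

#' Map cerevisiae features onto pombe features
#'
#' KEGG pathway features share a naming convention across species and are
#' joined on identical pathway ids. Complex features are joined via GO
#' accession: a cerevisiae complex is eligible iff its GO id is unique
#' within its catalog, and maps to the pombe complex with the same (equally
#' unique) GO id. Unmatched features are dropped with a message; complexes
#' with duplicated GO ids are excluded with a warning.
#'
#' @param features_sc feature descriptor data.frame of the cerevisiae table
#'   (`$features` of a [feature_table()]).
#' @param kegg_sp,complex_sp pombe [gene_set_collection()]s.
#' @param complex_sc cerevisiae complex collection (for the GO ids).
#' @return data.frame of class `feature_mapping` with columns `sc_id`,
#'   `sp_id`, `join_key`; one-to-one.
#' @export
map_cross_species_features <- function(features_sc, kegg_sp, complex_sp,
                                       complex_sc) {
  maps <- list()
  kegg_feats <- features_sc[features_sc$source == "KEGG", , drop = FALSE]
  hit <- kegg_feats$set_id %in% names(kegg_sp$sets)
  if (any(hit))
    maps$kegg <- data.frame(sc_id = kegg_feats$id[hit],
                            sp_id = paste(kegg_sp$source, kegg_feats$set_id[hit], sep = ":"),
                            join_key = "kegg_id")
  cx_feats <- features_sc[features_sc$source == "COMPLEX", , drop = FALSE]
  if (nrow(cx_feats)) {
    go_sc <- complex_sc$external_id[cx_feats$set_id]
    dup_sc <- go_sc %in% go_sc[duplicated(go_sc)] & !is.na(go_sc)
    if (any(dup_sc))
      warning("complexes with non-unique GO ids excluded: ",
              paste(cx_feats$set_id[dup_sc], collapse = ", "))
    go_sp <- complex_sp$external_id
    go_sp_unique <- go_sp[!is.na(go_sp) & !go_sp %in% go_sp[duplicated(go_sp)]]
    ok <- !is.na(go_sc) & !dup_sc & go_sc %in% go_sp_unique
    if (any(ok)) {
      sp_set <- names(go_sp_unique)[match(go_sc[ok], go_sp_unique)]
      maps$complex <- data.frame(sc_id = cx_feats$id[ok],
                                 sp_id = paste(complex_sp$source, sp_set, sep = ":"),
                                 join_key = "go_id")
    }
  }
  out <- do.call(rbind, maps)
  if (is.null(out) || !nrow(out)) stop("no cross-species features could be mapped")
  n_drop <- nrow(features_sc) - nrow(out)
  if (n_drop > 0) message(n_drop, " unmatched feature(s) dropped in mapping")
  rownames(out) <- NULL
  class(out) <- c("feature_mapping", "data.frame")
  out
}

#' Build the dataset for one of the five TLM-discovery methods
#'
#' Methods:
#' 1. label transfer — a pombe gene is predicted TLM iff its cerevisiae
#'    ortholog is a TLM gene (no model);
#' 2. cross-species transfer — train on cerevisiae rows of the mapped
#'    features, predict on the pombe rows (returned as `train`/`test`);
#' 3. pombe features and labels only;
#' 4. method 3 plus the cerevisiae feature block of each gene's ortholog
#'    (zero-imputed when a gene has no ortholog), doubling the width;
#' 5. method 3 plus the anchor-proximity propagation feature (width + 1;
#'    samples restricted to genes covered by the PPI network).
#'
#' @param method integer 1-5.
#' @param features_sp pombe [feature_table()] over the candidate universe.
#' @param labels_sp named `tlm`/`non_tlm` labels for pombe genes.
#' @param orthologs resolved [resolve_orthologs()] table.
#' @param labels_sc_tlm named `tlm`/`non_tlm` labels for cerevisiae genes
#'   (methods 1-2 and the ranking annotation).
#' @param features_sc cerevisiae [feature_table()] (methods 2 and 4).
#' @param mapping a [map_cross_species_features()] table (method 2).
#' @param propagation named propagation scores (method 5).
#' @param ortholog_flag add an extra indicator column marking genes with an
#'   ortholog in method 4 (default `FALSE`, keeping the width at exactly
#'   twice method 3's).
#' @return method 1: data.frame of direct predictions. Method 2: list with
#'   `train` and `test` (`X`, `y` each). Methods 3-5: list with `X`
#'   (feature_table) and `y`.
#' @export
build_method_dataset <- function(method, features_sp, labels_sp,
                                 orthologs = NULL, labels_sc_tlm = NULL,
                                 features_sc = NULL, mapping = NULL,
                                 propagation = NULL, ortholog_flag = FALSE) {
  stopifnot(method %in% 1:5)
  if (method == 1) {
    if (is.null(orthologs) || is.null(labels_sc_tlm))
      stop("method 1 requires an ortholog table and cerevisiae labels")
    ort <- setNames(orthologs$cerevisiae_gene, orthologs$pombe_gene)
    genes <- names(labels_sp)
    sc <- ort[genes]
    pred <- ifelse(!is.na(sc) & labels_sc_tlm[sc] == "tlm", "tlm", "non_tlm")
    return(data.frame(pombe_gene = genes, predicted = unname(pred),
                      cerevisiae_ortholog = unname(sc),
                      stringsAsFactors = FALSE))
  }
  if (method == 2) {
    if (is.null(features_sc) || is.null(mapping) || is.null(labels_sc_tlm))
      stop("method 2 requires cerevisiae features, labels and a feature mapping")
    m <- mapping[mapping$sc_id %in% features_sc$features$id &
                 mapping$sp_id %in% features_sp$features$id, , drop = FALSE]
    if (!nrow(m)) stop("mapping matches no columns of the supplied tables")
    Xtr <- subset_features(features_sc, m$sc_id)
    m <- m[match(Xtr$features$id, m$sc_id), , drop = FALSE]
    # pombe columns reordered into the cerevisiae descriptor space
    Xte <- features_sp
    Xte$values <- features_sp$values[, m$sp_id, drop = FALSE]
    colnames(Xte$values) <- m$sc_id
    Xte$features <- Xtr$features
    Xte$species <- "pombe"
    return(list(train = list(X = Xtr, y = labels_sc_tlm[Xtr$samples]),
                test = list(X = Xte, y = labels_sp[Xte$samples])))
  }
  if (method == 3)
    return(list(X = features_sp, y = labels_sp[features_sp$samples]))
  if (method == 4) {
    if (is.null(orthologs) || is.null(features_sc))
      stop("method 4 requires an ortholog table and cerevisiae features")
    ort <- setNames(orthologs$cerevisiae_gene, orthologs$pombe_gene)
    sc_block <- matrix(0, nrow = length(features_sp$samples),
                       ncol = ncol(features_sc$values),
                       dimnames = list(features_sp$samples,
                                       paste0("ortholog:", features_sc$features$id)))
    sc_of <- ort[features_sp$samples]
    has <- !is.na(sc_of) & sc_of %in% features_sc$samples
    sc_block[has, ] <- features_sc$values[sc_of[has], , drop = FALSE]
    feats <- rbind(features_sp$features,
                   data.frame(id = colnames(sc_block),
                              source = features_sc$features$source,
                              set_id = features_sc$features$set_id,
                              family = features_sc$features$family))
    vals <- cbind(features_sp$values, sc_block)
    if (ortholog_flag) {
      vals <- cbind(vals, has_ortholog = as.numeric(has))
      feats <- rbind(feats, data.frame(id = "has_ortholog", source = "ORTHOLOG",
                                       set_id = "flag", family = "membership"))
    }
    X <- features_sp; X$values <- vals; X$features <- feats
    colnames(X$values) <- feats$id
    return(list(X = X, y = labels_sp[X$samples]))
  }
  # method 5
  if (is.null(propagation))
    stop("method 5 requires propagation scores")
  X <- add_propagation_feature(features_sp, propagation)
  list(X = X, y = labels_sp[X$samples])
}

#' Leave-one-out candidate ranking
#'
#' Fits the model on all samples but one and predicts the held-out gene's
#' TLM probability, in turn for every gene, so the entire dataset serves as
#' training data for each prediction. Genes already labeled TLM are then
#' excluded and the remainder ranked by estimated probability (descending;
#' ties broken by gene name). Each fit standardizes and selects features on
#' its own training rows.
#'
#' @param X a [feature_table()].
#' @param y named `tlm`/`non_tlm` labels.
#' @param model a [model_spec()]; the study uses
#'   `model_spec("LRCV", class_weight = "balanced")`.
#' @param seed integer seed.
#' @param orthologs optional resolved ortholog table for annotation.
#' @param labels_sc_tlm optional cerevisiae `tlm`/`non_tlm` labels; adds the
#'   `ortholog_is_tlm` column.
#' @return data.frame of class `candidate_ranking`: `pombe_gene`,
#'   `probability`, `cerevisiae_ortholog`, `ortholog_is_tlm`, sorted by
#'   probability descending. Attribute `all_probabilities` holds the LOO
#'   probability of every gene (including TLM-labeled ones).
#' @export
loo_rank_candidates <- function(X, y,
                                model = model_spec("LRCV", class_weight = "balanced"),
                                seed = 1, orthologs = NULL,
                                labels_sc_tlm = NULL) {
  X <- subset_samples(X, sort(X$samples))  # canonical order: ranking must not
  y <- y[X$samples]                        # depend on input gene order
  if (length(X$samples) < 3) stop("leave-one-out needs at least 3 samples")
  if (anyNA(y)) stop("labels missing for some samples")
  y01 <- as.integer(y == "tlm")
  n <- length(X$samples)
  prob <- setNames(numeric(n), X$samples)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(y01[tr])) < 2) stop("degenerate single-class training fold")
    Xtr <- X; Xtr$values <- X$values[tr, , drop = FALSE]; Xtr$samples <- X$samples[tr]
    std <- standardize(Xtr)
    sel <- if (ncol(X$values) > length(tr))
      select_top_features(std$table, y, k = length(tr), positive = "tlm")
    else X$features$id
    Xtr_s <- subset_features(std$table, sel)
    m <- fit_model(model, Xtr_s$values, y01[tr], seed = as.integer(seed + i))
    Xte <- X; Xte$values <- X$values[i, , drop = FALSE]; Xte$samples <- X$samples[i]
    Xte_s <- subset_features(apply_scaler(std$scaler, Xte), sel)
    prob[i] <- predict(m, Xte_s$values)
  }
  cand <- X$samples[y != "tlm"]
  ord <- order(-prob[cand], cand)
  out <- data.frame(pombe_gene = cand[ord], probability = unname(prob[cand][ord]),
                    stringsAsFactors = FALSE)
  if (!is.null(orthologs)) {
    ort <- setNames(orthologs$cerevisiae_gene, orthologs$pombe_gene)
    out$cerevisiae_ortholog <- unname(ort[out$pombe_gene])
    if (!is.null(labels_sc_tlm))
      out$ortholog_is_tlm <- !is.na(out$cerevisiae_ortholog) &
        labels_sc_tlm[out$cerevisiae_ortholog] == "tlm"
  }
  attr(out, "all_probabilities") <- prob
  class(out) <- c("candidate_ranking", "data.frame")
  out
}

#' Gene-set overrepresentation analysis
#'
#' For each term with at most `max_term_size` background members, tests
#' overrepresentation of the candidate set with a one-sided Fisher's exact
#' test (alternative "greater") on the 2x2 candidate-by-membership table,
#' then adjusts p-values by Benjamini-Hochberg.
#'
#' @param candidates gene set of interest (subset of `background`).
#' @param background gene universe.
#' @param terms a [gene_set_collection()].
#' @param max_term_size largest background-restricted term tested (250).
#' @param alpha FDR significance threshold (0.05).
#' @return data.frame of class `enrichment_result`: `term_id`,
#'   `n_candidates_in_term`, `n_background_in_term`, `odds_ratio`,
#'   `p_value`, `q_value`, `significant`; rows ordered by p-value.
#' @export
enrich_terms <- function(candidates, background, terms,
                         max_term_size = 250, alpha = 0.05) {
  if (!length(candidates)) stop("empty candidate set")
  if (!all(candidates %in% background))
    stop("candidates must be a subset of the background")
  rows <- list()
  for (id in names(terms$sets)) {
    in_term <- intersect(terms$sets[[id]], background)
    if (length(in_term) == 0 || length(in_term) > max_term_size) next
    a <- sum(candidates %in% in_term)
    b <- length(candidates) - a
    c_ <- length(in_term) - a
    d <- length(background) - length(candidates) - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                             alternative = "greater")
    rows[[id]] <- data.frame(term_id = id, n_candidates_in_term = a,
                             n_background_in_term = length(in_term),
                             odds_ratio = unname(ft$estimate),
                             p_value = ft$p.value)
  }
  if (!length(rows)) stop("no terms eligible for testing")
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < alpha
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
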