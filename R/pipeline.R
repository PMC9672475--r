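# End-to-end dataset builders tying the modules together. These mirror the
# two study tasks: (i) short-vs-long phenotype classification among TLM
# genes, and (ii) TLM-vs-non-TLM gene discovery over the ortholog universe.

#' Build the short/long phenotype dataset for one species
#'
#' The headline feature configuration: genetic-interaction proportion
#' features over pathways plus protein-complex membership indicators,
#' merged on their shared samples and restricted to genes with a binary
#' phenotype.
#'
#' @param world a [generate_world()] result (or a list of the same shape
#'   built from files).
#' @param species `"cerevisiae"` or `"pombe"`.
#' @return list with `X` (a [feature_table()]), `y` (named `short`/`long`
#'   labels) and `raw_labels`.
#' @export
phenotype_dataset <- function(world, species = "cerevisiae") {
  check_species(species)
  gi <- world$gi[[species]]
  kegg <- gi_proportion_features(gi, world$sets[[species]]$kegg)
  cx <- membership_features(world$sets[[species]]$complex,
                            rownames(gi$scores), restrict = TRUE)
  merged <- merge_feature_tables(kegg, cx)
  y <- world$labels[[species]]
  keep <- merged$samples[merged$samples %in% names(y)]
  if (length(keep) < 20) stop("too few labeled samples with feature coverage")
  list(X = subset_samples(merged, keep), y = y[keep],
       raw_labels = world$raw_labels[[species]])
}

#' Build a TLM-discovery dataset for one of the five methods
#'
#' Resolves orthologs from the world's candidate table and sequences, builds
#' pathway and complex features over the ortholog gene universe (complex
#' indicators zero-filled rather than restricted, so the whole universe is
#' scored), computes the anchor propagation feature for method 5, and
#' dispatches to [build_method_dataset()].
#'
#' @param world a [generate_world()] result.
#' @param method integer 1-5.
#' @return the [build_method_dataset()] result, plus elements `orthologs`
#'   and `labels_sc_tlm` in an attribute for downstream annotation.
#' @export
discovery_dataset <- function(world, method) {
  orth <- resolve_orthologs(world$ortholog_candidates,
                            seqs_pombe = world$sequences$pombe,
                            seqs_cerevisiae = world$sequences$cerevisiae)
  universe_sp <- orth$pombe_gene
  universe_sc <- world$genes$cerevisiae
  y_sp <- tlm_labels(world$labels$pombe, universe_sp)
  y_sc <- tlm_labels(world$labels$cerevisiae, universe_sc)

  feats_for <- function(species, universe) {
    kegg <- gi_proportion_features(world$gi[[species]],
                                   world$sets[[species]]$kegg,
                                   samples = universe)
    cx <- membership_features(world$sets[[species]]$complex, universe,
                              restrict = FALSE)
    merge_feature_tables(kegg, cx)
  }
  X_sp <- feats_for("pombe", universe_sp)
  X_sc <- if (method %in% c(2, 4)) feats_for("cerevisiae", universe_sc) else NULL
  mapping <- if (method == 2)
    map_cross_species_features(X_sc$features, world$sets$pombe$kegg,
                               world$sets$pombe$complex,
                               world$sets$cerevisiae$complex) else NULL
  propagation <- if (method == 5) {
    W <- normalize_adjacency(world$ppi)
    rwr_propagate(W, world$anchors)$p
  } else NULL

  ds <- build_method_dataset(method, X_sp, y_sp, orthologs = orth,
                             labels_sc_tlm = y_sc, features_sc = X_sc,
                             mapping = mapping, propagation = propagation)
  attr(ds, "orthologs") <- orth
  attr(ds, "labels_sc_tlm") <- y_sc
  ds
}
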