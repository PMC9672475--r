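# Synthetic two-species worlds with planted TLM structure. The generator
# emulates the statistical shape of the real inputs -- sparse GI profiles
# correlated with phenotype-associated gene sets, protein complexes enriched
# for one phenotype, a PPI graph where TLM genes sit near anchor genes,
# orthologs with a tunable phenotype-conservation probability, and mutated
# protein sequence pairs -- so that every pipeline stage is testable without
# external downloads. Ground truth is stored apart from the pipeline-facing
# inputs.

#' Parameters of a synthetic world
#'
#' Defaults describe the study regime the pipeline is validated under:
#' 400 genes per species, a quarter of them TLM; strong genetic-interaction
#' signal (non-zero GI probability 0.6 towards members of a gene's
#' phenotype-associated sets vs 0.02 background); complexes 85% pure for
#' their phenotype; cerevisiae short-majority (P(short|TLM)=0.6) vs pombe
#' long-majority (P(short|TLM)=0.25), mirroring the inverted class balance
#' of the two species; ortholog phenotype-conservation probability 0.6,
#' near the empirically observed conservation among shared TLM orthologs.
#'
#' @param n_genes genes per species.
#' @param n_pathways,n_complexes,n_go_terms number of sets per collection.
#' @param pathway_size_range,complex_size_range,go_size_range inclusive
#'   sampling bounds for set sizes (GO sizes deliberately straddle the 3-30
#'   filter).
#' @param fraction_tlm fraction of genes with a telomere phenotype
#'   (`fraction_tlm * n_genes >= 20` required for stable stratification).
#' @param p_short_tlm_sc,p_short_tlm_sp P(short | TLM) per species.
#' @param gi_signal,gi_background non-zero GI probabilities for
#'   (TLM gene, member of a phenotype-associated set) pairs vs all others.
#' @param complex_purity fraction of complex members drawn from TLM genes
#'   of the complex's phenotype.
#' @param assoc_fraction fraction of pathways/GO terms associated with a
#'   phenotype.
#' @param ppi_density background PPI edge density.
#' @param n_anchors number of anchor genes (drawn from pombe TLM genes).
#' @param anchor_boost probability that a pombe TLM gene gains a direct
#'   edge to an anchor.
#' @param ortholog_coverage fraction of pombe genes with a cerevisiae
#'   ortholog.
#' @param tlm_transfer P(pombe gene is TLM | its ortholog is TLM).
#' @param base_tlm_rate P(pombe gene is TLM | ortholog not TLM / none).
#' @param conservation_prob P(same phenotype | both orthologs TLM).
#' @param ambiguous_fraction fraction of ortholog pairs that also get a
#'   decoy candidate.
#' @param seq_len_range ancestor protein length bounds.
#' @param mutation_rate,decoy_mutation_rate per-residue substitution rates
#'   for true partners and decoys (decoys mutate more, so alignment
#'   resolution has a knowable right answer).
#' @param mask_fraction fraction of pombe TLM genes whose label is withheld
#'   from the emitted files (recorded in ground truth; used to test
#'   candidate recovery).
#' @param seed master seed; every stage draws from a stream keyed by
#'   (seed, stage) so adding a stage never perturbs earlier stages.
#' @return list of class `world_params`.
#' @export
world_params <- function(n_genes = 400,
                         n_pathways = 25, n_complexes = 30, n_go_terms = 40,
                         pathway_size_range = c(5, 30),
                         complex_size_range = c(4, 10),
                         go_size_range = c(2, 40),
                         fraction_tlm = 0.25,
                         p_short_tlm_sc = 0.6, p_short_tlm_sp = 0.25,
                         gi_signal = 0.6, gi_background = 0.02,
                         complex_purity = 0.85, assoc_fraction = 0.6,
                         ppi_density = 0.02, n_anchors = 8,
                         anchor_boost = 0.35,
                         ortholog_coverage = 0.8, tlm_transfer = 0.6,
                         base_tlm_rate = 0.08, conservation_prob = 0.6,
                         ambiguous_fraction = 0.15,
                         seq_len_range = c(40, 80),
                         mutation_rate = 0.05, decoy_mutation_rate = 0.3,
                         mask_fraction = 0.2, seed = 1) {
  p <- as.list(environment())
  probs <- c(fraction_tlm, p_short_tlm_sc, p_short_tlm_sp, gi_signal,
             gi_background, complex_purity, assoc_fraction, ppi_density,
             anchor_boost, ortholog_coverage, tlm_transfer, base_tlm_rate,
             conservation_prob, ambiguous_fraction, mutation_rate,
             decoy_mutation_rate, mask_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (fraction_tlm * n_genes < 20)
    stop("fraction_tlm * n_genes must be >= 20 for stable stratification")
  if (max(pathway_size_range, complex_size_range, go_size_range) > n_genes)
    stop("set sizes exceed gene count")
  structure(p, class = "world_params")
}

sample_range <- function(n, range) sample(seq(range[1], range[2]), n, replace = TRUE)

mutate_seq <- function(s, rate, alphabet) {
  res <- strsplit(s, "")[[1]]
  hit <- runif(length(res)) < rate
  res[hit] <- sample(alphabet, sum(hit), replace = TRUE)
  paste(res, collapse = "")
}

raw_variant <- function(reduced) {
  if (reduced == "short") sample(c("short", "very short", "slightly short",
                                   "DAmP Short"), 1,
                                 prob = c(0.5, 0.2, 0.2, 0.1))
  else sample(c("long", "very long", "slightly long", "DAmP Long"), 1,
              prob = c(0.5, 0.2, 0.2, 0.1))
}

make_sets <- function(prefix, n_sets, size_range, genes, tlm_by_phen,
                      purity, assoc_fraction, source, species,
                      go_ids = FALSE) {
  phen <- rep("none", n_sets)
  n_assoc <- round(assoc_fraction * n_sets)
  phen[seq_len(n_assoc)] <- rep(c("short", "long"), length.out = n_assoc)
  sets <- list(); ext <- character(n_sets)
  sizes <- sample_range(n_sets, size_range)
  for (k in seq_len(n_sets)) {
    id <- sprintf("%s%03d", prefix, k)
    size <- sizes[k]
    if (phen[k] != "none" && purity > 0) {
      pool <- tlm_by_phen[[phen[k]]]
      n_pure <- min(rbinom(1, size, purity), length(pool))
      members <- sample(pool, n_pure)
      members <- c(members, sample(setdiff(genes, members), size - n_pure))
    } else {
      members <- sample(genes, size)
    }
    sets[[id]] <- sort(members)
    ext[k] <- if (go_ids) sprintf("GO:%07d", 320000 + k) else NA_character_
  }
  list(collection = gene_set_collection(
         sets, source = source,
         external_id = setNames(ext, names(sets)), species = species),
       phenotype = setNames(phen, names(sets)))
}

make_gi_edges <- function(genes, labels, assoc_sets, set_phen, params,
                          scored) {
  # signal edges: TLM gene -> members of sets associated with its phenotype
  rows <- list()
  for (g in names(labels)) {
    ph <- labels[[g]]
    partners <- character(0)
    for (id in names(set_phen)[set_phen == ph])
      partners <- c(partners, assoc_sets$sets[[id]])
    partners <- setdiff(unique(partners), g)
    hit <- partners[runif(length(partners)) < params$gi_signal]
    if (length(hit)) rows[[g]] <- data.frame(gene_a = g, gene_b = hit)
  }
  # background edges for every gene
  n <- length(genes)
  n_bg <- rbinom(n, n - 1L, params$gi_background)
  bg <- lapply(seq_len(n), function(i) {
    if (n_bg[i] == 0) return(NULL)
    data.frame(gene_a = genes[i],
               gene_b = sample(setdiff(genes, genes[i]), n_bg[i]))
  })
  df <- do.call(rbind, c(rows, bg))
  df <- df[!duplicated(df[, c("gene_a", "gene_b")]), , drop = FALSE]
  if (scored) {
    df$score <- round(rnorm(nrow(df), sd = 0.2), 6)
    df$p_value <- round(runif(nrow(df), 1e-6, 0.049), 6)
    # sub-threshold noise rows and duplicate re-measurements exercise the
    # significance filter and the lowest-p selection rule
    n_noise <- ceiling(nrow(df) * 0.2)
    noise <- data.frame(gene_a = sample(genes, n_noise, replace = TRUE),
                        gene_b = sample(genes, n_noise, replace = TRUE),
                        score = round(rnorm(n_noise, sd = 0.2), 6),
                        p_value = round(runif(n_noise, 0.05, 1), 6))
    dup_idx <- sample(nrow(df), min(20, nrow(df)))
    dups <- df[dup_idx, , drop = FALSE]
    dups$score <- round(rnorm(nrow(dups), sd = 0.2), 6)
    dups$p_value <- round(pmin(dups$p_value + runif(nrow(dups), 0, 0.04), 0.0499), 6)
    df <- rbind(df, noise, dups)
  }
  rownames(df) <- NULL
  df[sample(nrow(df)), , drop = FALSE]   # shuffled: assembly is order-free
}

#' Generate a synthetic two-species world
#'
#' See [world_params()] for the planted structure. Same seed, same world:
#' generation is deterministic, and stages draw from independent streams.
#'
#' @param params a [world_params()].
#' @return list of class `synthetic_world`; element `ground_truth` holds
#'   the planted assignments (masked TLM genes, set-phenotype associations,
#'   true ortholog partners), everything else is pipeline-facing input.
#' @export
generate_world <- function(params = world_params()) {
  stopifnot(inherits(params, "world_params"))
  seed <- params$seed
  n <- params$n_genes
  sc_genes <- sprintf("SCG%04d", seq_len(n))
  sp_genes <- sprintf("SPG%04d", seq_len(n))

  # --- cerevisiae labels ---
  lab_sc <- with_stage_seed(seed, "labels_sc", {
    tlm <- sort(sample(sc_genes, round(params$fraction_tlm * n)))
    setNames(ifelse(runif(length(tlm)) < params$p_short_tlm_sc,
                    "short", "long"), tlm)
  })

  # --- orthologs and pombe labels ---
  orth <- with_stage_seed(seed, "orthologs", {
    n_pairs <- round(params$ortholog_coverage * n)
    data.frame(pombe_gene = sort(sample(sp_genes, n_pairs)),
               cerevisiae_gene = sample(sc_genes, n_pairs),
               stringsAsFactors = FALSE)
  })
  lab_sp <- with_stage_seed(seed, "labels_sp", {
    out <- character(0)
    ort_of <- setNames(orth$cerevisiae_gene, orth$pombe_gene)
    for (g in sp_genes) {
      sc <- ort_of[g]
      if (!is.na(sc) && sc %in% names(lab_sc)) {
        if (runif(1) < params$tlm_transfer) {
          same <- runif(1) < params$conservation_prob
          out[g] <- if (same) lab_sc[[sc]]
                    else setdiff(c("short", "long"), lab_sc[[sc]])
        }
      } else if (runif(1) < params$base_tlm_rate) {
        out[g] <- ifelse(runif(1) < params$p_short_tlm_sp, "short", "long")
      }
    }
    out
  })

  tlm_by_phen <- function(lab) list(short = names(lab)[lab == "short"],
                                    long = names(lab)[lab == "long"])

  # --- gene sets ---
  sets_sc <- with_stage_seed(seed, "sets_sc", list(
    kegg = make_sets("PATH", params$n_pathways, params$pathway_size_range,
                     sc_genes, tlm_by_phen(lab_sc), 0,
                     params$assoc_fraction, "KEGG", "cerevisiae"),
    complex = make_sets("CPX", params$n_complexes, params$complex_size_range,
                        sc_genes, tlm_by_phen(lab_sc), params$complex_purity,
                        1, "COMPLEX", "cerevisiae", go_ids = TRUE),
    gobp = make_sets("GOBP", params$n_go_terms, params$go_size_range,
                     sc_genes, tlm_by_phen(lab_sc), 0,
                     params$assoc_fraction, "GO_BP", "cerevisiae")))
  sets_sp <- with_stage_seed(seed, "sets_sp", list(
    kegg = make_sets("PATH", params$n_pathways, params$pathway_size_range,
                     sp_genes, tlm_by_phen(lab_sp), 0,
                     params$assoc_fraction, "KEGG", "pombe"),
    complex = make_sets("CPX", params$n_complexes, params$complex_size_range,
                        sp_genes, tlm_by_phen(lab_sp), params$complex_purity,
                        1, "COMPLEX", "pombe", go_ids = TRUE),
    gobp = make_sets("GOBP", params$n_go_terms, params$go_size_range,
                     sp_genes, tlm_by_phen(lab_sp), 0,
                     params$assoc_fraction, "GO_BP", "pombe")))

  # --- genetic interactions ---
  gi_sc_edges <- with_stage_seed(seed, "gi_sc",
    make_gi_edges(sc_genes, lab_sc, sets_sc$kegg$collection,
                  sets_sc$kegg$phenotype, params, scored = TRUE))
  gi_sp_edges <- with_stage_seed(seed, "gi_sp",
    make_gi_edges(sp_genes, lab_sp, sets_sp$kegg$collection,
                  sets_sp$kegg$phenotype, params, scored = FALSE))

  # --- PPI + anchors (pombe) ---
  ppi <- with_stage_seed(seed, "ppi", {
    m <- rbinom(1, n * (n - 1) / 2, params$ppi_density)
    pairs <- matrix(sp_genes[arrayInd(sample(n * n, 2 * m), c(n, n))], ncol = 2)
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    pairs <- pairs[seq_len(min(m, nrow(pairs))), , drop = FALSE]
    anchors <- sample(names(lab_sp), min(params$n_anchors, length(lab_sp)))
    tlm <- names(lab_sp)
    boost <- tlm[runif(length(tlm)) < params$anchor_boost]
    extra <- if (length(boost))
      cbind(boost, sample(anchors, length(boost), replace = TRUE)) else NULL
    edges <- rbind(pairs, extra)
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    list(edges = data.frame(gene_a = edges[, 1], gene_b = edges[, 2],
                            stringsAsFactors = FALSE),
         anchors = sort(anchors))
  })

  # --- ortholog candidates + sequences ---
  seqs <- with_stage_seed(seed, "sequences", {
    aa20 <- setdiff(AA_ALPHABET, "X")
    cand <- orth
    cand$true <- TRUE
    sp_seq <- character(0); sc_seq <- character(0)
    unpaired_sc <- setdiff(sc_genes, orth$cerevisiae_gene)
    amb <- orth$pombe_gene[runif(nrow(orth)) < params$ambiguous_fraction]
    amb <- amb[seq_len(min(length(amb), length(unpaired_sc)))]
    decoys <- if (length(amb))
      data.frame(pombe_gene = amb,
                 cerevisiae_gene = sample(unpaired_sc, length(amb)),
                 true = FALSE, stringsAsFactors = FALSE) else NULL
    for (i in seq_len(nrow(orth))) {
      len <- sample_range(1, params$seq_len_range)
      anc <- paste(sample(aa20, len, replace = TRUE), collapse = "")
      sp_seq[orth$pombe_gene[i]] <- mutate_seq(anc, params$mutation_rate, aa20)
      sc_seq[orth$cerevisiae_gene[i]] <- mutate_seq(anc, params$mutation_rate, aa20)
      if (!is.null(decoys)) {
        j <- which(decoys$pombe_gene == orth$pombe_gene[i])
        if (length(j))
          sc_seq[decoys$cerevisiae_gene[j]] <-
            mutate_seq(anc, params$decoy_mutation_rate, aa20)
      }
    }
    cand <- rbind(cand, decoys)
    cand <- cand[order(cand$pombe_gene, cand$cerevisiae_gene), , drop = FALSE]
    rownames(cand) <- NULL
    list(candidates = cand[, c("pombe_gene", "cerevisiae_gene")],
         true = cand$true, sp = sp_seq, sc = sc_seq)
  })

  # --- mask part of the pombe TLM genes (anchors stay visible: they are
  # the curated knowledge the propagation feature assumes) ---
  maskable <- setdiff(names(lab_sp), ppi$anchors)
  masked <- with_stage_seed(seed, "mask",
    sort(sample(maskable, round(params$mask_fraction * length(lab_sp)))))
  lab_sp_visible <- lab_sp[setdiff(names(lab_sp), masked)]

  # --- raw (graded) label variants ---
  raw_sc <- with_stage_seed(seed, "labels_sc", {
    r <- lapply(lab_sc, raw_variant)
    # a couple of genes observed as both normal and a long variant
    lg <- names(lab_sc)[lab_sc == "long"]
    for (g in head(lg, 2)) r[[g]] <- c("normal", r[[g]])
    r
  })
  raw_sp <- with_stage_seed(seed, "labels_sp",
                            lapply(lab_sp_visible, raw_variant))

  structure(list(
    params = params,
    genes = list(cerevisiae = sc_genes, pombe = sp_genes),
    labels = list(cerevisiae = lab_sc, pombe = lab_sp_visible),
    raw_labels = list(cerevisiae = raw_sc, pombe = raw_sp),
    gi_edges = list(cerevisiae = gi_sc_edges, pombe = gi_sp_edges),
    gi = list(cerevisiae = assemble_gi_edges(gi_sc_edges, "scored", "cerevisiae"),
              pombe = assemble_gi_edges(gi_sp_edges, "binary", "pombe")),
    sets = list(cerevisiae = lapply(sets_sc, `[[`, "collection"),
                pombe = lapply(sets_sp, `[[`, "collection")),
    ppi_edges = ppi$edges,
    ppi = ppi_network(ppi$edges, species = "pombe"),
    anchors = ppi$anchors,
    ortholog_candidates = seqs$candidates,
    sequences = list(pombe = seqs$sp, cerevisiae = seqs$sc),
    ground_truth = list(
      masked_tlm_pombe = masked,
      labels_pombe_full = lab_sp,
      true_orthologs = seqs$candidates[seqs$true, , drop = FALSE],
      set_phenotype = list(
        cerevisiae = lapply(sets_sc, `[[`, "phenotype"),
        pombe = lapply(sets_sp, `[[`, "phenotype")),
      conservation_prob = params$conservation_prob)),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("synthetic_world: %d genes/species; TLM %d (sc) / %d visible",
                     " + %d masked (sp); %d ortholog candidate pairs\n"),
              length(x$genes$cerevisiae), length(x$labels$cerevisiae),
              length(x$labels$pombe), length(x$ground_truth$masked_tlm_pombe),
              nrow(x$ortholog_candidates)))
  invisible(x)
}

write_labels_tsv <- function(raw, path) {
  genes <- rep(names(raw), lengths(raw))
  df <- data.frame(gene = genes, raw_label = unlist(raw, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path,
             useBytes = TRUE)
}

#' Write a synthetic world to standard flat files
#'
#' Emits every pipeline-facing input in its standard exchange format (GI
#' edge TSVs, GMT set collections, raw-label TSVs, PPI edge TSV, anchor
#' list, ortholog candidate TSV, protein FASTAs) plus the ground truth as
#' JSON, and returns a manifest of md5 checksums.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if needed).
#' @return data.frame manifest (`file`, `md5`), invisibly the paths too.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(fn, name) {
    path <- file.path(dir, name)
    fn(path)
    written <<- c(written, path)
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  fmt_gi <- function(df) {
    if ("score" %in% names(df)) {
      df$score <- sprintf("%.6f", df$score)
      df$p_value <- sprintf("%.6f", df$p_value)
    }
    df
  }
  emit(function(p) write.table(fmt_gi(world$gi_edges$cerevisiae), p, sep = "\t",
                               quote = FALSE, row.names = FALSE), "sc_gi.tsv")
  emit(function(p) write.table(world$gi_edges$pombe, p, sep = "\t",
                               quote = FALSE, row.names = FALSE), "sp_gi.tsv")
  for (sp in c("cerevisiae", "pombe")) {
    tag <- if (sp == "cerevisiae") "sc" else "sp"
    for (coll in names(world$sets[[sp]]))
      emit(local({ s <- sp; cl <- coll; function(p)
        write_gene_sets(world$sets[[s]][[cl]], p) }),
        sprintf("%s_%s.gmt", tag, coll))
    emit(local({ s <- sp; function(p)
      write_labels_tsv(world$raw_labels[[s]], p) }),
      sprintf("%s_labels.tsv", tag))
    emit(local({ s <- sp; function(p)
      write_fasta(world$sequences[[s]], p) }),
      sprintf("%s_proteins.fasta", tag))
  }
  emit(function(p) write.table(world$ppi_edges, p, sep = "\t", quote = FALSE,
                               row.names = FALSE), "sp_ppi.tsv")
  emit(function(p) writeLines(world$anchors, p, useBytes = TRUE),
       "sp_anchors.txt")
  emit(function(p) write.table(world$ortholog_candidates, p, sep = "\t",
                               quote = FALSE, row.names = FALSE),
       "ortholog_candidates.tsv")
  emit(function(p) jsonlite::write_json(world$ground_truth, p,
                                        auto_unbox = TRUE, pretty = TRUE),
       "ground_truth.json")
  ok <- TRUE
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)))
  manifest[order(manifest$file), ]
}
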