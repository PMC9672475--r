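# Cross-species mapping, the five discovery-method datasets, leave-one-out
# ranking, gene-set overrepresentation.

test_that("cross-species mapping joins KEGG by pathway id and complexes by unique GO id", {
  kegg_sp <- gene_set_collection(list(PATH001 = c("sp1", "sp2"),
                                      PATH002 = c("sp3", "sp4")),
                                 "KEGG", species = "pombe")
  cx_sp <- gene_set_collection(
    list(CPXa = c("sp1", "sp2"), CPXb = c("sp2", "sp3")), "COMPLEX",
    external_id = c(CPXa = "GO:0000001", CPXb = "GO:0000002"),
    species = "pombe")
  cx_sc <- gene_set_collection(
    list(C1 = c("sc1", "sc2"), C2 = c("sc3", "sc4"), C3 = c("sc5", "sc6")),
    "COMPLEX",
    external_id = c(C1 = "GO:0000001", C2 = NA, C3 = "GO:0000009"))
  feats <- rbind(
    data.frame(id = "KEGG:PATH001", source = "KEGG", set_id = "PATH001",
               family = "gi_proportion"),
    data.frame(id = "KEGG:PATH999", source = "KEGG", set_id = "PATH999",
               family = "gi_proportion"),
    data.frame(id = c("COMPLEX:C1", "COMPLEX:C2", "COMPLEX:C3"),
               source = "COMPLEX", set_id = c("C1", "C2", "C3"),
               family = "membership"))
  expect_message(mp <- map_cross_species_features(feats, kegg_sp, cx_sp, cx_sc),
                 "dropped")
  expect_setequal(mp$sc_id, c("KEGG:PATH001", "COMPLEX:C1"))
  expect_equal(mp$sp_id[mp$sc_id == "COMPLEX:C1"], "COMPLEX:CPXa")
  # C2 has no GO id, C3's GO id is absent from pombe, PATH999 unmatched
  expect_false(any(c("COMPLEX:C2", "COMPLEX:C3", "KEGG:PATH999") %in% mp$sc_id))
  expect_error(map_cross_species_features(feats[2, , drop = FALSE],
                                          kegg_sp, cx_sp, cx_sc),
               "no cross-species features")
})

test_that("duplicated GO ids exclude complexes from the mapping with a warning", {
  kegg_sp <- gene_set_collection(list(PATH001 = "sp1"), "KEGG", species = "pombe")
  cx_sp <- gene_set_collection(list(CPXa = "sp1"), "COMPLEX",
                               external_id = c(CPXa = "GO:0000001"),
                               species = "pombe")
  cx_sc <- gene_set_collection(list(C1 = "sc1", C2 = "sc2"), "COMPLEX",
                               external_id = c(C1 = "GO:0000001",
                                               C2 = "GO:0000001"))
  feats <- data.frame(id = c("COMPLEX:C1", "COMPLEX:C2", "KEGG:PATH001"),
                      source = c("COMPLEX", "COMPLEX", "KEGG"),
                      set_id = c("C1", "C2", "PATH001"),
                      family = c("membership", "membership", "gi_proportion"))
  expect_warning(mp <- map_cross_species_features(feats, kegg_sp, cx_sp, cx_sc),
                 "non-unique GO ids")
  expect_identical(mp$sc_id, "KEGG:PATH001")
})

test_that("the five method datasets satisfy the published width relations", {
  w <- small_world()
  ds3 <- discovery_dataset(w, 3)
  ds4 <- discovery_dataset(w, 4)
  ds5 <- discovery_dataset(w, 5)
  expect_equal(ncol(ds4$X$values), 2 * ncol(ds3$X$values))
  expect_equal(ncol(ds5$X$values), ncol(ds3$X$values) + 1)
  expect_true(all(ds5$X$samples %in% ds3$X$samples))
  expect_identical(ds5$X$features$family[ncol(ds5$X$values)], "propagation")
})

test_that("method 1 transfers the ortholog's TLM status without any fitting", {
  w <- small_world()
  ds1 <- discovery_dataset(w, 1)
  orth <- attr(ds1, "orthologs")
  y_sc <- attr(ds1, "labels_sc_tlm")
  ort <- setNames(orth$cerevisiae_gene, orth$pombe_gene)
  manual <- ifelse(y_sc[ort[ds1$pombe_gene]] == "tlm", "tlm", "non_tlm")
  expect_identical(ds1$predicted, unname(manual))
  # deterministic: same world, same output
  expect_identical(ds1, discovery_dataset(w, 1))
})

test_that("method 2 returns aligned train/test tables in a shared descriptor space", {
  w <- small_world()
  ds2 <- discovery_dataset(w, 2)
  expect_identical(ds2$train$X$features$id, colnames(ds2$test$X$values))
  expect_identical(ds2$train$X$species, "cerevisiae")
  expect_identical(ds2$test$X$species, "pombe")
  expect_false(anyNA(ds2$train$y)); expect_false(anyNA(ds2$test$y))
})

test_that("leave-one-out ranking excludes known TLM genes and is order-invariant", {
  w <- small_world()
  ds <- discovery_dataset(w, 5)
  sub <- ds$X$samples[1:40]
  X <- subset_samples(ds$X, sub); y <- ds$y[sub]
  rk <- loo_rank_candidates(X, y, seed = 2)
  expect_setequal(rk$pombe_gene, sub[y[sub] != "tlm"])
  expect_true(all(diff(rk$probability) <= 0))
  probs <- attr(rk, "all_probabilities")
  expect_length(probs, 40)     # one LOO prediction per gene
  # permuting the input gene order leaves the ranking unchanged
  perm <- sample(sub)
  rk2 <- loo_rank_candidates(subset_samples(ds$X, perm), y[perm], seed = 2)
  expect_equal(rk$probability, rk2$probability, tolerance = 1e-6)
  expect_identical(rk$pombe_gene, rk2$pombe_gene)
})

test_that("planted-but-masked TLM genes rank above true negatives in LOO", {
  w <- small_world()
  ds <- discovery_dataset(w, 5)
  rk <- loo_rank_candidates(ds$X, ds$y, seed = 6)
  masked <- intersect(rk$pombe_gene, w$ground_truth$masked_tlm_pombe)
  negatives <- setdiff(rk$pombe_gene, names(w$ground_truth$labels_pombe_full))
  pm <- rk$probability[match(masked, rk$pombe_gene)]
  pn <- rk$probability[match(negatives, rk$pombe_gene)]
  res <- compare_distributions(pm, pn)
  expect_gt(median(pm), median(pn))
  expect_lt(res$p_value, 0.01)
})

test_that("Fisher enrichment matches hypergeometric tail enumeration", {
  background <- sprintf("g%03d", 1:200)
  terms <- gene_set_collection(
    list(hit = background[1:30], cold = background[101:140],
         broad = background),   # broad exceeds any sensible cap below
    "GO_BP")
  cand <- background[c(1:12, 150:157)]   # 12 of 20 inside "hit"
  res <- enrich_terms(cand, background, terms, max_term_size = 150)
  expect_false("broad" %in% res$term_id)   # size 200 > 150: never tested
  r <- res[res$term_id == "hit", ]
  expect_equal(r$p_value, hyper_tail(12, 20, 30, 200), tolerance = 1e-10)
  expect_true(r$significant)
  r2 <- res[res$term_id == "cold", ]
  expect_equal(r2$p_value, hyper_tail(0, 20, 40, 200), tolerance = 1e-10)
})

test_that("terms above 250 background genes are never tested and BH q-values are monotone", {
  withr::local_seed(14)
  background <- sprintf("b%04d", 1:600)
  sets <- c(list(too_broad = background[1:251], at_cap = background[1:250]),
            lapply(1:8, function(i) sample(background, 25)))
  names(sets)[3:10] <- sprintf("t%d", 1:8)
  terms <- gene_set_collection(sets, "GO_BP")
  cand <- c(background[1:15], sample(background[300:600], 10))
  res <- enrich_terms(cand, background, terms)
  expect_false("too_broad" %in% res$term_id)
  expect_true("at_cap" %in% res$term_id)
  # res is ordered by p; BH q must be non-decreasing in that order
  expect_true(all(diff(res$q_value) >= -1e-12))
  expect_error(enrich_terms(character(0), background, terms), "empty candidate")
  expect_error(enrich_terms("zzz", background, terms), "subset")
})
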