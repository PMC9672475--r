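# One-to-one ortholog resolution by Smith-Waterman local alignment and
# cross-species phenotype-conservation statistics.

#' Alignment parameters
#'
#' BLOSUM62 with affine gaps in the BLAST web-interface convention: a gap of
#' length L costs `gap_open + (L - 1) * gap_extend`, i.e. opening includes
#' the first gapped residue.
#'
#' @param matrix substitution matrix name (only `"BLOSUM62"` is shipped).
#' @param gap_open gap opening cost (default 11).
#' @param gap_extend gap extension cost (default 1).
#' @return list of class `alignment_params`.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (gap_open <= 0 || gap_extend <= 0) stop("gap costs must be positive")
  if (matrix != "BLOSUM62") stop("unsupported substitution matrix: ", matrix)
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Smith-Waterman local alignment score
#'
#' Maximum local-alignment score of two protein sequences under BLOSUM62
#' with affine gap penalties, floored at 0 as in Smith-Waterman.
#'
#' @param a,b protein sequences (character strings, uppercase amino acids).
#' @param params an [alignment_params()].
#' @return the alignment score (numeric scalar, deterministic).
#' @export
sw_local_align <- function(a, b, params = alignment_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  mat <- blosum62()
  for (s in list(a, b)) {
    bad <- setdiff(strsplit(s, "")[[1]], rownames(mat))
    if (length(bad)) stop("residue not in substitution alphabet: ", bad[1])
  }
  # Biostrings charges gapOpening + L * gapExtension for a length-L gap, so
  # gapOpening = gap_open - gap_extend reproduces open-includes-first-residue.
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = mat,
    gapOpening = params$gap_open - params$gap_extend,
    gapExtension = params$gap_extend, scoreOnly = TRUE)
  max(0, s)
}

#' Resolve one-to-one orthologs
#'
#' Pombe genes with a single candidate pass through unchanged. For pombe
#' genes with several cerevisiae candidates, the candidate with the maximal
#' Smith-Waterman alignment score between the two protein sequences is
#' selected; score ties keep the lexicographically smaller systematic name.
#'
#' @param candidates data.frame with columns `pombe_gene`, `cerevisiae_gene`
#'   (from [read_ortholog_candidates()]).
#' @param seqs_pombe,seqs_cerevisiae named character vectors of protein
#'   sequences; required for every gene involved in an ambiguous case.
#' @param params an [alignment_params()].
#' @return data.frame of class `ortholog_table` with columns `pombe_gene`,
#'   `cerevisiae_gene`, `alignment_score` (`NA` for unambiguous pairs) and
#'   `was_ambiguous`.
#' @export
resolve_orthologs <- function(candidates, seqs_pombe = NULL,
                              seqs_cerevisiae = NULL,
                              params = alignment_params()) {
  out <- list()
  for (sp in sort(unique(candidates$pombe_gene))) {
    cand <- sort(unique(candidates$cerevisiae_gene[candidates$pombe_gene == sp]))
    if (length(cand) == 1) {
      out[[sp]] <- data.frame(pombe_gene = sp, cerevisiae_gene = cand,
                              alignment_score = NA_real_, was_ambiguous = FALSE)
    } else {
      if (is.null(seqs_pombe) || !sp %in% names(seqs_pombe))
        stop("missing sequence for ambiguous pombe gene ", sp)
      missing <- setdiff(cand, names(seqs_cerevisiae))
      if (length(missing))
        stop("missing sequence for ambiguous candidate ", missing[1])
      scores <- vapply(cand, function(sc)
        sw_local_align(seqs_pombe[[sp]], seqs_cerevisiae[[sc]], params),
        numeric(1))
      best <- cand[which(scores == max(scores))][1]  # cand sorted -> lexicographic tie-break
      out[[sp]] <- data.frame(pombe_gene = sp, cerevisiae_gene = best,
                              alignment_score = max(scores), was_ambiguous = TRUE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ortholog_table", "data.frame")
  res
}

#' Cross-species phenotype conservation statistics
#'
#' Over resolved ortholog pairs, counts pairs that are TLM genes in both
#' species, in either species, and -- within the both-TLM subset -- pairs
#' whose short/long phenotype is preserved, split by phenotype. Percentages
#' are rounded half-up to `digits` decimals. The accompanying significance
#' check of phenotype preservation is a two-sided binomial test of the match
#' fraction against 0.5, a stand-in convention (no canonical test exists for
#' this contrast) and labelled as such in the output.
#'
#' @param orthologs an [resolve_orthologs()] table (or any data.frame with
#'   `pombe_gene`, `cerevisiae_gene`).
#' @param labels_sp,labels_sc named character `short`/`long` labels for the
#'   TLM genes of pombe and cerevisiae.
#' @param universe_sp,universe_sc optional gene universes; pairs referencing
#'   genes outside them are skipped with a warning.
#' @param digits decimals for reported percentages (default 2).
#' @return list of class `conservation_report` with counts, percentages and
#'   the binomial stand-in p-value.
#' @export
conservation_stats <- function(orthologs, labels_sp, labels_sc,
                               universe_sp = NULL, universe_sc = NULL,
                               digits = 2) {
  if (!is.null(universe_sp) || !is.null(universe_sc)) {
    bad <- (!is.null(universe_sp) & !orthologs$pombe_gene %in% universe_sp) |
           (!is.null(universe_sc) & !orthologs$cerevisiae_gene %in% universe_sc)
    if (any(bad)) {
      warning(sum(bad), " ortholog pair(s) reference unknown genes; skipped")
      orthologs <- orthologs[!bad, , drop = FALSE]
    }
  }
  n <- nrow(orthologs)
  sp_lab <- labels_sp[orthologs$pombe_gene]
  sc_lab <- labels_sc[orthologs$cerevisiae_gene]
  tlm_sp <- !is.na(sp_lab); tlm_sc <- !is.na(sc_lab)
  both <- tlm_sp & tlm_sc
  either <- tlm_sp | tlm_sc
  preserved <- both & sp_lab == sc_lab
  n_short <- sum(preserved & sp_lab == "short", na.rm = TRUE)
  n_long <- sum(preserved & sp_lab == "long", na.rm = TRUE)
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den, digits)
  }
  test <- if (sum(both) > 0)
    stats::binom.test(sum(preserved, na.rm = TRUE), sum(both), p = 0.5)$p.value
  else NA_real_
  structure(list(
    n_orthologs = n,
    n_tlm_both = sum(both),
    n_tlm_either = sum(either),
    n_phenotype_preserved = n_short + n_long,
    n_short_preserved = n_short,
    n_long_preserved = n_long,
    pct_tlm_both = pct(sum(both), n),
    pct_tlm_both_of_either = pct(sum(both), sum(either)),
    pct_phenotype_preserved = pct(n_short + n_long, sum(both)),
    pct_short_preserved = pct(n_short, sum(both)),
    pct_long_preserved = pct(n_long, sum(both)),
    preservation_test = list(method = "two-sided binomial vs 0.5 (stand-in convention)",
                             p_value = test)),
    class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("conservation_report: %d ortholog pairs\n", x$n_orthologs))
  cat(sprintf("  TLM in both species: %d (%s%%); of either-TLM: %s%%\n",
              x$n_tlm_both, x$pct_tlm_both, x$pct_tlm_both_of_either))
  cat(sprintf("  phenotype preserved: %d/%d (%s%%); short %s%%, long %s%%\n",
              x$n_phenotype_preserved, x$n_tlm_both, x$pct_phenotype_preserved,
              x$pct_short_preserved, x$pct_long_preserved))
  if (!is.na(x$preservation_test$p_value))
    cat(sprintf("  preservation vs chance: p = %.3f (%s)\n",
                x$preservation_test$p_value, x$preservation_test$method))
  invisible(x)
}
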