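# Domain containers and flat-file readers shared by all pipeline stages.
# All tabular dialects are tab-separated UTF-8 with a mandatory header line.

#' Sparse genetic-interaction matrix
#'
#' Wraps a sparse gene-by-gene score matrix. Rows are the profiled (sample)
#' genes, columns their interaction partners; the matrix is stored as given
#' (directed query/array pairs), never symmetrized.
#'
#' @param scores a [Matrix::sparseMatrix()] with row/column names.
#' @param value_kind `"scored"` (real SGA-style scores) or `"binary"` (0/1).
#' @param species `"cerevisiae"` or `"pombe"`.
#' @return an object of class `gi_matrix`.
#' @export
gi_matrix <- function(scores, value_kind = c("scored", "binary"),
                      species = "cerevisiae") {
  value_kind <- match.arg(value_kind)
  check_species(species)
  scores <- methods::as(scores, "CsparseMatrix")
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("gi_matrix requires row and column names")
  if (anyDuplicated(rownames(scores)) || anyDuplicated(colnames(scores)))
    stop("duplicate gene names in gi_matrix")
  v <- scores@x
  if (any(!is.finite(v))) stop("gi_matrix scores must be finite")
  if (value_kind == "binary" && !all(v %in% c(0, 1)))
    stop("binary gi_matrix may only contain 0/1 scores")
  structure(list(scores = scores, value_kind = value_kind, species = species),
            class = "gi_matrix")
}

#' @export
print.gi_matrix <- function(x, ...) {
  cat(sprintf("gi_matrix [%s, %s]: %d x %d genes, %d stored interactions\n",
              x$species, x$value_kind, nrow(x$scores), ncol(x$scores),
              Matrix::nnzero(x$scores)))
  invisible(x)
}

#' Named gene-set collection
#'
#' @param sets named list of character vectors (unique members, non-empty).
#' @param source one of `"KEGG"`, `"GO_BP"`, `"GO_CC"`, `"COMPLEX"`.
#' @param descriptions optional named character of set descriptions.
#' @param external_id optional named character of external accessions
#'   (e.g. GO ids for complexes); `NA` where absent.
#' @param species species tag.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = c("KEGG", "GO_BP", "GO_CC", "COMPLEX"),
                                descriptions = NULL, external_id = NULL,
                                species = "cerevisiae") {
  source <- match.arg(source)
  check_species(species)
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  for (id in names(sets)) {
    if (length(sets[[id]]) == 0) stop("empty gene set: ", id)
    if (anyDuplicated(sets[[id]])) stop("duplicate members in set: ", id)
  }
  if (is.null(descriptions)) descriptions <- setNames(names(sets), names(sets))
  if (is.null(external_id)) external_id <- setNames(rep(NA_character_, length(sets)), names(sets))
  structure(list(source = source, sets = sets,
                 descriptions = descriptions[names(sets)],
                 external_id = external_id[names(sets)],
                 species = species),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection [%s, %s]: %d sets, sizes %d-%d\n",
              x$species, x$source, length(x$sets),
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

read_tsv_checked <- function(path, required) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", check.names = FALSE,
                   blank.lines.skip = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  df
}

as_numeric_col <- function(x, col, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop(sprintf("%s: non-numeric %s at line %d (value '%s')",
                 path, col, bad[1] + 1L, x[bad[1]]))
  v
}

#' Read genetic-interaction edges
#'
#' Assembles a [gi_matrix()] from a tab-separated edge list. For the
#' `"scored"` dialect (SGA-style) the columns are
#' `gene_a`, `gene_b`, `score`, `p_value`; only edges with
#' `p_value < 0.05` (the lenient significance threshold) are kept, and among
#' repeated measurements of a pair the row with the smallest p-value wins.
#' Ties on p-value keep the row with the larger absolute score, remaining
#' ties the first row in file order. The `"binary"` dialect (BioGRID-style)
#' has columns `gene_a`, `gene_b` and stores 1 for every listed pair.
#'
#' @param path TSV file path.
#' @param dialect `"scored"` or `"binary"`.
#' @param species species tag attached to the matrix.
#' @param p_threshold significance cutoff for the scored dialect.
#' @return a [gi_matrix()] whose rows are the distinct `gene_a` values.
#' @export
read_gi_edges <- function(path, dialect = c("scored", "binary"),
                          species = "cerevisiae", p_threshold = 0.05) {
  dialect <- match.arg(dialect)
  if (dialect == "scored") {
    df <- read_tsv_checked(path, c("gene_a", "gene_b", "score", "p_value"))
    bad <- which(df$gene_a == "" | df$gene_b == "")
    if (length(bad)) stop(sprintf("%s: malformed row at line %d", path, bad[1] + 1L))
    df$score <- as_numeric_col(df$score, "score", path)
    df$p_value <- as_numeric_col(df$p_value, "p_value", path)
  } else {
    df <- read_tsv_checked(path, c("gene_a", "gene_b"))
    bad <- which(df$gene_a == "" | df$gene_b == "")
    if (length(bad)) stop(sprintf("%s: malformed row at line %d", path, bad[1] + 1L))
  }
  assemble_gi_edges(df, dialect = dialect, species = species,
                    p_threshold = p_threshold)
}

#' Assemble a GI matrix from an in-memory edge table
#'
#' The assembly step of [read_gi_edges()] (significance filtering, lowest-p
#' deduplication, sparse-matrix construction), usable on a data.frame.
#'
#' @inheritParams read_gi_edges
#' @param edges data.frame of edges (see [read_gi_edges()] for columns).
#' @return a [gi_matrix()].
#' @export
assemble_gi_edges <- function(edges, dialect = c("scored", "binary"),
                              species = "cerevisiae", p_threshold = 0.05) {
  dialect <- match.arg(dialect)
  df <- edges
  if (dialect == "scored") {
    df$.ord <- seq_len(nrow(df))
    df <- df[df$p_value < p_threshold, , drop = FALSE]
    # lowest-p selection per (gene_a, gene_b); ties -> larger |score|, then file order
    o <- order(df$gene_a, df$gene_b, df$p_value, -abs(df$score), df$.ord)
    df <- df[o, , drop = FALSE]
    df <- df[!duplicated(df[, c("gene_a", "gene_b")]), , drop = FALSE]
    value <- df$score
    kind <- "scored"
  } else {
    df <- df[!duplicated(df[, c("gene_a", "gene_b")]), , drop = FALSE]
    value <- rep(1, nrow(df))
    kind <- "binary"
  }
  rows <- sort(unique(df$gene_a))
  cols <- sort(unique(df$gene_b))
  m <- Matrix::sparseMatrix(
    i = match(df$gene_a, rows), j = match(df$gene_b, cols), x = value,
    dims = c(length(rows), length(cols)), dimnames = list(rows, cols))
  gi_matrix(m, value_kind = kind, species = species)
}

RAW_PHENOTYPES <- c("very short", "short", "slightly short", "slightly long",
                    "long", "very long", "DAmP Short", "DAmP Long", "normal")
SHORT_VARIANTS <- c("very short", "short", "slightly short", "DAmP Short")
LONG_VARIANTS  <- c("slightly long", "long", "very long", "DAmP Long")

#' Reduce raw telomere-length categories to binary phenotypes
#'
#' Collapses graded knockout phenotypes (`very short` ... `very long`,
#' including the hypomorphic `DAmP Short`/`DAmP Long` alleles) to the binary
#' `short`/`long` labels used for classification. A gene observed as both
#' `normal` and a long variant is assigned `long`; genes observed only as
#' `normal` are excluded. A gene carrying both a short and a long variant is
#' a curation conflict and raises an error.
#'
#' @param raw named list of character vectors of raw categories, or a
#'   data.frame with columns `gene` and `raw_label`.
#' @return named character vector of reduced labels (`"short"`/`"long"`),
#'   with the raw categories kept in attribute `raw_labels`.
#' @export
reduce_phenotypes <- function(raw) {
  if (is.data.frame(raw)) raw <- split(raw$raw_label, raw$gene)
  out <- character(0)
  for (g in names(raw)) {
    cats <- unique(raw[[g]])
    bad <- setdiff(cats, RAW_PHENOTYPES)
    if (length(bad))
      stop(sprintf("gene %s: unknown phenotype category '%s'", g, bad[1]))
    is_short <- any(cats %in% SHORT_VARIANTS)
    is_long <- any(cats %in% LONG_VARIANTS)
    if (is_short && is_long)
      stop(sprintf("gene %s: conflicting short and long phenotypes", g))
    if (is_short) out[g] <- "short"
    else if (is_long) out[g] <- "long"   # includes the normal + long case
    # normal-only genes are excluded from the binary task
  }
  structure(out, raw_labels = raw[names(out)])
}

#' Read a phenotype label table
#'
#' TSV with columns `gene`, `raw_label`; a gene may appear on several rows
#' (one per observed category).
#'
#' @param path TSV path.
#' @param reduce if `TRUE` (default) apply [reduce_phenotypes()].
#' @return reduced labels (named character) or the raw data.frame.
#' @export
read_labels <- function(path, reduce = TRUE) {
  df <- read_tsv_checked(path, c("gene", "raw_label"))
  if (reduce) reduce_phenotypes(df) else df
}

#' Read gene sets in GMT format
#'
#' Standard GMT: `set_id <tab> description <tab> member1 <tab> member2 ...`.
#' Duplicate members within a line are deduplicated with a warning. A
#' description matching a GO accession (`GO:NNNNNNN`) is also recorded as the
#' set's external id.
#'
#' @param path GMT file path.
#' @param source collection source tag.
#' @param species species tag.
#' @return a [gene_set_collection()], sets in file order.
#' @export
read_gene_sets <- function(path, source = "KEGG", species = "cerevisiae") {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0); ext <- character(0)
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("%s: line %d: empty member list for set '%s'", path, k, f[1]))
    id <- f[1]
    if (id %in% names(sets)) stop(sprintf("%s: duplicate set_id '%s'", path, id))
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("%s: line %d: empty member list for set '%s'", path, k, id))
    if (anyDuplicated(members)) {
      warning(sprintf("%s: set '%s': duplicate members deduplicated", path, id))
      members <- unique(members)
    }
    sets[[id]] <- members
    desc[id] <- f[2]
    ext[id] <- if (grepl("^GO:\\d+$", f[2])) f[2] else NA_character_
  }
  gene_set_collection(sets, source = source, descriptions = desc,
                      external_id = ext, species = species)
}

#' Write gene sets in GMT format
#'
#' Inverse of [read_gene_sets()]; round-trips byte-identically.
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    d <- collection$descriptions[[id]]
    e <- collection$external_id[[id]]
    if (!is.na(e)) d <- e
    paste(c(id, d, collection$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an anchor-gene list
#'
#' Plain text, one systematic name per line; blank lines skipped.
#'
#' @param path file path.
#' @return character vector of gene names.
#' @export
read_anchor_genes <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8"))
  unique(x[nzchar(x)])
}

#' Read ortholog candidate pairs
#'
#' TSV with columns `pombe_gene`, `cerevisiae_gene`. A pombe gene listed on
#' several rows has multiple candidates, retained for later resolution.
#'
#' @param path TSV path.
#' @return data.frame with columns `pombe_gene`, `cerevisiae_gene`.
#' @export
read_ortholog_candidates <- function(path) {
  df <- read_tsv_checked(path, c("pombe_gene", "cerevisiae_gene"))
  bad <- which(df$pombe_gene == "" | df$cerevisiae_gene == "")
  if (length(bad)) stop(sprintf("%s: malformed row at line %d", path, bad[1] + 1L))
  df[, c("pombe_gene", "cerevisiae_gene")]
}

AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Read protein sequences from FASTA
#'
#' Residues must be uppercase letters of the 20-residue amino-acid alphabet
#' (plus `X`); an illegal residue raises an error naming the record.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta_proteins <- function(path) {
  # parsed as raw strings first so residue validation can name the record
  aa <- Biostrings::readBStringSet(path)
  seqs <- setNames(as.character(aa), names(aa))
  for (nm in names(seqs)) {
    if (!nzchar(seqs[[nm]])) stop("empty sequence for record ", nm)
    res <- strsplit(seqs[[nm]], "")[[1]]
    bad <- setdiff(res, AA_ALPHABET)
    if (length(bad))
      stop(sprintf("record %s: illegal residue '%s'", nm, bad[1]))
  }
  seqs
}

#' Derive TLM/non-TLM discovery labels
#'
#' For the gene-discovery task every gene with a binary telomere phenotype is
#' `tlm`, every other gene of the universe `non_tlm`.
#'
#' @param reduced named character of `short`/`long` labels.
#' @param universe character vector of all genes under consideration.
#' @return named character of `"tlm"`/`"non_tlm"` over `universe`.
#' @export
tlm_labels <- function(reduced, universe) {
  setNames(ifelse(universe %in% names(reduced), "tlm", "non_tlm"), universe)
}
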