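---
title: "Classifying and discovering telomere length maintenance genes in yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and discovering telomere length maintenance genes in yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlmnet)
```

## The problem

Telomere length is under tight genetic control: in budding yeast
(*Saccharomyces cerevisiae*) systematic knockout screens identified roughly
500 telomere length maintenance (TLM) genes whose deletion or hypomorphic
perturbation shifts steady-state telomere length towards "short" or "long".
In fission yeast (*Schizosaccharomyces pombe*) the corresponding network is
much less completely mapped. `tlmnet` implements an interpretable
machine-learning pipeline for two tasks on this kind of data:

1. **Phenotype classification** — given a TLM gene, predict whether its
   knockout phenotype is *short* or *long*, from functional-genomics
   features.
2. **Gene discovery** — rank genes of a species by their probability of
   being TLM genes at all, transferring signal across species through
   orthology and network propagation.

The package consumes local flat files in standard exchange formats (TSV edge
lists, GMT gene sets, FASTA proteins) and ships a synthetic-world generator
with planted ground truth so the whole pipeline is exercised end to end
without any external downloads.

## Inputs and label curation

Telomere phenotypes arrive as graded categories (`very short`, `short`,
`slightly short`, `slightly long`, `long`, `very long`, plus the hypomorphic
`DAmP Short`/`DAmP Long` alleles and `normal`). `reduce_phenotypes()`
collapses every short variant to `short` and every long variant to `long`;
a gene observed as both `normal` and a long variant is assigned `long`,
genes observed only as `normal` are excluded from the binary task, and a
gene carrying both a short and a long variant is surfaced as an error rather
than silently reconciled — curation conflicts are the curator's call, not
the reader's.

Genetic-interaction (GI) evidence comes in two dialects. Scored edges
(SGA-style, with a score and a p-value per measurement) are filtered at the
lenient `p < 0.05` threshold; when a pair was measured repeatedly, the
measurement with the smallest p-value is kept. The p-value-tie rule (larger
absolute score, then file order) is our own determinism choice; the upstream
convention is unstated. Binary edges (curated interaction databases) store 1
for every listed pair. Matrices are kept directed as given — SGA
query/array designs are asymmetric — and row genes act as samples.

## Feature families

Three feature families feed the classifiers:

* **GI proportion** (pathways, GO biological-process terms): for gene $g$
  and gene set $S$, the fraction of $S$ with a non-zero GI score with $g$,
  $x_{gS} = |\{h \in S : \mathrm{score}(g,h) \neq 0\}| / |S|$. The
  denominator is the background-restricted set size, reading "proportion of
  the group" as fraction-of-the-group; the alternative normalization by the
  gene's partner count is a documented open choice we did not take.
* **Complex membership** (complex catalogs, GO cellular-component terms):
  binary indicators $x_{gC} = \mathbb{1}[g \in C]$. For the phenotype task
  the samples are restricted to genes in at least one complex (which is why
  complex feature tables cover fewer genes); for the genome-wide discovery
  task the indicators are zero-filled over the whole universe instead, since
  restricting would silently discard most of the candidate space.
* **Anchor proximity** (discovery task, method 5): a random walk with
  restart on the PPI network from a curated set of anchor genes (endpoints
  of TLM-related processes). With column-normalized adjacency
  $W = AD^{-1}$ and restart vector $p_0$ uniform over the $|G|$ anchors,
  the walk iterates $p_k = 0.2\,p_0 + 0.8\,W p_{k-1}$ to convergence
  (L1 change below $10^{-8}$; our choice — only "until convergence" is
  prescribed). The map is a contraction with ratio 0.8, so convergence is
  guaranteed; columns of isolated nodes stay zero, so total mass can leak
  below 1 on fragmented graphs (we deliberately do not add self-loops,
  keeping $W = AD^{-1}$ exactly).

GO term sets are intersected with the background of genes that have GI data
and only terms with 3–30 background members are kept; pathway and complex
catalogs are used as curated. Feature tables merge on the intersection of
their sample sets, concatenating columns.

## Models and evaluation protocol

Six classifiers are registered with fixed hyperparameters chosen prior to
all experiments: gradient boosting (500 rounds, depth 3, learning rate 0.1,
logloss), random forest (500 trees, `mtry` = 0.25 p), extremely randomized
trees (1000 trees, `mtry` = log2 p), a polynomial-kernel SVC (C = 0.01,
gamma = 0.1, degree 3, coef0 = 10), a linear SVC, and cross-validated ridge
logistic regression (LRCV). The training algorithms come from established
backends (`xgboost`, `randomForest`, `ranger`, `e1071`, `glmnet`); the
package's contribution is the protocol around them. Two mappings are worth
noting: neither R forest backend exposes an entropy split criterion, so both
forests split on Gini; and the boosting "log2 feature subsampling" is
expressed as a per-tree column subsample of log2(p)/p.

Evaluation is 5-repeat stratified 10-fold cross-validation. Inside every
fold the pipeline is fitted on training rows only: per-feature
standardization, then — whenever there are more features than training
samples — Bernoulli naive-Bayes feature selection down to the number of
training samples. Importance is the add-one-smoothed log probability of
observing the (binarized) feature in the positive class; values are
binarized at zero after standardization, i.e. "above the training average",
our explicit choice where the Bernoulli model leaves the threshold implicit.
Selection is refit inside every training fold, never on held-out rows.

Per fold we record the Matthews correlation coefficient

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
 {\sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}}$$

(zero by convention when a denominator factor vanishes — the statistic is
undefined there) and the ROC AUC in its rank formulation (ties count one
half). The reported statistic is the median across all 50 runs, pooling
folds and repeats jointly. Feature-set score distributions are compared by
the two-sided Mann-Whitney U test with normal approximation, tie correction
and continuity correction. Model interpretation uses the mean absolute LRCV
coefficients across runs (restricted to features selected in every run) and
permutation importance (baseline held-out accuracy minus mean accuracy over
5 shuffles of a column).

## Orthology and conservation

Fission-to-budding ortholog candidates may be many-to-one; ambiguous cases
are resolved by the maximal Smith-Waterman local alignment score under
BLOSUM62 with affine gaps costing $11 + (L-1)\cdot 1$ for a length-$L$ gap
(the BLAST web-interface convention; opening includes the first gapped
residue). Score ties keep the lexicographically smaller systematic name so
resolution is deterministic and order-stable. `conservation_stats()` then
counts, over resolved pairs, genes that are TLM in both species, in either
species, and — within the shared TLM set — pairs preserving the short/long
phenotype, split by phenotype. The accompanying significance check is a
two-sided binomial test of the match fraction against 0.5; no canonical
test exists for this contrast, and the output labels it a stand-in.
Percentages are rounded half-up.

## The five discovery methods

For TLM/non-TLM discovery over the ortholog universe:

1. label transfer from the cerevisiae ortholog (no model);
2. train on cerevisiae, predict on pombe, through a cross-species feature
   mapping (pathways joined on their shared naming convention, complexes on
   unique GO accessions);
3. pombe features and labels only;
4. method 3 plus the ortholog's cerevisiae feature block (zero-imputed for
   genes without an ortholog), exactly doubling the width — an optional
   has-ortholog flag column exists but is off by default to preserve that
   arithmetic;
5. method 3 plus the anchor-proximity feature (width + 1, samples
   restricted to network-covered genes).

Candidate ranking runs the balanced-class-weight LRCV model in a
leave-one-out setting: every gene is predicted by a model trained on all
others, so the full dataset serves as training data while predictions stay
held-out. Genes already labeled TLM are excluded from the output ranking.
Candidate sets are tested for gene-set overrepresentation with one-sided
Fisher's exact tests over terms of at most 250 background members,
Benjamini-Hochberg corrected at q < 0.05.

## The synthetic world

`generate_world()` plants a complete two-species study: TLM genes (default
25% of 400 genes per species) with short/long phenotypes (short-majority in
cerevisiae at P(short|TLM) = 0.6, long-majority in pombe at 0.25, mirroring
the species' inverted class balances); pathway/complex/GO catalogs where a
subset of sets is phenotype-associated; GI edges hitting members of a TLM
gene's associated sets with probability 0.6 against a 0.02 background
(scored edges get sub-threshold noise rows and duplicate re-measurements so
the assembly rules are actually exercised); complexes drawn 85% from TLM
genes of one phenotype; a PPI graph (density 0.02) in which TLM genes
preferentially attach to anchors; orthologs covering 80% of genes with TLM
status transferring at 0.6 and phenotype conserving at 0.6; and protein
pairs mutated from a common ancestor (5% per residue for true partners, 30%
for decoy candidates, so alignment-based resolution has a knowable right
answer). A fifth of pombe TLM genes are masked — emitted as unlabeled —
and recorded in the ground truth, giving the discovery task a recoverable
target. Every stage draws from an RNG stream keyed by (seed, stage), so the
same seed reproduces byte-identical files and adding a stage never perturbs
earlier ones.

What the generator does *not* emulate: real SGA score magnitudes and their
correlation structure, realistic proteome length/composition statistics,
scale-free PPI topology, or GO term nesting. Passing tests therefore
demonstrate that the machinery recovers planted structure of the assumed
form at realistic sizes — not that the biological effect sizes of real
screens are reproduced; the published headline performance numbers depend
on the real curated datasets and are out of desk-scale reach.

## Numerical choices and degenerate inputs

* Constant features standardize to zero (sd below 1e-12 treated as
  constant); MCC returns 0 on zero denominators; AUC refuses single-class
  inputs.
* Stratified folding requires at least `folds` members per class and
  errors otherwise; per-repeat seeds are `seed + repeat`, per-fit seeds
  `seed + 1000*repeat + fold`.
* Leave-one-out ranking canonicalizes gene order before fitting, making the
  output invariant to input order; probability ties rank lexicographically.
* Smith-Waterman scores are floored at zero; sequences are validated
  against the 20-letter alphabet plus `X` before alignment.
* Problem sizes used in the shipped checks: worlds of 120 genes for unit
  tests and the default 400-gene regime for the end-to-end protocol runs,
  with 5x10 cross-validation and full leave-one-out ranking over the
  ortholog universe.

## Known limitations

* The pipeline consumes flat local files only; there are no API clients,
  GO-DAG reasoning, or database version resolution.
* Enrichment is flat and one-sided; parent-term propagation is out of
  scope.
* The SVC models expose sigmoid-mapped decision values rather than
  calibrated probabilities; threshold-based metrics at 0.5 coincide with
  the decision boundary but the scores should not be read as probabilities.
* Method 2 (cross-species transfer) evaluates under the same CV protocol
  as the within-species methods; how to weight its inverted class balance
  is left to the caller.

## A minimal run

```{r example, eval = FALSE}
world <- generate_world(world_params(seed = 1))

# task 1: short vs long among TLM genes
ds <- phenotype_dataset(world, "cerevisiae")
cv <- repeated_stratified_cv(ds$X, ds$y, model_spec("LRCV"),
                             repeats = 5, folds = 10, seed = 1)
aggregate_records(cv$records, by = "metric", stat = "median")

# task 2: rank unknown pombe genes by TLM probability
dsd <- discovery_dataset(world, 5)
ranking <- loo_rank_candidates(dsd$X, dsd$y, seed = 1,
                               orthologs = attr(dsd, "orthologs"),
                               labels_sc_tlm = attr(dsd, "labels_sc_tlm"))
head(ranking, 10)
```
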