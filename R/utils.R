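#' @importFrom stats median sd rnorm runif rbinom quantile setNames aggregate
#' @importFrom utils head read.delim write.table
NULL

SPECIES <- c("cerevisiae", "pombe")

check_species <- function(species) {
  if (length(species) != 1L || !species %in% SPECIES) {
    stop("unknown species tag: ", paste(species, collapse = ", "),
         " (expected one of: ", paste(SPECIES, collapse = ", "), ")",
         call. = FALSE)
  }
  species
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going up (half-up), unlike base
#' [round()]'s round-half-even. Used for reported percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Stage-keyed seeding: one master seed, deterministic per-stage offsets so
# adding a stage never perturbs earlier stages' draws. Offsets kept small so
# seed + offset stays well below .Machine$integer.max for any sane seed.
stage_seed <- function(seed, stage) {
  offsets <- c(genes = 11, labels_sc = 23, orthologs = 37, labels_sp = 41,
               sets_sc = 53, sets_sp = 67, gi_sc = 79, gi_sp = 97,
               ppi = 113, sequences = 131, mask = 151, cv = 173,
               model = 197, perm = 211)
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown RNG stage: ", stage)
  as.integer((seed %% 2000000L) * 1000L + off)
}

with_stage_seed <- function(seed, stage, code) {
  withr::with_seed(stage_seed(seed, stage), code)
}
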