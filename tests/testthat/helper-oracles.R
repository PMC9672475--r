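# Independent oracles used to check pipeline operations. Each is written
# from first principles (enumeration, closed forms, direct counting), never
# reusing the code paths under test.

# Reference BLOSUM62 matrix for alignment oracles.
b62 <- local({
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Exhaustive local alignment: enumerate every alignment path (match or gap
# operations, affine costs with open-includes-first-residue) over every pair
# of substrings; Smith-Waterman score is the best, floored at 0.
brute_force_sw <- function(a, b, mat, open = 11, extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  enum <- function(ai, aj, bi, bj, prev) {
    # best score aligning av[ai..aj] fully against bv[bi..bj]
    a_done <- ai > aj; b_done <- bi > bj
    if (a_done && b_done) return(0)
    best <- -Inf
    if (!a_done && !b_done)
      best <- max(best, mat[av[ai], bv[bi]] + enum(ai + 1, aj, bi + 1, bj, "m"))
    if (!a_done)  # gap in b consumes a residue of a
      best <- max(best, -(if (prev == "ga") extend else open) +
                    enum(ai + 1, aj, bi, bj, "ga"))
    if (!b_done)
      best <- max(best, -(if (prev == "gb") extend else open) +
                    enum(ai, aj, bi + 1, bj, "gb"))
    best
  }
  best <- 0
  for (i1 in seq_along(av)) for (i2 in i1:length(av))
    for (j1 in seq_along(bv)) for (j2 in j1:length(bv))
      best <- max(best, enum(i1, i2, j1, j2, "m"))
  best
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments of the
# observed pooled values (valid for small samples).
exact_mw <- function(x, y) {
  pooled <- c(x, y); n <- length(x); m <- length(y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, u_of)
  u_obs <- u_of(seq_len(n))
  dev <- abs(us - n * m / 2)
  list(U = u_obs, p = mean(dev >= abs(u_obs - n * m / 2) - 1e-12))
}

# Upper hypergeometric tail by direct summation of binomial coefficients.
hyper_tail <- function(a, n_cand, K, N) {
  ks <- a:min(K, n_cand)
  sum(choose(K, ks) * choose(N - K, n_cand - ks)) / choose(N, n_cand)
}

# Closed-form random walk with restart stationary vector.
rwr_closed_form <- function(W, p0, alpha = 0.2) {
  as.numeric(solve(diag(nrow(W)) - (1 - alpha) * as.matrix(W),
                   alpha * p0))
}

# Pairwise-comparison AUC: probability a random positive outranks a random
# negative, ties counted one half.
pairwise_auc <- function(scores, y01) {
  pos <- scores[y01 == 1]; neg <- scores[y01 == 0]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}
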