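# Random walk with restart on a protein-protein interaction network.
# Produces the anchor-proximity feature: how close each gene sits to a
# curated set of anchor genes (endpoints of telomere-maintenance processes).

#' Build a PPI network from an edge list
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` (binary,
#'   undirected edges); or a path to such a TSV.
#' @param species species tag.
#' @return object of class `ppi_network` with a symmetric binary adjacency.
#' @export
ppi_network <- function(edges, species = "pombe") {
  check_species(species)
  if (is.character(edges)) edges <- read_tsv_checked(edges, c("gene_a", "gene_b"))
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  i <- match(edges$gene_a, nodes); j <- match(edges$gene_b, nodes)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(length(nodes), length(nodes)),
                            dimnames = list(nodes, nodes))
  A@x[A@x > 0] <- 1              # collapse duplicate listings
  A <- Matrix::drop0(A)
  structure(list(nodes = nodes, A = A,
                 degree = Matrix::rowSums(A), species = species),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network [%s]: %d nodes, %d edges\n", x$species,
              length(x$nodes), Matrix::nnzero(x$A) / 2))
  invisible(x)
}

#' Column-normalize an adjacency matrix
#'
#' Computes W = A D^-1 where D is the diagonal degree matrix: column v of W
#' is column v of A divided by deg(v). Columns of isolated (zero-degree)
#' nodes stay all-zero, so walk mass entering them leaks; no self-loop
#' augmentation is applied.
#'
#' @param net a [ppi_network()].
#' @return sparse column-stochastic (up to isolated nodes) matrix W.
#' @export
normalize_adjacency <- function(net) {
  if (any(net$A@x < 0)) stop("adjacency must be non-negative")
  d <- Matrix::colSums(net$A)
  inv <- ifelse(d > 0, 1 / d, 0)
  W <- net$A %*% Matrix::Diagonal(x = inv)
  dimnames(W) <- dimnames(net$A)
  W
}

#' Random walk with restart
#'
#' Iterates `p_k = alpha * p_0 + (1 - alpha) * W p_{k-1}` with restart
#' probability `alpha = 0.2`, starting from `p_0` uniform over the anchor
#' genes (`1/|G|` each, zero elsewhere), until the L1 change between
#' iterates drops below `tol`. With `alpha` in (0,1) the map is a
#' contraction of ratio `1 - alpha`, so convergence is guaranteed; on a
#' graph without isolated nodes the total mass stays exactly 1.
#'
#' @param W column-normalized adjacency from [normalize_adjacency()].
#' @param anchors character vector of anchor genes (must be nodes).
#' @param alpha restart probability (default 0.2).
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @return object of class `propagation_result`: list with `p` (named
#'   stationary vector), `iterations`, `residual`, `anchors`, `alpha`.
#' @export
rwr_propagate <- function(W, anchors, alpha = 0.2, tol = 1e-8, max_iter = 10000) {
  nodes <- rownames(W)
  if (length(anchors) == 0) stop("anchor set must be non-empty")
  missing <- setdiff(anchors, nodes)
  if (length(missing))
    stop("anchors unknown to the network: ", paste(missing, collapse = ", "))
  p0 <- setNames(numeric(length(nodes)), nodes)
  p0[anchors] <- 1 / length(anchors)
  p <- p0
  for (it in seq_len(max_iter)) {
    pn <- alpha * p0 + (1 - alpha) * as.numeric(W %*% p)
    res <- sum(abs(pn - p))
    p <- setNames(pn, nodes)
    if (res < tol)
      return(structure(list(p = p, iterations = it, residual = res,
                            anchors = anchors, alpha = alpha),
                       class = "propagation_result"))
  }
  stop(sprintf("random walk did not converge in %d iterations (residual %.3g)",
               max_iter, res))
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf("propagation_result: %d nodes, %d anchors, alpha=%.2f, %d iterations (L1 residual %.2g)\n",
              length(x$p), length(x$anchors), x$alpha, x$iterations, x$residual))
  invisible(x)
}
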