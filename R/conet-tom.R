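#' Topological overlap matrix
#'
#' The TOM similarity of proteins i and j combines their direct adjacency
#' with the adjacency they share through common neighbours:
#'
#' \deqn{TOM_{ij} = \frac{\ell_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}, \quad
#'       \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}}
#'
#' using off-diagonal adjacencies only; `TOM_ii = 1`.  `1 - TOM` is the
#' clustering distance.
#'
#' @param adjacency Symmetric adjacency matrix in `[0, 1]`.
#' @return List with `tom` (similarity) and `dist` (`1 - tom`, zero
#'   diagonal), both symmetric.
#' @export
topological_overlap <- function(adjacency) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (max(abs(adjacency - t(adjacency))) > 1e-12) {
    abort("adjacency must be symmetric", class = "coabund_value_error")
  }
  a <- adjacency
  diag(a) <- 0
  if (any(a < 0) || any(a > 1)) {
    abort("adjacency entries must lie in [0, 1]", class = "coabund_value_error")
  }
  l <- a %*% a                     # l_ij = sum_u a_iu a_uj (u != i, j handled below)
  k <- rowSums(a)
  # a %*% a includes u = i and u = j terms only through a_ii = a_jj = 0, so l is exact
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2        # symmetrize round-off
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  list(tom = tom, dist = {
    d <- 1 - tom
    diag(d) <- 0
    d
  })
}

#' Average-linkage dendrogram of the TOM distance
#'
#' Hierarchical clustering (UPGMA) of proteins by `1 - TOM`.  `stats::hclust`
#' is deterministic for tied merges (lowest-index pair first), so repeated
#' runs give identical trees.
#'
#' @param tom_distance Symmetric distance matrix with zero diagonal.
#' @return An `hclust` object (UPGMA merge tree, heights non-decreasing).
#' @export
cluster_tree <- function(tom_distance) {
  stopifnot(is.matrix(tom_distance))
  if (any(!is.finite(tom_distance))) {
    abort("distance matrix contains non-finite values",
          class = "coabund_value_error")
  }
  if (max(abs(diag(tom_distance))) > 1e-12) {
    abort("distance matrix must have a zero diagonal",
          class = "coabund_value_error")
  }
  stats::hclust(stats::as.dist(tom_distance), method = "average")
}

#' Export a dendrogram as Newick text
#'
#' @param tree An `hclust` object with labels.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the 'ape' package is required for Newick export")
  }
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
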