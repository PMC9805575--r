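#' Louvain clustering of cells from a factor matrix
#'
#' Builds an exact k-nearest-neighbor graph on the rows of a cell-by-factor
#' matrix (Euclidean distance, each cell among its own neighbors), weights
#' edges by the Jaccard similarity of the two cells' neighbor sets
#' (shared-nearest-neighbor weighting, pruned below `prune`), and partitions
#' the graph by Louvain modularity optimization. When `target_k` is given,
#' the modularity resolution is searched by bisection on `[0.01, 10]` until
#' the partition has `target_k` communities; if the target is unreachable in
#' `max_steps` bisection steps the closest achievable partition is returned
#' with a warning.
#'
#' @param x Cell-by-factor matrix (e.g. [coef.awmv()]), or an `awmv` fit.
#' @param target_k Requested number of clusters, or `NULL` to cluster at
#'   `resolution` directly.
#' @param knn_k Neighbors per cell. Default 20.
#' @param resolution Modularity resolution used when `target_k` is `NULL`.
#' @param prune Drop shared-neighbor edges with Jaccard weight below this.
#'   Default 1/15.
#' @param l2_normalize Scale each row to unit Euclidean norm before
#'   computing distances. Default `FALSE` (raw rows).
#' @param max_steps Bisection step cap. Default 40.
#' @param seed Integer seed (Louvain is randomized).
#' @return A `cluster_assignment`: list with `labels` (0-based, per cell,
#'   no empty cluster), `n_clusters`, `resolution` and `knn_k`.
#' @export
louvain_cluster <- function(x, target_k = NULL, knn_k = 20, resolution = 1,
                            prune = 1 / 15, l2_normalize = FALSE,
                            max_steps = 40, seed = 1L) {
  if (inherits(x, "awmv")) x <- stats::coef(x)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < knn_k + 1)
    stop("need at least knn_k + 1 = ", knn_k + 1, " cells, got ", n)
  if (!is.null(target_k) && target_k > n)
    stop("target_k (", target_k, ") exceeds the number of cells (", n, ")")
  if (l2_normalize) {
    nrm <- sqrt(rowSums(x^2))
    x <- x / pmax(nrm, 1e-12)
  }

  d <- as.matrix(stats::dist(x))
  nb <- t(apply(d, 1, function(r) order(r)[seq_len(knn_k)]))
  M <- Matrix::sparseMatrix(i = rep(seq_len(n), knn_k), j = as.vector(nb),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(M)
  jac <- shared
  jac@x <- jac@x / (2 * knn_k - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)

  run <- function(res) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    igraph::membership(igraph::cluster_louvain(g, resolution = res))
  }
  if (is.null(target_k)) {
    memb <- run(resolution)
    res <- resolution
  } else {
    lo <- 0.01; hi <- 10
    best <- NULL; best_gap <- Inf; res <- NA_real_
    for (step in seq_len(max_steps)) {
      mid <- (lo + hi) / 2
      memb <- run(mid)
      k <- length(unique(memb))
      gap <- abs(k - target_k)
      if (gap < best_gap) { best <- memb; best_gap <- gap; res <- mid }
      if (k == target_k) break
      if (k < target_k) lo <- mid else hi <- mid
    }
    memb <- best
    if (best_gap > 0)
      warning("target_k = ", target_k, " not reachable; returning the ",
              "closest partition (", length(unique(memb)), " clusters)")
  }
  labels <- as.integer(factor(memb)) - 1L
  names(labels) <- rownames(x)
  structure(list(labels = labels, n_clusters = length(unique(labels)),
                 resolution = res, knn_k = knn_k),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment:", length(x$labels), "cells in", x$n_clusters,
      "clusters (resolution", format(x$resolution, digits = 4), ")\n")
  print(table(cluster = x$labels))
  invisible(x)
}
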