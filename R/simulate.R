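#' Simulate a four-view single-cell multi-omics dataset
#'
#' Generates non-negative views with a planted partition of the cells into
#' `k_true` groups, mimicking the structure of paired expression /
#' accessibility data: all views share one cell partition, the two linked
#' views share feature identities and correlated basis structure, and the
#' ATAC-derived views are sparser and noisier than the RNA views.
#'
#' Construction: a membership-dominant loading matrix `H` (each cell loads
#' 0.8-1.2 on its own cluster's factor and `0` to `h_leak` elsewhere) and per-view
#' block bases `W` (features split evenly over factors; in-block loadings
#' `signal * U(0.5, 1.5)`, off-block `U(0, 0.05 * signal)`). The linked
#' ATAC basis is `link_corr * W_rna_linked + (1 - link_corr) * W_indep`
#' with `W_indep` an independent block basis on the same panel. Views are
#' `X = W H^T` plus truncated Gaussian noise (`pmax(. + N(0, noise_sd), 0)`)
#' followed by elementwise Bernoulli dropout, heavier on the ATAC views.
#'
#' For evaluation without labels, the first `n_marker` linked-RNA features
#' are planted markers loading on exactly one factor each (cycling), and
#' the next `n_housekeeping` load equally on every factor.
#'
#' @param n_cells Number of cells. Default 300.
#' @param k_true Planted cluster count (`<= n_cells / 10`). Default 3.
#' @param cluster_props Mixing proportions (summing to 1); default uniform.
#' @param p Per-view feature counts, in the order
#'   `rna_linked, rna_unlinked, atac_linked, atac_unlinked`; the two linked
#'   counts must be equal. Default `c(100, 100, 100, 200)`.
#' @param signal In-block basis intensity. Default 1.
#' @param noise_sd Additive noise scale. Default 0.1.
#' @param dropout Per-view zeroing probabilities in `[0, 1)`, same order as
#'   `p`. Default `c(0.3, 0.3, 0.6, 0.6)` (ATAC sparser).
#' @param link_corr Correlation of the two linked bases in `[0, 1]`.
#'   Default 0.9.
#' @param h_leak Upper bound of the off-block cell loadings; 0 gives a
#'   strictly block loading matrix. Default 0.05.
#' @param n_marker,n_housekeeping Planted gene counts for RAGI tests.
#'   Default 10 each.
#' @param seed Integer seed; the dataset is deterministic given `seed`.
#' @return List with `dataset` (a [multiview_dataset] of raw, unnormalized
#'   views), `labels` (planted cluster per cell, 1-based), `marker_ids`,
#'   `housekeeping_ids`, and `config` (the arguments as given).
#' @export
simulate_multiview <- function(n_cells = 300, k_true = 3,
                               cluster_props = NULL,
                               p = c(rna_linked = 100, rna_unlinked = 100,
                                     atac_linked = 100, atac_unlinked = 200),
                               signal = 1, noise_sd = 0.1,
                               dropout = c(rna_linked = 0.3,
                                           rna_unlinked = 0.3,
                                           atac_linked = 0.6,
                                           atac_unlinked = 0.6),
                               link_corr = 0.9, h_leak = 0.05, n_marker = 10,
                               n_housekeeping = 10, seed = 1L) {
  if (k_true > n_cells / 10)
    stop("k_true must be at most n_cells / 10")
  p <- rep_len(p, 4); names(p) <- VIEW_KEYS
  dropout <- rep_len(dropout, 4); names(dropout) <- VIEW_KEYS
  if (p[["rna_linked"]] != p[["atac_linked"]])
    stop("the two linked views must have equal feature counts")
  if (any(dropout < 0 | dropout >= 1)) stop("dropout must lie in [0, 1)")
  if (link_corr < 0 || link_corr > 1) stop("link_corr must lie in [0, 1]")
  if (is.null(cluster_props)) cluster_props <- rep(1 / k_true, k_true)
  if (abs(sum(cluster_props) - 1) > 1e-8)
    stop("cluster_props must sum to 1")
  if (n_marker + n_housekeeping > p[["rna_linked"]])
    stop("marker + housekeeping counts exceed the linked panel size")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  sizes <- diff(round(cumsum(c(0, cluster_props)) * n_cells))
  labels <- sample(rep.int(seq_len(k_true), sizes))
  H <- matrix(stats::runif(n_cells * k_true, 0, h_leak), n_cells, k_true)
  H[cbind(seq_len(n_cells), labels)] <- stats::runif(n_cells, 0.8, 1.2)

  block_basis <- function(nf) {
    W <- matrix(stats::runif(nf * k_true, 0, 0.05 * signal), nf, k_true)
    fac <- rep_len(seq_len(k_true), nf)
    W[cbind(seq_len(nf), fac)] <- signal * stats::runif(nf, 0.5, 1.5)
    W
  }
  W <- list()
  W$rna_linked <- block_basis(p[["rna_linked"]])
  # planted markers: one factor only; housekeeping: flat across factors
  if (n_marker > 0) {
    idx <- seq_len(n_marker)
    W$rna_linked[idx, ] <- 0
    W$rna_linked[cbind(idx, rep_len(seq_len(k_true), n_marker))] <-
      signal * stats::runif(n_marker, 0.8, 1.2)
  }
  if (n_housekeeping > 0) {
    idx <- n_marker + seq_len(n_housekeeping)
    W$rna_linked[idx, ] <- signal * stats::runif(n_housekeeping, 0.4, 0.6)
  }
  W$rna_unlinked <- block_basis(p[["rna_unlinked"]])
  W$atac_linked <- link_corr * W$rna_linked +
    (1 - link_corr) * block_basis(p[["atac_linked"]])
  W$atac_unlinked <- block_basis(p[["atac_unlinked"]])

  linked_ids <- sprintf("gene%04d", seq_len(p[["rna_linked"]]))
  feat_ids <- list(
    rna_linked = linked_ids,
    rna_unlinked = sprintf("uGene%04d", seq_len(p[["rna_unlinked"]])),
    atac_linked = linked_ids,
    atac_unlinked = sprintf("peak%05d", seq_len(p[["atac_unlinked"]])))
  cells <- sprintf("cell%04d", seq_len(n_cells))

  views <- list()
  for (k in VIEW_KEYS) {
    X <- tcrossprod(W[[k]], H)
    if (noise_sd > 0)
      X <- pmax(X + matrix(stats::rnorm(length(X), 0, noise_sd), nrow(X)), 0)
    if (dropout[[k]] > 0)
      X <- X * matrix(stats::rbinom(length(X), 1, 1 - dropout[[k]]), nrow(X))
    dimnames(X) <- list(feat_ids[[k]], cells)
    views[[k]] <- X
  }
  ds <- multiview_dataset(rna_linked = views$rna_linked,
                          rna_unlinked = views$rna_unlinked,
                          atac_linked = views$atac_linked,
                          atac_unlinked = views$atac_unlinked)
  list(dataset = ds, labels = labels,
       marker_ids = if (n_marker > 0) linked_ids[seq_len(n_marker)]
                    else character(0),
       housekeeping_ids = if (n_housekeeping > 0)
         linked_ids[n_marker + seq_len(n_housekeeping)] else character(0),
       config = list(n_cells = n_cells, k_true = k_true,
                     cluster_props = cluster_props, p = p, signal = signal,
                     noise_sd = noise_sd, dropout = dropout,
                     link_corr = link_corr, h_leak = h_leak,
                     n_marker = n_marker,
                     n_housekeeping = n_housekeeping, seed = seed))
}
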