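#' Normalized mutual information between two partitions
#'
#' Mutual information of the label contingency table divided by the
#' geometric mean of the two label entropies (natural logarithms;
#' `0 * log 0` taken as 0). Returns 0 when either partition has zero
#' entropy, by the 0/0 convention.
#'
#' @param truth,pred Label vectors of equal length (any atomic type).
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("label vectors differ in length (", length(truth), " vs ",
         length(pred), ")")
  n <- length(truth)
  tab <- table(truth, pred)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  den <- sqrt(ent(pi_) * ent(pj_))
  if (den == 0) return(0)
  mi / den
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement, computed from the contingency
#' table by the standard formula. Degenerate cases where all cell pairs
#' trivially agree (both partitions all-singleton or both single-cluster)
#' return 1.
#'
#' @param truth,pred Label vectors of equal length (>= 2).
#' @return ARI in `(-1, 1]`; 1 iff the partitions are identical up to
#'   relabeling.
#' @export
ari <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("label vectors differ in length (", length(truth), " vs ",
         length(pred), ")")
  n <- length(truth)
  if (n < 2) stop("need at least 2 observations")
  tab <- table(truth, pred)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expct <- si * sj / choose(n, 2)
  den <- (si + sj) / 2 - expct
  if (den == 0) return(1)
  (sij - expct) / den
}

#' Gini index of per-cluster mean expression
#'
#' Measures how imbalanced one gene's expression is across cell clusters,
#' by the pairwise mean-absolute-difference form over the `m` cluster means
#' `x`: `sum_ij |x_i - x_j| / (2 m^2 mean(x))`. Scale-invariant; 0 for
#' perfectly balanced expression (and, by convention, for a single cluster
#' or an all-zero gene); bounded by `1 - 1/m`.
#'
#' @param x Non-negative vector of per-cluster mean expression values.
#' @return Gini index in `[0, 1)`.
#' @examples
#' gini_index(c(0, 0, 0, 1))  # 0.75
#' @export
gini_index <- function(x) {
  if (any(x < 0)) stop("cluster means must be non-negative")
  m <- length(x)
  xbar <- mean(x)
  if (m < 2 || xbar == 0) return(0)
  sum(abs(outer(x, x, "-"))) / (2 * m^2 * xbar)
}

#' Residual average Gini index (RAGI) of a clustering
#'
#' A label-free clustering quality score: marker genes should be expressed
#' in few clusters (high Gini across cluster means) while housekeeping
#' genes should be expressed uniformly (low Gini). RAGI is the mean Gini
#' over the marker genes minus the mean Gini over the housekeeping genes;
#' higher means cleaner cluster separation.
#'
#' @param expression Gene-by-cell expression matrix (rownames = gene ids).
#'   Typically log-transformed counts.
#' @param labels Per-cell cluster labels (vector or `cluster_assignment`).
#' @param markers,housekeeping Character vectors of gene identifiers. Genes
#'   absent from `expression` are dropped with a warning; an empty
#'   intersection on either list is an error.
#' @return List with `ragi`, per-gene `gini_markers` and
#'   `gini_housekeeping` (named), and the identifiers that were
#'   `missing_markers` / `missing_housekeeping`.
#' @export
ragi <- function(expression, labels, markers, housekeeping) {
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  if (length(labels) != ncol(expression))
    stop("labels must cover the ", ncol(expression), " cells")
  genes <- rownames(expression)
  miss_m <- setdiff(markers, genes)
  miss_h <- setdiff(housekeeping, genes)
  markers <- intersect(markers, genes)
  housekeeping <- intersect(housekeeping, genes)
  if (length(miss_m) || length(miss_h))
    warning(length(miss_m), " marker and ", length(miss_h),
            " housekeeping genes absent from the expression matrix")
  if (length(markers) == 0) stop("no marker gene found in the expression matrix")
  if (length(housekeeping) == 0)
    stop("no housekeeping gene found in the expression matrix")

  cl <- factor(labels)
  sel <- unique(c(markers, housekeeping))
  sub <- as.matrix(expression[sel, , drop = FALSE])
  # per-gene mean within each cluster
  means <- t(apply(sub, 1, function(r) tapply(r, cl, mean)))
  g <- apply(means, 1, gini_index)
  list(ragi = mean(g[markers]) - mean(g[housekeeping]),
       gini_markers = g[markers], gini_housekeeping = g[housekeeping],
       missing_markers = miss_m, missing_housekeeping = miss_h)
}

#' Full clustering evaluation report
#'
#' Convenience wrapper combining [nmi()], [ari()] (when ground-truth labels
#' are available) and [ragi()] (when expression plus gene lists are
#' available) into one report.
#'
#' @param pred Predicted labels (vector or `cluster_assignment`).
#' @param truth Optional ground-truth labels.
#' @param expression,markers,housekeeping Optional inputs for [ragi()].
#' @return An `eval_report` list with whichever of `nmi`, `ari`, `ragi`,
#'   `gini_markers`, `gini_housekeeping` could be computed.
#' @export
evaluate_clustering <- function(pred, truth = NULL, expression = NULL,
                                markers = NULL, housekeeping = NULL) {
  if (inherits(pred, "cluster_assignment")) pred <- pred$labels
  rep <- list()
  if (!is.null(truth)) {
    rep$nmi <- nmi(truth, pred)
    rep$ari <- ari(truth, pred)
  }
  if (!is.null(expression)) {
    r <- ragi(expression, pred, markers, housekeeping)
    rep$ragi <- r$ragi
    rep$gini_markers <- r$gini_markers
    rep$gini_housekeeping <- r$gini_housekeeping
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Clustering evaluation\n")
  for (m in c("nmi", "ari", "ragi"))
    if (!is.null(x[[m]]))
      cat(sprintf("  %-5s %.4f\n", toupper(m), x[[m]]))
  invisible(x)
}
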