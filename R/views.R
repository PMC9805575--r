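#' View keys used throughout the package
#'
#' The four views of a paired scRNA-seq / scATAC-seq experiment, in canonical
#' order: linked gene expression, unlinked gene expression, linked gene
#' activity, unlinked peak accessibility.
#' @keywords internal
VIEW_KEYS <- c("rna_linked", "rna_unlinked", "atac_linked", "atac_unlinked")

# non-negativity and dimname checks shared by all view constructors
check_view_matrix <- function(x, key = "view") {
  if (!(is.matrix(x) || inherits(x, "Matrix")))
    stop(key, ": a view must be a matrix (features x cells)")
  if (anyNA(x)) stop(key, ": view contains missing values")
  if (min(x) < 0) stop(key, ": view contains negative entries")
  if (sum(x) == 0) stop(key, ": view is all zero")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(key, ": view must carry feature (row) and cell (column) names")
  if (anyDuplicated(rownames(x)))
    stop(key, ": duplicated feature identifiers")
  if (anyDuplicated(colnames(x)))
    stop(key, ": duplicated cell identifiers")
  invisible(x)
}

#' Assemble a multi-view single-cell dataset
#'
#' Bundles up to four non-negative feature-by-cell matrices into one dataset
#' sharing a single cell ordering. The two linked views (gene expression and
#' gene activity) must carry identical, identically ordered feature panels;
#' all views must carry identical, identically ordered cell identifiers.
#'
#' @param rna_linked,rna_unlinked,atac_linked,atac_unlinked Non-negative
#'   feature-by-cell matrices (base or \pkg{Matrix}) with row and column
#'   names. Any subset may be supplied, but at least one view is required.
#' @return An object of class `multiview_dataset`: a list with elements
#'   `views` (named list of matrices in canonical order), `n` (number of
#'   cells) and `cell_ids`.
#' @examples
#' x <- matrix(rpois(20, 2), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' multiview_dataset(rna_linked = x, atac_linked = x + 1)
#' @export
multiview_dataset <- function(rna_linked = NULL, rna_unlinked = NULL,
                              atac_linked = NULL, atac_unlinked = NULL) {
  views <- list(rna_linked = rna_linked, rna_unlinked = rna_unlinked,
                atac_linked = atac_linked, atac_unlinked = atac_unlinked)
  views <- views[!vapply(views, is.null, logical(1))]
  if (length(views) == 0) stop("at least one view is required")
  views <- views[intersect(VIEW_KEYS, names(views))]
  for (k in names(views)) check_view_matrix(views[[k]], k)
  cells <- colnames(views[[1]])
  for (k in names(views)) {
    if (!identical(colnames(views[[k]]), cells))
      stop("cell identifiers differ between views '", names(views)[1],
           "' and '", k, "' (all views must share one cell ordering)")
  }
  if (all(c("rna_linked", "atac_linked") %in% names(views)) &&
      !identical(rownames(views$rna_linked), rownames(views$atac_linked)))
    stop("linked views must share an identical, identically ordered feature panel")
  structure(list(views = views, n = length(cells), cell_ids = cells),
            class = "multiview_dataset")
}

#' @export
print.multiview_dataset <- function(x, ...) {
  cat("Multi-view single-cell dataset:", x$n, "cells\n")
  for (k in names(x$views))
    cat(sprintf("  %-14s %6d features\n", k, nrow(x$views[[k]])))
  invisible(x)
}

#' Normalize a view to unit total mass
#'
#' Divides every entry of a non-negative matrix by the grand total of its
#' entries, so the result sums to one. This puts views with very different
#' feature counts and count depths on a comparable scale before joint
#' factorization.
#'
#' @param x Non-negative matrix with at least one positive entry.
#' @return Matrix of the same shape whose entries sum to 1.
#' @export
normalize_view <- function(x) {
  if (anyNA(x)) stop("matrix contains missing values")
  if (min(x) < 0) stop("matrix contains negative entries")
  total <- sum(x)
  if (total <= 0) stop("cannot normalize an all-zero matrix")
  x / total
}
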