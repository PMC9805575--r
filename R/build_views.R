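#' Build the four factorization views from expression and accessibility
#'
#' Constructs the linked and unlinked views entering the joint factorization:
#' \itemize{
#'   \item `rna_linked` / `atac_linked`: expression and gene activity
#'     restricted to `n_linked` highly variable genes, selected on the RNA
#'     matrix over the genes that have both an expression and an activity
#'     profile. The two linked views share one identically ordered panel.
#'   \item `rna_unlinked`: `n_unlinked_rna` highly variable genes among the
#'     RNA genes excluded from the linked panel.
#'   \item `atac_unlinked`: the `n_unlinked_atac` peaks with the largest
#'     total count over all cells (ties broken by peak identifier).
#' }
#' HVG selection runs on raw counts; RNA-derived views are then transformed
#' `x -> log(1 + x)` (activity and peak views are left untransformed by
#' default, configurable), and finally each view is scaled to unit total
#' mass by [normalize_view()].
#'
#' @param rna Gene-by-cell raw count matrix (rownames = gene ids).
#' @param activity Gene-by-cell activity matrix, e.g. from [gene_activity()].
#' @param peak_counts Peak-by-cell count matrix (rownames = peak ids).
#' @param n_linked,n_unlinked_rna,n_unlinked_atac Panel sizes; defaults
#'   2000 / 2000 / 5000.
#' @param log_rna Apply `log1p` to the RNA-derived views. Default `TRUE`.
#' @param log_activity Apply `log1p` to the gene-activity view. Default
#'   `FALSE`.
#' @param normalize Sum-to-one normalize every view. Default `TRUE`.
#' @return A [multiview_dataset] whose `"panels"` attribute records the
#'   provenance of each feature panel.
#' @export
build_views <- function(rna, activity, peak_counts,
                        n_linked = 2000, n_unlinked_rna = 2000,
                        n_unlinked_atac = 5000,
                        log_rna = TRUE, log_activity = FALSE,
                        normalize = TRUE) {
  if (anyDuplicated(rownames(rna))) stop("duplicated gene ids in rna")
  if (anyDuplicated(rownames(activity))) stop("duplicated gene ids in activity")
  if (anyDuplicated(rownames(peak_counts))) stop("duplicated peak ids")
  if (!identical(colnames(rna), colnames(activity)) ||
      !identical(colnames(rna), colnames(peak_counts)))
    stop("rna, activity and peak_counts must share one cell ordering")

  shared <- intersect(rownames(rna), rownames(activity))
  # drop activity genes with no accessible peak: no information to link
  shared <- shared[Matrix::rowSums(activity[shared, , drop = FALSE]) > 0]
  if (length(shared) < n_linked)
    stop("only ", length(shared), " genes have both expression and activity; ",
         n_linked, " linked genes requested")
  linked_panel <- select_hvg(rna[shared, , drop = FALSE], n_linked)

  rest <- setdiff(rownames(rna), linked_panel)
  if (n_unlinked_rna > length(rest))
    stop("n_unlinked_rna (", n_unlinked_rna, ") exceeds the ", length(rest),
         " genes outside the linked panel")
  unlinked_panel <- select_hvg(rna[rest, , drop = FALSE], n_unlinked_rna)

  if (n_unlinked_atac > nrow(peak_counts))
    stop("n_unlinked_atac (", n_unlinked_atac, ") exceeds the ",
         nrow(peak_counts), " available peaks")
  tot <- Matrix::rowSums(peak_counts)
  peak_panel <- rownames(peak_counts)[
    order(-tot, rownames(peak_counts), method = "radix")][seq_len(n_unlinked_atac)]

  tf <- function(m, log_it) {
    m <- as.matrix(m)
    if (log_it) m <- log1p(m)
    if (normalize) m <- normalize_view(m)
    m
  }
  ds <- multiview_dataset(
    rna_linked    = tf(rna[linked_panel, , drop = FALSE], log_rna),
    rna_unlinked  = tf(rna[unlinked_panel, , drop = FALSE], log_rna),
    atac_linked   = tf(activity[linked_panel, , drop = FALSE], log_activity),
    atac_unlinked = tf(peak_counts[peak_panel, , drop = FALSE], FALSE))
  attr(ds, "panels") <- list(linked = linked_panel, rna_unlinked = unlinked_panel,
                             atac_unlinked = peak_panel)
  ds
}
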