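#' Read a 10x-convention Matrix Market directory
#'
#' Expects `matrix.mtx`, `features.tsv` (first column = feature id) and
#' `barcodes.tsv` in `dir` (alternative file names can be given).
#'
#' @param dir Directory path.
#' @param matrix_file,features_file,barcodes_file File names inside `dir`.
#' @return Sparse `dgCMatrix`, features x cells, with dimnames.
#' @export
read_mtx_dir <- function(dir, matrix_file = "matrix.mtx",
                         features_file = "features.tsv",
                         barcodes_file = "barcodes.tsv") {
  paths <- file.path(dir, c(matrix_file, features_file, barcodes_file))
  for (p in paths) if (!file.exists(p)) stop("missing file: ", p)
  m <- methods::as(Matrix::readMM(paths[1]), "CsparseMatrix")
  feats <- utils::read.table(paths[2], sep = "\t", header = FALSE,
                             colClasses = "character")[[1]]
  cells <- utils::read.table(paths[3], sep = "\t", header = FALSE,
                             colClasses = "character")[[1]]
  if (length(feats) != nrow(m))
    stop(paths[2], ": ", length(feats), " feature ids for ", nrow(m), " rows")
  if (length(cells) != ncol(m))
    stop(paths[3], ": ", length(cells), " barcodes for ", ncol(m), " columns")
  dimnames(m) <- list(feats, cells)
  m
}

#' Write a matrix as a 10x-convention Matrix Market directory
#'
#' @param m Feature-by-cell matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @inheritParams read_mtx_dir
#' @export
write_mtx_dir <- function(m, dir, matrix_file = "matrix.mtx",
                          features_file = "features.tsv",
                          barcodes_file = "barcodes.tsv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(as(m, "CsparseMatrix"), "generalMatrix"),
                  file.path(dir, matrix_file))
  writeLines(rownames(m), file.path(dir, features_file))
  writeLines(colnames(m), file.path(dir, barcodes_file))
  invisible(dir)
}

#' Read peak intervals from a BED3+ file
#'
#' Only the first three columns are used (0-based half-open). Peak ids are
#' taken from column 4 when present, otherwise formed as
#' `chrom:start-end`.
#'
#' @param path BED file path.
#' @return `data.frame` with `chrom`, `start`, `end`, `peak_id`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("missing BED file: ", path)
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(b) < 3) stop(path, ": BED needs at least 3 columns")
  out <- data.frame(chrom = as.character(b[[1]]), start = as.integer(b[[2]]),
                    end = as.integer(b[[3]]), stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) {
    bad <- which(out$start >= out$end)[1]
    stop(path, ": record ", bad, " has start >= end")
  }
  out$peak_id <- if (ncol(b) >= 4) as.character(b[[4]]) else
    sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out
}

#' Read a gene annotation with TSS coordinates
#'
#' Accepts either a 4-column TSV (`gene_id`, `chrom`, `tss`, `strand`,
#' with a header line) or a GTF file (extension `.gtf`, requires
#' \pkg{rtracklayer}), from which gene records are extracted and the TSS
#' computed strand-aware (5' end of the gene).
#'
#' @param path Annotation file path.
#' @return `data.frame` with `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("missing annotation file: ", path)
  if (grepl("\\.gtf(\\.gz)?$", path)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "gene"]
    if (length(gr) == 0) stop(path, ": no gene records found")
    df <- as.data.frame(gr)
    strand <- as.character(df$strand)
    # import() is 1-based closed; convert the 5' end to 0-based
    tss <- ifelse(strand == "-", df$end - 1, df$start - 1)
    data.frame(gene_id = as.character(df$gene_id),
               chrom = as.character(df$seqnames),
               tss = tss, strand = strand, stringsAsFactors = FALSE)
  } else {
    a <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss")
    if (!all(need %in% names(a)))
      stop(path, ": annotation TSV needs columns ",
           paste(need, collapse = ", "))
    if (is.null(a$strand)) a$strand <- "*"
    a[c("gene_id", "chrom", "tss", "strand")]
  }
}

#' Read a one-gene-per-line list
#' @param path File path.
#' @return Character vector (blank lines dropped).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("missing gene list: ", path)
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Write / read a multi-view dataset directory
#'
#' Each view is written as a 10x-convention MTX triplet under
#' `<dir>/<view key>/`, with a `manifest.yaml` recording dimensions and,
#' when available, feature-panel provenance.
#'
#' @param dataset A [multiview_dataset].
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing directory.
#' @return `dir`, invisibly.
#' @export
write_multiview <- function(dataset, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop(dir, " exists and is not empty; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- list(n_cells = dataset$n, views = list())
  for (k in names(dataset$views)) {
    write_mtx_dir(dataset$views[[k]], file.path(dir, k))
    man$views[[k]] <- list(features = nrow(dataset$views[[k]]),
                           cells = ncol(dataset$views[[k]]))
  }
  panels <- attr(dataset, "panels")
  if (!is.null(panels))
    man$panels <- lapply(panels, length)
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_multiview
#' @export
read_multiview <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  views <- lapply(stats::setNames(nm = names(man$views)), function(k)
    read_mtx_dir(file.path(dir, k)))
  do.call(multiview_dataset, views)
}

#' Write / read a fitted model archive
#'
#' Stores `W` and `H` per view, the consensus, weights and objective trace
#' as TSV tables, plus a `manifest.yaml` with the resolved hyperparameters,
#' seed, ablation flags and iteration count.
#'
#' @param fit An `awmv` fit.
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing directory.
#' @return `dir`, invisibly; `read_awmv()` returns the reconstructed
#'   `awmv` object (objective trace and dimensions included).
#' @export
write_awmv <- function(fit, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop(dir, " exists and is not empty; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(m, f) utils::write.table(
    m, file.path(dir, f), sep = "\t", quote = FALSE, col.names = NA)
  for (k in fit$view_keys) {
    wtsv(fit$factors[[k]]$W, paste0("W_", k, ".tsv"))
    wtsv(fit$factors[[k]]$H, paste0("H_", k, ".tsv"))
  }
  wtsv(fit$H_star, "H_star.tsv")
  utils::write.table(
    data.frame(view = fit$view_keys, weight = unname(fit$weights),
               recon_error = unname(fit$errors)),
    file.path(dir, "weights.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(format(fit$objective, digits = 17),
             file.path(dir, "objective_trace.tsv"))
  yaml::write_yaml(list(
    K = fit$K, lambda = unname(fit$lambda[1]), beta = fit$beta,
    gamma = fit$gamma, tol = fit$tol, seed = fit$seed,
    link_enabled = fit$link_enabled,
    fixed_weights = if (is.null(fit$fixed_weights)) "adaptive"
                    else unname(fit$fixed_weights),
    n_iter = fit$n_iter, converged = fit$converged,
    views = as.list(fit$p)), file.path(dir, "manifest.yaml"),
    precision = 15)
  invisible(dir)
}

#' @rdname write_awmv
#' @export
read_awmv <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  keys <- names(man$views)
  rtsv <- function(f, keep_rows = FALSE) {
    m <- as.matrix(utils::read.table(
      file.path(dir, f), sep = "\t", header = TRUE, row.names = 1,
      check.names = FALSE))
    dimnames(m) <- if (keep_rows) list(rownames(m), NULL) else NULL
    m
  }
  factors <- lapply(stats::setNames(nm = keys), function(k)
    list(W = rtsv(paste0("W_", k, ".tsv")), H = rtsv(paste0("H_", k, ".tsv"))))
  H_star <- rtsv("H_star.tsv", keep_rows = TRUE)
  wt <- utils::read.table(file.path(dir, "weights.tsv"), sep = "\t",
                          header = TRUE)
  structure(list(
    factors = factors, H_star = H_star,
    weights = stats::setNames(wt$weight, wt$view),
    errors = stats::setNames(wt$recon_error, wt$view),
    objective = as.numeric(readLines(file.path(dir, "objective_trace.tsv"))),
    n_iter = man$n_iter, converged = man$converged, K = man$K,
    lambda = stats::setNames(rep(man$lambda, length(keys)), keys),
    beta = man$beta, gamma = man$gamma, tol = man$tol,
    link_enabled = man$link_enabled,
    fixed_weights = if (identical(man$fixed_weights, "adaptive")) NULL
                    else unlist(man$fixed_weights),
    seed = man$seed, view_keys = keys, n = nrow(H_star),
    p = unlist(man$views), cell_ids = rownames(H_star),
    call = NULL), class = "awmv")
}

#' Write / read cluster labels as a two-column TSV
#'
#' @param assignment A `cluster_assignment` (or bare label vector with
#'   names).
#' @param path Output TSV path (`cell_id`, `cluster`).
#' @export
write_labels <- function(assignment, path) {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else assignment
  utils::write.table(
    data.frame(cell_id = names(labels), cluster = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stats::setNames(as.integer(d$cluster), d$cell_id)
}
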