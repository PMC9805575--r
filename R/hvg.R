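#' Select highly variable genes by a variance-stabilizing statistic
#'
#' Ranks genes by standardized variance after removing the empirical
#' mean-variance trend, in the spirit of the `vst` selection used by the main
#' single-cell toolkits: a loess curve of `log10(variance)` on `log10(mean)`
#' predicts the expected standard deviation of each gene; counts are
#' standardized by it, clipped at `sqrt(n)`, and the variance of the clipped
#' standardized values is the ranking statistic. Selection is deterministic:
#' ties are broken by feature identifier (ascending), and the result is
#' invariant to the ordering of cells.
#'
#' For very small panels (fewer than 30 genes with positive variance) the
#' loess trend is not identifiable; the statistic falls back to the plain
#' dispersion variance/mean.
#'
#' @param counts Gene-by-cell matrix of raw (pre-log) counts with rownames.
#' @param n_top Number of genes to return; must not exceed the number of
#'   genes with nonzero variance.
#' @param span Loess span for the mean-variance trend. Default 0.3.
#' @return Character vector of `n_top` feature identifiers, ranked by
#'   decreasing standardized variance.
#' @export
select_hvg <- function(counts, n_top, span = 0.3) {
  if (is.null(rownames(counts))) stop("counts must have gene rownames")
  n <- ncol(counts)
  x <- as.matrix(counts)
  mu <- rowMeans(x)
  v <- rowSums((x - mu)^2) / (n - 1)
  n_var <- sum(v > 0)
  if (n_top > n_var)
    stop("n_top (", n_top, ") exceeds the ", n_var,
         " features with nonzero variance")

  if (n_var >= 30) {
    use <- v > 0 & mu > 0
    fit <- stats::loess(log10(v[use]) ~ log10(mu[use]), span = span,
                        degree = 2)
    exp_sd <- rep(NA_real_, length(mu))
    exp_sd[use] <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(n)
    stat <- rep(-Inf, length(mu))
    for (i in which(use)) {
      z <- pmin((x[i, ] - mu[i]) / exp_sd[i], clip)
      stat[i] <- sum((z - mean(z))^2) / (n - 1)
    }
  } else {
    stat <- ifelse(mu > 0, v / mu, ifelse(v > 0, v, -Inf))
  }
  ids <- rownames(counts)
  ord <- order(-stat, ids, method = "radix")
  ids[ord][seq_len(n_top)]
}
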