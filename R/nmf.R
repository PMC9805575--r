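#' Single-view NMF by multiplicative updates
#'
#' Minimizes `||X - W H^T||_F^2` over non-negative `W` (p x K) and `H`
#' (n x K) with the classical multiplicative update rules. Used to
#' initialize the joint multi-view factorization, and as the single-view
#' baseline.
#'
#' Factors are initialized from `runif(0, 1)` entries scaled by
#' `sqrt(mean(X) / K)` so the initial reconstruction matches the data scale;
#' the run is deterministic given `seed`.
#'
#' @param X Non-negative feature-by-cell matrix with at least one positive
#'   entry.
#' @param K Number of factors, `1 <= K <= min(dim(X))`.
#' @param seed Integer seed for the random initialization.
#' @param n_iter Number of multiplicative update sweeps. Default 200.
#' @param eps Denominator guard. Default 1e-12.
#' @return List with `W` (p x K), `H` (n x K) and `trace`, the squared
#'   Frobenius reconstruction error after each sweep (non-increasing).
#' @export
nmf_single <- function(X, K, seed = 1L, n_iter = 200L, eps = 1e-12) {
  X <- as.matrix(X)
  p <- nrow(X); n <- ncol(X)
  if (min(X) < 0) stop("X must be non-negative")
  if (sum(X) <= 0) stop("X must have a positive entry")
  if (K > min(p, n)) stop("K (", K, ") exceeds min(dim(X)) = ", min(p, n))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  sc <- sqrt(mean(X) / K)
  W <- matrix(stats::runif(p * K), p, K) * sc
  H <- matrix(stats::runif(n * K), n, K) * sc
  trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    W <- W * (X %*% H) / (W %*% crossprod(H) + eps)
    H <- H * (crossprod(X, W)) / (H %*% crossprod(W) + eps)
    trace[it] <- frob2(X - tcrossprod(W, H))
  }
  list(W = W, H = H, trace = trace)
}

frob2 <- function(m) sum(m * m)

# save/restore global RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
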