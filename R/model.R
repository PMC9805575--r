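#' Column-sum normalizer of a basis matrix
#'
#' Returns the diagonal of `Q = Diag(colSums(W))`, the per-factor scaling
#' that makes coefficient matrices from views with different feature counts
#' comparable before consensus averaging: the consensus pulls together the
#' products `H Q`, which are invariant to the diagonal rescaling ambiguity
#' of `W H^T`.
#'
#' Zero columns of `W` yield zero diagonal entries; their consensus
#' contribution is simply zero (degenerate factors are inert, not an error).
#'
#' @param W Non-negative basis matrix (features x K).
#' @return Numeric vector of length K (the diagonal of Q).
#' @export
compute_q <- function(W) {
  if (min(W) < 0) stop("W must be non-negative")
  colSums(W)
}

#' Joint factorization objective
#'
#' Evaluates the weighted multi-view objective
#' \deqn{\sum_{v} [\omega_v \|X_v - W_v H_v^T\|_F^2
#'   + \lambda_v \|H_v Q_v - H^*\|_F^2]
#'   + \beta \|W_{rna,linked} - W_{atac,linked}\|_F^2
#'   + \gamma \sum_v \omega_v \ln \omega_v}
#' with the weights \eqn{\omega} constrained to the probability simplex.
#' The \eqn{\beta} coupling term is included only when both linked views are
#' present and `link_enabled` is `TRUE`.
#'
#' @param views Named list of non-negative matrices (the data views).
#' @param factors Named list (same names) of `list(W, H)` factor pairs.
#' @param H_star Consensus cell-by-factor matrix.
#' @param weights Named per-view weights on the simplex.
#' @param lambda Per-view consensus penalties (scalar recycled).
#' @param beta Linked-basis coupling penalty.
#' @param gamma Weight-entropy bandwidth.
#' @param link_enabled Include the `beta` term. Default `TRUE`.
#' @return Scalar objective value.
#' @export
awmv_objective <- function(views, factors, H_star, weights, lambda,
                           beta = 0, gamma = 1, link_enabled = TRUE) {
  keys <- names(views)
  lambda <- rep_len(lambda, length(keys))
  names(lambda) <- keys
  w <- weights[keys]
  if (abs(sum(w) - 1) > 1e-8 || any(w < 0))
    stop("weights must lie on the probability simplex")
  obj <- 0
  for (k in keys) {
    W <- factors[[k]]$W; H <- factors[[k]]$H
    obj <- obj + w[[k]] * frob2(views[[k]] - tcrossprod(W, H))
    obj <- obj + lambda[[k]] *
      frob2(sweep(H, 2, compute_q(W), "*") - H_star)
  }
  if (link_enabled && all(c("rna_linked", "atac_linked") %in% keys))
    obj <- obj + beta * frob2(factors$rna_linked$W - factors$atac_linked$W)
  obj + gamma * sum(ifelse(w > 0, w * log(w), 0))
}

# shared multiplicative W update; beta/W_other = 0/NULL gives the unlinked rule
mult_update_w <- function(W, H, X, H_star, omega, lambda, beta = 0,
                          W_other = NULL, eps = 1e-12) {
  p <- nrow(W); K <- ncol(W)
  num <- omega * (X %*% H) +
    matrix(lambda * colSums(H * H_star), p, K, byrow = TRUE)
  den <- omega * (W %*% crossprod(H)) +
    matrix(lambda * colSums(W) * colSums(H^2), p, K, byrow = TRUE)
  if (beta > 0) {
    num <- num + beta * W_other
    den <- den + beta * W
  }
  W * num / (den + eps)
}

#' Multiplicative update of a linked basis matrix
#'
#' One multiplicative step for the basis `W` of a linked view, pulling it
#' toward its reconstruction optimum, the consensus, and the basis
#' `W_other` of the partner linked view (strength `beta`). Entries equal to
#' zero stay zero; non-negativity is preserved.
#'
#' @param W Current basis (p x K) of the view being updated.
#' @param W_other Basis of the other linked view (same shape).
#' @param H Current coefficients (n x K) of the view being updated.
#' @param X Data matrix of the view (p x n).
#' @param H_star Consensus matrix (n x K).
#' @param omega View weight.
#' @param lambda Consensus penalty for the view.
#' @param beta Linked-basis coupling penalty.
#' @param eps Denominator guard. Default 1e-12.
#' @return Updated `W`.
#' @export
update_w_linked <- function(W, W_other, H, X, H_star, omega, lambda, beta,
                            eps = 1e-12) {
  stopifnot(identical(dim(W), dim(W_other)), nrow(H) == ncol(X),
            nrow(W) == nrow(X))
  mult_update_w(W, H, X, H_star, omega, lambda, beta, W_other, eps)
}

#' Multiplicative update of an unlinked basis matrix
#'
#' As [update_w_linked()] with the coupling term absent.
#' @inheritParams update_w_linked
#' @return Updated `W`.
#' @export
update_w_unlinked <- function(W, H, X, H_star, omega, lambda, eps = 1e-12) {
  stopifnot(nrow(H) == ncol(X), nrow(W) == nrow(X))
  mult_update_w(W, H, X, H_star, omega, lambda, 0, NULL, eps)
}

#' Multiplicative update of a coefficient matrix
#'
#' One multiplicative step for the cell-by-factor coefficients `H` of a
#' view, balancing reconstruction (weight `omega`) against agreement with
#' the consensus (`lambda`). Zeros are preserved.
#'
#' @inheritParams update_w_linked
#' @return Updated `H` (n x K).
#' @export
update_h <- function(H, W, X, H_star, omega, lambda, eps = 1e-12) {
  stopifnot(nrow(H) == ncol(X), nrow(W) == nrow(X))
  num <- omega * crossprod(X, W) + lambda * H_star
  den <- omega * (H %*% crossprod(W)) + lambda * H
  H * num / (den + eps)
}

#' Closed-form adaptive view weights
#'
#' The weights minimizing \eqn{\sum_v \omega_v e_v + \gamma \sum_v \omega_v
#' \ln \omega_v} on the probability simplex: a softmax of the negative
#' reconstruction errors, `omega_v = exp(-e_v / gamma) / sum(exp(-e / gamma))`,
#' computed with a max-shift for numerical stability. Views with smaller
#' reconstruction error always receive larger weight; `gamma` acts as a
#' bandwidth (large `gamma` flattens the weights toward uniform).
#'
#' @param errors Per-view squared Frobenius reconstruction errors.
#' @param gamma Bandwidth, > 0.
#' @return Weights summing to one, named as `errors`.
#' @examples
#' update_weights(c(1, 2, 3, 4), gamma = 1)
#' @export
update_weights <- function(errors, gamma) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (any(!is.finite(errors))) stop("reconstruction errors must be finite")
  z <- -errors / gamma
  z <- z - max(z)
  w <- exp(z)
  w / sum(w)
}

#' Closed-form consensus update
#'
#' The consensus matrix minimizing \eqn{\sum_v \lambda_v \|H_v Q_v -
#' H^*\|_F^2}: the lambda-weighted average of the scaled coefficient
#' matrices, `H* = sum(lambda_v H_v Q_v) / sum(lambda_v)`.
#'
#' @param H_list List of coefficient matrices (n x K each).
#' @param Q_list List of Q diagonals (length-K vectors), as [compute_q()].
#' @param lambda Per-view penalties (recycled).
#' @return Consensus matrix (n x K); the zero matrix if all `lambda` are 0.
#' @export
update_consensus <- function(H_list, Q_list, lambda) {
  lambda <- rep_len(lambda, length(H_list))
  acc <- 0
  for (i in seq_along(H_list))
    acc <- acc + lambda[i] * sweep(H_list[[i]], 2, Q_list[[i]], "*")
  tot <- sum(lambda)
  if (tot > 0) acc / tot
  else matrix(0, nrow(H_list[[1]]), ncol(H_list[[1]]))
}

#' Default linked-basis penalty
#'
#' The automatic choice of the coupling strength: the weighted total initial
#' reconstruction error divided by the initial squared distance between the
#' two linked bases,
#' `beta = sum(weights * errors) / ||W_rna - W_atac||_F^2`,
#' which puts the coupling term on the scale of the reconstruction terms at
#' initialization.
#'
#' @param errors Per-view initial squared reconstruction errors.
#' @param weights Initial weights (default uniform over the views).
#' @param W_rna,W_atac Initial bases of the two linked views.
#' @return Scalar `beta`.
#' @export
default_beta <- function(errors, W_rna, W_atac,
                         weights = rep(1 / length(errors), length(errors))) {
  den <- frob2(W_rna - W_atac)
  if (den <= 0)
    stop("initial linked bases are identical; supply beta explicitly")
  sum(weights * errors) / den
}

#' Default weight-entropy bandwidth
#'
#' The automatic bandwidth `gamma = max(|errors / log(weights)|)` over the
#' views, evaluated at the initial factors and initial weights (uniform 1/V
#' by default, giving `max(errors) / log(V)`). This calibrates the softmax
#' so the learned weights stay moderate rather than collapsing onto the
#' best-reconstructed view.
#'
#' @param errors Per-view initial squared reconstruction errors.
#' @param weights Initial weights in (0, 1), default uniform.
#' @return Scalar `gamma`.
#' @export
default_gamma <- function(errors,
                          weights = rep(1 / length(errors), length(errors))) {
  if (any(weights <= 0 | weights >= 1))
    stop("initial weights must lie strictly inside (0, 1)")
  g <- max(abs(errors / log(weights)))
  if (g <= 0) stop("all initial reconstruction errors are zero; ",
                   "supply gamma explicitly")
  g
}
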