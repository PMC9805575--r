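#' Fit the adaptively weighted multi-view factorization
#'
#' Jointly factorizes up to four non-negative views of the same cells as
#' `X_v ~ W_v H_v^T`, regularizing every scaled coefficient matrix
#' `H_v Q_v` toward a shared consensus `H*`, coupling the bases of the two
#' linked views (gene expression and gene activity share a feature panel),
#' and learning a per-view weight on the probability simplex by an
#' entropy-regularized softmax of the reconstruction errors. The consensus
#' `H*` is the low-dimensional cell representation used for clustering.
#'
#' Each view is first factorized on its own ([nmf_single()]) to initialize
#' `W_v`, `H_v`; weights start uniform, and the penalties `beta` (linked
#' bases) and `gamma` (weight bandwidth) default to the data-driven choices
#' of [default_beta()] and [default_gamma()] evaluated at that
#' initialization. The optimizer then cycles multiplicative updates of all
#' `W_v`, then all `H_v`, then the closed-form weight and consensus updates,
#' recording the objective after every cycle, until the change in objective
#' between adjacent cycles falls below the stopping threshold or `max_iter`
#' cycles are reached.
#'
#' Stopping: the threshold is `tol * sum_v ||X_v||_F^2` by default
#' (`stop_rule = "scaled"`), i.e. the objective decrement is measured per
#' unit of total squared data mass. Because every view is normalized to
#' unit total mass, a fixed absolute threshold would be data-scale
#' dependent (and degenerate for large matrices); the scaled rule is
#' scale-free and strictly positive even though the objective itself can
#' cross zero (its entropy term is negative). `stop_rule = "absolute"`
#' compares the raw decrement against `tol`, and `rel_tol` (if set)
#' overrides both with a relative-to-objective rule.
#'
#' Ablations: `link_enabled = FALSE` removes the basis-coupling term;
#' `fixed_weights` freezes the view weights (e.g. `"uniform"`); dropping a
#' view from `data` (or via `drop_view`) fits the remaining views, down to
#' single-view plain NMF.
#'
#' @param data A [multiview_dataset], or a named list of non-negative
#'   feature-by-cell matrices with names among
#'   `rna_linked`, `rna_unlinked`, `atac_linked`, `atac_unlinked`.
#' @param K Number of factors (>= 2). Default 20.
#' @param lambda Consensus penalty, one scalar applied to every view (a
#'   per-view vector is accepted). Default 0.01.
#' @param beta Linked-basis coupling penalty; `NULL` (default) uses
#'   [default_beta()]. Ignored unless both linked views are present and
#'   `link_enabled` is `TRUE`.
#' @param gamma Weight-entropy bandwidth; `NULL` (default) uses
#'   [default_gamma()].
#' @param tol Stopping threshold on the objective difference between
#'   adjacent cycles. Default 1e-4 (see Details for the scale it is
#'   measured on).
#' @param stop_rule `"scaled"` (default; threshold `tol * sum ||X_v||_F^2`)
#'   or `"absolute"` (threshold `tol`).
#' @param rel_tol If non-`NULL`, stop on `|diff| < rel_tol * |objective|`
#'   instead, overriding `stop_rule`.
#' @param max_iter Cycle cap. Default 500.
#' @param init_nmf_iter Multiplicative sweeps of the per-view
#'   initialization. Default 200.
#' @param link_enabled Couple the linked bases. Default `TRUE`.
#' @param fixed_weights `NULL` for adaptive weights, `"uniform"`, or a
#'   numeric vector over the present views summing to 1.
#' @param normalize Sum-to-one normalize each view before fitting
#'   ([normalize_view()]). Default `TRUE`.
#' @param drop_view Optional view keys to exclude (ablation).
#' @param seed Integer seed controlling the random initialization.
#' @param eps Multiplicative-update denominator guard. Default 1e-12.
#' @param verbose Print the objective every 10 cycles.
#' @return An object of class `awmv`; see [coef.awmv()], [summary.awmv()],
#'   [plot.awmv()], [fitted.awmv()]. Components include `factors` (per-view
#'   `W`, `H`), `H_star`, `weights`, `objective` (the per-cycle trace,
#'   non-increasing), `n_iter`, `converged`, and the resolved
#'   hyperparameters.
#' @examples
#' sim <- simulate_multiview(n_cells = 60, k_true = 2,
#'                           p = c(20, 20, 20, 30), seed = 1)
#' fit <- awmv(sim$dataset, K = 2, init_nmf_iter = 50, seed = 1)
#' fit$weights
#' @export
awmv <- function(data, K = 20, lambda = 0.01, beta = NULL, gamma = NULL,
                 tol = 1e-4, stop_rule = c("scaled", "absolute"),
                 rel_tol = NULL, max_iter = 500L,
                 init_nmf_iter = 200L, link_enabled = TRUE,
                 fixed_weights = NULL, normalize = TRUE, drop_view = NULL,
                 seed = 1L, eps = 1e-12, verbose = FALSE) {
  cl <- match.call()
  views <- if (inherits(data, "multiview_dataset")) data$views else data
  if (is.null(names(views)) || !all(names(views) %in% VIEW_KEYS))
    stop("views must be named among: ", paste(VIEW_KEYS, collapse = ", "))
  if (!is.null(drop_view)) views <- views[setdiff(names(views), drop_view)]
  views <- views[intersect(VIEW_KEYS, names(views))]
  V <- length(views)
  if (V == 0) stop("no views left to fit")
  keys <- names(views)
  views <- lapply(views, function(m) {
    m <- as.matrix(m)
    if (normalize) normalize_view(m) else m
  })
  n <- ncol(views[[1]])
  if (K < 2 && V > 1) stop("K must be >= 2")
  if (K > min(vapply(views, nrow, 0L), n))
    stop("K exceeds the smallest view dimension")
  if (any(lambda < 0)) stop("lambda must be >= 0")
  if (tol <= 0) stop("tol must be > 0")
  stop_rule <- match.arg(stop_rule)
  stop_scale <- if (stop_rule == "scaled")
    sum(vapply(views, frob2, 0)) else 1
  lambda <- rep_len(lambda, V); names(lambda) <- keys

  has_link <- all(c("rna_linked", "atac_linked") %in% keys)
  link_on <- isTRUE(link_enabled) && has_link

  # --- initialization: independent per-view NMF ---------------------------
  factors <- vector("list", V); names(factors) <- keys
  for (i in seq_len(V))
    factors[[i]] <- nmf_single(views[[i]], K, seed = as.integer(seed) + i - 1L,
                               n_iter = init_nmf_iter, eps = eps)[c("W", "H")]
  errors <- vapply(keys, function(k)
    frob2(views[[k]] - tcrossprod(factors[[k]]$W, factors[[k]]$H)), 0)
  w_init <- rep(1 / V, V); names(w_init) <- keys

  if (link_on && is.null(beta))
    beta <- default_beta(errors, factors$rna_linked$W, factors$atac_linked$W,
                         weights = w_init)
  if (!link_on) beta <- 0
  if (is.null(gamma))
    gamma <- if (V == 1) 1 else default_gamma(errors, weights = w_init)
  if (gamma <= 0) stop("gamma must be > 0")

  fixed <- NULL
  if (!is.null(fixed_weights)) {
    fixed <- if (identical(fixed_weights, "uniform")) w_init
             else rep_len(as.numeric(fixed_weights), V)
    names(fixed) <- keys
    if (abs(sum(fixed) - 1) > 1e-8 || any(fixed < 0))
      stop("fixed_weights must lie on the probability simplex")
  }
  omega <- if (is.null(fixed)) w_init else fixed
  Q <- lapply(factors, function(f) compute_q(f$W))
  H_star <- update_consensus(lapply(factors, `[[`, "H"), Q, lambda)

  obj <- awmv_objective(views, factors, H_star, omega, lambda, beta, gamma,
                        link_on)
  trace <- obj
  converged <- FALSE
  it <- 0L
  check_finite <- function(m, what, key) {
    if (any(!is.finite(m)))
      stop("non-finite values after the ", what, " update of view '", key, "'")
    m
  }
  for (it in seq_len(max_iter)) {
    for (k in keys) {
      f <- factors[[k]]
      if (link_on && k %in% c("rna_linked", "atac_linked")) {
        other <- if (k == "rna_linked") "atac_linked" else "rna_linked"
        f$W <- update_w_linked(f$W, factors[[other]]$W, f$H, views[[k]],
                               H_star, omega[[k]], lambda[[k]], beta, eps)
      } else {
        f$W <- update_w_unlinked(f$W, f$H, views[[k]], H_star,
                                 omega[[k]], lambda[[k]], eps)
      }
      factors[[k]] <- f
      check_finite(f$W, "W", k)
    }
    for (k in keys) {
      f <- factors[[k]]
      f$H <- update_h(f$H, f$W, views[[k]], H_star, omega[[k]], lambda[[k]],
                      eps)
      factors[[k]] <- f
      check_finite(f$H, "H", k)
    }
    errors <- vapply(keys, function(k)
      frob2(views[[k]] - tcrossprod(factors[[k]]$W, factors[[k]]$H)), 0)
    if (is.null(fixed)) omega <- update_weights(errors, gamma)
    Q <- lapply(factors, function(f) compute_q(f$W))
    H_star <- update_consensus(lapply(factors, `[[`, "H"), Q, lambda)
    check_finite(H_star, "consensus", "H_star")

    obj <- awmv_objective(views, factors, H_star, omega, lambda, beta, gamma,
                          link_on)
    trace <- c(trace, obj)
    if (verbose && it %% 10 == 0)
      message(sprintf("iter %4d  objective %.8e", it, obj))
    d <- abs(trace[it] - trace[it + 1])
    thr <- if (is.null(rel_tol)) tol * stop_scale
           else rel_tol * abs(trace[it + 1])
    if (d < thr) { converged <- TRUE; break }
  }
  if (!converged)
    warning("factorization did not converge in ", max_iter, " iterations")

  cells <- colnames(views[[1]])
  rownames(H_star) <- cells
  structure(list(
    factors = factors, H_star = H_star, weights = omega,
    objective = trace, n_iter = it, converged = converged,
    errors = errors, K = K, lambda = lambda, beta = beta, gamma = gamma,
    tol = tol, stop_rule = stop_rule, rel_tol = rel_tol,
    link_enabled = link_on,
    fixed_weights = fixed, seed = as.integer(seed),
    view_keys = keys, n = n,
    p = vapply(views, nrow, 0L), cell_ids = cells, call = cl),
    class = "awmv")
}

#' @export
print.awmv <- function(x, ...) {
  cat("Adaptively weighted multi-view NMF\n")
  cat(sprintf("  %d views, %d cells, K = %d factors\n",
              length(x$view_keys), x$n, x$K))
  cat(sprintf("  %d iterations (%s), objective %.6e\n", x$n_iter,
              if (x$converged) "converged" else "not converged",
              x$objective[length(x$objective)]))
  cat("  view weights:\n")
  for (k in x$view_keys)
    cat(sprintf("    %-14s %.4f\n", k, x$weights[[k]]))
  invisible(x)
}

#' Summarize a fitted multi-view factorization
#'
#' @param object An `awmv` fit.
#' @param ... Unused.
#' @return A `summary.awmv` list: per-view dimensions, weights and
#'   reconstruction errors, the hyperparameters, and the objective trace
#'   endpoints.
#' @export
summary.awmv <- function(object, ...) {
  s <- list(
    views = data.frame(view = object$view_keys,
                       features = unname(object$p[object$view_keys]),
                       weight = unname(object$weights[object$view_keys]),
                       recon_error = unname(object$errors[object$view_keys])),
    K = object$K, n = object$n, lambda = object$lambda[[1]],
    beta = object$beta, gamma = object$gamma,
    n_iter = object$n_iter, converged = object$converged,
    objective_first = object$objective[1],
    objective_last = object$objective[length(object$objective)])
  class(s) <- "summary.awmv"
  s
}

#' @export
print.summary.awmv <- function(x, ...) {
  cat(sprintf("Multi-view NMF: %d cells, K = %d\n", x$n, x$K))
  cat(sprintf("lambda = %g, beta = %g, gamma = %g\n", x$lambda, x$beta,
              x$gamma))
  cat(sprintf("objective %.6e -> %.6e in %d iterations (%s)\n",
              x$objective_first, x$objective_last, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  print(x$views, row.names = FALSE)
  invisible(x)
}

#' Extract the consensus cell-factor matrix
#'
#' The consensus `H*` (cells x K) is the shared low-dimensional cell
#' representation; feed it to [louvain_cluster()].
#'
#' @param object An `awmv` fit.
#' @param ... Unused.
#' @return Numeric matrix, cells x K.
#' @export
coef.awmv <- function(object, ...) object$H_star

#' Per-view reconstructions
#'
#' @param object An `awmv` fit.
#' @param ... Unused.
#' @return Named list of `W_v H_v^T` matrices on the (normalized) scale the
#'   model was fitted on.
#' @export
fitted.awmv <- function(object, ...)
  lapply(object$factors, function(f) tcrossprod(f$W, f$H))

#' Plot the objective trace of a fit
#'
#' @param x An `awmv` fit.
#' @param ... Passed to [plot.default()].
#' @export
plot.awmv <- function(x, ...) {
  plot(seq_along(x$objective) - 1, x$objective, type = "b",
       xlab = "iteration", ylab = "objective", ...)
  invisible(x)
}
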