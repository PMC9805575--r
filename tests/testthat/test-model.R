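test_that("single-view NMF recovers a planted rank-1 factorization", {
  set.seed(3)
  w <- runif(12, 0.5, 2); h <- runif(9, 0.5, 2)
  X <- outer(w, h)
  f <- nmf_single(X, K = 1, seed = 5, n_iter = 200)
  rel <- sqrt(sum((X - tcrossprod(f$W, f$H))^2) / sum(X^2))
  expect_lt(rel, 1e-3)
  expect_true(all(diff(f$trace) <= 1e-12))
  # seeded determinism, bitwise
  expect_identical(f, nmf_single(X, K = 1, seed = 5, n_iter = 200))
  expect_error(nmf_single(X, K = 10), "exceeds")
})

test_that("compute_q returns basis column sums", {
  expect_equal(compute_q(diag(2)), c(1, 1))
  expect_equal(compute_q(matrix(c(1, 3, 2, 4), 2)), c(4, 6))
  W <- matrix(runif(12), 4, 3)
  expect_equal(compute_q(2.5 * W), 2.5 * compute_q(W))
  expect_equal(compute_q(cbind(W, 0))[4], 0)  # zero column is inert, not an error
})

test_that("objective matches an independent term-by-term recomputation", {
  vs <- random_views(p = c(6, 6, 6, 9), n = 4, seed = 21)
  st <- random_state(vs, K = 2, seed = 22)
  for (link in c(TRUE, FALSE)) {
    got <- awmv_objective(vs, st$factors, st$H_star, st$weights,
                          lambda = c(0.03, 0.01, 0.02, 0.01), beta = 0.7,
                          gamma = 1.3, link_enabled = link)
    want <- oracle_objective(vs, st$factors, st$H_star, st$weights,
                             lambda = c(0.03, 0.01, 0.02, 0.01), beta = 0.7,
                             gamma = 1.3, link_enabled = link)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # beta = 0 equals removing the coupling term
  expect_equal(
    awmv_objective(vs, st$factors, st$H_star, st$weights, 0.01, beta = 0,
                   gamma = 1, link_enabled = TRUE),
    awmv_objective(vs, st$factors, st$H_star, st$weights, 0.01, beta = 5,
                   gamma = 1, link_enabled = FALSE))
  expect_error(
    awmv_objective(vs, st$factors, st$H_star, st$weights * 2, 0.01),
    "simplex")
})

test_that("objective at an exact fit reduces to the entropy term", {
  set.seed(30)
  K <- 2; n <- 5
  H <- matrix(runif(n * K, 0.5, 1.5), n, K)
  Wl <- matrix(runif(6 * K, 0.5, 1.5), 6, K)
  # both linked views share W; unlinked views get their own bases
  vs <- list(rna_linked = tcrossprod(Wl, H), rna_unlinked = NULL,
             atac_linked = tcrossprod(Wl, H), atac_unlinked = NULL)
  W2 <- matrix(runif(6 * K, 0.5, 1.5), 6, K)
  W4 <- matrix(runif(8 * K, 0.5, 1.5), 8, K)
  vs$rna_unlinked <- tcrossprod(W2, H); vs$atac_unlinked <- tcrossprod(W4, H)
  factors <- list(
    rna_linked = list(W = Wl, H = H), rna_unlinked = list(W = W2, H = H),
    atac_linked = list(W = Wl, H = H), atac_unlinked = list(W = W4, H = H))
  # choose H* = H Q for a common Q only possible per view; set lambda = 0
  # per-view consensus disagreement vanishes when H* = H Q(v) for each view,
  # which requires equal Q; instead verify with all H Q equal by scaling W
  # columns to unit sum so Q = 1 for every view
  for (k in names(factors)) {
    q <- compute_q(factors[[k]]$W)
    factors[[k]]$W <- sweep(factors[[k]]$W, 2, q, "/")
    factors[[k]]$H <- sweep(factors[[k]]$H, 2, q, "*")
    vs[[k]] <- tcrossprod(factors[[k]]$W, factors[[k]]$H)
  }
  # after scaling, W H^T is unchanged per view but H differs across views;
  # rebuild the views so every H equals the common H* exactly
  H_common <- factors$rna_linked$H
  for (k in names(factors)) {
    factors[[k]]$H <- H_common
    vs[[k]] <- tcrossprod(factors[[k]]$W, H_common)
  }
  w <- rep(1 / 4, 4); names(w) <- names(vs)
  gamma <- 0.8
  got <- awmv_objective(vs, factors, H_star = H_common, weights = w,
                        lambda = 0.01, beta = 3, gamma = gamma,
                        link_enabled = FALSE)
  expect_equal(got, gamma * log(1 / 4), tolerance = 1e-10)
})

test_that("W updates are fixed at stationary points and preserve zeros", {
  vs <- random_views(seed = 31)
  st <- random_state(vs, K = 2, seed = 32)
  X <- vs$rna_linked; f <- st$factors$rna_linked
  # zero preservation
  f$W[1, 1] <- 0
  up <- update_w_linked(f$W, st$factors$atac_linked$W, f$H, X, st$H_star,
                        omega = 0.3, lambda = 0.01, beta = 0.5)
  expect_equal(unname(up[1, 1]), 0)
  expect_true(all(up >= 0))
  # unlinked rule is the linked rule with beta = 0
  expect_equal(
    update_w_unlinked(f$W, f$H, X, st$H_star, omega = 0.3, lambda = 0.01),
    update_w_linked(f$W, st$factors$atac_linked$W, f$H, X, st$H_star,
                    omega = 0.3, lambda = 0.01, beta = 0))
  # single-view limit reproduces the plain NMF multiplicative W step
  plain <- f$W * (X %*% f$H) / (f$W %*% crossprod(f$H) + 1e-12)
  expect_equal(
    update_w_unlinked(f$W, f$H, X, matrix(0, nrow(f$H), 2), omega = 1,
                      lambda = 0),
    plain, tolerance = 1e-12)
})

test_that("H update reduces to plain NMF when lambda = 0 and preserves zeros", {
  vs <- random_views(seed = 41)
  st <- random_state(vs, K = 2, seed = 42)
  X <- vs$atac_unlinked; f <- st$factors$atac_unlinked
  f$H[2, 1] <- 0
  up <- update_h(f$H, f$W, X, st$H_star, omega = 0.4, lambda = 0.02)
  expect_equal(unname(up[2, 1]), 0)
  expect_true(all(up >= 0))
  plain <- f$H * crossprod(X, f$W) / (f$H %*% crossprod(f$W) + 1e-12)
  expect_equal(update_h(f$H, f$W, X, st$H_star, omega = 1, lambda = 0),
               plain, tolerance = 1e-12)
})

test_that("full update sweeps never increase the objective", {
  lam <- 0.01
  for (s in 1:20) {
    vs <- random_views(p = c(7, 7, 7, 10), n = 6, seed = 100 + s)
    st <- random_state(vs, K = 2, seed = 200 + s)
    gamma <- default_gamma(vapply(names(vs), function(k)
      sum((vs[[k]] - tcrossprod(st$factors[[k]]$W, st$factors[[k]]$H))^2), 0))
    beta <- 0.1
    obj <- function(stt) oracle_objective(vs, stt$factors, stt$H_star,
                                          stt$weights, lam, beta, gamma)
    before <- obj(st)
    # one full cycle: all W, all H, weights, consensus
    for (k in names(vs)) {
      f <- st$factors[[k]]
      if (k %in% c("rna_linked", "atac_linked")) {
        o <- setdiff(c("rna_linked", "atac_linked"), k)
        f$W <- update_w_linked(f$W, st$factors[[o]]$W, f$H, vs[[k]],
                               st$H_star, st$weights[[k]], lam, beta)
      } else {
        f$W <- update_w_unlinked(f$W, f$H, vs[[k]], st$H_star,
                                 st$weights[[k]], lam)
      }
      st$factors[[k]] <- f
    }
    mid_w <- obj(st)
    expect_lte(mid_w, before + 1e-8 * abs(before))
    for (k in names(vs))
      st$factors[[k]]$H <- update_h(st$factors[[k]]$H, st$factors[[k]]$W,
                                    vs[[k]], st$H_star, st$weights[[k]], lam)
    errs <- vapply(names(vs), function(k)
      sum((vs[[k]] - tcrossprod(st$factors[[k]]$W, st$factors[[k]]$H))^2), 0)
    st$weights <- update_weights(errs, gamma)
    st$H_star <- update_consensus(lapply(st$factors, `[[`, "H"),
                                  lapply(st$factors, function(f)
                                    compute_q(f$W)), lam)
    after <- obj(st)
    expect_lte(after, mid_w + 1e-8 * abs(mid_w))
  }
})

test_that("weight update is the softmax of negative errors", {
  expect_equal(unname(update_weights(rep(2, 4), 1)), rep(0.25, 4))
  w <- update_weights(c(1, 2, 3, 4), 1)
  soft <- exp(-c(1, 2, 3, 4)); soft <- soft / sum(soft)
  expect_equal(unname(w), soft, tolerance = 1e-10)
  expect_equal(round(unname(w), 4), c(0.6439, 0.2369, 0.0871, 0.0321))
  # huge bandwidth flattens to uniform; order always follows errors
  expect_equal(unname(update_weights(c(1, 5, 9, 2), 1e12)), rep(0.25, 4),
               tolerance = 1e-9)
  expect_true(all(diff(update_weights(c(4, 3, 2, 1), 0.5)) > 0))
  expect_error(update_weights(c(1, 2), 0), "gamma")
})

test_that("consensus update is the lambda-weighted average of H Q", {
  set.seed(50)
  A <- matrix(runif(12), 4, 3); B <- matrix(runif(12), 4, 3)
  I3 <- rep(1, 3)
  expect_equal(update_consensus(list(A, A), list(I3, I3), 0.01), A)
  expect_equal(update_consensus(list(A, B), list(I3, I3), c(0.02, 0.02)),
               (A + B) / 2)
  expect_equal(update_consensus(list(A, B), list(I3, I3), c(0.03, 0.01)),
               (3 * A + B) / 4)
  # Q scales columns before averaging
  q <- c(2, 1, 0.5)
  expect_equal(update_consensus(list(A), list(q), 0.01),
               sweep(A, 2, q, "*"))
})

test_that("automatic beta and gamma match direct plug-in evaluation", {
  set.seed(60)
  W1 <- matrix(runif(10), 5, 2); W2 <- matrix(runif(10), 5, 2)
  errs <- c(1, 1, 1, 1)
  # make the denominator exactly 2
  W2 <- W1; W2[1, 1] <- W1[1, 1] + sqrt(2)
  expect_equal(default_beta(errs, W1, W2), 0.5)
  # halving the basis difference quadruples beta
  W3 <- W1; W3[1, 1] <- W1[1, 1] + sqrt(2) / 2
  expect_equal(default_beta(errs, W1, W3), 2)
  expect_error(default_beta(errs, W1, W1), "identical")
  expect_equal(default_gamma(c(1, 2, 3, 4)), 4 / log(4))
  expect_equal(default_gamma(c(4, 3, 2, 1)), 4 / log(4))  # order-invariant
  expect_error(default_gamma(c(0, 0, 0, 0)), "zero")
  # random draws against the printed formulas
  for (s in 1:10) {
    set.seed(s)
    e <- runif(4, 0.1, 5)
    Wa <- matrix(runif(8), 4, 2); Wb <- matrix(runif(8), 4, 2)
    expect_equal(default_beta(e, Wa, Wb),
                 sum(0.25 * e) / sum((Wa - Wb)^2), tolerance = 1e-10)
    expect_equal(default_gamma(e), max(abs(e / log(1 / 4))),
                 tolerance = 1e-10)
  }
})

test_that("fit is seed-deterministic and monotone, and flags non-convergence", {
  sim <- simulate_multiview(n_cells = 60, k_true = 2, p = c(24, 24, 24, 30),
                            seed = 5)
  f1 <- awmv(sim$dataset, K = 2, seed = 9, max_iter = 40)
  f2 <- awmv(sim$dataset, K = 2, seed = 9, max_iter = 40)
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$H_star, f2$H_star)
  d <- diff(f1$objective)
  expect_true(all(d <= 1e-8 * pmax(abs(f1$objective[-1]), 1)))
  expect_warning(awmv(sim$dataset, K = 2, seed = 9, max_iter = 2,
                      rel_tol = 1e-14), "converge")
})

test_that("weights track view quality throughout the fit", {
  sim <- simulate_multiview(n_cells = 60, k_true = 2, p = c(24, 24, 24, 30),
                            seed = 6)
  f <- awmv(sim$dataset, K = 2, seed = 3)
  # smaller reconstruction error never gets smaller weight
  ord_e <- order(f$errors)
  expect_true(all(diff(f$weights[ord_e]) <= 1e-12))
})

test_that("ablation switches behave as documented", {
  sim <- simulate_multiview(n_cells = 60, k_true = 2, p = c(24, 24, 24, 30),
                            seed = 8)
  # no-link equals beta = 0
  f_nolink <- awmv(sim$dataset, K = 2, seed = 2, link_enabled = FALSE,
                   max_iter = 20)
  f_b0 <- awmv(sim$dataset, K = 2, seed = 2, beta = 0, max_iter = 20)
  expect_equal(f_nolink$H_star, f_b0$H_star, tolerance = 1e-12)
  # fixed uniform weights stay fixed
  f_fix <- awmv(sim$dataset, K = 2, seed = 2, fixed_weights = "uniform",
                max_iter = 20)
  expect_equal(unname(f_fix$weights), rep(0.25, 4))
  # dropping the gene-activity view fits the remaining three
  f_drop <- awmv(sim$dataset, K = 2, seed = 2, drop_view = "atac_linked",
                 max_iter = 20)
  expect_setequal(f_drop$view_keys,
                  c("rna_linked", "rna_unlinked", "atac_unlinked"))
  expect_false(f_drop$link_enabled)
  # single-view fit works (plain NMF baseline)
  f_rna <- awmv(sim$dataset$views["rna_linked"], K = 2, seed = 2,
                fixed_weights = 1, lambda = 0, max_iter = 10)
  expect_equal(unname(f_rna$weights), 1)
})

test_that("single-view fit with lambda = 0 tracks plain NMF updates exactly", {
  set.seed(70)
  X <- matrix(runif(12 * 8), 12, 8,
              dimnames = list(paste0("g", 1:12), paste0("c", 1:8)))
  Xn <- X / sum(X)
  n_steps <- 50
  f <- suppressWarnings(
    awmv(list(rna_linked = X), K = 2, seed = 4, lambda = 0, beta = 0,
         fixed_weights = 1, gamma = 1, max_iter = n_steps,
         rel_tol = 1e-300, init_nmf_iter = 30))
  init <- nmf_single(Xn, K = 2, seed = 4, n_iter = 30)
  W <- init$W; H <- init$H
  for (i in seq_len(n_steps)) {
    W <- W * (Xn %*% H) / (W %*% crossprod(H) + 1e-12)
    H <- H * crossprod(Xn, W) / (H %*% crossprod(W) + 1e-12)
  }
  expect_equal(f$factors$rna_linked$W, W, tolerance = 1e-12)
  expect_equal(f$factors$rna_linked$H, H, tolerance = 1e-12)
})

test_that("fit rejects invalid inputs", {
  sim <- simulate_multiview(n_cells = 60, k_true = 2, p = c(24, 24, 24, 30),
                            seed = 1)
  expect_error(awmv(sim$dataset, K = 200), "dimension")
  expect_error(awmv(list(bogus = sim$dataset$views$rna_linked)), "named")
  expect_error(awmv(sim$dataset, K = 2, fixed_weights = c(1, 1, 1, 1)),
               "simplex")
})
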