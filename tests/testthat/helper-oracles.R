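# Independent oracles used to cross-check the package implementations.
# These deliberately use different code paths (explicit loops, direct
# plug-in of the printed formulas) from the functions under test.

# mutual-information NMI from the contingency table, looped
oracle_nmi <- function(g, p) {
  n <- length(g)
  gu <- unique(g); pu <- unique(p)
  mi <- 0
  for (a in gu) for (b in pu) {
    nij <- sum(g == a & p == b)
    if (nij > 0)
      mi <- mi + (nij / n) * log((nij / n) / ((sum(g == a) / n) * (sum(p == b) / n)))
  }
  eg <- -sum(sapply(gu, function(a) { q <- sum(g == a) / n; q * log(q) }))
  ep <- -sum(sapply(pu, function(b) { q <- sum(p == b) / n; q * log(q) }))
  if (eg * ep == 0) return(0)
  mi / sqrt(eg * ep)
}

# pair-counting ARI: classify every unordered pair directly
oracle_ari <- function(g, p) {
  n <- length(g)
  a <- b <- c <- d <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sg <- g[i] == g[j]; sp <- p[i] == p[j]
    if (sg && sp) a <- a + 1
    else if (sg && !sp) b <- b + 1
    else if (!sg && sp) c <- c + 1
    else d <- d + 1
  }
  tot <- a + b + c + d
  exp_a <- (a + b) * (a + c) / tot
  den <- ((a + b) + (a + c)) / 2 - exp_a
  if (den == 0) return(1)
  (a - exp_a) / den
}

# mean-absolute-difference Gini over cluster means, looped
oracle_gini <- function(x) {
  m <- length(x)
  if (m < 2 || mean(x) == 0) return(0)
  s <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) s <- s + abs(x[i] - x[j])
  s / (2 * m^2 * mean(x))
}

# term-by-term recomputation of the joint objective
oracle_objective <- function(views, factors, H_star, weights, lambda, beta,
                             gamma, link_enabled = TRUE) {
  keys <- names(views)
  lambda <- rep_len(lambda, length(keys)); names(lambda) <- keys
  total <- 0
  for (k in keys) {
    W <- factors[[k]]$W; H <- factors[[k]]$H
    R <- views[[k]] - W %*% t(H)
    total <- total + weights[[k]] * sum(R^2)
    Q <- diag(colSums(W), ncol(W))
    D <- H %*% Q - H_star
    total <- total + lambda[[k]] * sum(D^2)
  }
  if (link_enabled && all(c("rna_linked", "atac_linked") %in% keys)) {
    D <- factors$rna_linked$W - factors$atac_linked$W
    total <- total + beta * sum(D^2)
  }
  total + gamma * sum(weights * log(weights))
}

# small random multi-view problem (unstructured, for update-rule tests)
random_views <- function(p = c(6, 6, 6, 9), n = 5, seed = 1) {
  set.seed(seed)
  keys <- c("rna_linked", "rna_unlinked", "atac_linked", "atac_unlinked")
  vs <- list()
  for (i in seq_along(keys)) {
    m <- matrix(runif(p[i] * n), p[i], n)
    dimnames(m) <- list(sprintf("%s_f%02d", keys[i], seq_len(p[i])),
                        sprintf("c%02d", seq_len(n)))
    vs[[keys[i]]] <- m
  }
  vs
}

# random non-negative factor state consistent with the given views
random_state <- function(views, K = 2, seed = 1) {
  set.seed(seed)
  factors <- lapply(views, function(X)
    list(W = matrix(runif(nrow(X) * K), nrow(X), K),
         H = matrix(runif(ncol(X) * K), ncol(X), K)))
  H_star <- matrix(runif(ncol(views[[1]]) * K), ncol(views[[1]]), K)
  w <- runif(length(views)); w <- w / sum(w); names(w) <- names(views)
  list(factors = factors, H_star = H_star, weights = w)
}
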