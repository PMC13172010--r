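# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: plain coordinate descent, brute-force component
# counting, dense eigendecomposition.

# Coordinate-descent lasso for objective (1/2n)||y - Xb||^2 + lambda||b||_1,
# X assumed column-standardized to mean 0 and norm sqrt(n).
oracle_lasso <- function(x, y, lambda, max_iter = 20000, tol = 1e-12) {
  n <- nrow(x); p <- ncol(x)
  b <- rep(0, p)
  r <- y
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      cj <- sum(x[, j] * r) / n + b[j]
      bj_new <- sign(cj) * max(abs(cj) - lambda, 0)
      if (bj_new != b[j]) {
        r <- r - (bj_new - b[j]) * x[, j]
        delta <- max(delta, abs(bj_new - b[j]))
        b[j] <- bj_new
      }
    }
    if (delta < tol) break
  }
  b
}

# standardization matching the package convention (1/n variance)
oracle_standardize <- function(x) {
  cen <- sweep(x, 2, colMeans(x))
  sweep(cen, 2, sqrt(colSums(cen^2) / nrow(x)), "/")
}

# LCC sizes along a removal order via igraph components on induced subgraphs
oracle_decay <- function(g, ord) {
  nm <- igraph::V(g)$name
  vapply(0:length(ord), function(k) {
    rem <- setdiff(nm, ord[seq_len(k)])
    if (!length(rem)) return(0)
    max(igraph::components(igraph::induced_subgraph(g, rem))$csize)
  }, numeric(1))
}

# PCA scores via explicit eigendecomposition of the covariance matrix
oracle_pca_scores <- function(m, k = 2) {
  cen <- scale(m, center = TRUE, scale = FALSE)
  ei <- eigen(cov(cen), symmetric = TRUE)
  scores <- cen %*% ei$vectors[, seq_len(k), drop = FALSE]
  list(scores = scores, values = ei$values)
}

# support-recovery F1 of an inferred network against a true adjacency
recovery_f1 <- function(net, truth) {
  est <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  nm <- rownames(est)
  tr <- truth[nm, nm]
  tp <- sum(est * tr) / 2
  fp <- sum(est * (1 - tr)) / 2
  fn <- sum((1 - est) * tr) / 2
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}
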