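#' Standardize CLR columns for neighborhood regression
#'
#' Centers each column and scales it to unit norm `sqrt(n)` (the 1/n variance
#' convention, matching the coordinate-descent lasso objective
#' `(1/2n)||y - Xb||^2 + lambda ||b||_1`). Constant columns are dropped with
#' a warning.
#' @noRd
standardize_clr <- function(clr) {
  x <- unclass(as.matrix(clr))
  n <- nrow(x)
  cen <- sweep(x, 2, colMeans(x))
  s <- sqrt(colSums(cen^2) / n)
  const <- s < 1e-12
  if (any(const)) {
    warning("dropping constant CLR column(s): ",
            paste(colnames(x)[const], collapse = ", "))
    cen <- cen[, !const, drop = FALSE]
    s <- s[!const]
  }
  sweep(cen, 2, s, "/")
}

#' Largest penalty of the neighborhood-selection path
#'
#' The smallest lambda at which every per-taxon lasso is empty: the maximum
#' absolute standardized cross-covariance between any pair of distinct taxa.
#'
#' @param clr CLR matrix (samples x taxa).
#' @return Positive scalar `lambda_max`.
#' @export
compute_lambda_max <- function(clr) {
  xs <- standardize_clr(clr)
  if (ncol(xs) < 2 || nrow(xs) < 3)
    stop("need at least 2 taxa and 3 samples")
  s <- crossprod(xs) / nrow(xs)
  diag(s) <- 0
  max(abs(s))
}

#' Log-spaced penalty path
#'
#' @param lambda_max Path endpoint (empty graph); typically
#'   [compute_lambda_max()].
#' @param n_lambda Number of penalties (default 30).
#' @param min_ratio Smallest/largest penalty ratio (default 0.01).
#' @return Strictly decreasing numeric vector of class `lambda_path`.
#' @export
lambda_path <- function(lambda_max, n_lambda = 30L, min_ratio = 0.01) {
  stopifnot(lambda_max > 0, n_lambda >= 2, min_ratio > 0, min_ratio < 1)
  structure(exp(seq(log(lambda_max), log(lambda_max * min_ratio),
                    length.out = n_lambda)), class = "lambda_path")
}

#' Meinshausen-Buhlmann neighborhood regressions along a penalty path
#'
#' For each taxon j, fits the L1-penalized regression of its standardized CLR
#' column on all other columns at every penalty in `lambdas`. Row j of each
#' coefficient matrix holds taxon j's neighborhood.
#'
#' @param clr CLR matrix.
#' @param lambdas Decreasing penalty vector.
#' @param thresh glmnet convergence threshold.
#' @return List of p x p coefficient matrices, one per penalty.
#' @export
fit_mb_path <- function(clr, lambdas, thresh = 1e-9) {
  xs <- standardize_clr(clr)
  p <- ncol(xs)
  if (p < 2) stop("need at least 2 non-constant taxa")
  betas <- lapply(seq_along(lambdas), function(i)
    matrix(0, p, p, dimnames = list(colnames(xs), colnames(xs))))
  for (j in seq_len(p)) {
    if (p == 2) {
      # single-predictor lasso has the closed soft-threshold solution
      cc <- sum(xs[, -j] * xs[, j]) / nrow(xs)
      for (i in seq_along(lambdas))
        betas[[i]][j, -j] <- sign(cc) * max(abs(cc) - lambdas[i], 0)
      next
    }
    fit <- glmnet::glmnet(xs[, -j, drop = FALSE], xs[, j],
                          lambda = lambdas, standardize = FALSE,
                          intercept = FALSE, thresh = thresh)
    cf <- as.matrix(coef(fit))[-1, , drop = FALSE]  # drop intercept row
    # glmnet may stop early on the path; missing columns stay at last fit
    for (i in seq_along(lambdas)) {
      col <- min(i, ncol(cf))
      betas[[i]][j, -j] <- cf[, col]
    }
  }
  betas
}

#' Neighborhood regression at a single penalty
#'
#' @inheritParams fit_mb_path
#' @param lambda Positive penalty.
#' @return p x p coefficient matrix (row j = taxon j's neighborhood).
#' @export
fit_mb_graph <- function(clr, lambda, thresh = 1e-9) {
  stopifnot(lambda > 0)
  # a short warm-start path improves glmnet's convergence to the exact
  # single-lambda solution
  lambdas <- c(lambda * 4, lambda * 2, lambda)
  fit_mb_path(clr, lambdas, thresh = thresh)[[3]]
}

#' Symmetrize a directed coefficient matrix into a network
#'
#' OR rule: edge (i, j) exists when either beta_ij or beta_ji is nonzero;
#' its weight is the entry of larger magnitude (sign preserved). The AND
#' variant requires both directions nonzero. Conflicting signs between the
#' two directions are resolved toward the larger magnitude and counted.
#'
#' @param coefficients p x p matrix from [fit_mb_graph()].
#' @param rule `"or"` (default) or `"and"`.
#' @param abundances Optional named mean relative abundances for the nodes.
#' @param tol Entries below this magnitude are treated as zero.
#' @return A [co_network()].
#' @export
symmetrize <- function(coefficients, rule = c("or", "and"),
                       abundances = NULL, tol = 1e-10) {
  rule <- match.arg(rule)
  b <- as.matrix(coefficients)
  p <- nrow(b)
  nm <- rownames(b)
  if (is.null(nm)) nm <- paste0("v", seq_len(p))
  sel <- abs(b) > tol
  keep <- if (rule == "or") sel | t(sel) else sel & t(sel)
  w <- ifelse(abs(b) >= abs(t(b)), b, t(b))
  conflicts <- sum(sel & t(sel) & sign(b) != sign(t(b)) &
                     upper.tri(b))
  if (conflicts > 0)
    message(conflicts, " edge(s) had conflicting direction signs; ",
            "larger magnitude kept")
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  edges <- data.frame(source = nm[idx[, 1]], target = nm[idx[, 2]],
                      weight = w[idx])
  co_network(edges, abundances = abundances, nodes = nm)
}

#' StARS penalty selection over subsampled neighborhood fits
#'
#' Draws `n_subsamples` subsamples without replacement of size
#' `b = min(floor(10 sqrt(n)), floor(0.8 n))`, fits the penalty path on each,
#' and measures per-penalty average edge instability `mean(2 theta (1 -
#' theta))` over all node pairs, where `theta` is an edge's selection
#' frequency. The instability curve is monotonized by a running maximum along
#' decreasing penalties and the selected penalty is the smallest (densest)
#' one whose monotonized instability stays at or below `beta`. The final
#' network is the symmetrized full-data fit at the selected penalty.
#'
#' @param clr CLR matrix (needs >= 20 samples).
#' @param path Penalty vector; default [lambda_path()] from the data.
#' @param n_subsamples Number of subsamples (default 100).
#' @param beta Instability threshold (default 0.05).
#' @param seed Integer seed governing subsample draws only.
#' @param rule Symmetrization rule.
#' @param abundances Optional node abundances for the returned network.
#' @return Object of class `stars_result`: `lambda_path`, `instability`,
#'   `instability_monotone`, `beta`, `selected_lambda`, `selected_index`,
#'   `edge_stability` (p x p selection frequencies at the selected penalty),
#'   `network`, `n_subsamples`, `subsample_size`, `seed`,
#'   `criterion_unreachable`.
#' @export
stars_select <- function(clr, path = NULL, n_subsamples = 100L, beta = 0.05,
                         seed = 1L, rule = "or", abundances = NULL) {
  x <- unclass(as.matrix(clr))
  n <- nrow(x)
  if (n < 20) stop("StARS needs at least 20 samples")
  if (is.null(path)) path <- lambda_path(compute_lambda_max(x))
  nl <- length(path)
  p <- ncol(x)
  b <- min(floor(10 * sqrt(n)), floor(0.8 * n))
  counts <- array(0L, dim = c(p, p, nl))
  subsamples <- with_seed(derive_seed(seed, "stars"), {
    lapply(seq_len(n_subsamples), function(r) sample.int(n, b))
  })
  for (r in seq_len(n_subsamples)) {
    betas <- fit_mb_path(x[subsamples[[r]], , drop = FALSE], path)
    for (i in seq_len(nl)) {
      sel <- abs(betas[[i]]) > 1e-10
      counts[, , i] <- counts[, , i] + (sel | t(sel))
    }
  }
  theta <- counts / n_subsamples
  npairs <- p * (p - 1) / 2
  instab <- vapply(seq_len(nl), function(i) {
    th <- theta[, , i][upper.tri(theta[, , i])]
    sum(2 * th * (1 - th)) / npairs
  }, numeric(1))
  mono <- cummax(instab)  # path is decreasing, instability running max
  ok <- which(mono <= beta)
  unreachable <- length(ok) == 0
  sel_idx <- if (unreachable) {
    warning("no penalty satisfies the StARS criterion; returning the ",
            "penalty with minimal instability")
    which.min(mono)
  } else max(ok)  # smallest penalty (densest graph) still under beta
  selected <- path[sel_idx]
  full_beta <- fit_mb_graph(x, selected)
  net <- symmetrize(full_beta, rule = rule, abundances = abundances)
  es <- theta[, , sel_idx]
  dimnames(es) <- list(colnames(full_beta), colnames(full_beta))
  structure(list(lambda_path = path, instability = instab,
                 instability_monotone = mono, beta = beta,
                 selected_lambda = selected, selected_index = sel_idx,
                 edge_stability = es, network = net,
                 n_subsamples = n_subsamples, subsample_size = b,
                 seed = seed, criterion_unreachable = unreachable),
            class = "stars_result")
}

#' Full inference pipeline: filter, CLR, StARS, network
#'
#' Applies the prevalence/abundance filter (abundance > `min_abund` in at
#' least a `min_prev` fraction of samples), CLR-transforms, selects the
#' penalty by StARS and returns the co-occurrence network with per-node mean
#' relative abundances and provenance attached.
#'
#' @param table An [abundance_table()].
#' @param min_abund,min_prev Filter thresholds (defaults 0.001 and 0.10).
#' @param n_lambda,min_ratio Penalty path shape.
#' @param n_subsamples,beta,seed StARS settings.
#' @param rule Symmetrization rule.
#' @param pseudocount CLR zero replacement (default global half-minimum).
#' @param filter Set `FALSE` to skip filtering (already-filtered input).
#' @return A [co_network()] with a `stars` attribute holding the
#'   `stars_result`.
#' @export
infer_network <- function(table, min_abund = 0.001, min_prev = 0.10,
                          n_lambda = 30L, min_ratio = 0.01,
                          n_subsamples = 100L, beta = 0.05, seed = 1L,
                          rule = "or", pseudocount = NULL, filter = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  if (filter)
    table <- prevalence_abundance_filter(table, min_abund, min_prev)
  clr <- clr_transform(table, pseudocount = pseudocount)
  path <- lambda_path(compute_lambda_max(clr), n_lambda, min_ratio)
  ab <- colMeans(table$values)
  res <- stars_select(clr, path = path, n_subsamples = n_subsamples,
                      beta = beta, seed = seed, rule = rule,
                      abundances = ab)
  net <- res$network
  net <- igraph::set_graph_attr(net, "provenance", list(
    min_abund = min_abund, min_prev = min_prev, n_lambda = n_lambda,
    min_ratio = min_ratio, n_subsamples = n_subsamples, beta = beta,
    seed = seed, rule = rule, selected_lambda = res$selected_lambda,
    n_samples = nrow(table$values), n_taxa = ncol(table$values)))
  attr(net, "stars") <- res
  net
}

#' Write a StARS result to TSV files
#'
#' Emits the penalty/instability curve (`<prefix>_stars.tsv`, columns
#' lambda, instability, instability_monotone) and the per-edge selection
#' frequencies at the selected penalty (`<prefix>_edge_stability.tsv`,
#' long format over node pairs).
#'
#' @param stars A `stars_result` from [stars_select()].
#' @param prefix Output path prefix.
#' @return Invisibly, the two written paths.
#' @export
write_stars_result <- function(stars, prefix) {
  stopifnot(inherits(stars, "stars_result"))
  curve_path <- paste0(prefix, "_stars.tsv")
  write.table(data.frame(lambda = as.numeric(stars$lambda_path),
                         instability = stars$instability,
                         instability_monotone = stars$instability_monotone),
              curve_path, sep = "\t", quote = FALSE, row.names = FALSE)
  es <- stars$edge_stability
  idx <- which(upper.tri(es), arr.ind = TRUE)
  stab_path <- paste0(prefix, "_edge_stability.tsv")
  write.table(data.frame(source = rownames(es)[idx[, 1]],
                         target = colnames(es)[idx[, 2]],
                         stability = es[idx]),
              stab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(curve_path, stab_path))
}
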