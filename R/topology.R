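#' Edge distances for weighted shortest paths
#'
#' Shortest-path algorithms read weights as costs, while co-occurrence
#' weights are association strengths; each weight is therefore subtracted
#' from 1 (d = 1 - w, applied literally, so negative associations map to
#' distances above 1).
#'
#' @param network A [co_network()] (igraph) with edge weights.
#' @return The same graph with edge attribute `distance` = 1 - weight.
#' @export
distance_graph <- function(network) {
  w <- igraph::E(network)$weight
  if (is.null(w)) stop("network has no edge weights")
  if (any(w >= 1)) stop("weights must be < 1 for the distance transform")
  igraph::set_edge_attr(network, "distance", value = 1 - w)
}

edge_distances <- function(network, weighted) {
  if (!weighted) return(NA)  # igraph: NA => unweighted
  if (is.null(igraph::E(network)$weight)) return(NA)  # unweighted graph
  igraph::E(distance_graph(network))$distance
}

#' Extract the largest connected component
#'
#' Ties between equally sized components are broken toward the component
#' containing the lexicographically smallest node identifier.
#'
#' @param network igraph/[co_network()].
#' @return Induced subgraph on the largest component.
#' @export
extract_lcc <- function(network) {
  if (igraph::vcount(network) == 0) stop("empty graph")
  comp <- igraph::components(network)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1) {
    first_member <- vapply(big, function(k)
      min(igraph::V(network)$name[comp$membership == k]), character(1))
    big <- big[order(first_member)][1]
  }
  igraph::induced_subgraph(network,
                           which(comp$membership == big),
                           impl = "copy_and_delete")
}

#' Global network metrics
#'
#' Order, size, percentage of negative edges, edge density and component
#' count are reported for the full graph; mean degree, shortest path length,
#' betweenness and closeness for the largest connected component (weighted
#' shortest paths over d = 1 - w by default).
#'
#' @param network A [co_network()].
#' @param weighted Use the 1 - w distance transform for path-based metrics.
#' @return One-row data.frame of class `global_metrics`.
#' @export
global_metrics <- function(network, weighted = TRUE) {
  n <- igraph::vcount(network)
  m <- igraph::ecount(network)
  w <- igraph::E(network)$weight
  pct_neg <- if (m > 0 && !is.null(w)) 100 * sum(w < 0) / m else 0
  comp <- igraph::components(network)
  lcc <- extract_lcc(network)
  nm <- node_metrics(lcc, weighted = weighted)
  nl <- igraph::vcount(lcc)
  d <- igraph::distances(lcc, weights = edge_distances(lcc, weighted))
  mean_sp <- if (nl > 1) mean(d[upper.tri(d)]) else 0
  out <- data.frame(
    order = n, size = m, pct_negative_edges = pct_neg,
    edge_density = if (n > 1) 2 * m / (n * (n - 1)) else 0,
    n_components = comp$no, lcc_order = nl,
    mean_degree = mean(nm$degree),
    mean_shortest_path = mean_sp,
    mean_betweenness = mean(nm$betweenness),
    mean_closeness = mean(nm$closeness))
  class(out) <- c("global_metrics", class(out))
  out
}

#' Per-node metrics on a connected graph
#'
#' Degree (unweighted), normalized betweenness (divided by
#' `(n-1)(n-2)/2`), normalized closeness (`(n-1)` over the sum of shortest
#' path lengths) and coreness. Path-based metrics use the 1 - w distance
#' transform when `weighted`.
#'
#' @param network Connected igraph/[co_network()]; run [extract_lcc()]
#'   first on fragmented graphs.
#' @param weighted Logical.
#' @return data.frame with columns `taxon`, `degree`, `betweenness`,
#'   `closeness`, `coreness`.
#' @export
node_metrics <- function(network, weighted = TRUE) {
  if (igraph::components(network)$no > 1)
    stop("graph is disconnected; extract the LCC first (extract_lcc)")
  n <- igraph::vcount(network)
  wts <- edge_distances(network, weighted)
  btw <- igraph::betweenness(network, weights = wts, directed = FALSE)
  if (n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  clo <- if (n > 1) {
    d <- igraph::distances(network, weights = wts)
    (n - 1) / rowSums(d)
  } else 0
  data.frame(taxon = igraph::V(network)$name,
             degree = igraph::degree(network),
             betweenness = unname(btw), closeness = unname(clo),
             coreness = igraph::coreness(network),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' k-core histogram
#'
#' Per-node coreness (iterative minimum-degree peeling) over the full
#' network, reported as the percentage of total nodes at each maximum k.
#'
#' @param network igraph/[co_network()].
#' @return data.frame with columns `k` and `pct_nodes`.
#' @export
kcore_histogram <- function(network) {
  k <- igraph::coreness(network)
  tab <- table(k)
  data.frame(k = as.integer(names(tab)),
             pct_nodes = 100 * as.numeric(tab) / length(k))
}

#' Compare node-metric distributions across networks
#'
#' Kruskal-Wallis rank test per metric across groups, Benjamini-Hochberg
#' adjusted across the metric family; optional Dunn-style pairwise post-hoc
#' with FDR correction.
#'
#' @param metrics_by_group Named list of [node_metrics()] data.frames.
#' @param metrics Metric columns to test.
#' @param posthoc Also run pairwise Dunn tests.
#' @return data.frame with statistic, p-value and BH-adjusted p per metric;
#'   when `posthoc`, a `posthoc` attribute with pairwise results.
#' @export
compare_node_distributions <- function(metrics_by_group,
                                       metrics = c("degree", "betweenness",
                                                   "closeness", "coreness"),
                                       posthoc = FALSE) {
  if (length(metrics_by_group) < 2) stop("need at least 2 groups")
  groups <- names(metrics_by_group)
  res <- lapply(metrics, function(m) {
    vals <- lapply(metrics_by_group, function(df) df[[m]])
    pooled <- unlist(vals)
    if (length(unique(pooled)) == 1) {
      warning("metric '", m, "' is constant across all groups; p = 1")
      return(data.frame(metric = m, statistic = 0, p_value = 1))
    }
    kt <- kruskal.test(vals)
    data.frame(metric = m, statistic = unname(kt$statistic),
               p_value = kt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  if (posthoc) {
    ph <- do.call(rbind, lapply(metrics, function(m) {
      vals <- lapply(metrics_by_group, function(df) df[[m]])
      dt <- dunn_test(vals)
      cbind(metric = m, dt)
    }))
    ph$p_adjusted <- p.adjust(ph$p_value, method = "BH")
    attr(out, "posthoc") <- ph
  }
  out
}

# Dunn's pairwise rank test (normal approximation with tie correction).
dunn_test <- function(vals) {
  g <- rep(names(vals), lengths(vals))
  x <- unlist(vals)
  r <- rank(x)
  n <- length(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mr <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  pairs <- utils::combn(names(vals), 2)
  do.call(rbind, apply(pairs, 2, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    z <- (mr[pr[1]] - mr[pr[2]]) / se
    data.frame(group1 = pr[1], group2 = pr[2], z = unname(z),
               p_value = 2 * stats::pnorm(-abs(unname(z))))
  }))
}
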