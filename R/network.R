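#' Construct a signed weighted co-occurrence network
#'
#' A thin igraph wrapper: an undirected simple graph over taxa whose edges
#' carry a signed weight in (-1, 1) (a conditional-dependence strength) and a
#' `sign` label, and whose nodes may carry a mean relative abundance used for
#' abundance-ordered attacks.
#'
#' @param edges data.frame with columns `source`, `target`, `weight`.
#' @param abundances Optional named numeric vector of per-taxon mean relative
#'   abundances; names matching node ids.
#' @param nodes Optional character vector of node ids (to retain isolated
#'   nodes absent from the edge list).
#' @param provenance Optional list recording how the network was built.
#' @return igraph object with class `co_network`.
#' @export
co_network <- function(edges, abundances = NULL, nodes = NULL,
                       provenance = NULL) {
  edges <- as.data.frame(edges)
  names(edges)[1:3] <- c("source", "target", "weight")
  ids <- union(nodes, union(edges$source, edges$target))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  if (igraph::any_loop(g)) stop("self-loops are not allowed")
  igraph::E(g)$sign <- ifelse(igraph::E(g)$weight >= 0, "positive",
                              "negative")
  if (!is.null(abundances)) {
    ab <- abundances[igraph::V(g)$name]
    igraph::V(g)$abundance <- unname(ab)
  }
  if (!is.null(provenance)) g <- igraph::set_graph_attr(g, "provenance",
                                                        provenance)
  class(g) <- c("co_network", class(g))
  g
}

#' @export
print.co_network <- function(x, ...) {
  cat("co_network:", igraph::vcount(x), "taxa,", igraph::ecount(x),
      "edges (", sum(igraph::E(x)$weight < 0), "negative )\n")
  invisible(x)
}
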