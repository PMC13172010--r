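# Toy graph constructors used across test files.

named_graph <- function(g, prefix = "n") {
  igraph::V(g)$name <- sprintf("%s%02d", prefix, seq_len(igraph::vcount(g)))
  g
}

make_clique <- function(n) named_graph(igraph::make_full_graph(n))

make_star <- function(leaves) {
  # center first so it gets the lexicographically smallest name
  named_graph(igraph::make_star(leaves + 1, mode = "undirected", center = 1))
}

make_path <- function(n) named_graph(igraph::make_ring(n, circular = FALSE))

with_weights <- function(g, w) {
  igraph::E(g)$weight <- rep(w, length.out = igraph::ecount(g))
  g
}

random_weighted_graph <- function(n, p_edge = 0.2, neg_frac = 0.2) {
  g <- named_graph(igraph::sample_gnp(n, p_edge))
  m <- igraph::ecount(g)
  if (m > 0)
    igraph::E(g)$weight <- runif(m, 0.05, 0.8) *
      ifelse(runif(m) < neg_frac, -1, 1)
  g
}

as_co_network <- function(g, abundances = NULL) {
  el <- igraph::as_data_frame(g, what = "edges")
  if (is.null(el$weight)) el$weight <- 0.5
  names(el)[1:2] <- c("source", "target")
  co_network(el, abundances = abundances, nodes = igraph::V(g)$name)
}
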