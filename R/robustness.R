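#' Remove negative edges from a signed network
#'
#' Percolation analysis considers only positive microbe-microbe
#' associations; negative edges are dropped, nodes retained.
#'
#' @param network A [co_network()].
#' @return Subgraph with only positive-weight edges.
#' @export
strip_negative_edges <- function(network) {
  w <- igraph::E(network)$weight
  if (is.null(w)) return(network)
  out <- igraph::delete_edges(network, which(w < 0))
  if (igraph::ecount(out) == 0 && igraph::ecount(network) > 0)
    warning("all edges were negative; the stripped network is empty")
  out
}

#' Node-removal order for an attack
#'
#' Static ordering computed once on the intact graph: by decreasing degree
#' or betweenness, by decreasing/increasing mean relative abundance, or a
#' seeded uniform permutation for random attacks. Ties are broken by
#' ascending node identifier.
#'
#' @param network Graph to attack (typically the LCC after
#'   [strip_negative_edges()]).
#' @param strategy One of `"random"`, `"degree"`, `"betweenness"`,
#'   `"abundance_desc"`, `"abundance_asc"`.
#' @param seed Seed for `strategy = "random"`.
#' @param weighted Weighted betweenness (1 - w distances).
#' @return Character vector: a permutation of the node names.
#' @export
attack_order <- function(network, strategy = c("degree", "betweenness",
                                               "abundance_desc",
                                               "abundance_asc", "random"),
                         seed = 1L, weighted = TRUE) {
  strategy <- match.arg(strategy)
  nm <- igraph::V(network)$name
  if (strategy == "random") {
    return(with_seed(derive_seed(seed, "attack"), nm[sample.int(length(nm))]))
  }
  key <- switch(strategy,
    degree = igraph::degree(network),
    betweenness = igraph::betweenness(network,
                                      weights = edge_distances(network,
                                                               weighted),
                                      directed = FALSE),
    abundance_desc = ,
    abundance_asc = {
      ab <- igraph::V(network)$abundance
      if (is.null(ab) || anyNA(ab))
        stop("abundance-ordered attacks need node abundance annotations")
      if (strategy == "abundance_asc") -ab else ab
    })
  nm[order(-key, nm)]
}

#' Execute one attack and record the LCC decay curve
#'
#' Removes nodes one at a time in the given order, recording the size of
#' the largest connected component of the remaining graph after each
#' removal (components may re-rank as the graph fragments). Implemented by
#' reverse node addition with union-find, linear in nodes + edges.
#'
#' @param network Graph to attack.
#' @param order Permutation of the node names.
#' @return data.frame of class `decay_curve`: `n_removed` (0..N),
#'   `fraction_removed`, `lcc_size`, `lcc_norm` (relative to the initial
#'   LCC).
#' @export
attack_once <- function(network, order) {
  nm <- igraph::V(network)$name
  if (length(order) != length(nm) || !setequal(order, nm) ||
      anyDuplicated(order))
    stop("order must be a permutation of the node set")
  n <- length(nm)
  el <- igraph::as_edgelist(network, names = TRUE)
  pos <- match(order, nm)           # order index -> vertex index
  when <- integer(n); when[pos] <- seq_len(n)  # vertex index -> removal step
  # reverse process: add nodes back from last-removed to first-removed,
  # attaching edges whose other endpoint is already present
  e1 <- match(el[, 1], nm); e2 <- match(el[, 2], nm)
  # an edge becomes active when the earlier-removed endpoint rejoins
  activate_at <- pmin(when[e1], when[e2])
  parent <- seq_len(n); size <- rep(1L, n); present <- rep(FALSE, n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges_by_step <- split(seq_along(activate_at), activate_at)
  lcc_after <- numeric(n + 1)  # lcc_after[k+1] = LCC size after k removals
  best <- 0L
  for (step in n:1) {
    v <- pos[step]
    present[v] <- TRUE
    if (best < 1L) best <- 1L
    for (ei in edges_by_step[[as.character(step)]]) {
      a <- e1[ei]; b <- e2[ei]
      if (present[a] && present[b]) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) {
          if (size[ra] < size[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
          parent[rb] <- ra
          size[ra] <- size[ra] + size[rb]
          if (size[ra] > best) best <- size[ra]
        }
      }
    }
    lcc_after[step] <- best
  }
  lcc_after[n + 1] <- 0
  n0 <- lcc_after[1]
  out <- data.frame(n_removed = 0:n, fraction_removed = (0:n) / n,
                    lcc_size = lcc_after,
                    lcc_norm = if (n0 > 0) lcc_after / n0 else 0)
  class(out) <- c("decay_curve", class(out))
  out
}

#' NR50: node removals to halve the largest connected component
#'
#' The percentage of nodes that must be removed so that the remaining LCC
#' first has at most half the nodes of the initial LCC:
#' `100 * k / N0` with `N0` the initial LCC size and `k` the smallest
#' removal count with `lcc_size <= N0 / 2`. With
#' `denominator = "graph"` the percentage is taken over all nodes of the
#' attacked graph instead of the initial LCC.
#'
#' @param curve A [attack_once()] decay curve.
#' @param denominator `"lcc"` (default) or `"graph"`.
#' @return Percentage in (0, 100].
#' @export
nr50 <- function(curve, denominator = c("lcc", "graph")) {
  denominator <- match.arg(denominator)
  n0 <- curve$lcc_size[1]
  k <- curve$n_removed[which(curve$lcc_size <= n0 / 2)[1]]
  den <- if (denominator == "lcc") n0 else max(curve$n_removed)
  100 * k / den
}

#' Percolation threshold of a decay curve
#'
#' Finite-difference derivative of the normalized LCC size against the
#' fraction of removed nodes; the threshold is the fraction removed at the
#' step with the most negative slope (earliest on ties). When the steepest
#' slope does not exceed the uniform-decay slope by `min_slope_factor`, no
#' phase transition is evident and `NA` is returned with attribute
#' `undefined = TRUE`.
#'
#' @param curve A [attack_once()] decay curve.
#' @param min_slope_factor Detectability guard (default 1.5 times the
#'   uniform slope).
#' @return Percentage, or `NA` when undefined.
#' @export
percolation_threshold <- function(curve, min_slope_factor = 1.5) {
  if (nrow(curve) < 3) stop("curve must have at least 3 points")
  slope <- diff(curve$lcc_norm) / diff(curve$fraction_removed)
  uniform <- (curve$lcc_norm[nrow(curve)] - curve$lcc_norm[1]) /
    (curve$fraction_removed[nrow(curve)] - curve$fraction_removed[1])
  idx <- which.min(slope)  # which.min returns the earliest minimum
  if (slope[idx] > min_slope_factor * uniform) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  100 * curve$fraction_removed[idx + 1]
}

#' Run the full attack suite on a network
#'
#' Strips negative edges, restricts to the LCC, and runs every requested
#' strategy: deterministic strategies give one curve each; random attacks
#' run `n_reps` seeded permutations and report per-rep NR50 values, their
#' mean and sd, and the mean decay curve with an sd band.
#'
#' @param network A [co_network()].
#' @param strategies Subset of degree/betweenness/abundance_desc/
#'   abundance_asc/random.
#' @param n_reps Random-attack repetitions (default 1000).
#' @param seed Root seed; each repetition uses a derived sub-seed so results
#'   do not depend on `n_reps` ordering.
#' @param weighted Weighted betweenness ordering.
#' @param nr50_denominator Passed to [nr50()].
#' @return Named list of `robustness_result` objects: for deterministic
#'   strategies `curve`, `nr50`, `pc`; for random additionally `nr50_reps`,
#'   `nr50_mean`, `nr50_sd`, `mean_curve`.
#' @export
run_attack_suite <- function(network,
                             strategies = c("random", "degree",
                                            "betweenness",
                                            "abundance_desc",
                                            "abundance_asc"),
                             n_reps = 1000L, seed = 1L, weighted = TRUE,
                             nr50_denominator = "lcc") {
  g <- extract_lcc(strip_negative_edges(network))
  if (igraph::vcount(g) < 2) stop("LCC after negative-edge stripping is empty")
  out <- list()
  for (st in strategies) {
    if (st == "random") {
      curves <- lapply(seq_len(n_reps), function(r)
        attack_once(g, attack_order(g, "random",
                                    seed = derive_seed(seed, "rep", r))))
      nrs <- vapply(curves, nr50, numeric(1),
                    denominator = nr50_denominator)
      norm_mat <- vapply(curves, function(cv) cv$lcc_norm,
                         numeric(nrow(curves[[1]])))
      mean_curve <- data.frame(
        fraction_removed = curves[[1]]$fraction_removed,
        lcc_norm_mean = rowMeans(norm_mat),
        lcc_norm_sd = apply(norm_mat, 1, sd))
      out[[st]] <- structure(list(
        strategy = st, n_reps = n_reps, nr50_reps = nrs,
        nr50_mean = mean(nrs), nr50_sd = sd(nrs),
        mean_curve = mean_curve, curve = curves[[1]]),
        class = "robustness_result")
    } else {
      cv <- attack_once(g, attack_order(g, st, weighted = weighted))
      out[[st]] <- structure(list(
        strategy = st, curve = cv,
        nr50 = nr50(cv, denominator = nr50_denominator),
        pc = percolation_threshold(cv)), class = "robustness_result")
    }
  }
  out
}
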