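#' Detect keystone taxa
#'
#' Keystone taxa are nodes whose degree AND betweenness centrality both
#' strictly exceed the q-th percentile (default 90th) of the respective
#' metric over the graph's nodes. Percentiles use linear interpolation
#' between order statistics (quantile type 7).
#'
#' @param x A [node_metrics()] data.frame, or a connected
#'   igraph/[co_network()] (metrics are computed on it, weighted).
#' @param q Percentile in (0, 1); default 0.9.
#' @param weighted Passed to [node_metrics()] when `x` is a graph.
#' @return Character vector of keystone taxa (possibly empty).
#' @export
detect_keystones <- function(x, q = 0.9, weighted = TRUE) {
  stopifnot(q > 0, q < 1)
  nm <- if (is.data.frame(x)) x else node_metrics(x, weighted = weighted)
  if (nrow(nm) < 10)
    warning("fewer than 10 nodes; percentile thresholds are unstable")
  deg_thr <- quantile(nm$degree, q, type = 7, names = FALSE)
  btw_thr <- quantile(nm$betweenness, q, type = 7, names = FALSE)
  nm$taxon[nm$degree > deg_thr & nm$betweenness > btw_thr]
}

#' Keystone composition across an ensemble of networks
#'
#' Computes the keystone set of each member network (on its LCC), assembles
#' the presence/absence matrix over the union of all keystones, and reports
#' per-group set sizes (union), core sets (taxa keystone in every member of
#' a group) and pairwise between-group intersection counts of the union
#' sets.
#'
#' @param networks List of [co_network()] objects (>= 2).
#' @param groups Character vector of group labels, one per network; default
#'   a single group.
#' @param q Keystone percentile.
#' @param weighted Weighted betweenness.
#' @return List with `presence` (binary matrix, rows = networks), `sets`
#'   (list of keystone sets), `set_sizes` (per-group union sizes),
#'   `core_sets`, `intersections` (data.frame of pairwise group
#'   intersection counts).
#' @export
ensemble_keystones <- function(networks, groups = NULL, q = 0.9,
                               weighted = TRUE) {
  if (length(networks) < 2) stop("need at least 2 networks")
  if (is.null(groups)) groups <- rep("all", length(networks))
  stopifnot(length(groups) == length(networks))
  sets <- lapply(networks, function(g)
    suppressWarnings(detect_keystones(extract_lcc(g), q = q,
                                      weighted = weighted)))
  universe <- sort(Reduce(union, sets))
  presence <- matrix(0L, length(networks), length(universe),
                     dimnames = list(
                       paste(groups, seq_along(networks), sep = "_rep"),
                       universe))
  for (i in seq_along(sets)) presence[i, sets[[i]]] <- 1L
  by_group <- split(seq_along(sets), groups)
  unions <- lapply(by_group, function(i) Reduce(union, sets[i]))
  cores <- lapply(by_group, function(i) Reduce(intersect, sets[i]))
  gn <- names(by_group)
  inter <- if (length(gn) >= 2) {
    prs <- utils::combn(gn, 2)
    data.frame(group1 = prs[1, ], group2 = prs[2, ],
               intersection = apply(prs, 2, function(pr)
                 length(intersect(unions[[pr[1]]], unions[[pr[2]]]))))
  } else data.frame(group1 = character(), group2 = character(),
                    intersection = integer())
  list(presence = presence, sets = sets,
       set_sizes = vapply(unions, length, integer(1)),
       core_sets = cores, intersections = inter)
}

#' PCA of a keystone presence/absence matrix
#'
#' Principal components of the centered binary matrix, mirroring
#' ordination of keystone composition variability across resampled
#' networks.
#'
#' @param presence Binary matrix (rows = ensemble members).
#' @param n_components Number of components to return (default 2).
#' @return List with `coordinates` (rows x components) and
#'   `explained_variance` (fractions).
#' @export
presence_pca <- function(presence, n_components = 2L) {
  if (nrow(presence) < 3) stop("need at least 3 rows for PCA")
  vars <- apply(presence, 2, var)
  if (all(vars == 0)) {
    warning("presence matrix has zero variance; coordinates are all zero")
    co <- matrix(0, nrow(presence), n_components,
                 dimnames = list(rownames(presence),
                                 paste0("PC", seq_len(n_components))))
    return(list(coordinates = co,
                explained_variance = rep(0, n_components)))
  }
  pc <- prcomp(presence, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  co <- pc$x[, seq_len(k), drop = FALSE]
  if (k < n_components)
    co <- cbind(co, matrix(0, nrow(co), n_components - k))
  colnames(co) <- paste0("PC", seq_len(n_components))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = co,
       explained_variance = c(ev, rep(0, n_components))[seq_len(n_components)])
}
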