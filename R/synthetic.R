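#' Specification for a synthetic compositional dataset
#'
#' Describes a ground-truth conditional-dependence graph among `n_taxa`
#' species and the logistic-normal-multinomial observation model used to
#' generate compositional counts from it.
#'
#' @param n_taxa Number of taxa (>= 3).
#' @param n_samples Number of samples.
#' @param topology Graph topology: `"erdos_renyi"`, `"scale_free"`,
#'   `"band"` or `"modular"`.
#' @param target_edge_density Desired edge density in (0, 1].
#' @param edge_weight_range Magnitude bounds for off-diagonal precision
#'   entries, length-2 numeric.
#' @param negative_edge_fraction Fraction of edges given a negative
#'   precision-implied association. Default 0.1: real co-occurrence networks
#'   of this kind carry only a few percent negative edges, so the generator
#'   must produce both signs but predominantly positive ones.
#' @param depth_log_mean,depth_log_sd Log-normal sequencing-depth model
#'   (mean depth defaults to 1e5 reads).
#' @param band_width Band half-width for `topology = "band"`; default derived
#'   from `target_edge_density`.
#' @param n_modules Number of blocks for `topology = "modular"`.
#' @param seed Integer seed; all generation is reproducible given it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_taxa = 50, n_samples = 200,
                           topology = c("erdos_renyi", "scale_free",
                                        "band", "modular"),
                           target_edge_density = 0.1,
                           edge_weight_range = c(0.15, 0.35),
                           negative_edge_fraction = 0.1,
                           depth_log_mean = log(1e5), depth_log_sd = 0.3,
                           band_width = NULL, n_modules = 4L,
                           seed = 1L) {
  topology <- match.arg(topology)
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (target_edge_density <= 0 || target_edge_density > 1)
    stop("target_edge_density must lie in (0, 1]")
  if (length(edge_weight_range) != 2 || any(edge_weight_range <= 0))
    stop("edge_weight_range must be two positive magnitudes")
  if (negative_edge_fraction < 0 || negative_edge_fraction > 1)
    stop("negative_edge_fraction must lie in [0, 1]")
  if (depth_log_sd < 0) stop("depth_log_sd must be >= 0")
  structure(list(
    n_taxa = as.integer(n_taxa), n_samples = as.integer(n_samples),
    topology = topology, target_edge_density = target_edge_density,
    edge_weight_range = sort(as.numeric(edge_weight_range)),
    negative_edge_fraction = negative_edge_fraction,
    depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
    band_width = band_width, n_modules = as.integer(n_modules),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Generate a ground-truth adjacency matrix
#'
#' Draws an undirected simple graph on `spec$n_taxa` nodes with the requested
#' topology. For random topologies the realized density is close to
#' `target_edge_density`; structured topologies (band) hit the density their
#' width allows.
#'
#' @param spec A [synthetic_spec()].
#' @return Symmetric binary matrix with zero diagonal and taxon dimnames.
#' @export
generate_true_graph <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$n_taxa
  g <- with_seed(derive_seed(spec$seed, "graph"), {
    switch(spec$topology,
      erdos_renyi = igraph::sample_gnp(p, spec$target_edge_density),
      scale_free = {
        m <- max(1L, round(spec$target_edge_density * (p - 1) / 2))
        igraph::sample_pa(p, m = m, directed = FALSE)
      },
      band = {
        w <- spec$band_width
        if (is.null(w)) {
          # smallest half-width whose band density reaches the target
          dens <- function(k) (k * p - k * (k + 1) / 2) / (p * (p - 1) / 2)
          w <- 1L
          while (w < p - 1 && dens(w) < spec$target_edge_density) w <- w + 1L
        }
        if (w > p - 1) stop("band width exceeds n_taxa - 1")
        a <- abs(outer(seq_len(p), seq_len(p), "-"))
        igraph::graph_from_adjacency_matrix((a >= 1 & a <= w) * 1,
                                            mode = "undirected")
      },
      modular = {
        sizes <- rep(p %/% spec$n_modules, spec$n_modules)
        sizes[seq_len(p %% spec$n_modules)] <-
          sizes[seq_len(p %% spec$n_modules)] + 1L
        within_pairs <- sum(sizes * (sizes - 1) / 2)
        total_pairs <- p * (p - 1) / 2
        between_pairs <- total_pairs - within_pairs
        # between-block density fixed at a tenth of within-block density
        pw <- min(1, spec$target_edge_density * total_pairs /
                       (within_pairs + between_pairs / 10))
        pm <- matrix(pw / 10, spec$n_modules, spec$n_modules)
        diag(pm) <- pw
        igraph::sample_sbm(p, pref.matrix = pm, block.sizes = sizes)
      }
    )
  })
  adj <- as.matrix(igraph::as_adjacency_matrix(igraph::simplify(g)))
  adj <- (adj + t(adj) > 0) * 1L
  diag(adj) <- 0L
  dimnames(adj) <- list(taxon_names(p), taxon_names(p))
  adj
}

taxon_names <- function(p) sprintf("sp%03d", seq_len(p))

#' Build a positive-definite precision matrix on a given support
#'
#' Assigns signed weights to the edges of `adjacency` (magnitudes uniform in
#' `edge_weight_range`, negative with probability `negative_edge_fraction`)
#' and boosts the diagonal until the minimum eigenvalue reaches `eig_floor`,
#' so the off-diagonal support equals the adjacency exactly.
#'
#' @param adjacency Symmetric binary matrix, zero diagonal.
#' @param edge_weight_range Length-2 positive magnitudes.
#' @param negative_edge_fraction Probability an edge weight is negative.
#' @param seed Integer seed.
#' @param eig_floor Minimum eigenvalue of the returned matrix (default 0.05).
#' @return Symmetric positive-definite precision matrix.
#' @export
graph_to_precision <- function(adjacency, edge_weight_range = c(0.15, 0.35),
                               negative_edge_fraction = 0.1, seed = 1L,
                               eig_floor = 0.05) {
  if (!isTRUE(all.equal(adjacency, t(adjacency))) ||
      any(diag(adjacency) != 0))
    stop("adjacency must be symmetric with zero diagonal")
  p <- nrow(adjacency)
  omega <- with_seed(derive_seed(seed, "precision"), {
    w <- matrix(0, p, p)
    up <- which(upper.tri(adjacency) & adjacency != 0)
    mag <- runif(length(up), edge_weight_range[1], edge_weight_range[2])
    # a NEGATIVE precision off-diagonal implies a POSITIVE partial
    # correlation (association); negative_edge_fraction is the fraction of
    # negatively associated edges, hence positive precision entries
    sgn <- ifelse(runif(length(up)) < negative_edge_fraction, 1, -1)
    w[up] <- mag * sgn
    w + t(w)
  })
  diag(omega) <- 1
  emin <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (emin < eig_floor) diag(omega) <- diag(omega) + (eig_floor - emin)
  dimnames(omega) <- dimnames(adjacency)
  omega
}

#' Sample compositional counts from a logistic-normal-multinomial model
#'
#' Latent log-abundance vectors are drawn from the zero-mean multivariate
#' normal with the given precision, closed by exponential-and-normalize, and
#' observed as multinomial counts at log-normally distributed depths.
#'
#' @param precision Positive-definite precision matrix.
#' @param n_samples Number of samples to draw.
#' @param depth_log_mean,depth_log_sd Log-normal depth parameters.
#' @param seed Integer seed.
#' @return List with `counts` (integer matrix), `relabund` (rows sum to 1),
#'   `latent` (the normal draws), `depths`.
#' @export
sample_compositions <- function(precision, n_samples,
                                depth_log_mean = log(1e5),
                                depth_log_sd = 0.3, seed = 1L) {
  p <- nrow(precision)
  ch <- tryCatch(chol(precision), error = function(e)
    stop("precision matrix is not positive definite: ", conditionMessage(e)))
  # z ~ N(0, Omega^{-1}): solve R' x = e for chol factor R gives covariance
  with_seed(derive_seed(seed, "samples"), {
    e <- matrix(rnorm(n_samples * p), p, n_samples)
    latent <- t(backsolve(ch, e))
    comp <- exp(latent - apply(latent, 1, max))
    comp <- comp / rowSums(comp)
    depths <- pmax(1, round(rlnorm(n_samples, depth_log_mean, depth_log_sd)))
    counts <- t(vapply(seq_len(n_samples), function(i)
      rmultinom(1, depths[i], comp[i, ])[, 1], numeric(p)))
    dimnames(counts) <- list(sprintf("s%04d", seq_len(n_samples)),
                             colnames(precision))
    list(counts = counts, relabund = counts / depths, latent = latent,
         depths = depths)
  })
}

#' Generate a full synthetic dataset from a spec
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `synthetic_dataset`: `true_adjacency`,
#'   `precision`, `counts`, `relabund`, `spec`.
#' @export
simulate_dataset <- function(spec) {
  adj <- generate_true_graph(spec)
  omega <- graph_to_precision(adj, spec$edge_weight_range,
                              spec$negative_edge_fraction, spec$seed)
  draws <- sample_compositions(omega, spec$n_samples, spec$depth_log_mean,
                               spec$depth_log_sd, spec$seed)
  structure(list(true_adjacency = adj, precision = omega,
                 counts = draws$counts, relabund = draws$relabund,
                 depths = draws$depths, spec = spec),
            class = "synthetic_dataset")
}

#' Generate a multi-group synthetic dataset
#'
#' One [synthetic_spec()] per phenotype group (e.g. distinct topologies per
#' metabolic phenotype); samples are concatenated with group labels and the
#' per-group ground truth retained for recovery scoring.
#'
#' @param specs Named list of [synthetic_spec()] objects, one per group.
#' @return List with `table` (an [abundance_table()]) and `truth` (named list
#'   of `synthetic_dataset` objects).
#' @export
make_group_dataset <- function(specs) {
  if (length(specs) < 1) stop("at least one group spec is required")
  if (is.null(names(specs)) || anyDuplicated(names(specs)))
    stop("specs must be a uniquely named list")
  truth <- lapply(specs, simulate_dataset)
  vals <- list(); meta <- list()
  for (g in names(truth)) {
    v <- truth[[g]]$relabund
    rownames(v) <- paste(g, rownames(v), sep = "_")
    vals[[g]] <- v
    meta[[g]] <- data.frame(sample_id = rownames(v), group = g,
                            stringsAsFactors = FALSE)
  }
  taxa <- Reduce(union, lapply(vals, colnames))
  values <- do.call(rbind, lapply(vals, function(v) {
    out <- matrix(0, nrow(v), length(taxa),
                  dimnames = list(rownames(v), taxa))
    out[, colnames(v)] <- v
    out
  }))
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- metadata$sample_id
  if (anyDuplicated(rownames(values))) stop("duplicate sample identifiers")
  list(table = abundance_table(values, metadata = metadata), truth = truth)
}
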