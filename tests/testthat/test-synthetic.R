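test_that("band topology with width 1 yields a path graph; seeds reproduce", {
  spec <- synthetic_spec(n_taxa = 10, topology = "band", band_width = 1,
                         target_edge_density = 0.2, seed = 42)
  adj <- generate_true_graph(spec)
  expect_equal(sum(adj) / 2, 9)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  expect_equal(sort(igraph::degree(g)), c(1, 1, rep(2, 8)),
               ignore_attr = TRUE)
  expect_identical(adj, generate_true_graph(spec))
  expect_error(generate_true_graph(
    synthetic_spec(n_taxa = 5, topology = "band", band_width = 6)),
    "band width")
})

test_that("Erdos-Renyi density matches the Bernoulli edge model", {
  dens <- vapply(1:200, function(s) {
    adj <- generate_true_graph(synthetic_spec(n_taxa = 50, seed = s,
                                              target_edge_density = 0.1))
    sum(adj) / (50 * 49)
  }, numeric(1))
  expect_gt(mean(dens), 0.08)
  expect_lt(mean(dens), 0.12)
})

test_that("graph_to_precision preserves support and is positive definite", {
  for (s in 1:5) {
    adj <- generate_true_graph(synthetic_spec(n_taxa = 20, seed = s,
                                              target_edge_density = 0.15))
    omega <- graph_to_precision(adj, seed = s)
    off <- omega; diag(off) <- 0
    expect_identical(unname(1 * (off != 0)), unname(adj * 1))
    expect_gt(min(eigen(omega, symmetric = TRUE)$values), 0)
  }
  # empty graph: diagonal precision, diagonal implied covariance
  empty <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  om <- graph_to_precision(empty, seed = 1)
  expect_true(all(om[upper.tri(om)] == 0))
  expect_true(all(abs(solve(om)[upper.tri(om)]) < 1e-12))
})

test_that("path precision: conditional zero but marginal dependence", {
  adj <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  adj["a", "b"] <- adj["b", "a"] <- 1
  adj["b", "c"] <- adj["c", "b"] <- 1
  omega <- graph_to_precision(adj, edge_weight_range = c(0.3, 0.4), seed = 2)
  expect_identical(omega["a", "c"], 0)
  sigma <- solve(omega)
  expect_gt(abs(sigma["a", "c"]), 1e-8)
})

test_that("compositions close to 1 and counts sum to drawn depths", {
  omega <- graph_to_precision(
    generate_true_graph(synthetic_spec(n_taxa = 12, seed = 3)), seed = 3)
  draws <- sample_compositions(omega, 50, seed = 3)
  expect_equal(rowSums(draws$relabund), rep(1, 50), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(unname(rowSums(draws$counts)), as.numeric(draws$depths))
  bad <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(sample_compositions(bad, 10), "positive definite")
})

test_that("empirical latent covariance converges to the inverse precision", {
  # law-of-large-numbers: Frobenius error decreases with n in >= 8/10 seeds
  adj <- generate_true_graph(synthetic_spec(n_taxa = 8, seed = 1,
                                            target_edge_density = 0.3))
  omega <- graph_to_precision(adj, seed = 1)
  sigma <- solve(omega)
  frob <- function(n, s) {
    z <- sample_compositions(omega, n, seed = s)$latent
    norm(cov(z) - sigma, "F")
  }
  wins <- sum(vapply(1:10, function(s) frob(5000, s) < frob(200, s),
                     logical(1)))
  expect_gte(wins, 8)
})

test_that("make_group_dataset bookkeeping and distinct topologies", {
  specs <- list(
    A = synthetic_spec(n_taxa = 12, n_samples = 50, topology = "band",
                       band_width = 1, target_edge_density = 0.1, seed = 1),
    B = synthetic_spec(n_taxa = 12, n_samples = 50, seed = 2))
  ds <- make_group_dataset(specs)
  expect_equal(dim(ds$table)[1], 100)
  expect_setequal(unique(ds$table$metadata$group), c("A", "B"))
  expect_false(identical(ds$truth$A$true_adjacency,
                         ds$truth$B$true_adjacency))
  expect_error(make_group_dataset(setNames(specs, c("A", "A"))), "named")
})

test_that("denser true graphs yield more estimated edges on average", {
  # pipeline-level link between generator truth and inference output,
  # scaled to desk size (reduced StARS subsamples; see methods vignette)
  edge_counts <- vapply(1:6, function(s) {
    nets <- lapply(c(sparse = 0.04, dense = 0.20), function(d) {
      ds <- simulate_dataset(synthetic_spec(n_taxa = 15, n_samples = 150,
                                            target_edge_density = d,
                                            seed = s))
      infer_network(abundance_table(ds$relabund), n_subsamples = 20,
                    seed = s, min_prev = 0.05)
    })
    igraph::ecount(nets$dense) - igraph::ecount(nets$sparse)
  }, numeric(1))
  expect_gt(mean(edge_counts), 0)
})
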