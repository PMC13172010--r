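#' Read and validate a pipeline configuration
#'
#' Configuration files are JSON (default) or YAML (when the `yaml` package
#' is available). Unknown top-level keys are rejected before any
#' computation; CLI flags override file values.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file, or a named list.
#' @param overrides Named list of overriding values.
#' @return Validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  cfg <- if (is.list(path)) path else {
    if (grepl("\\.ya?ml$", path)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config requires the 'yaml' package; use JSON instead")
      yaml::read_yaml(path)
    } else jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("input", "metadata", "output_dir", "seed", "log_level",
             "phenotype_column", "simulate", "classify", "filter",
             "inference", "robustness", "keystones", "ensemble", "paired",
             "force", "version")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, overrides)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$output_dir)) cfg$output_dir <- "."
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)
  h <- 0
  for (ch in utf8ToInt(as.character(s))) h <- (h * 131 + ch) %% 2^28
  sprintf("%07x", h)
}

prov_header <- function(cfg) {
  sprintf("micronet %s | config=%s seed=%s | %s",
          as.character(utils::packageVersion("micronet")),
          config_hash(cfg), cfg$seed, format(Sys.time(), "%Y-%m-%d"))
}

write_prov_tsv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", prov_header(cfg)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Simulate a synthetic multi-group dataset to disk
#'
#' Writes a MetaPhlAn-dialect abundance TSV, a per-sample metadata TSV and,
#' per group, the ground-truth edge list (and optional dense adjacency
#' TSV). Refuses to overwrite existing outputs unless `force`.
#'
#' @param config [read_pipeline_config()] input; its `simulate` block holds
#'   per-group [synthetic_spec()] argument lists under `groups`.
#' @param force Overwrite existing outputs.
#' @return Invisibly, the list of written paths.
#' @export
cmd_simulate <- function(config, force = FALSE) {
  cfg <- read_pipeline_config(config)
  sim <- cfg$simulate
  if (is.null(sim$groups)) stop("config$simulate$groups is required")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  force <- isTRUE(force) || isTRUE(cfg$force)
  specs <- lapply(seq_along(sim$groups), function(i) {
    args <- as.list(sim$groups[[i]])
    args$seed <- derive_seed(cfg$seed, "simulate", i)
    do.call(synthetic_spec, args)
  })
  names(specs) <- names(sim$groups)
  ds <- make_group_dataset(specs)
  paths <- c(abundance = file.path(cfg$output_dir, "abundance.tsv"),
             metadata = file.path(cfg$output_dir, "metadata.tsv"))
  truth_paths <- setNames(file.path(cfg$output_dir,
                                    paste0("truth_", names(specs), ".tsv")),
                          names(specs))
  existing <- c(paths, truth_paths)[file.exists(c(paths, truth_paths))]
  if (length(existing) && !force)
    stop("output exists (use force = TRUE): ",
         paste(existing, collapse = ", "))
  write_metaphlan_table(ds$table, paths[["abundance"]])
  write_prov_tsv(ds$table$metadata, paths[["metadata"]], cfg)
  for (g in names(specs)) {
    adj <- ds$truth[[g]]$true_adjacency
    idx <- which(adj != 0 & upper.tri(adj), arr.ind = TRUE)
    el <- data.frame(source = rownames(adj)[idx[, 1]],
                     target = colnames(adj)[idx[, 2]],
                     weight = ds$truth[[g]]$precision[idx])
    write_prov_tsv(el, truth_paths[[g]], cfg)
  }
  invisible(c(paths, truth_paths))
}

#' Classify subject metadata into metabolic-health phenotypes
#'
#' Reads a metadata CSV/TSV, applies [classify_phenotype_table()] (with
#' threshold overrides from the `classify` config block) and writes the
#' labeled table, logging the number of indeterminate subjects.
#'
#' @param config Pipeline config; `metadata` is the input path.
#' @return Invisibly, the labeled data.frame.
#' @export
cmd_classify <- function(config) {
  cfg <- read_pipeline_config(config)
  if (is.null(cfg$metadata)) stop("config$metadata path is required")
  sep <- if (grepl("\\.csv$", cfg$metadata)) "," else "\t"
  md <- read.delim(cfg$metadata, sep = sep, stringsAsFactors = FALSE,
                   comment.char = "#")
  crit_args <- cfg$classify$criteria
  crit <- if (is.null(crit_args)) phenotype_criteria()
          else do.call(phenotype_criteria, crit_args)
  units <- unlist(cfg$classify$units)
  labeled <- classify_phenotype_table(md, crit, units)
  n_ind <- sum(labeled$phenotype == "indeterminate")
  message(nrow(labeled), " subjects classified; ", n_ind, " indeterminate")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_prov_tsv(labeled, file.path(cfg$output_dir,
                                    "metadata_labeled.tsv"), cfg)
  invisible(labeled)
}

analyze_one_group <- function(table, cfg, group) {
  inf_args <- c(list(table = table,
                     seed = derive_seed(cfg$seed, "analyze", group)),
                cfg$filter, cfg$inference)
  do.call(infer_network, inf_args)
}

#' Per-group network analysis: inference, topology, keystones, robustness
#'
#' For each phenotype group: infer the network, write its edge list, and
#' emit a global-metrics summary table (one column per group, rows matching
#' the standard network-property summary), k-core histograms, keystone
#' lists and an attack-robustness summary. Inference for a group is skipped
#' when a cached edge list with a matching provenance hash exists.
#'
#' @param config Pipeline config: `input` abundance TSV (plain or MetaPhlAn
#'   dialect), `metadata` TSV with a group column (`phenotype_column`,
#'   default `"group"`).
#' @return Invisibly, a list with networks and summary tables.
#' @export
cmd_analyze <- function(config) {
  cfg <- read_pipeline_config(config)
  tab <- load_abundance_input(cfg)
  col <- if (is.null(cfg$phenotype_column)) "group" else cfg$phenotype_column
  if (!col %in% names(tab$metadata))
    stop("metadata lacks phenotype column '", col, "'")
  groups <- sort(unique(tab$metadata[[col]]))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  nets <- list()
  for (g in groups) {
    el_path <- file.path(cfg$output_dir, paste0("network_", g, ".tsv"))
    hash_path <- paste0(el_path, ".hash")
    if (file.exists(el_path) && file.exists(hash_path) &&
        readLines(hash_path)[1] == hash) {
      message("group ", g, ": cached network found, skipping inference")
      nets[[g]] <- read_edge_list(el_path)
      next
    }
    idx <- tab$metadata[[col]] == g
    sub <- abundance_table(tab$values[idx, , drop = FALSE],
                           metadata = tab$metadata[idx, , drop = FALSE])
    nets[[g]] <- analyze_one_group(sub, cfg, g)
    write_edge_list(nets[[g]], el_path, header = prov_header(cfg))
    writeLines(hash, hash_path)
  }
  summary_tab <- global_summary_table(nets)
  write_prov_tsv(summary_tab, file.path(cfg$output_dir,
                                        "global_metrics.tsv"), cfg)
  kcores <- do.call(rbind, lapply(groups, function(g)
    cbind(group = g, kcore_histogram(nets[[g]]))))
  write_prov_tsv(kcores, file.path(cfg$output_dir, "kcore_histogram.tsv"),
                 cfg)
  keystones <- lapply(nets, function(n)
    suppressWarnings(detect_keystones(extract_lcc(n))))
  writeLines(unlist(lapply(groups, function(g)
    c(paste0("[", g, "]"), keystones[[g]], ""))),
    file.path(cfg$output_dir, "keystones.txt"))
  rob_args <- cfg$robustness
  if (is.null(rob_args)) rob_args <- list()
  rob <- do.call(rbind, lapply(groups, function(g) {
    tryCatch({
      suite <- do.call(run_attack_suite,
                       c(list(network = nets[[g]],
                              seed = derive_seed(cfg$seed, "attack", g)),
                         rob_args))
      robustness_summary_rows(suite, g)
    }, error = function(e) {
      warning("robustness analysis failed for group ", g, ": ",
              conditionMessage(e))
      data.frame(group = g, strategy = NA_character_, nr50 = NA_real_,
                 nr50_sd = NA_real_, pc = NA_real_)
    })
  }))
  write_prov_tsv(rob, file.path(cfg$output_dir, "robustness.tsv"), cfg)
  invisible(list(networks = nets, global_metrics = summary_tab,
                 keystones = keystones, robustness = rob))
}

load_abundance_input <- function(cfg) {
  if (is.null(cfg$input)) stop("config$input path is required")
  first <- readLines(cfg$input, n = 5)
  tab <- if (any(grepl("clade_name|\\|s__", first)))
    read_metaphlan_table(cfg$input)
  else read_abundance_table(cfg$input)
  if (!is.null(cfg$metadata)) {
    md <- read.delim(cfg$metadata, stringsAsFactors = FALSE,
                     comment.char = "#")
    rownames(md) <- md[[1]]
    tab <- abundance_table(tab$values, metadata = md,
                           taxonomy = tab$taxonomy)
  }
  tab
}

# The standard network-property summary rows, one column per group.
global_summary_table <- function(nets) {
  rows <- c("order", "size", "% negative edges", "edge density",
            "number of CCs", "degree (mean)", "shortest path length (mean)",
            "betweenness centrality (mean)", "closeness centrality (mean)")
  cols <- lapply(nets, function(n) {
    gm <- global_metrics(n)
    c(gm$order, gm$size, gm$pct_negative_edges, gm$edge_density,
      gm$n_components, gm$mean_degree, gm$mean_shortest_path,
      gm$mean_betweenness, gm$mean_closeness)
  })
  out <- data.frame(property = rows, cols, check.names = FALSE)
  names(out)[-1] <- names(nets)
  out
}

robustness_summary_rows <- function(suite, group) {
  do.call(rbind, lapply(suite, function(rr) {
    if (rr$strategy == "random")
      data.frame(group = group, strategy = "random", nr50 = rr$nr50_mean,
                 nr50_sd = rr$nr50_sd, pc = NA_real_)
    else data.frame(group = group, strategy = rr$strategy, nr50 = rr$nr50,
                    nr50_sd = NA_real_, pc = as.numeric(rr$pc))
  }))
}

#' Robustness analysis of precomputed edge lists
#'
#' Consumes external edge-list TSVs directly (no inference) and emits
#' per-strategy decay curves plus an NR50/p_c summary.
#'
#' @param config Pipeline config.
#' @param edge_list_inputs Named character vector of edge-list paths
#'   (names used as group labels).
#' @return Invisibly, the per-group attack suites.
#' @export
cmd_attack <- function(config, edge_list_inputs) {
  cfg <- read_pipeline_config(config)
  if (is.null(names(edge_list_inputs)))
    names(edge_list_inputs) <- sub("\\.tsv$", "",
                                   basename(edge_list_inputs))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  rob_args <- cfg$robustness
  if (is.null(rob_args)) rob_args <- list()
  suites <- list(); curves <- list()
  for (g in names(edge_list_inputs)) {
    net <- read_edge_list(edge_list_inputs[[g]])
    suites[[g]] <- do.call(run_attack_suite,
                           c(list(network = net,
                                  seed = derive_seed(cfg$seed, "attack", g)),
                             rob_args))
    curves[[g]] <- do.call(rbind, lapply(suites[[g]], function(rr)
      cbind(group = g, strategy = rr$strategy, rr$curve)))
  }
  write_prov_tsv(do.call(rbind, curves),
                 file.path(cfg$output_dir, "decay_curves.tsv"), cfg)
  write_prov_tsv(do.call(rbind, lapply(names(suites), function(g)
    robustness_summary_rows(suites[[g]], g))),
    file.path(cfg$output_dir, "robustness.tsv"), cfg)
  invisible(suites)
}

#' Subsampled-ensemble analysis from the command line
#'
#' @param config Pipeline config; the `ensemble` block holds
#'   [ensemble_config()] arguments.
#' @return Invisibly, the [run_ensemble()] summary.
#' @export
cmd_ensemble <- function(config) {
  cfg <- read_pipeline_config(config)
  tab <- load_abundance_input(cfg)
  ens_args <- cfg$ensemble
  if (is.null(ens_args)) ens_args <- list()
  ens_args$seed <- cfg$seed
  ecfg <- do.call(ensemble_config, ens_args)
  col <- if (is.null(cfg$phenotype_column)) "group" else cfg$phenotype_column
  res <- run_ensemble(tab, ecfg, group_labels = tab$metadata[[col]])
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_prov_tsv(res$global, file.path(cfg$output_dir,
                                       "ensemble_global.tsv"), cfg)
  write_prov_tsv(res$robustness, file.path(cfg$output_dir,
                                           "ensemble_robustness.tsv"), cfg)
  invisible(res)
}

#' Before/after paired network comparison
#'
#' Infers a network per timepoint and reports deltas of global metrics and
#' degree/betweenness-attack NR50. Sign convention: after minus before.
#'
#' @param config Pipeline config with a `paired` block holding `before` and
#'   `after` abundance-table paths.
#' @return Invisibly, the delta data.frame.
#' @export
cmd_paired_compare <- function(config) {
  cfg <- read_pipeline_config(config)
  if (is.null(cfg$paired$before) || is.null(cfg$paired$after))
    stop("config$paired must name 'before' and 'after' inputs")
  nets <- lapply(c(before = cfg$paired$before, after = cfg$paired$after),
                 function(p) {
    c2 <- cfg; c2$input <- p; c2$metadata <- NULL
    tab <- load_abundance_input(c2)
    do.call(infer_network,
            c(list(table = tab, seed = derive_seed(cfg$seed, "paired")),
              cfg$filter, cfg$inference))
  })
  gms <- lapply(nets, global_metrics)
  suites <- lapply(nets, function(n) tryCatch(
    run_attack_suite(n, strategies = c("degree", "betweenness"),
                     seed = derive_seed(cfg$seed, "paired_attack")),
    error = function(e) {
      warning("robustness analysis failed: ", conditionMessage(e))
      list(degree = list(nr50 = NA_real_),
           betweenness = list(nr50 = NA_real_))
    }))
  metric <- c(names(gms$before),
              "nr50_degree", "nr50_betweenness")
  val <- function(g, s) c(unlist(gms[[g]]),
                          suites[[g]]$degree$nr50,
                          suites[[g]]$betweenness$nr50)
  delta <- data.frame(metric = metric, before = val("before"),
                      after = val("after"))
  delta$delta <- delta$after - delta$before
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_prov_tsv(delta, file.path(cfg$output_dir, "paired_deltas.tsv"),
                 cfg)
  invisible(delta)
}
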