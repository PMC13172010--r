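#' Configuration for a subsampled-network ensemble
#'
#' @param subsample_n Samples drawn per replicate (without replacement by
#'   default; default 100 per the subsampling validation design).
#' @param n_reps Replicates per group (default 100).
#' @param seed Root seed.
#' @param groups Group labels to analyze; default all groups present.
#' @param replace Bootstrap instead of subsampling.
#' @param min_abund,min_prev Within-subsample filter thresholds.
#' @param inference Named list of extra arguments to [infer_network()]
#'   (e.g. `n_subsamples`, `n_lambda` for desk-scale runs).
#' @param robustness_strategies Attack strategies per replicate network
#'   (default degree + betweenness; random attacks across an ensemble are
#'   expensive).
#' @param random_attack_reps Random-attack repetitions when `"random"` is
#'   among the strategies.
#' @param keystone_q Keystone percentile.
#' @return List of class `ensemble_config`.
#' @export
ensemble_config <- function(subsample_n = 100L, n_reps = 100L, seed = 1L,
                            groups = NULL, replace = FALSE,
                            min_abund = 0.001, min_prev = 0.10,
                            inference = list(),
                            robustness_strategies = c("degree",
                                                      "betweenness"),
                            random_attack_reps = 100L,
                            keystone_q = 0.9) {
  if (n_reps < 2) stop("n_reps must be >= 2")
  structure(as.list(environment()), class = "ensemble_config")
}

#' Run a subsampled-network ensemble
#'
#' For each group and replicate: draw `subsample_n` samples (without
#' replacement), re-apply the prevalence/abundance filter *within* the
#' subsample, infer the network, and compute global metrics, keystones and
#' attack robustness. Failed replicates are logged and skipped, never
#' imputed.
#'
#' @param table An [abundance_table()] whose metadata has a `group` column
#'   (or supply `group_labels`).
#' @param config An [ensemble_config()].
#' @param group_labels Optional per-sample group vector overriding metadata.
#' @return Object of class `ensemble_summary`: `global` (per-rep global
#'   metrics), `robustness` (per-rep NR50/pc rows), `keystones` (from
#'   [ensemble_keystones()]), `networks`, `failures`.
#' @export
run_ensemble <- function(table, config = ensemble_config(),
                         group_labels = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(group_labels)) {
    if (is.null(table$metadata) || is.null(table$metadata$group))
      stop("metadata must contain a 'group' column")
    group_labels <- table$metadata$group
  }
  groups <- config$groups
  if (is.null(groups)) groups <- sort(unique(group_labels))
  idx_by_group <- split(seq_len(nrow(table$values)), group_labels)
  too_small <- groups[vapply(groups, function(g)
    length(idx_by_group[[g]]) < config$subsample_n, logical(1))]
  if (length(too_small))
    stop("group(s) smaller than subsample_n: ",
         paste(too_small, collapse = ", "))
  global_rows <- list(); rob_rows <- list(); nets <- list()
  net_groups <- character(); failures <- list()
  for (g in groups) {
    for (rep in seq_len(config$n_reps)) {
      rep_seed <- derive_seed(config$seed, g, rep)
      res <- tryCatch({
        idx <- with_seed(rep_seed,
          sample(idx_by_group[[g]], config$subsample_n,
                 replace = config$replace))
        sub <- abundance_table(table$values[idx, , drop = FALSE],
                               metadata = table$metadata[idx, , drop = FALSE])
        args <- c(list(table = sub, min_abund = config$min_abund,
                       min_prev = config$min_prev, seed = rep_seed),
                  config$inference)
        net <- do.call(infer_network, args)
        gm <- global_metrics(net)
        # a sparse replicate can lose its positive-edge LCC; robustness is
        # then reported as NA rather than failing the whole replicate
        suite <- tryCatch(
          run_attack_suite(net, strategies = config$robustness_strategies,
                           n_reps = config$random_attack_reps,
                           seed = rep_seed),
          error = function(e) NULL)
        list(net = net, gm = gm, suite = suite)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          data.frame(group = g, rep = rep,
                     message = conditionMessage(res))
        next
      }
      tag <- paste0(g, "_rep", rep)
      global_rows[[tag]] <- cbind(group = g, rep = rep, res$gm)
      rob_rows[[tag]] <- if (is.null(res$suite)) {
        data.frame(group = g, rep = rep,
                   strategy = config$robustness_strategies,
                   nr50 = NA_real_, pc = NA_real_)
      } else do.call(rbind, lapply(res$suite, function(rr) {
        data.frame(group = g, rep = rep, strategy = rr$strategy,
                   nr50 = if (rr$strategy == "random") rr$nr50_mean
                          else rr$nr50,
                   pc = if (rr$strategy == "random") NA_real_
                        else as.numeric(rr$pc))
      }))
      nets[[tag]] <- res$net
      net_groups <- c(net_groups, g)
    }
  }
  if (!length(nets)) stop("every ensemble replicate failed")
  ks <- if (length(nets) >= 2)
    ensemble_keystones(nets, groups = net_groups, q = config$keystone_q)
  else NULL
  structure(list(global = do.call(rbind, c(global_rows,
                                           make.row.names = FALSE)),
                 robustness = do.call(rbind, c(rob_rows,
                                               make.row.names = FALSE)),
                 keystones = ks, networks = nets,
                 failures = if (length(failures))
                   do.call(rbind, failures)
                 else data.frame(group = character(), rep = integer(),
                                 message = character()),
                 config = config),
            class = "ensemble_summary")
}

#' Summarize ensemble metric distributions across groups
#'
#' Per-group medians and IQRs, Kruskal-Wallis rank tests across groups with
#' Benjamini-Hochberg correction across metrics, and optionally a
#' ranking-consistency score for a hypothesized group ordering: replicates
#' are paired by index and each adjacent pair in the ordering scores 1 when
#' strictly ordered, 0.5 on a tie, 0 otherwise; the score is the average
#' over replicates and adjacent pairs.
#'
#' @param summary An `ensemble_summary` (or its `$global` data.frame).
#' @param metrics Metric columns to summarize.
#' @param ordering Optional character vector of groups, hypothesized
#'   largest-first, for the ranking-consistency score.
#' @return List with `stats` (median/IQR per group and metric), `tests`
#'   (per-metric Kruskal-Wallis with BH adjustment) and
#'   `ranking_consistency` (per metric, when `ordering` is given).
#' @export
summarize_distributions <- function(summary,
                                    metrics = c("order", "size",
                                                "mean_degree",
                                                "mean_closeness"),
                                    ordering = NULL) {
  df <- if (inherits(summary, "ensemble_summary")) summary$global else summary
  groups <- sort(unique(df$group))
  if (length(groups) < 2) stop("need at least 2 groups")
  stats <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(groups, function(g) {
      v <- df[[m]][df$group == g]
      data.frame(metric = m, group = g, median = median(v),
                 q25 = quantile(v, 0.25, names = FALSE),
                 q75 = quantile(v, 0.75, names = FALSE), n = length(v))
    }))
  }))
  tests <- do.call(rbind, lapply(metrics, function(m) {
    vals <- split(df[[m]], df$group)
    if (length(unique(unlist(vals))) == 1) {
      warning("metric '", m, "' constant across groups; p = 1")
      return(data.frame(metric = m, statistic = 0, p_value = 1))
    }
    kt <- kruskal.test(vals)
    data.frame(metric = m, statistic = unname(kt$statistic),
               p_value = kt$p.value)
  }))
  tests$p_adjusted <- p.adjust(tests$p_value, method = "BH")
  rc <- NULL
  if (!is.null(ordering)) {
    stopifnot(all(ordering %in% groups), length(ordering) >= 2)
    rc <- vapply(metrics, function(m) {
      per_rep <- lapply(ordering, function(g) {
        sub <- df[df$group == g, ]
        sub[[m]][order(sub$rep)]
      })
      nrep <- min(lengths(per_rep))
      scores <- vapply(seq_len(length(ordering) - 1), function(k) {
        a <- per_rep[[k]][seq_len(nrep)]
        b <- per_rep[[k + 1]][seq_len(nrep)]
        mean((a > b) + 0.5 * (a == b))
      }, numeric(1))
      mean(scores)
    }, numeric(1))
  }
  list(stats = stats, tests = tests, ranking_consistency = rc)
}
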