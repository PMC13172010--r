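#' Construct an abundance table
#'
#' The package's primary input container: a samples x taxa matrix of
#' nonnegative relative abundances plus optional per-sample metadata.
#' Species-level tables need not sum to exactly 1 per sample (unclassified
#' mass may be absent) but may not exceed it.
#'
#' @param values Numeric matrix, samples in rows, taxa in columns, with
#'   dimnames.
#' @param metadata Optional data.frame keyed by sample id (rownames).
#' @param taxonomy Optional named character vector of full clade strings.
#' @return Object of class `abundance_table`.
#' @export
abundance_table <- function(values, metadata = NULL, taxonomy = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry sample and taxon dimnames")
  if (anyDuplicated(rownames(values))) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate taxon identifiers")
  if (any(values < 0)) stop("abundances must be nonnegative")
  if (any(rowSums(values) > 1 + 1e-6))
    stop("per-sample abundance totals exceed 1")
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    missing <- setdiff(rownames(values), rownames(metadata))
    if (length(missing))
      stop("metadata missing for samples: ", paste(head(missing), collapse = ", "))
    metadata <- metadata[rownames(values), , drop = FALSE]
  }
  structure(list(values = values, metadata = metadata, taxonomy = taxonomy),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$values), "samples x", ncol(x$values),
      "taxa\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Read a MetaPhlAn-style merged profile table
#'
#' Expects taxa as rows (pipe-separated clade strings) and samples as
#' columns, with optional leading comment lines. Only species-level rows
#' (containing an `s__` rank and no `t__` strain rank) are retained, and
#' percentage-scale values are rescaled to fractions when column maxima
#' exceed 1.5.
#'
#' @param path Path to the TSV file.
#' @return An [abundance_table()] (samples x taxa) with full clade strings
#'   kept in `$taxonomy`.
#' @export
read_metaphlan_table <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  # the header itself may be a '#clade_name...' comment line
  hdr_idx <- which(is_comment & grepl("clade_name", lines))
  if (length(hdr_idx)) {
    lines[hdr_idx[length(hdr_idx)]] <-
      sub("^#+\\s*", "", lines[hdr_idx[length(hdr_idx)]])
    is_comment[hdr_idx[length(hdr_idx)]] <- FALSE
  }
  tc <- textConnection(lines[!is_comment])
  on.exit(close(tc))
  df <- read.delim(tc, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed header in ", path)
  clades <- as.character(df[[1]])
  num <- df[, -1, drop = FALSE]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    if (anyNA(v) && !anyNA(num[[j]]))
      stop("non-numeric cell in column '", names(num)[j], "', row ",
           which(is.na(v))[1])
    num[[j]] <- v
  }
  keep <- grepl("s__", clades) & !grepl("t__", clades)
  if (!any(keep)) stop("no species-level rows found in ", path)
  m <- t(as.matrix(num[keep, , drop = FALSE]))
  species <- sub("^.*s__", "", clades[keep])
  species <- gsub("_", " ", species)
  colnames(m) <- species
  if (max(m, na.rm = TRUE) > 1.5) m <- m / 100
  taxonomy <- setNames(clades[keep], species)
  abundance_table(m, taxonomy = taxonomy)
}

#' Write an abundance table in the MetaPhlAn merged dialect
#'
#' Taxa as rows, samples as columns, values as percentages, full clade
#' strings when available.
#'
#' @param table An [abundance_table()].
#' @param path Output path.
#' @export
write_metaphlan_table <- function(table, path) {
  m <- t(table$values) * 100
  clades <- rownames(m)
  if (!is.null(table$taxonomy))
    clades <- ifelse(clades %in% names(table$taxonomy),
                     table$taxonomy[clades],
                     paste0("k__x|s__", gsub(" ", "_", clades)))
  else clades <- paste0("k__x|s__", gsub(" ", "_", clades))
  df <- data.frame(clade_name = clades, m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Prevalence/abundance filter
#'
#' Keeps taxa whose abundance strictly exceeds `min_abund` in at least
#' `ceiling(min_prev * n)` samples. With `per_group`, a taxon is kept when it
#' passes the rule within at least one group.
#'
#' @param table An [abundance_table()].
#' @param min_abund Abundance threshold (fraction), strict `>`.
#' @param min_prev Prevalence threshold (fraction of samples), `>=` after
#'   ceiling.
#' @param per_group Optional character vector of group labels per sample, or
#'   the name of a metadata column.
#' @return Filtered [abundance_table()].
#' @export
prevalence_abundance_filter <- function(table, min_abund = 0.001,
                                        min_prev = 0.10, per_group = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (min_abund <= 0 || min_abund >= 1) stop("min_abund must be in (0, 1)")
  if (min_prev <= 0 || min_prev > 1) stop("min_prev must be in (0, 1]")
  v <- table$values
  if (is.character(per_group) && length(per_group) == 1) {
    if (is.null(table$metadata) || !per_group %in% names(table$metadata))
      stop("metadata column '", per_group, "' not found")
    per_group <- table$metadata[[per_group]]
  }
  passes <- function(sub) colSums(sub > min_abund) >= ceiling(min_prev * nrow(sub))
  keep <- if (is.null(per_group)) passes(v) else {
    Reduce(`|`, lapply(split(seq_len(nrow(v)), per_group),
                       function(i) passes(v[i, , drop = FALSE])))
  }
  if (!any(keep))
    stop("prevalence/abundance filter removed all taxa")
  abundance_table(v[, keep, drop = FALSE], metadata = table$metadata,
                  taxonomy = table$taxonomy[colnames(v)[keep]])
}

#' Centered log-ratio transform
#'
#' Per sample: replace zeros by a pseudocount, renormalize to sum 1, take
#' logs and subtract the row mean log. Rows of the result sum to zero.
#'
#' @param table An [abundance_table()] or nonnegative matrix.
#' @param pseudocount Zero replacement value; default half the smallest
#'   nonzero value in the whole table (global, scale-aware).
#' @return Numeric matrix of CLR coordinates (class `clr_matrix`).
#' @export
clr_transform <- function(table, pseudocount = NULL) {
  v <- if (inherits(table, "abundance_table")) table$values else as.matrix(table)
  if (any(v < 0)) stop("abundances must be nonnegative")
  zero_rows <- rowSums(v) == 0
  if (any(zero_rows))
    stop("all-zero abundance row for sample(s): ",
         paste(head(rownames(v)[zero_rows]), collapse = ", "))
  if (is.null(pseudocount)) {
    nz <- v[v > 0]
    pseudocount <- min(nz) / 2
  }
  v[v == 0] <- pseudocount
  v <- v / rowSums(v)
  lv <- log(v)
  out <- lv - rowMeans(lv)
  class(out) <- c("clr_matrix", class(out))
  out
}

canon_cols <- function(nms) {
  map <- c(source = "source", from = "source", node1 = "source", v1 = "source",
           target = "target", to = "target", node2 = "target", v2 = "target",
           weight = "weight", value = "weight", w = "weight")
  out <- map[tolower(nms)]
  out[is.na(out)] <- nms[is.na(out)]
  out
}

#' Read a signed weighted edge list
#'
#' TSV with source/target/weight columns (tolerant naming: from/to, value).
#' Duplicate undirected pairs are collapsed with a warning; self-loops are a
#' format error.
#'
#' @param path Path to the edge-list TSV.
#' @param abundances Optional named vector of node mean relative abundances.
#' @return A [co_network()].
#' @export
read_edge_list <- function(path, abundances = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- canon_cols(names(df))
  need <- c("source", "target", "weight")
  if (!all(need %in% names(df)))
    stop("edge list must contain source/target/weight columns")
  if (!is.numeric(df$weight))
    stop("non-numeric weight column in ", path)
  edges_to_network(df[, need], abundances = abundances)
}

edges_to_network <- function(edges, abundances = NULL, nodes = NULL) {
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (any(edges$source == edges$target))
    stop("self-loops are not allowed in co-occurrence edge lists")
  key <- paste(pmin(edges$source, edges$target),
               pmax(edges$source, edges$target))
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate undirected pair(s) collapsed")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  co_network(edges, abundances = abundances, nodes = nodes)
}

#' Write a network as an edge-list TSV
#'
#' @param network A [co_network()] (igraph).
#' @param path Output path.
#' @param header Optional provenance comment lines (written prefixed `#`).
#' @export
write_edge_list <- function(network, path, header = NULL) {
  el <- igraph::as_data_frame(network, what = "edges")
  names(el)[1:2] <- c("source", "target")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(el[, c("source", "target", "weight")], con, sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' Write a network as GraphML
#'
#' @param network A [co_network()] (igraph).
#' @param path Output path.
#' @export
write_network_graphml <- function(network, path) {
  g <- network
  class(g) <- "igraph"
  igraph::write_graph(g, path, format = "graphml")
}

#' Write an abundance table as a plain samples x taxa TSV
#' @param table An [abundance_table()].
#' @param path Output path.
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table$values), table$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a plain samples x taxa TSV written by [write_abundance_table()]
#' @param path Input path.
#' @param metadata Optional per-sample metadata data.frame.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, metadata = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  abundance_table(m, metadata = metadata)
}
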