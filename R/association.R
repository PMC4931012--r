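#' Spearman rank correlation with t-approximation p-value
#'
#' Ties receive average ranks; rho is the Pearson correlation of the ranks.
#' The two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (`|rho| = 1` gives p = 0). The approximation is flagged for `n < 10`.
#' Missing values are removed pairwise.
#'
#' @param x,y numeric vectors of equal length; at least 3 complete pairs.
#' @return list with `rho`, `p`, `n`, `defined` (FALSE when an input is
#'   constant, in which case rho/p are NA and the pair is not edge-eligible)
#'   and `approx_flagged`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, defined = FALSE,
                approx_flagged = n < 10))
  rho <- stats::cor(rx, ry)
  rho <- max(-1, min(1, rho))
  p <- if (abs(rho) == 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n, defined = TRUE, approx_flagged = n < 10)
}

#' Build a thresholded Spearman co-occurrence network
#'
#' Taxa with mean relative abundance (within the chosen sample subset)
#' strictly greater than `min_mean` are retained; environment variables, if
#' supplied, enter the network as additional nodes but never the abundance
#' filter. All pairwise Spearman correlations are computed and an edge is
#' kept iff `|rho| > rho_min` AND `p < p_max` (both strict).
#'
#' @param table an [abundance_table()].
#' @param subset sample ids to use (default: all samples).
#' @param env optional [environment_table()] whose numeric columns join the
#'   network.
#' @param rho_min absolute-correlation threshold (default 0.3, strict).
#' @param p_max p-value threshold (default 0.05, strict).
#' @param min_mean taxon mean-abundance filter (default 0.01, strict).
#' @param p_adjust optionally `"bonferroni"`-adjust edge p-values over the
#'   tested pairs before thresholding (default `"none"`).
#' @return object of class `correlation_network`: list with `nodes`
#'   (data.frame: name, type, mean_abundance), `edges` (data.frame: from,
#'   to, rho, p, n, sign) and the thresholds used. `as_igraph()` converts
#'   to an igraph object.
#' @export
build_network <- function(table, subset = NULL, env = NULL,
                          rho_min = 0.3, p_max = 0.05, min_mean = 0.01,
                          p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(subset)) subset <- rownames(table)
  if (length(subset) < 3) stop("need at least 3 samples")
  filt <- filter_prevalent(table, min_mean = min_mean, samples = subset)
  vars <- as.data.frame(filt$table)
  node_type <- stats::setNames(rep("taxon", ncol(vars)), colnames(vars))
  mean_ab <- colMeans(filt$table)
  if (!is.null(env)) {
    env_sub <- env[match(subset, env$sample_id), , drop = FALSE]
    for (nm in setdiff(names(env), "sample_id")) {
      if (!is.numeric(env_sub[[nm]])) next
      vars[[nm]] <- env_sub[[nm]]
      node_type[nm] <- "environment"
      mean_ab[nm] <- NA_real_
    }
  }
  if (ncol(vars) < 2) {
    warning("fewer than 2 variables survive the filter; returning an empty network")
    return(structure(list(
      nodes = data.frame(name = colnames(vars),
                         type = unname(node_type[colnames(vars)]),
                         mean_abundance = unname(mean_ab[colnames(vars)])),
      edges = data.frame(from = character(0), to = character(0),
                         rho = numeric(0), p = numeric(0), n = integer(0),
                         sign = character(0)),
      rho_min = rho_min, p_max = p_max, min_mean = min_mean),
      class = "correlation_network"))
  }
  nm <- colnames(vars)
  pairs <- utils::combn(nm, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i)
    spearman_cor(vars[[pairs[1, i]]], vars[[pairs[2, i]]]))
  rho <- vapply(res, `[[`, numeric(1), "rho")
  p <- vapply(res, `[[`, numeric(1), "p")
  n <- vapply(res, `[[`, numeric(1), "n")
  defined <- vapply(res, `[[`, logical(1), "defined")
  if (p_adjust == "bonferroni") p[defined] <- bonferroni(p[defined])
  keep <- defined & abs(rho) > rho_min & p < p_max
  edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                      rho = rho[keep], p = p[keep], n = as.integer(n[keep]),
                      sign = ifelse(rho[keep] > 0, "+", "-"),
                      stringsAsFactors = FALSE)
  structure(list(
    nodes = data.frame(name = nm, type = unname(node_type[nm]),
                       mean_abundance = unname(mean_ab[nm]),
                       stringsAsFactors = FALSE),
    edges = edges, rho_min = rho_min, p_max = p_max, min_mean = min_mean),
    class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation network: %d nodes, %d edges (|rho| > %g, p < %g)\n",
              nrow(x$nodes), nrow(x$edges), x$rho_min, x$p_max))
  invisible(x)
}

#' Convert a correlation network to igraph
#'
#' Node attribute `size` carries the mean abundance, edge attribute
#' `weight` carries `|rho|`.
#'
#' @param network a `correlation_network`.
#' @return an igraph graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "correlation_network"))
  v <- network$nodes
  v$size <- ifelse(is.na(v$mean_abundance), 0, v$mean_abundance)
  e <- network$edges
  if (nrow(e) > 0) e$weight <- abs(e$rho)
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
}

#' Export a correlation network
#'
#' @param network a `correlation_network`.
#' @param path output path.
#' @param format `"graphml"` (node size = mean abundance, edge weight =
#'   `|rho|`) or `"edge_tsv"` (columns from, to, rho, p, sign).
#' @export
export_graph <- function(network, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else {
    utils::write.table(network$edges[, c("from", "to", "rho", "p", "sign")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back an edge-list TSV
#'
#' @param path path written by [export_graph()] with `format = "edge_tsv"`.
#' @return data.frame of edges.
#' @export
read_edge_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Taxa-by-environment Spearman correlation table
#'
#' Full matrix of Spearman correlations between bacterial family abundances
#' and gut-environment variables, with per-cell n and p. Missing values are
#' removed pairwise per cell; cells with fewer than 3 complete pairs or a
#' constant variable are marked untestable (NA).
#'
#' @param table an [abundance_table()] (already restricted/aligned).
#' @param env an [environment_table()] aligned to the same samples (same
#'   order).
#' @return list of matrices `rho`, `p`, `n` (taxa x environment variables)
#'   and logical `untestable`.
#' @export
correlation_heatmap_table <- function(table, env) {
  stopifnot(inherits(table, "abundance_table"))
  env_vars <- setdiff(names(env), "sample_id")
  env_vars <- env_vars[vapply(env_vars, function(v) is.numeric(env[[v]]), logical(1))]
  if (nrow(env) != nrow(table)) stop("table and env must be sample-aligned")
  taxa <- colnames(table)
  rho <- p <- matrix(NA_real_, length(taxa), length(env_vars),
                     dimnames = list(taxa, env_vars))
  nmat <- matrix(NA_integer_, length(taxa), length(env_vars),
                 dimnames = list(taxa, env_vars))
  for (i in seq_along(taxa)) for (j in seq_along(env_vars)) {
    x <- unclass(table)[, i]
    y <- env[[env_vars[j]]]
    ok <- !is.na(x) & !is.na(y)
    nmat[i, j] <- sum(ok)
    if (sum(ok) < 3) next
    s <- spearman_cor(x, y)
    if (s$defined) { rho[i, j] <- s$rho; p[i, j] <- s$p }
  }
  list(rho = rho, p = p, n = nmat, untestable = is.na(rho))
}

#' Write a correlation heatmap table as TSV
#'
#' Long format: taxon, variable, rho, p, n.
#'
#' @param heatmap result of [correlation_heatmap_table()].
#' @param path output path.
#' @export
write_heatmap_table <- function(heatmap, path) {
  long <- expand.grid(taxon = rownames(heatmap$rho),
                      variable = colnames(heatmap$rho),
                      stringsAsFactors = FALSE)
  long$rho <- as.vector(heatmap$rho)
  long$p <- as.vector(heatmap$p)
  long$n <- as.vector(heatmap$n)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
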