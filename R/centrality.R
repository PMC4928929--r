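#' Node centrality table
#'
#' Computes, on the directed expansion of the network:
#' * degree centrality: (in-degree + out-degree) / (2 (n - 1)), so each
#'   undirected edge counts once in each direction;
#' * PageRank with uniform teleport at damping `damping`, edge weights used
#'   as transition weights (row-normalized by out-strength);
#' * betweenness centrality on directed hop-count shortest paths,
#'   normalized by (n - 1)(n - 2).
#'
#' @param g gene_network
#' @param damping PageRank damping factor
#' @return data.frame with columns `gene`, `degree_centrality`, `pagerank`,
#'   `betweenness`, one row per node
#' @export
compute_centralities <- function(g, damping = 0.85) {
  if (g$n == 0L) stop("empty network")
  ig <- as_igraph(g)
  deg <- igraph::degree(ig, mode = "all")          # in + out on the expansion
  degc <- if (g$n > 1) deg / (2 * (g$n - 1)) else rep(0, g$n)
  pr <- igraph::page_rank(ig, damping = damping,
                          weights = igraph::E(ig)$weight)$vector
  btw <- igraph::betweenness(ig, directed = TRUE, weights = NA,
                             normalized = g$n > 2)
  out <- data.frame(gene = g$nodes,
                    degree_centrality = as.numeric(degc[g$nodes]),
                    pagerank = as.numeric(pr[g$nodes]),
                    betweenness = as.numeric(btw[g$nodes]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Correlate two per-gene quantities
#'
#' Pearson and Spearman correlations with two-sided p-values, over the
#' genes present in both inputs.
#'
#' @param values_x,values_y named numeric vectors (gene -> value)
#' @param level descriptive tag carried into the report (`"gene"` or
#'   `"group"`)
#' @param attribute optional descriptive tag
#' @return object of class `correlation_report`: `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`, `n`, `flagged` (TRUE when an input is
#'   constant and the coefficients are undefined)
#' @export
correlate <- function(values_x, values_y, level = "gene", attribute = NA_character_) {
  common <- intersect(names(values_x), names(values_y))
  common <- common[!is.na(values_x[common]) & !is.na(values_y[common])]
  if (length(common) < 3L) stop("need at least 3 genes with both values")
  x <- as.numeric(values_x[common]); y <- as.numeric(values_y[common])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input vector; correlation undefined")
    return(structure(list(level = level, attribute = attribute,
                          pearson_r = NA_real_, pearson_p = NA_real_,
                          spearman_rho = NA_real_, spearman_p = NA_real_,
                          n = length(common), flagged = TRUE),
                     class = "correlation_report"))
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  structure(list(level = level, attribute = attribute,
                 pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
                 spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
                 n = length(common), flagged = FALSE),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report (%s%s, n = %d): Pearson R = %.3f (p = %.3g), Spearman rho = %.3f (p = %.3g)%s\n",
              x$level, if (is.na(x$attribute)) "" else paste0(", ", x$attribute),
              x$n, x$pearson_r, x$pearson_p, x$spearman_rho, x$spearman_p,
              if (isTRUE(x$flagged)) " [flagged: constant input]" else ""))
  invisible(x)
}

#' Group-level centrality vs evolutionary attribute correlation
#'
#' Reduces each gene group to one point (mean centrality, mean attribute)
#' and correlates over groups — the group-level analogue of the gene-level
#' centrality/evolution correlation (e.g. mean PageRank versus mean age
#' per annotation group).
#'
#' @param groups named list of gene sets
#' @param ct centrality table from [compute_centralities()]
#' @param ann evo_annotation
#' @param measure centrality column: `"pagerank"`, `"degree_centrality"` or
#'   `"betweenness"`
#' @param attribute `"er"` or `"age"`
#' @return correlation_report over group means
#' @export
group_centrality_correlation <- function(groups, ct, ann,
                                         measure = c("pagerank", "degree_centrality", "betweenness"),
                                         attribute = c("er", "age")) {
  measure <- match.arg(measure)
  attribute <- match.arg(attribute)
  if (length(groups) < 3L) stop("need at least 3 groups")
  cvals <- stats::setNames(ct[[measure]], ct$gene)
  avals <- annotation_values(ann, attribute)
  pts <- lapply(groups, function(gs) {
    gs <- canonical_gene(gs)
    both <- gs[gs %in% names(cvals) & gs %in% names(avals)]
    if (!length(both)) return(c(NA_real_, NA_real_))
    c(mean(cvals[both]), mean(avals[both]))
  })
  cx <- vapply(pts, `[`, numeric(1), 1L)
  ax <- vapply(pts, `[`, numeric(1), 2L)
  keep <- !is.na(cx) & !is.na(ax)
  if (sum(keep) < length(groups))
    warning("groups without annotated genes dropped from the correlation")
  names(cx) <- names(ax) <- names(groups)
  correlate(cx[keep], ax[keep], level = "group", attribute = attribute)
}
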