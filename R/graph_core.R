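#' @useDynLib grnevo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

canonical_gene <- function(x) toupper(trimws(as.character(x)))

#' Construct a gene network
#'
#' A `gene_network` is a weighted, partially directed graph over gene
#' symbols. Undirected edges are represented internally as two reciprocal
#' directed edges sharing one weight; this directed expansion is the only
#' representation used by the distance, centrality, modularity and
#' efficiency machinery.
#'
#' Gene symbols are canonicalized (uppercased, whitespace stripped; no alias
#' resolution). Self-loops are rejected. Duplicate edges are merged by
#' `merge` (default: keep the maximum weight). A pair listed both as a
#' directed and as an undirected edge collapses to the undirected edge under
#' the same merge rule.
#'
#' @param edges data.frame with columns `source`, `target`, optional
#'   `weight` (strictly positive, default 1) and `directed` (logical or 0/1,
#'   default `directed_default`).
#' @param nodes optional character vector of additional (possibly isolated)
#'   gene symbols.
#' @param directed_default logical, directedness assumed for rows lacking a
#'   `directed` column.
#' @param merge duplicate-edge merge rule: `"max"`, `"sum"` or `"first"`.
#' @return object of class `gene_network` with fields `edges` (canonical
#'   edge table), `nodes`, `n` (node count) and `m` (total weight of the
#'   directed expansion; undirected edges count once per direction).
#' @export
gene_network <- function(edges, nodes = NULL, directed_default = TRUE,
                         merge = c("max", "sum", "first")) {
  merge <- match.arg(merge)
  stopifnot(is.data.frame(edges))
  if (!all(c("source", "target") %in% names(edges)))
    stop("edge table must have 'source' and 'target' columns")
  src <- canonical_gene(edges$source)
  tgt <- canonical_gene(edges$target)
  w <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, nrow(edges))
  dir <- if ("directed" %in% names(edges)) as.logical(as.integer(edges$directed))
         else rep(directed_default, nrow(edges))
  if (anyNA(w) || anyNA(dir))
    stop("non-numeric weight or non-boolean directed flag in edge table")
  if (any(w <= 0)) {
    bad <- which(w <= 0)[1]
    stop(sprintf("edge weight must be strictly positive (row %d: %g)", bad, w[bad]))
  }
  if (any(src == tgt)) {
    bad <- which(src == tgt)[1]
    stop(sprintf("self-loop rejected: '%s' (row %d)", src[bad], bad))
  }
  # canonical order for undirected endpoints
  flip <- !dir & src > tgt
  tmp <- src[flip]; src[flip] <- tgt[flip]; tgt[flip] <- tmp

  ed <- data.frame(source = src, target = tgt, weight = w, directed = dir,
                   stringsAsFactors = FALSE)
  ed <- merge_duplicates(ed, merge)
  ed <- collapse_cross_class(ed, merge)
  rownames(ed) <- NULL

  nodes <- sort(unique(c(ed$source, ed$target, canonical_gene(nodes))))
  nodes <- nodes[nzchar(nodes)]
  exp_w <- sum(ed$weight * ifelse(ed$directed, 1, 2))
  structure(list(edges = ed, nodes = nodes, n = length(nodes), m = exp_w,
                 cache = new.env(parent = emptyenv())),
            class = "gene_network")
}

merge_duplicates <- function(ed, merge) {
  key <- paste(ed$source, ed$target, ed$directed, sep = "\r")
  if (!anyDuplicated(key)) return(ed)
  agg <- switch(merge,
                max = tapply(ed$weight, key, max),
                sum = tapply(ed$weight, key, sum),
                first = tapply(ed$weight, key, function(x) x[1]))
  keep <- !duplicated(key)
  out <- ed[keep, , drop = FALSE]
  out$weight <- as.numeric(agg[paste(out$source, out$target, out$directed, sep = "\r")])
  rownames(out) <- NULL
  out
}

# a directed a->b duplicated by an undirected a-b collapses into the
# undirected edge under the weight-merge rule
collapse_cross_class <- function(ed, merge) {
  und <- ed[!ed$directed, , drop = FALSE]
  if (nrow(und) == 0L || !any(ed$directed)) return(ed)
  ukey <- c(paste(und$source, und$target), paste(und$target, und$source))
  dkey <- paste(ed$source, ed$target)
  clash <- ed$directed & dkey %in% ukey
  if (!any(clash)) return(ed)
  for (i in which(clash)) {
    a <- ed$source[i]; b <- ed$target[i]
    j <- which(!ed$directed &
               ((ed$source == a & ed$target == b) | (ed$source == b & ed$target == a)))[1]
    ed$weight[j] <- switch(merge,
                           max = max(ed$weight[j], ed$weight[i]),
                           sum = ed$weight[j] + ed$weight[i],
                           first = ed$weight[j])
  }
  out <- ed[!clash, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.gene_network <- function(x, ...) {
  nd <- sum(x$edges$directed); nu <- nrow(x$edges) - nd
  cat(sprintf("gene_network: %d nodes, %d edges (%d directed, %d undirected), total directed weight %.4g\n",
              x$n, nrow(x$edges), nd, nu, x$m))
  invisible(x)
}

#' Directed expansion of a gene network
#'
#' Every undirected edge becomes two reciprocal directed edges sharing its
#' weight; directed edges pass through unchanged.
#'
#' @param g gene_network
#' @return data.frame with columns `source`, `target`, `weight`
#' @export
directed_expansion <- function(g) {
  ed <- g$edges
  und <- ed[!ed$directed, , drop = FALSE]
  out <- rbind(
    data.frame(source = ed$source, target = ed$target, weight = ed$weight,
               stringsAsFactors = FALSE),
    data.frame(source = und$target, target = und$source, weight = und$weight,
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Convert to an igraph object
#'
#' Returns the directed expansion as a directed, weighted igraph graph with
#' all nodes (including isolates) as vertices.
#'
#' @param g gene_network
#' @return igraph graph
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "gene_network"))
  if (!is.null(g$cache$ig)) return(g$cache$ig)
  ex <- directed_expansion(g)
  ig <- igraph::graph_from_data_frame(ex, directed = TRUE,
                                      vertices = data.frame(name = g$nodes))
  g$cache$ig <- ig
  ig
}

#' Read a gene network from a TSV edge list
#'
#' Expects a header with columns `source` and `target`; optional `weight`
#' (default 1) and `directed` (0/1, default `directed_default`). Lines
#' starting with `#` are skipped.
#'
#' @inheritParams gene_network
#' @param path file path
#' @return gene_network
#' @export
load_edge_list <- function(path, directed_default = TRUE,
                           merge = c("max", "sum", "first")) {
  merge <- match.arg(merge)
  if (!file.exists(path)) stop(sprintf("edge list not found: %s", path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, strip.white = TRUE)
  if (!all(c("source", "target") %in% names(tab)))
    stop(sprintf("%s: header must name 'source' and 'target' columns", path))
  if ("weight" %in% names(tab)) {
    wnum <- suppressWarnings(as.numeric(tab$weight))
    if (anyNA(wnum)) {
      bad <- which(is.na(wnum))[1]
      stop(sprintf("%s: malformed weight '%s' at data row %d", path, tab$weight[bad], bad))
    }
    if (any(wnum < 0)) {
      bad <- which(wnum < 0)[1]
      stop(sprintf("%s: negative weight %g at data row %d", path, wnum[bad], bad))
    }
    tab$weight <- wnum
  }
  gene_network(tab, directed_default = directed_default, merge = merge)
}

#' Write a gene network as a TSV edge list
#'
#' @param g gene_network
#' @param path output file path
#' @param header_lines optional character vector of `#`-prefixed comment
#'   lines written before the column header
#' @export
write_edge_list <- function(g, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  writeLines("source\ttarget\tweight\tdirected", con)
  ed <- g$edges
  writeLines(sprintf("%s\t%s\t%.10g\t%d", ed$source, ed$target, ed$weight,
                     as.integer(ed$directed)), con)
  invisible(path)
}

#' Shortest-path distances on the full network
#'
#' Hop-count (unweighted BFS) distances on the directed expansion, from each
#' source to every node. `D[j, i]` is the number of directed edges on a
#' shortest path from `j` to `i`; unreachable pairs are `Inf`. Edge weights
#' are confidence scores, not lengths, so hops are the default metric; set
#' `weighted = TRUE` to use `1/weight` edge lengths instead.
#'
#' @param g gene_network
#' @param sources character vector of source genes (default: all nodes)
#' @param weighted use `1/weight` lengths instead of hop counts
#' @return numeric matrix, rows = sources, columns = all nodes
#' @export
shortest_path_distances <- function(g, sources = NULL, weighted = FALSE) {
  if (is.null(sources)) sources <- g$nodes
  sources <- canonical_gene(sources)
  unknown <- setdiff(sources, g$nodes)
  if (length(unknown))
    stop(sprintf("unknown source gene(s): %s", paste(unknown, collapse = ", ")))
  ig <- as_igraph(g)
  wts <- if (weighted) 1 / igraph::E(ig)$weight else NA
  D <- igraph::distances(ig, v = sources, to = igraph::V(ig), mode = "out",
                         weights = wts)
  D[sources, g$nodes, drop = FALSE]
}
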