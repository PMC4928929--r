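#' Degree-preserving rewiring of a gene network
#'
#' Randomizes the topology by double-edge swaps while preserving the exact
#' in- and out-degree of every node. Swaps are proposed separately within
#' the strictly directed edge class and the undirected edge class; a
#' proposal that would create a self-loop or duplicate an existing directed
#' pair is rejected. `n_swaps` counts swap *attempts*, not accepted swaps.
#' Edge weights travel with the edge slots, so the weight multiset per
#' class is preserved as well.
#'
#' @param g gene_network
#' @param n_swaps number of swap attempts (default: 10 x the number of
#'   canonical edges)
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used
#' @return rewired gene_network
#' @export
rewire <- function(g, n_swaps = NULL, seed = NULL) {
  if (is.null(n_swaps)) n_swaps <- 10L * nrow(g$edges)
  stopifnot(n_swaps >= 0)
  run <- function() rewire_int(g, n_swaps)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

rewire_int <- function(g, n_swaps) {
  ed <- g$edges
  if (n_swaps == 0L || nrow(ed) == 0L) return(g)
  nd <- sum(ed$directed); nu <- nrow(ed) - nd
  if (nd > 0 && nd < 2) warning("fewer than 2 strictly directed edges; class not rewired")
  if (nu > 0 && nu < 2) warning("fewer than 2 undirected edges; class not rewired")
  id <- stats::setNames(seq_len(g$n), g$nodes)
  res <- rewire_edges_cpp(unname(id[ed$source]), unname(id[ed$target]),
                          !ed$directed, g$n, as.integer(n_swaps))
  new_ed <- data.frame(source = g$nodes[res$source], target = g$nodes[res$target],
                       weight = ed$weight, directed = ed$directed,
                       stringsAsFactors = FALSE)
  gene_network(new_ed, nodes = g$nodes)
}

#' Edge-level assortativity test of an evolutionary attribute
#'
#' For every directed edge j -> i (undirected edges contribute both
#' orientations) with both endpoints annotated, records the difference
#' value(j) - value(i). The width (standard deviation) of this difference
#' distribution is compared with the widths obtained on `n_random`
#' degree-preserving rewirings of the network: interacting genes with
#' similar attribute values give a real width far below the null widths,
#' i.e. a strongly negative z-score.
#'
#' The empirical p-value uses the (r + 1) / (n + 1) estimator with r the
#' number of null widths at or below the real width, so with no null width
#' below the real one at n_random = 20000 the p-value is bounded at
#' 5.0e-5.
#'
#' @param g gene_network
#' @param ann evo_annotation
#' @param attribute `"er"` or `"age"`
#' @param n_random number of rewired replicates
#' @param seed integer seed
#' @param n_swaps swap attempts per replicate (default 10 x edges)
#' @return object of class `edge_diff_result`: `diffs`, `width`,
#'   `null_widths`, `z`, `p_upper`
#' @export
edge_diff_test <- function(g, ann, attribute = c("er", "age"),
                           n_random = 200L, seed = 1L, n_swaps = NULL) {
  attribute <- match.arg(attribute)
  stopifnot(n_random >= 1)
  if (is.null(n_swaps)) n_swaps <- 10L * nrow(g$edges)
  vals <- annotation_values(ann, attribute, drop_na = FALSE)
  v <- stats::setNames(rep(NA_real_, g$n), g$nodes)
  common <- intersect(g$nodes, names(vals))
  v[common] <- vals[common]

  ed <- g$edges
  id <- stats::setNames(seq_len(g$n), g$nodes)
  es <- unname(id[ed$source]); et <- unname(id[ed$target])
  vv <- unname(v)

  diffs_of <- function(s, t) {
    und <- !ed$directed
    sj <- c(s, t[und]); ti <- c(t, s[und])   # directed expansion j -> i
    d <- vv[sj] - vv[ti]
    d[!is.na(d)]
  }
  diffs <- diffs_of(es, et)
  if (!length(diffs)) stop("no edge has both endpoints annotated")
  width <- stats::sd(diffs)

  null_widths <- withr::with_seed(seed, {
    vapply(seq_len(n_random), function(r) {
      rw <- rewire_edges_cpp(es, et, !ed$directed, g$n, as.integer(n_swaps))
      stats::sd(diffs_of(rw$source, rw$target))
    }, numeric(1))
  })
  sdn <- stats::sd(null_widths)
  z <- if (is.na(sdn) || sdn == 0) {
    warning("null widths have zero variance; z undefined")
    NA_real_
  } else (width - mean(null_widths)) / sdn
  r <- sum(null_widths <= width)
  structure(list(diffs = diffs, width = width, null_widths = null_widths,
                 z = z, p_upper = (r + 1) / (n_random + 1),
                 attribute = attribute),
            class = "edge_diff_result")
}

#' @export
print.edge_diff_result <- function(x, ...) {
  cat(sprintf("edge_diff_result (%s): %d edge differences, width %.4g, null %.4g +/- %.3g, z = %.2f, p <= %.3g\n",
              x$attribute, length(x$diffs), x$width, mean(x$null_widths),
              stats::sd(x$null_widths), x$z, x$p_upper))
  invisible(x)
}

#' Group mean-shift test against equal-size random gene sets
#'
#' Tests whether a gene group (a community or an annotation group) has a
#' significantly higher or lower mean ER/age than `n_sets` equally sized
#' sets of genes drawn uniformly (without replacement) from the annotated
#' genes of the network. The one-tailed p-value is a normal tail computed
#' from the mean and standard deviation of the null set-means, in the
#' direction of the observed difference; groups significant at `alpha` are
#' labeled `hot`/`cold` (ER) or `young`/`old` (age; larger index =
#' younger), otherwise `average`. A two-sample Kolmogorov-Smirnov statistic
#' of the group values against all annotated values is reported alongside.
#'
#' @param g gene_network
#' @param ann evo_annotation
#' @param group character vector of gene symbols (subset of the annotated
#'   network genes)
#' @param attribute `"er"` or `"age"`
#' @param n_sets number of random sets
#' @param alpha one-tailed significance threshold for labeling
#' @param seed integer seed
#' @param name optional group name carried into the result
#' @return object of class `group_stats`: `name`, `size`, `attribute`,
#'   `group_mean`, `diff_in_mean`, `p`, `label`, `ks_stat`, `ks_p`
#' @export
group_mean_test <- function(g, ann, group, attribute = c("er", "age"),
                            n_sets = 300L, alpha = 1e-3, seed = 1L,
                            name = NA_character_) {
  attribute <- match.arg(attribute)
  group <- canonical_gene(group)
  vals <- annotation_values(ann, attribute)
  universe <- intersect(g$nodes, names(vals))
  if (length(group) < 2L) stop("group must contain at least 2 genes")
  if (!all(group %in% universe)) {
    bad <- setdiff(group, universe)[1]
    stop(sprintf("group gene '%s' is not an annotated network gene", bad))
  }
  if (length(group) > length(universe))
    stop("group larger than the annotated gene universe")
  gv <- vals[group]
  # sample from the sorted value vector so the null depends only on the
  # value multiset and the group size, not on gene labels
  uv <- sort(as.numeric(vals[universe]))
  set_means <- withr::with_seed(seed, {
    vapply(seq_len(n_sets), function(s)
      mean(uv[sample.int(length(uv), length(group))]), numeric(1))
  })
  mu <- mean(set_means); sdv <- stats::sd(set_means)
  diff <- mean(gv) - mu
  p <- if (is.na(sdv) || sdv == 0) {
    if (diff == 0) 1 else 0
  } else {
    z <- diff / sdv
    stats::pnorm(z, lower.tail = diff < 0)
  }
  label <- "average"
  if (p < alpha && diff != 0) {
    label <- if (attribute == "er") {
      if (diff > 0) "hot" else "cold"
    } else {
      if (diff > 0) "young" else "old"
    }
  }
  ks <- suppressWarnings(stats::ks.test(gv, vals[universe]))
  structure(list(name = name, size = length(group), attribute = attribute,
                 group_mean = mean(gv), diff_in_mean = diff, p = p,
                 label = label, ks_stat = unname(ks$statistic),
                 ks_p = ks$p.value),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("group_stats '%s' (%s, n = %d): mean %.4g, diff %.4g, p = %.3g -> %s; KS = %.3f (p = %.3g)\n",
              x$name, x$attribute, x$size, x$group_mean, x$diff_in_mean,
              x$p, x$label, x$ks_stat, x$ks_p))
  invisible(x)
}

#' Shuffled-community control partition
#'
#' Randomly permutes genes across communities while keeping every community
#' size exactly as in the input partition; the control used to show that
#' evolutionary homogeneity and annotation enrichment of real communities
#' is not a size artifact.
#'
#' @param p community_partition
#' @param seed integer seed
#' @param g optional gene_network to recompute Q on the shuffled partition
#' @return community_partition
#' @export
shuffled_community_control <- function(p, seed = 1L, g = NULL) {
  stopifnot(inherits(p, "community_partition"))
  genes <- names(p$assignment)
  labels <- unname(p$assignment)
  shuffled <- withr::with_seed(seed, sample(labels))
  community_partition(stats::setNames(shuffled, genes), g)
}
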