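efficiency_result <- function(value, contributing, unreachable) {
  structure(list(value = value, contributing_pairs = as.integer(contributing),
                 unreachable_pairs = as.integer(unreachable)),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("efficiency_result: %.6g (%d contributing, %d unreachable ordered pairs)\n",
              x$value, x$contributing_pairs, x$unreachable_pairs))
  invisible(x)
}

inv_dist_sum <- function(D, same = NULL) {
  # sum of 1/d over finite, nonzero entries; `same` marks ordered pairs of
  # identical genes (excluded from numerator and denominator)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  if (!is.null(same)) inv[same] <- 0
  n_excl <- if (is.null(same)) sum(D == 0) else sum(same)
  list(s = sum(inv), contributing = sum(inv > 0),
       pairs = length(D) - n_excl)
}

#' Global efficiency of a network
#'
#' \deqn{E_{global} = \frac{1}{n(n-1)} \sum_{i \ne j} \frac{1}{d_{ij}}}
#' with \eqn{d_{ij}} the hop-count distance from node j to node i on the
#' directed expansion. Unreachable ordered pairs contribute 0, so
#' \eqn{0 \le E \le 1} in unweighted mode; the denominator is always
#' \eqn{n(n-1)}.
#'
#' @param g gene_network
#' @param weighted use `1/weight` edge lengths instead of hop counts
#' @return efficiency_result
#' @export
global_efficiency <- function(g, weighted = FALSE) {
  if (g$n < 2L) stop("global efficiency undefined for fewer than 2 nodes")
  D <- shortest_path_distances(g, weighted = weighted)
  r <- inv_dist_sum(D, same = outer(rownames(D), colnames(D), `==`))
  efficiency_result(r$s / (g$n * (g$n - 1)), r$contributing,
                    r$pairs - r$contributing)
}

#' Set efficiency of a gene set
#'
#' \deqn{E_M = \frac{1}{|M|(|M|-1)} \sum_{i \ne j \in M} \frac{1}{d_{ij}}}
#' Distances are measured on the full network, so shortest paths may pass
#' through nodes outside `M`. With `M` equal to the whole node set this is
#' exactly the global efficiency.
#'
#' @param g gene_network
#' @param M character vector of gene symbols, at least 2
#' @param weighted use `1/weight` edge lengths
#' @return efficiency_result
#' @export
set_efficiency <- function(g, M, weighted = FALSE) {
  M <- unique(canonical_gene(M))
  if (length(M) < 2L) stop("set efficiency undefined for a singleton set")
  unknown <- setdiff(M, g$nodes)
  if (length(unknown))
    stop(sprintf("unknown gene(s) in set: %s", paste(unknown, collapse = ", ")))
  D <- shortest_path_distances(g, sources = M, weighted = weighted)[, M, drop = FALSE]
  r <- inv_dist_sum(D, same = outer(rownames(D), colnames(D), `==`))
  k <- length(M)
  efficiency_result(r$s / (k * (k - 1)), r$contributing, r$pairs - r$contributing)
}

#' Interset efficiency from set J to set I
#'
#' \deqn{E_{IJ} = \frac{1}{|I||J| - |I \cap J|} \sum_{i \in I, j \in J, i \ne j} \frac{1}{d_{ij}}}
#' with \eqn{d_{ij}} the distance from j to i on the full network. The
#' measure is asymmetric on directed networks; the overlap correction in
#' the denominator makes \eqn{E_{II} = E_I} exactly.
#'
#' @param g gene_network
#' @param I target gene set (rows)
#' @param J source gene set (columns)
#' @param weighted use `1/weight` edge lengths
#' @return efficiency_result
#' @export
interset_efficiency <- function(g, I, J, weighted = FALSE) {
  I <- unique(canonical_gene(I)); J <- unique(canonical_gene(J))
  unknown <- setdiff(c(I, J), g$nodes)
  if (length(unknown))
    stop(sprintf("unknown gene(s) in set: %s", paste(unknown, collapse = ", ")))
  denom <- length(I) * length(J) - length(intersect(I, J))
  if (denom <= 0) stop("interset efficiency undefined: denominator |I||J| - |I^J| is 0")
  D <- shortest_path_distances(g, sources = J, weighted = weighted)[, I, drop = FALSE]
  r <- inv_dist_sum(D, same = outer(rownames(D), colnames(D), `==`))
  efficiency_result(r$s / denom, r$contributing, r$pairs - r$contributing)
}

#' Cumulative set-efficiency curve along an attribute ranking
#'
#' Sorts annotated genes ascending by the attribute (coldest to hottest,
#' or oldest to youngest; ties broken by gene symbol), then computes the
#' set efficiency of the first `start` genes, the first `start + step`,
#' and so on until all annotated genes are included. `n_controls` control
#' curves are computed on random orderings of the same genes (seeded by
#' `seed`), reported as mean and standard deviation per window; the final
#' window covers the same set in the real and every control curve, so the
#' values coincide there exactly.
#'
#' @param g gene_network
#' @param ann evo_annotation
#' @param attribute `"er"` or `"age"`
#' @param start first window size
#' @param step window increment in genes
#' @param n_controls number of shuffled-order control curves
#' @param seed integer seed (governs control shuffles only)
#' @return object of class `se_curve`: data.frame-like fields `ranks`,
#'   `se`, `control_mean`, `control_sd`
#' @export
cumulative_se_curve <- function(g, ann, attribute = c("er", "age"),
                                start = 500L, step = 10L, n_controls = 100L,
                                seed = 1L) {
  attribute <- match.arg(attribute)
  vals <- annotation_values(ann, attribute)
  genes <- intersect(g$nodes, names(vals))
  n_ann <- length(genes)
  if (start > n_ann)
    stop(sprintf("first window (%d) exceeds annotated gene count (%d)", start, n_ann))
  ordg <- genes[order(vals[genes], genes)]
  ranks <- seq.int(start, n_ann, by = step)
  if (ranks[length(ranks)] < n_ann) ranks <- c(ranks, n_ann)

  D <- shortest_path_distances(g, sources = ordg)[, ordg, drop = FALSE]
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0

  prefix_se <- function(perm) {
    # running sum of 1/d over ordered pairs within growing prefixes
    s <- 0
    out <- numeric(length(ranks))
    ri <- 1L
    for (k in seq_len(n_ann)) {
      idx <- perm[k]
      if (k > 1L) {
        prev <- perm[seq_len(k - 1L)]
        s <- s + sum(inv[idx, prev]) + sum(inv[prev, idx])
      }
      if (ri <= length(ranks) && k == ranks[ri]) {
        out[ri] <- s / (k * (k - 1))
        ri <- ri + 1L
      }
    }
    out
  }
  se <- prefix_se(seq_len(n_ann))
  controls <- withr::with_seed(seed, {
    vapply(seq_len(n_controls), function(cc) prefix_se(sample.int(n_ann)),
           numeric(length(ranks)))
  })
  structure(list(ranks = ranks, se = se,
                 control_mean = rowMeans(controls),
                 control_sd = apply(controls, 1L, stats::sd),
                 attribute = attribute, genes = ordg),
            class = "se_curve")
}

#' @export
print.se_curve <- function(x, ...) {
  cat(sprintf("se_curve (%s): %d windows from %d to %d genes; SE %.4g -> %.4g\n",
              x$attribute, length(x$ranks), x$ranks[1], x$ranks[length(x$ranks)],
              x$se[1], x$se[length(x$se)]))
  invisible(x)
}

#' Interset-efficiency matrix over age-ordered groups
#'
#' Orders the groups by mean age ascending (oldest first) and fills the
#' full asymmetric matrix of interset efficiencies, entry (row i, column j)
#' being the efficiency from group j to group i. Diagonal entries equal
#' each group's set efficiency. Groups without annotated genes are dropped
#' with a warning.
#'
#' @param g gene_network
#' @param groups named list of gene sets
#' @param ann evo_annotation
#' @param weighted use `1/weight` edge lengths
#' @return object of class `ie_matrix`: `matrix` (named), `group_order`,
#'   `mean_age`
#' @export
ie_matrix <- function(g, groups, ann, weighted = FALSE) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  ages <- annotation_values(ann, "age")
  mean_age <- vapply(groups, function(gs) {
    gs <- intersect(canonical_gene(gs), names(ages))
    if (!length(gs)) NA_real_ else mean(ages[gs])
  }, numeric(1))
  if (anyNA(mean_age)) {
    warning(sprintf("group(s) with no annotated genes excluded: %s",
                    paste(names(groups)[is.na(mean_age)], collapse = ", ")))
    groups <- groups[!is.na(mean_age)]
    mean_age <- mean_age[!is.na(mean_age)]
  }
  ord <- order(mean_age, names(groups))
  groups <- groups[ord]; mean_age <- mean_age[ord]
  k <- length(groups)
  M <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    M[i, j] <- interset_efficiency(g, I = groups[[i]], J = groups[[j]],
                                   weighted = weighted)$value
  }
  structure(list(matrix = M, group_order = names(groups), mean_age = mean_age),
            class = "ie_matrix")
}

#' @export
print.ie_matrix <- function(x, ...) {
  cat(sprintf("ie_matrix: %d groups ordered oldest to youngest (mean ages %s)\n",
              length(x$group_order),
              paste(sprintf("%.2f", x$mean_age), collapse = ", ")))
  print(round(x$matrix, 4))
  invisible(x)
}
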