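# Independent oracles used across tests: brute-force all-pairs distances,
# efficiency summation, modularity evaluation, PageRank power iteration,
# and a random partially-directed graph generator.

random_mixed_graph <- function(n, p_dir = 0.12, p_und = 0.08, seed = 1) {
  withr::with_seed(seed, {
    nodes <- sprintf("N%02d", seq_len(n))
    op <- expand.grid(i = seq_len(n), j = seq_len(n))
    op <- op[op$i != op$j, ]
    dsel <- op[stats::runif(nrow(op)) < p_dir, ]
    up <- t(utils::combn(n, 2L))
    usel <- up[stats::runif(nrow(up)) < p_und, , drop = FALSE]
    ed <- rbind(
      if (nrow(dsel)) data.frame(source = nodes[dsel$i], target = nodes[dsel$j],
                                 weight = 1, directed = TRUE),
      if (nrow(usel)) data.frame(source = nodes[usel[, 1]], target = nodes[usel[, 2]],
                                 weight = 1, directed = FALSE))
    if (is.null(ed) || nrow(ed) == 0L)
      ed <- data.frame(source = nodes[1], target = nodes[2], weight = 1,
                       directed = TRUE)
    gene_network(ed, nodes = nodes)
  })
}

# Floyd-Warshall hop distances on the directed expansion; D[i, j] = hops
# from i to j (same orientation as shortest_path_distances rows).
fw_distances <- function(g) {
  n <- g$n
  D <- matrix(Inf, n, n, dimnames = list(g$nodes, g$nodes))
  diag(D) <- 0
  ex <- directed_expansion(g)
  for (k in seq_len(nrow(ex))) D[ex$source[k], ex$target[k]] <- 1
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

brute_pair_sum <- function(D, I, J) {
  # sum over i in I, j in J, i != j of 1 / d(j -> i); D rows are sources
  s <- 0
  for (i in I) for (j in J) {
    if (i == j) next
    d <- D[j, i]
    if (is.finite(d) && d > 0) s <- s + 1 / d
  }
  s
}

brute_global_efficiency <- function(g) {
  D <- fw_distances(g)
  brute_pair_sum(D, g$nodes, g$nodes) / (g$n * (g$n - 1))
}

brute_set_efficiency <- function(g, M) {
  D <- fw_distances(g)
  brute_pair_sum(D, M, M) / (length(M) * (length(M) - 1))
}

brute_interset_efficiency <- function(g, I, J) {
  D <- fw_distances(g)
  brute_pair_sum(D, I, J) / (length(I) * length(J) - length(intersect(I, J)))
}

brute_modularity <- function(g, memb) {
  ex <- directed_expansion(g)
  W <- matrix(0, g$n, g$n, dimnames = list(g$nodes, g$nodes))
  for (k in seq_len(nrow(ex)))
    W[ex$source[k], ex$target[k]] <- W[ex$source[k], ex$target[k]] + ex$weight[k]
  m <- sum(W)
  so <- rowSums(W); si <- colSums(W)
  q <- 0
  for (i in g$nodes) for (j in g$nodes) {
    if (memb[[i]] == memb[[j]]) q <- q + W[i, j] / m - so[[i]] * si[[j]] / m^2
  }
  q
}

power_iteration_pagerank <- function(g, damping = 0.85, tol = 1e-13) {
  ex <- directed_expansion(g)
  n <- g$n
  W <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  for (k in seq_len(nrow(ex)))
    W[ex$source[k], ex$target[k]] <- W[ex$source[k], ex$target[k]] + ex$weight[k]
  outs <- rowSums(W)
  P <- W / ifelse(outs > 0, outs, 1)
  dangling <- outs == 0
  x <- rep(1 / n, n)
  repeat {
    x_new <- (1 - damping) / n +
      damping * (as.numeric(crossprod(P, x)) + sum(x[dangling]) / n)
    if (max(abs(x_new - x)) < tol) break
    x <- x_new
  }
  stats::setNames(x_new / sum(x_new), g$nodes)
}

expansion_degrees <- function(g) {
  ex <- directed_expansion(g)
  list(out = table(factor(ex$source, levels = g$nodes)),
       `in` = table(factor(ex$target, levels = g$nodes)))
}

# larger core-periphery configuration used where a 500-gene first window
# is meaningful
big_cp_config <- function(seed = 1L) {
  synth_config(n_communities = 6L, sizes = 200L,
               er_centers = seq(0.5, 3, length.out = 6),
               age_centers = round(seq(1, 11, length.out = 6)),
               seed = seed)
}
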