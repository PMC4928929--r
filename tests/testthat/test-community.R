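two_cycles <- function() {
  gene_network(data.frame(source = c("a", "b", "c", "d", "e", "f"),
                          target = c("b", "c", "a", "e", "f", "d")))
}

test_that("directed modularity matches hand and brute-force evaluation", {
  g <- two_cycles()
  comp <- stats::setNames(c(1, 1, 1, 2, 2, 2), g$nodes)
  expect_equal(directed_modularity(g, comp), 0.5)
  expect_equal(directed_modularity(g, stats::setNames(rep(1, 6), g$nodes)), 0)
  expect_error(directed_modularity(g, comp[-1]), "missing from partition")

  for (s in 1:10) {
    gr <- random_mixed_graph(8, seed = s)
    memb <- stats::setNames(withr::with_seed(s, sample(1:3, 8, replace = TRUE)),
                            gr$nodes)
    expect_equal(directed_modularity(gr, memb), brute_modularity(gr, memb))
    # independent library implementation agrees as well
    ig <- as_igraph(gr)
    expect_equal(directed_modularity(gr, memb),
                 igraph::modularity(ig, memb[igraph::V(ig)$name],
                                    weights = igraph::E(ig)$weight,
                                    directed = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("trivial one-community partition has Q = 0 on arbitrary graphs", {
  for (s in 1:12) {
    g <- random_mixed_graph(6L + s, seed = 100 + s)
    expect_equal(directed_modularity(g, stats::setNames(rep(1, g$n), g$nodes)), 0)
  }
})

test_that("community detection recovers planted blocks and never loses to trivial", {
  # two dense blocks joined by one edge
  nodes <- c(sprintf("A%d", 1:6), sprintf("B%d", 1:6))
  ed <- withr::with_seed(3, {
    pairs <- rbind(t(utils::combn(1:6, 2)), t(utils::combn(7:12, 2)))
    pairs <- pairs[stats::runif(nrow(pairs)) < 0.9, ]
    rbind(data.frame(source = nodes[pairs[, 1]], target = nodes[pairs[, 2]],
                     directed = FALSE),
          data.frame(source = "A1", target = "B1", directed = FALSE))
  })
  g <- gene_network(ed)
  p <- detect_communities(g, seed = 7)
  expect_equal(length(p$communities), 2L)
  expect_setequal(p$communities[[which(vapply(p$communities, function(x) "A1" %in% x, TRUE))]],
                  toupper(nodes[1:6]))
  expect_gte(p$Q, 0)

  # complete digraph cannot be improved by splitting
  cg <- gene_network(expand.grid(source = letters[1:5], target = letters[1:5],
                                 stringsAsFactors = FALSE) |>
                       subset(source != target))
  pc <- detect_communities(cg, seed = 1)
  expect_equal(length(pc$communities), 1L)
  expect_equal(pc$Q, 0)
})

test_that("detection is deterministic given the seed", {
  b <- generate(synth_config(sizes = 40L, seed = 5))
  p1 <- detect_communities(b$network, seed = 11)
  p2 <- detect_communities(b$network, seed = 11)
  expect_identical(p1$assignment, p2$assignment)
  expect_identical(p1$Q, p2$Q)
})

test_that("planted stochastic-block partitions are recovered with high NMI", {
  nmis <- vapply(1:5, function(s) {
    b <- generate(synth_config(seed = s))
    partition_nmi(detect_communities(b$network, seed = s), b$partition)
  }, numeric(1))
  expect_true(all(nmis >= 0.8))
})

test_that("top_communities orders by size with deterministic ties", {
  assign <- stats::setNames(c(1, 1, 1, 1, 1, 2, 2, 2, 3, 3, 3, 4),
                            c(paste0("P", 1:5), paste0("Z", 1:3),
                              paste0("B", 1:3), "Q"))
  p <- community_partition(assign)
  tops <- top_communities(p, 2)
  expect_equal(lengths(tops), c(`0` = 5L, `1` = 3L))
  # equal-size tie broken by smallest member gene: B* before Z*
  expect_true("B1" %in% tops[[2]])
  expect_warning(all4 <- top_communities(p, 10), "has 4")
  expect_equal(length(all4), 4L)
})

test_that("spy order sorts by community size then out-degree", {
  g <- gene_network(data.frame(source = c("a", "a", "a", "b", "d"),
                               target = c("b", "c", "d", "c", "e")))
  p <- community_partition(stats::setNames(c(1, 1, 1, 2, 2),
                                           c("A", "B", "C", "D", "E")))
  ord <- spy_order(g, p)
  # size-2 community {D, E} first; D has out-degree 1 > E
  expect_equal(ord[1:2], c("D", "E"))
  # within {A,B,C}: A out-degree 3, B 1, C 0
  expect_equal(ord[3:5], c("A", "B", "C"))
})

test_that("NMI is 1 for identical partitions and low for independent ones", {
  a <- stats::setNames(rep(1:4, each = 25), sprintf("G%03d", 1:100))
  expect_equal(partition_nmi(a, a), 1)
  b <- stats::setNames(withr::with_seed(1, sample(rep(1:4, each = 25))),
                       sprintf("G%03d", 1:100))
  expect_lt(partition_nmi(a, b), 0.2)
})
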