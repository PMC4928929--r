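test_that("rewiring preserves degree sequences and graph invariants", {
  for (s in 1:6) {
    g <- random_mixed_graph(15, p_dir = 0.15, p_und = 0.1, seed = s)
    rw <- rewire(g, n_swaps = 2000L, seed = s + 100)
    expect_equal(rw$n, g$n)
    expect_equal(rw$m, g$m)
    d0 <- expansion_degrees(g); d1 <- expansion_degrees(rw)
    expect_equal(d1$out, d0$out)
    expect_equal(d1$`in`, d0$`in`)
    ex <- directed_expansion(rw)
    expect_false(any(ex$source == ex$target))
    expect_false(anyDuplicated(paste(ex$source, ex$target)) > 0)
    # directed/undirected class sizes unchanged
    expect_equal(sum(rw$edges$directed), sum(g$edges$directed))
  }
})

test_that("a directed 3-cycle cannot be rewired and n_swaps = 0 is identity", {
  g3 <- gene_network(data.frame(source = c("a", "b", "c"),
                                target = c("b", "c", "a")))
  rw <- rewire(g3, n_swaps = 500L, seed = 4)
  expect_setequal(paste(rw$edges$source, rw$edges$target),
                  paste(g3$edges$source, g3$edges$target))
  g <- random_mixed_graph(10, seed = 2)
  expect_identical(rewire(g, n_swaps = 0L)$edges, g$edges)
})

test_that("rewiring actually randomizes larger graphs", {
  g <- generate(synth_config(sizes = 50L, seed = 9))$network
  rw <- rewire(g, seed = 1)
  ov <- mean(paste(directed_expansion(rw)$source, directed_expansion(rw)$target) %in%
             paste(directed_expansion(g)$source, directed_expansion(g)$target))
  expect_lt(ov, 0.3)
})

test_that("edge differences and their width behave at fixed points", {
  g <- random_mixed_graph(12, seed = 3)
  # constant attribute: all differences zero, zero width
  ann <- evo_annotation(er = stats::setNames(rep(1.5, g$n), g$nodes))
  res <- suppressWarnings(edge_diff_test(g, ann, "er", n_random = 20, seed = 1))
  expect_true(all(res$diffs == 0))
  expect_equal(res$width, 0)
  # p estimator is (r+1)/(n+1): never 0, at most 1
  expect_gte(res$p_upper, 1 / 21)
  expect_lte(res$p_upper, 1)
})

test_that("edge differences include both orientations of undirected edges", {
  g <- gene_network(data.frame(source = c("a", "b"), target = c("b", "c"),
                               directed = c(FALSE, TRUE)))
  ann <- evo_annotation(er = c(A = 1, B = 2, C = 4))
  d <- suppressWarnings(edge_diff_test(g, ann, "er", n_random = 1, seed = 1))$diffs
  expect_setequal(d, c(-1, 1, -2))
})

test_that("group mean test recovers planted shifts and labels correctly", {
  b <- generate(synth_config(seed = 21))
  ervals <- annotation_values(b$annotation, "er")
  comm_means <- vapply(b$partition$communities, function(cc) mean(ervals[cc]),
                       numeric(1))
  hot <- b$partition$communities[[which.max(comm_means)]]
  cold <- b$partition$communities[[which.min(comm_means)]]
  gs_hot <- group_mean_test(b$network, b$annotation, hot, "er", seed = 2)
  gs_cold <- group_mean_test(b$network, b$annotation, cold, "er", seed = 2)
  expect_equal(gs_hot$label, "hot")
  expect_lt(gs_hot$p, 1e-3)
  expect_equal(gs_cold$label, "cold")
  expect_gt(gs_hot$ks_stat, 0)

  # oldest community (lowest mean age) labels "old"
  agevals <- annotation_values(b$annotation, "age")
  old <- b$partition$communities[[which.min(vapply(b$partition$communities,
                                                   function(cc) mean(agevals[cc]),
                                                   numeric(1)))]]
  expect_equal(group_mean_test(b$network, b$annotation, old, "age", seed = 2)$label,
               "old")
})

test_that("group equal to the whole annotated universe is average with zero shift", {
  g <- random_mixed_graph(10, seed = 5)
  ann <- evo_annotation(er = stats::setNames(withr::with_seed(5, stats::runif(10)),
                                             g$nodes))
  gs <- group_mean_test(g, ann, g$nodes, "er", seed = 3)
  expect_equal(gs$diff_in_mean, 0)
  expect_equal(gs$label, "average")
  # identical group and background distributions give KS = 0
  expect_equal(gs$ks_stat, 0)
})

test_that("group mean p depends only on the value multiset and group size", {
  g <- random_mixed_graph(12, seed = 8)
  vals <- withr::with_seed(8, stats::rnorm(12, 1, 0.3))
  ann1 <- evo_annotation(er = stats::setNames(vals, g$nodes))
  relabel <- withr::with_seed(9, sample(g$nodes))
  ann2 <- evo_annotation(er = stats::setNames(vals, relabel))
  grp1 <- g$nodes[1:4]
  grp2 <- relabel[1:4]
  p1 <- group_mean_test(g, ann1, grp1, "er", seed = 7)$p
  p2 <- group_mean_test(g, ann2, grp2, "er", seed = 7)$p
  expect_equal(p1, p2)
})

test_that("shuffled community control preserves sizes exactly", {
  b <- generate(synth_config(sizes = 30L, seed = 4))
  sh <- shuffled_community_control(b$partition, seed = 5)
  expect_equal(sort(lengths(sh$communities)), sort(lengths(b$partition$communities)))
  expect_setequal(names(sh$assignment), names(b$partition$assignment))
  # single community: identical partition
  one <- community_partition(stats::setNames(rep(1, 5), sprintf("G%d", 1:5)))
  expect_identical(shuffled_community_control(one, seed = 1)$assignment,
                   one$assignment)
  # shuffling destroys enrichment: planted sets enrich less significantly
  enr_real <- enrich_communities(b$partition, b$sets, universe = b$network$nodes,
                                 threshold = 1.01, top_k = 100L)
  enr_sh <- enrich_communities(sh, b$sets, universe = b$network$nodes,
                               threshold = 1.01, top_k = 100L)
  expect_lt(min(enr_real$p_adj), min(enr_sh$p_adj))
})
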