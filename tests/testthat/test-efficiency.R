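test_that("worked toy values are exact", {
  g3 <- gene_network(data.frame(source = c("a", "b", "c"),
                                target = c("b", "c", "a")))
  expect_equal(global_efficiency(g3)$value, 0.75)

  path <- gene_network(data.frame(source = c("a", "b"), target = c("b", "c"),
                                  directed = FALSE))
  expect_equal(set_efficiency(path, c("a", "c"))$value, 0.5)

  tri <- gene_network(data.frame(source = c("a", "a", "b"),
                                 target = c("b", "c", "c"), directed = FALSE))
  expect_equal(interset_efficiency(tri, I = c("a", "b"), J = c("b", "c"))$value, 1.0)

  # complete digraph: efficiency 1; edgeless pairs: 0
  cd <- gene_network(subset(expand.grid(source = letters[1:4], target = letters[1:4],
                                        stringsAsFactors = FALSE), source != target))
  expect_equal(global_efficiency(cd)$value, 1.0)
  two <- gene_network(data.frame(source = "a", target = "b"), nodes = c("c", "d"))
  expect_equal(set_efficiency(two, c("c", "d"))$value, 0.0)
})

test_that("degenerate sets are rejected", {
  g <- gene_network(data.frame(source = "a", target = "b"))
  expect_error(set_efficiency(g, "a"), "singleton")
  expect_error(interset_efficiency(g, "a", "a"), "denominator")
  expect_error(set_efficiency(g, c("a", "zz")), "unknown gene")
  expect_error(global_efficiency(gene_network(data.frame(source = "a", target = "b")[0, ],
                                              nodes = "a")), "fewer than 2")
})

test_that("efficiencies match brute-force summation over a distance oracle", {
  for (s in 1:20) {
    g <- random_mixed_graph(6L + (s %% 8L), seed = 300 + s)
    expect_equal(global_efficiency(g)$value, brute_global_efficiency(g),
                 tolerance = 1e-12)
    sets <- withr::with_seed(s, list(
      M = sample(g$nodes, 4),
      I = sample(g$nodes, 3),
      J = sample(g$nodes, 4)))
    expect_equal(set_efficiency(g, sets$M)$value,
                 brute_set_efficiency(g, sets$M), tolerance = 1e-12)
    expect_equal(interset_efficiency(g, sets$I, sets$J)$value,
                 brute_interset_efficiency(g, sets$I, sets$J), tolerance = 1e-12)
  }
})

test_that("E_II equals E_I exactly and whole-node set equals global", {
  for (s in 1:8) {
    g <- random_mixed_graph(12, seed = 400 + s)
    M <- withr::with_seed(s, sample(g$nodes, 5))
    expect_identical(interset_efficiency(g, M, M)$value,
                     set_efficiency(g, M)$value)
    expect_equal(set_efficiency(g, g$nodes)$value, global_efficiency(g)$value)
  }
})

test_that("adding edges never decreases any efficiency", {
  g <- random_mixed_graph(12, p_dir = 0.08, seed = 17)
  extra <- data.frame(source = c("N01", "N05", "N09"),
                      target = c("N07", "N11", "N02"), weight = 1, directed = TRUE)
  g2 <- gene_network(rbind(g$edges, extra), nodes = g$nodes)
  expect_gte(global_efficiency(g2)$value, global_efficiency(g)$value)
  M <- c("N01", "N04", "N07", "N11")
  expect_gte(set_efficiency(g2, M)$value, set_efficiency(g, M)$value)
})

test_that("directed IE matrices are asymmetric, age-ordered and diagonal-consistent", {
  b <- generate(synth_config(sizes = 30L, seed = 31))
  iem <- ie_matrix(b$network, b$sets$sets, b$annotation)
  expect_false(isSymmetric(iem$matrix))
  expect_true(all(diff(iem$mean_age) >= 0))     # oldest group first
  for (nm in iem$group_order)
    expect_equal(iem$matrix[nm, nm], set_efficiency(b$network, b$sets$sets[[nm]])$value)
  expect_true(all(iem$matrix >= 0 & iem$matrix <= 1))
  # element-wise brute-force check on a small directed toy graph
  g <- random_mixed_graph(10, seed = 77)
  ann <- evo_annotation(age = stats::setNames(rep(c(1, 9), each = 5), g$nodes))
  groups <- list(old = g$nodes[1:5], young = g$nodes[6:10])
  iem2 <- ie_matrix(g, groups, ann)
  expect_equal(iem2$group_order, c("old", "young"))
  for (i in 1:2) for (j in 1:2)
    expect_equal(iem2$matrix[i, j],
                 brute_interset_efficiency(g, groups[[iem2$group_order[i]]],
                                           groups[[iem2$group_order[j]]]),
                 tolerance = 1e-12)
})

test_that("identical groups repeated give identical rows and columns", {
  g <- random_mixed_graph(10, seed = 55)
  ann <- evo_annotation(age = stats::setNames(rep(3L, 10), g$nodes))
  groups <- list(g1 = g$nodes[1:4], g2 = g$nodes[1:4])
  iem <- ie_matrix(g, groups, ann)
  expect_equal(iem$matrix[1, ], iem$matrix[2, ], ignore_attr = TRUE)
  expect_equal(iem$matrix[, 1], iem$matrix[, 2], ignore_attr = TRUE)
})

test_that("cumulative SE curve windows and controls behave", {
  b <- generate(synth_config(sizes = 40L, seed = 19))
  crv <- cumulative_se_curve(b$network, b$annotation, "er", start = 30,
                             step = 10, n_controls = 30, seed = 3)
  expect_true(all(diff(crv$ranks) > 0))
  expect_equal(crv$ranks[length(crv$ranks)], 160L)
  # final window covers the same gene set in real and control curves
  nw <- length(crv$ranks)
  expect_equal(crv$se[nw], crv$control_mean[nw])
  expect_equal(crv$control_sd[nw], 0, tolerance = 1e-12)
  # constant attribute on an unstructured graph: ordering uninformative,
  # curve stays within the control band
  gu <- random_mixed_graph(40, p_dir = 0.1, p_und = 0.1, seed = 23)
  annc <- evo_annotation(er = stats::setNames(rep(1, gu$n), gu$nodes))
  crc <- cumulative_se_curve(gu, annc, "er", start = 20, step = 10,
                             n_controls = 30, seed = 5)
  expect_true(all(abs(crc$se - crc$control_mean) <=
                  pmax(3 * crc$control_sd, 1e-12)))
  expect_error(cumulative_se_curve(b$network, b$annotation, "er", start = 1000),
               "exceeds")
})
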