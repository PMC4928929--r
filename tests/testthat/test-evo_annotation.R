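test_that("column rates follow the distinct-residue rule", {
  expect_equal(column_rate(c("A", "A", "A"), 2.0, "distinct_minus_one"), 0.0)
  expect_equal(column_rate(c("A", "A", "A"), 2.0, "distinct"), 0.5)
  expect_equal(column_rate(c("A", "L", "S", "-"), 3.0, "distinct"), 1.0)
  # gap/ambiguity characters are excluded from the count
  expect_equal(column_rate(c("A", "L", "X", "B", "Z"), 2.0, "distinct"), 1.0)
  # uninformative columns (fewer than 2 residues) are flagged
  expect_true(is.na(column_rate(c("-", "-", "A"), 1.0)))
  expect_true(is.na(column_rate(c("-", "-", "-"), 1.0)))
})

test_that("column rate is invariant under permutation and duplication", {
  col <- c("A", "L", "S", "A", "-")
  for (s in 1:10) {
    perm <- withr::with_seed(s, sample(col))
    expect_equal(column_rate(perm, 3.0), column_rate(col, 3.0))
  }
  expect_equal(column_rate(c(col, col), 3.0), column_rate(col, 3.0))
})

make_test_tree <- function(labels, bl = 1) {
  tr <- ape::rtree(length(labels), tip.label = labels, br = NULL)
  tr$edge.length <- rep(bl, nrow(tr$edge))
  tr
}

test_that("gene ER averages per-column rates over informative columns", {
  aln <- rbind(T1 = c("A", "A", "A"), T2 = c("A", "L", "A"), T3 = c("A", "L", "S"))
  tree <- withr::with_seed(1, make_test_tree(rownames(aln), bl = 0.5))
  span <- sum(tree$edge.length)
  expected <- mean(c(1, 2, 2) / span)        # distinct counts per column
  expect_equal(gene_er(aln, tree, "distinct"), expected)
  expect_equal(gene_er(aln, tree, "distinct_minus_one"), mean(c(0, 1, 1) / span))
  # fully conserved alignment has rate 0 under distinct_minus_one
  cons <- rbind(T1 = c("A", "A"), T2 = c("A", "A"), T3 = c("A", "A"))
  expect_equal(gene_er(cons, tree, "distinct_minus_one"), 0.0)
})

test_that("gene ER round-trips through FASTA and Newick files", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">T1", "ALSA", ">T2", "ALTA", ">T3", "GLSA"), fa)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((T1:0.5,T2:0.5):0.5,T3:1.0);", nwk)
  span <- 2.5
  expect_equal(gene_er(fa, nwk, "distinct"),
               mean(c(2, 1, 2, 1) / span))
  # unknown taxa in the tree only warn; the span is taken from the tree
  nwk2 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((T1:0.5,T2:0.5):0.5,OTHER:1.0);", nwk2)
  expect_warning(gene_er(fa, nwk2), "taxa")
})

test_that("gene age is the earliest clade with an ortholog", {
  pres <- matrix(FALSE, 3, 13,
                 dimnames = list(c("OLD", "YNG", "MID"), paste0("c", 0:12)))
  pres["OLD", ] <- TRUE
  pres["YNG", 13] <- TRUE
  pres["MID", c(4, 8, 13)] <- TRUE
  prof <- clade_profile(pres)
  expect_equal(gene_age(prof, "old"), 0L)
  expect_equal(gene_age(prof, "YNG"), 12L)
  expect_equal(gene_age(prof, "MID"), 3L)
  expect_error(gene_age(prof, "ABSENT"), "absent")
  # adding presence at an older clade can only decrease the age
  pres2 <- pres; pres2["MID", 2] <- TRUE
  expect_lte(gene_age(clade_profile(pres2), "MID"), gene_age(prof, "MID"))
})

test_that("annotation tables load, merge and survive missing attributes", {
  er_p <- withr::local_tempfile(fileext = ".tsv")
  age_p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ter", "lsm2\t0.011", "cdrt15\t6.928", "tp53\t0.5"), er_p)
  writeLines(c("gene\tage", "LSM2\t0", "TP53\t3", "NEWGENE\t12"), age_p)
  ann <- load_annotation(er_p, age_p)
  expect_equal(length(ann$genes), 4L)
  expect_equal(unname(ann$er["LSM2"]), 0.011)
  expect_equal(unname(ann$age["NEWGENE"]), 12L)
  expect_true(is.na(ann$age["CDRT15"]))      # retained with missing age
  expect_true(is.na(ann$er["NEWGENE"]))
  expect_equal(names(which.min(annotation_values(ann, "er"))), "LSM2")

  writeLines(c("gene\ter", "a\toops"), er_p)
  expect_error(load_annotation(er_p), "non-numeric")
  writeLines("gene\ter", er_p)
  expect_warning(load_annotation(er_p), "empty")
})

test_that("annotation writing round-trips", {
  ann <- evo_annotation(er = c(A = 0.25, B = 1.5), age = c(B = 4, C = 11))
  er_p <- withr::local_tempfile(fileext = ".tsv")
  age_p <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ann, er_p, age_p)
  ann2 <- load_annotation(er_p, age_p)
  expect_equal(ann2$er, ann$er)
  expect_equal(ann2$age, ann$age)
})
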