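test_that("pairwise distances match brute-force recomputation", {
  m <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(pairwise_distance(m, "euclidean")["a", "b"], 5)
  expect_equal(pairwise_distance(m, "manhattan")["a", "b"], 7)
  expect_equal(pairwise_distance(rbind(a = c(1, 2, 3), b = c(1, 2, 3)),
                                 "euclidean")["a", "b"], 0)

  set.seed(31)
  profiles <- matrix(rnorm(6 * 40), 6,
                     dimnames = list(paste0("S", 1:6), NULL))
  for (metric in c("euclidean", "manhattan", "correlation")) {
    got <- pairwise_distance(profiles, metric)
    want <- oracle_distance(profiles, metric)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(got, t(got))
    expect_equal(unname(diag(got)), rep(0, 6))
  }
})

test_that("LOH layer enters the distance at the configured weight", {
  cnv <- structure(list(
    sample_ids = c("A", "B"),
    bins = data.frame(chrom = "chr1", start = 1, end = 10),
    cn = matrix(0, 2, 1, dimnames = list(c("A", "B"), NULL)),
    loh = matrix(c(1, 0), 2, 1, dimnames = list(c("A", "B"), NULL))),
    class = "cnv_matrix")
  expect_equal(pairwise_distance(cnv, "euclidean")["A", "B"], 1)
  expect_equal(pairwise_distance(cnv, "euclidean", loh_weight = 2)["A", "B"], 2)
  expect_equal(pairwise_distance(cnv, "euclidean", loh_weight = 0)["A", "B"], 0)
})

test_that("small forced topologies cluster as expected", {
  d2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  h2 <- hierarchical_cluster(d2)
  expect_equal(h2$height, 4)

  labs <- c("A", "B", "C")
  d3 <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
               dimnames = list(labs, labs))
  h3 <- hierarchical_cluster(d3, "complete")
  expect_equal(h3$height, c(1, 10))
  expect_true(leaf_pair_adjacent(h3, "A", "B"))
  expect_false(leaf_pair_adjacent(h3, "A", "C"))
  expect_error(leaf_pair_adjacent(h3, "A", "Z"), "unknown leaf")

  expect_error(hierarchical_cluster(matrix(0, 1, 1)), "at least 2")
})

test_that("merge sequences equal the naive agglomerator on random matrices", {
  set.seed(32)
  for (rep in 1:60) {
    n <- sample(3:8, 1)
    d <- random_distance_matrix(n)
    for (linkage in c("complete", "average", "single")) {
      tree <- hierarchical_cluster(d, linkage)
      oracle <- oracle_agglomerate(d, linkage)
      expect_equal(hclust_partitions(tree), oracle$merges)
      expect_equal(tree$height, oracle$heights, tolerance = 1e-12)
    }
  }
})

test_that("clustering agrees with stats::hclust and is order-invariant", {
  set.seed(33)
  d <- random_distance_matrix(12)
  for (linkage in c("complete", "average", "single")) {
    mine <- hierarchical_cluster(d, linkage)
    ref <- stats::hclust(stats::as.dist(d), method = linkage)
    expect_equal(stats::cophenetic(mine), stats::cophenetic(ref),
                 tolerance = 1e-12)
    # merge heights non-decreasing (no inversions for these linkages)
    expect_true(all(diff(mine$height) >= -1e-12))
  }
  # permuting the leaf input order permutes labels, not the tree
  perm <- sample(12)
  reordered <- hierarchical_cluster(d[perm, perm], "complete")
  original <- hierarchical_cluster(d, "complete")
  co_r <- as.matrix(stats::cophenetic(reordered))
  co_o <- as.matrix(stats::cophenetic(original))
  expect_equal(co_r[rownames(co_o), colnames(co_o)], co_o,
               tolerance = 1e-12)
})

test_that("deterministic tie-break picks the earliest-created pair", {
  labs <- c("A", "B", "C", "D")
  d <- matrix(1, 4, 4, dimnames = list(labs, labs))
  diag(d) <- 0
  # all distances tie: A,B merge first, then C,D, then the two pairs
  tree <- hierarchical_cluster(d, "complete")
  expect_true(leaf_pair_adjacent(tree, "A", "B"))
  expect_true(leaf_pair_adjacent(tree, "C", "D"))
})

test_that("zero-distance duplicates always become siblings", {
  set.seed(34)
  profiles <- matrix(rnorm(10 * 30), 10,
                     dimnames = list(paste0("S", 1:10), NULL))
  profiles["S7", ] <- profiles["S2", ]
  d <- pairwise_distance(profiles, "euclidean")
  tree <- hierarchical_cluster(d, "complete")
  expect_true(leaf_pair_adjacent(tree, "S2", "S7"))
})

test_that("cohort adjacency reports per-pair flags and the grouped fraction", {
  set.seed(35)
  n <- 15
  man <- data.frame(patient = sprintf("P%02d", 1:n),
                    primary = sprintf("P%02d-CRC", 1:n),
                    metastasis = sprintf("P%02d-CLM", 1:n),
                    normal = NA_character_)
  # plant 8 related pairs (near-identical profiles), 7 independent
  base <- matrix(rnorm(n * 50, sd = 3), n)
  profiles <- matrix(0, 2 * n, 50)
  rownames(profiles) <- c(rbind(man$primary, man$metastasis))
  related <- seq_len(8)
  for (i in 1:n) {
    profiles[man$primary[i], ] <- base[i, ]
    profiles[man$metastasis[i], ] <- if (i %in% related)
      base[i, ] + rnorm(50, sd = 0.01) else matrix(rnorm(50, sd = 3), 1)
  }
  tree <- hierarchical_cluster(pairwise_distance(profiles, "euclidean"))
  adj <- cohort_adjacency(tree, man)
  expect_true(all(adj$pairs$adjacent[related]))
  expect_equal(adj$fraction_grouped, mean(adj$pairs$adjacent))
  expect_true(all(!is.na(adj$pairs$merge_height[adj$pairs$adjacent])))

  bad_man <- man
  bad_man$primary[1] <- "nope"
  expect_error(cohort_adjacency(tree, bad_man), "absent from tree")
})

test_that("chance sibling rate for independent profiles is low", {
  # Monte-Carlo estimate of the chance that a designated pair of iid
  # profiles ends up as dendrogram siblings among 30 leaves
  set.seed(36)
  hits <- 0; reps <- 40
  for (r in seq_len(reps)) {
    profiles <- matrix(rnorm(30 * 40), 30,
                       dimnames = list(paste0("S", 1:30), NULL))
    tree <- hierarchical_cluster(pairwise_distance(profiles, "euclidean"))
    hits <- hits + leaf_pair_adjacent(tree, "S1", "S2")
  }
  expect_lt(hits / reps, 0.2)
})

test_that("newick export round-trips through a standard reader", {
  set.seed(37)
  d <- random_distance_matrix(8)
  tree <- hierarchical_cluster(d, "complete")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_s3_class(phy, "phylo")
  expect_setequal(phy$tip.label, rownames(d))
})
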