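# Binary Jaccard distances, PCoA, NMDS and UPGMA.

test_that("binary Jaccard distances: identities, worked value, metric axioms", {
  m <- rbind(S1 = c(5, 2, 1, 0), S2 = c(5, 2, 1, 0), S3 = c(0, 0, 0, 7))
  d <- as.matrix(jaccard_distance_matrix(m))
  expect_equal(d["S1", "S2"], 0)
  expect_equal(d["S1", "S3"], 1)        # disjoint
  m2 <- rbind(A = c(1, 1, 1, 0), B = c(0, 1, 1, 1))
  expect_equal(as.matrix(jaccard_distance_matrix(m2))["A", "B"], 0.5)
  # both-empty pair -> distance 0
  m3 <- rbind(E1 = c(0, 0), E2 = c(0, 0))
  expect_equal(as.matrix(jaccard_distance_matrix(m3))["E1", "E2"], 0)
  # triangle inequality on fuzzed tables
  set.seed(13)
  for (i in 1:10) {
    mm <- matrix(rbinom(8 * 20, 1, 0.4) * rpois(8 * 20, 5), nrow = 8)
    rownames(mm) <- paste0("S", 1:8)
    dd <- as.matrix(jaccard_distance_matrix(mm))
    expect_equal(dd, t(dd))
    for (a in 1:8) for (b in 1:8) for (cc in 1:8)
      expect_lte(dd[a, b], dd[a, cc] + dd[cc, b] + 1e-12)
  }
})

test_that("PCoA: equilateral triangle eigenvalues and Euclidean identity", {
  tri <- matrix(1, 3, 3) - diag(3)
  dimnames(tri) <- list(LETTERS[1:3], LETTERS[1:3])
  p <- pcoa(as.dist(tri))
  expect_equal(p$eigenvalues, c(0.5, 0.5, 0), tolerance = 1e-9)
  # 1-D points {0, 1, 3}: axis-1 inter-point distances reproduce input
  pts <- c(0, 1, 3)
  d <- as.matrix(dist(pts))
  p1 <- pcoa(as.dist(d))
  rec <- as.matrix(dist(p1$coordinates[, 1]))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  # planted points in R^3 reconstruct all pairwise distances
  set.seed(19)
  X <- matrix(rnorm(8 * 3), 8, 3)
  pr <- pcoa(dist(X))
  expect_equal(unname(as.matrix(dist(pr$coordinates))),
               unname(as.matrix(dist(X))), tolerance = 1e-9)
  expect_true(all(diff(pr$eigenvalues) <= 1e-9))  # non-increasing
  # two samples at distance 1 -> coordinates +/- 0.5
  d2 <- matrix(c(0, 1, 1, 0), 2)
  expect_setequal(round(pcoa(as.dist(d2))$coordinates[, 1], 9), c(0.5, -0.5))
  # asymmetric input rejected
  bad <- matrix(c(0, 1, 2, 0.5, 0, 1, 2, 1, 0), 3)
  expect_error(pcoa(bad), "symmetric")
  skip_if_not_installed("vegan")
  cmd <- stats::cmdscale(dist(X), k = 3, eig = TRUE)
  expect_equal(unname(abs(pr$coordinates[, 1])), unname(abs(cmd$points[, 1])),
               tolerance = 1e-7)
})

test_that("NMDS: near-zero stress on embeddable data, monotone trace", {
  set.seed(23)
  X <- matrix(rnorm(18), 9, 2)
  nm <- nmds(dist(X), k = 2, n_starts = 5, seed = 2)
  expect_lt(nm$stress, 0.01)
  expect_true(nm$valid)
  expect_true(all(diff(nm$stress_trace) <= 1e-12))
  # separated Dirichlet-multinomial groups: stress < 0.2 and clear split
  ft <- gen_feature_table(n_samples_per_group = 6, n_features = 60,
                          n_diff_features = 25, fold_change = 40, seed = 5)
  d <- jaccard_distance_matrix(ft$table)
  nm2 <- nmds(d, k = 2, n_starts = 10, seed = 3)
  expect_lt(nm2$stress, 0.2)
  grp <- ft$table$groups[rownames(nm2$points)]
  dd <- as.matrix(dist(nm2$points))
  same <- outer(grp, grp, "==")
  expect_gt(mean(dd[!same]), mean(dd[same & upper.tri(same)]))
  skip_if_not_installed("vegan")
  # multi-start majorization should do at least as well as monoMDS's
  # single default start under the same stress-1 objective
  ref <- vegan::monoMDS(d, k = 2)
  expect_lte(nm2$stress, ref$stress + 0.02)
})

test_that("UPGMA: worked 3-leaf tree, ultrametric exactness, 2-sample case", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  u <- upgma(as.dist(d))
  expect_equal(u$newick, "((A:1,B:1):1,C:2);")
  expect_equal(unname(as.matrix(stats::cophenetic(u$hclust))[c("A", "B", "C"),
                                                            c("A", "B", "C")]),
               unname(d))
  # ultrametric input reproduced exactly by cophenetic distances
  set.seed(29)
  base <- upgma(dist(matrix(rnorm(12), 6)))   # any UPGMA tree is ultrametric
  um <- stats::cophenetic(base$hclust)
  again <- upgma(um)
  expect_equal(as.matrix(stats::cophenetic(again$hclust)), as.matrix(um),
               tolerance = 1e-9)
  # agreement with hclust average linkage on random euclidean data
  dd <- dist(matrix(rnorm(20), 10))
  mine <- upgma(dd)
  ref <- stats::hclust(dd, method = "average")
  expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-9)
  expect_equal(as.matrix(stats::cophenetic(mine$hclust)),
               as.matrix(stats::cophenetic(ref)), tolerance = 1e-9)
  # two samples merge at half distance per branch
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  u2 <- upgma(as.dist(d2))
  expect_equal(u2$newick, "(X:1.5,Y:1.5);")
  # the newick string parses and matches cophenetic distances
  tr <- ape::read.tree(text = u$newick)
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[c("A", "B", "C"),
                                                           c("A", "B", "C")]),
               unname(d))
})
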