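test_that("well-separated blobs are recovered with ascending means", {
  set.seed(1)
  centers <- c(1, 10, 20, 40, 80)
  vals <- unlist(lapply(centers, function(m) rnorm(500, m, 0.5)))
  truth <- rep(1:5, each = 500)
  ca <- kmeansCluster(vals, k = 5)
  lab <- labelMap(ca)
  expect_identical(as.integer(lab), truth)
  expect_true(all(diff(clusterCenters(ca)) > 0))
  expect_equal(clusterCounts(ca), rep(500L, 5))
})

test_that("final assignment is a nearest-center fixed point", {
  set.seed(2)
  for (rep in 1:5) {
    vals <- c(rlnorm(800, 3, 1), runif(200, 0, 5))
    ca <- kmeansCluster(vals, k = 5)
    lab <- as.integer(labelMap(ca))
    # exhaustive oracle: every point in the cluster of its nearest center
    d <- abs(outer(vals, clusterCenters(ca), "-"))
    nearest <- max.col(-d, ties.method = "first")
    expect_identical(lab, nearest)
    # centers are the means of their members
    for (j in 1:5)
      expect_equal(clusterCenters(ca)[j], mean(vals[lab == j]),
                   tolerance = 1e-12)
  }
})

test_that("objective matches stats::kmeans from the same partition", {
  # independent cross-check: Lloyd from our converged centers cannot be
  # improved by stats::kmeans started at those centers
  set.seed(3)
  vals <- rlnorm(2000, 2, 0.8)
  ca <- kmeansCluster(vals, k = 5)
  wss <- sum((vals - clusterCenters(ca)[as.integer(labelMap(ca))])^2)
  km <- stats::kmeans(vals, centers = matrix(clusterCenters(ca)),
                      iter.max = 100, algorithm = "Lloyd")
  expect_equal(wss, km$tot.withinss, tolerance = 1e-8)
})

test_that("relabeling permutes labels without changing the partition", {
  set.seed(4)
  vals <- rlnorm(1000, 2, 0.8)
  ca <- kmeansCluster(vals, k = 5)
  lab <- as.integer(labelMap(ca))
  # partition sizes equal sizes of the value-sorted blocks: a pure
  # permutation preserves the multiset of cluster sizes and memberships
  expect_equal(sum(clusterCounts(ca)), length(vals))
  expect_setequal(unique(lab), 1:5)
  # boundary consistency in 1-D: sorted values change cluster monotonically
  expect_true(all(diff(lab[order(vals)]) >= 0))
})

test_that("degenerate inputs raise named errors", {
  expect_error(kmeansCluster(rep(1, 100), k = 5, region = "tumor"),
               "degenerate clustering in region 'tumor'")
  expect_error(kmeansCluster(c(1, 2, 3, 4), k = 5), "fewer than 5")
})

test_that("clustering is reproducible and ignores unassignable voxels", {
  set.seed(5)
  vals <- array(rlnorm(600, 2, 0.6), c(10, 20, 3))
  mask <- array(TRUE, dim(vals))
  vals[1, 1, 1] <- NA                      # failed fit stays label 0
  a <- kmeansCluster(vals, mask, k = 5)
  b <- kmeansCluster(vals, mask, k = 5)
  expect_identical(labelMap(a), labelMap(b))
  expect_identical(labelMap(a)[1, 1, 1], 0L)
  expect_equal(sum(clusterCounts(a)), 599L)
})

test_that("cluster mean curves average raw signal then convert", {
  # two-voxel cluster with signals 100 and 200 at one frame -> mean 150
  pse <- rbind(c(rep(0, 17), 0), c(rep(100, 18)))
  s <- seriesFromPse(pse)              # voxel1 stays 100, voxel2 is 200
  lab <- array(0L, c(2, 1, 1)); lab[] <- 1L
  ca <- new("ClusterAssignment", labelMap = lab, counts = 2L,
            centers = 1, region = "test")
  cur <- clusterMeanCurves(s, ca)[[1]]
  expect_equal(cur@baseline, 100)                 # shared precontrast level
  nt <- length(cur@times)
  expect_equal(100 * (1 + cur@pse[nt] / 100), 150)  # mean of 100 and 200
  expect_equal(cur@nVoxels, 2L)
  # identical voxels: cluster curve equals any member's curve
  pse2 <- rbind(c(1:18), c(1:18))
  s2 <- seriesFromPse(pse2)
  ca2 <- new("ClusterAssignment", labelMap = lab, counts = 2L,
             centers = 1, region = "test")
  cur2 <- clusterMeanCurves(s2, ca2)[[1]]
  expect_equal(cur2@pse, computePse(s2, voxel = c(1, 1, 1))@pse)
})

test_that("noiseless phantom cluster curves refit inside the truth range", {
  ph <- generatePhantom(phantomSpec(grid = c(16, 32, 4), seed = 6))
  f <- fitEmm2Voxelwise(ph$series, ph$labels, "ips_parenchyma")
  ca <- kmeansCluster(f$Aalpha, f$valid, k = 5, region = "ips_parenchyma")
  curves <- clusterMeanCurves(ph$series, ca)
  truthAa <- (ph$truth$voxel$A * ph$truth$voxel$alpha)[
    labelMap(ph$labels) == REGION_CODES[["ips_parenchyma"]]]
  for (j in c(2, 3, 4)) {
    fit <- fitEmm3Curve(curves[[j]])
    members <- truthAa[as.integer(labelMap(ca))[
      labelMap(ph$labels) == REGION_CODES[["ips_parenchyma"]]] == j]
    expect_gt(fit$Aalpha, min(members) * 0.95)
    expect_lt(fit$Aalpha, max(members) * 1.05)
  }
})
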