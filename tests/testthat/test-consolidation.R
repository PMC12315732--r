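# build a VoxelInversionResult from a list of component matrices
mkResult <- function(param_list) {
  new("VoxelInversionResult",
      solutions = lapply(param_list, function(p) new("DRComponents", params = p)),
      residuals = rep(0, length(param_list)),
      residual_trace = rep(list(numeric(0)), length(param_list)))
}

test_that("clustering groups identical components into one cluster and normalizes features", {
  p <- components(flatComponent(1, 0.3, r1 = 0.6, r2 = 12, weight = 0.5,
                                theta = 0.4, phi = 1))
  res <- mkResult(rep(list(p), 5))
  labs <- clusterComponents(res, k = 1, seed = 2)
  expect_true(all(labs == 1))

  pooled <- mdmri:::poolComponents(res)
  feat <- mdmri:::clusterFeatures(pooled, 2 * pi * 6.6)
  expect_equal(unname(apply(abs(feat), 2, max)), rep(1, 6))
})

test_that("two separated populations are recovered exactly by k = 2 clustering", {
  a <- components(flatComponent(0.5, 0.05, r1 = 0.3, r2 = 5, weight = 0.5))
  b <- components(flatComponent(3.0, 0.7, r1 = 1.5, r2 = 25, weight = 0.5,
                                theta = 1.5, phi = 3))
  set.seed(7)
  sols <- lapply(1:10, function(i) {
    aj <- a; bj <- b
    aj[, c("d_par", "d_perp")] <- aj[, c("d_par", "d_perp")] * exp(rnorm(2, 0, 0.02))
    bj[, c("d_par", "d_perp")] <- bj[, c("d_par", "d_perp")] * exp(rnorm(2, 0, 0.02))
    rbind(aj, bj)
  })
  res <- mkResult(sols)
  labs <- clusterComponents(res, k = 2, seed = 4)
  truth_pop <- rep(c(1, 2), 10)
  expect_equal(length(unique(labs[truth_pop == 1])), 1)
  expect_equal(length(unique(labs[truth_pop == 2])), 1)
  expect_false(labs[1] == labs[2])

  # brute-force check: every member is nearest (L1) to its own centroid
  pooled <- attr(labs, "pooled")
  feat <- mdmri:::clusterFeatures(pooled, 2 * pi * 6.6)
  for (kk in 1:2) {
    cen <- apply(feat[labs == kk, , drop = FALSE], 2, median)
    oth <- apply(feat[labs != kk, , drop = FALSE], 2, median)
    for (i in which(labs == kk))
      expect_lt(sum(abs(feat[i, ] - cen)), sum(abs(feat[i, ] - oth)))
  }

  expect_error(clusterComponents(res, k = 100, seed = 1), "distinct")
})

test_that("clustering is invariant to component order under a fixed seed", {
  a <- components(flatComponent(0.5, 0.05, r1 = 0.3, r2 = 5))
  b <- components(flatComponent(3.0, 0.7, r1 = 1.5, r2 = 25))
  res1 <- mkResult(list(rbind(a, b), rbind(a, b)))
  res2 <- mkResult(list(rbind(b, a), rbind(b, a)))
  l1 <- clusterComponents(res1, k = 2, seed = 9)
  l2 <- clusterComponents(res2, k = 2, seed = 9)
  # same partition up to label names: component 1 of res1 is component 2 of res2
  expect_equal(l1[c(1, 3)] == l1[c(2, 4)], c(FALSE, FALSE))
  expect_equal(l2[c(1, 3)] == l2[c(2, 4)], c(FALSE, FALSE))
  expect_true(l1[1] != l1[2] && l2[1] != l2[2])
})

test_that("consolidation takes weighted parameter means and median weights", {
  # three identical-parameter members with weights 0.2, 0.4, 0.6
  p <- do.call(rbind, lapply(c(0.2, 0.4, 0.6), function(w)
    components(flatComponent(1, 0.2, weight = w))))
  res <- mkResult(list(p))
  v <- consolidate(res, rep(1L, 3))
  expect_equal(components(v)[1, "weight"], 0.4, ignore_attr = TRUE)

  # weighted mean of Diso: values 1 (w 1) and 3 (w 3) -> 2.5
  q <- rbind(components(flatComponent(1, 0, weight = 1)),
             components(flatComponent(3, 0, weight = 3)))
  res2 <- mkResult(list(q))
  v2 <- consolidate(res2, rep(1L, 2))
  sh <- mdmri:::componentSpectralShape(components(v2), 0)
  expect_equal(sh$d_iso, 2.5, ignore_attr = TRUE)

  # single-member cluster reproduces the member
  v3 <- consolidate(res2, c(1L, 2L))
  expect_equal(components(v3)[1, ], q[1, ], ignore_attr = TRUE)
  expect_equal(components(v3)[2, ], q[2, ], ignore_attr = TRUE)
})

test_that("2D projection deposits weights in the right cells and normalizes", {
  v <- flatComponent(1, 0.3, weight = 0.7)
  mesh <- project2D(v, "diso_ddelta2")
  expect_s4_class(mesh, "ProjectionMesh")
  expect_equal(dim(mesh@grid), c(64, 64))
  expect_equal(sum(mesh@grid), 1, tolerance = 1e-12)
  expect_equal(sum(mesh@grid > 0), 1)
  ix <- which(mesh@grid > 0, arr.ind = TRUE)
  # Diso = 1 on the log axis, DDelta^2 = 0.3 on the linear axis
  expect_equal(unname(ix[1, 1]),
               findInterval(log10(1), mesh@xbreaks, rightmost.closed = TRUE))
  expect_equal(unname(ix[1, 2]),
               findInterval(0.3, mesh@ybreaks, rightmost.closed = TRUE))

  # out-of-range component clips to the edge cell
  big <- flatComponent(4.9, 0.2)
  p <- components(big); p[, c("d_par", "d_perp", "d0")] <- 50
  mesh2 <- project2D(new("DRComponents", params = p), "diso_ddelta2")
  expect_equal(which(rowSums(mesh2@grid) > 0), 64L)

  # two equal components across the r1/r2 planes
  two <- new("DRComponents", params = rbind(
    components(flatComponent(0.5, 0.1, r1 = 0.3, r2 = 5, weight = 0.5)),
    components(flatComponent(2.5, 0.1, r1 = 1.5, r2 = 20, weight = 0.5))))
  for (pl in c("diso_r1", "diso_r2", "ddelta2_r1", "ddelta2_r2")) {
    m <- project2D(two, pl)
    expect_equal(sum(m@grid), 1, tolerance = 1e-12)
    expect_equal(sort(m@grid[m@grid > 0]), c(0.5, 0.5))
  }
})

test_that("ROI-characteristic distributions average per-scan normalized sums", {
  m1 <- project2D(flatComponent(1, 0.3), "diso_ddelta2")
  # one scan, two identical voxel meshes -> the same mesh
  avg <- roiCharacteristicDistribution(list(m1, m1), scan = c(1, 1))
  expect_equal(avg@grid, m1@grid)

  # two scans with disjoint single-cell meshes -> 0.5 in each cell
  m2 <- project2D(flatComponent(3, 0.8), "diso_ddelta2")
  avg2 <- roiCharacteristicDistribution(list(m1, m2), scan = c(1, 2))
  expect_equal(sum(avg2@grid), 1, tolerance = 1e-12)
  expect_equal(sort(avg2@grid[avg2@grid > 0]), c(0.5, 0.5))

  expect_error(roiCharacteristicDistribution(list(), scan = integer(0)),
               "empty ROI")
})
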