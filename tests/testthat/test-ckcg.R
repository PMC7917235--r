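test_that("block partition tiles the retained voxels with M <= N", {
  map <- tinyBlobMap()
  p <- partitionBlocks(map, nBeads = 5)
  expect_lte(p$M, 5)
  expect_equal(length(p$w), sum(retainedMask(map)))   # blocks cover all voxels
  expect_true(all(p$blockId >= 1 & p$blockId <= p$M))
  p1 <- partitionBlocks(map, nBeads = 1)
  expect_equal(p1$M, 1)
  expect_error(partitionBlocks(map, 5, blockEdge = 0.5), "voxel")
})

test_that("auto tiling reproduces the 12-beads-9-blocks seeding regime", {
  # a 6 x 6 x 2 uniform slab: edge 1 gives 72 blocks (> 12), edge 2 gives
  # the 3 x 3 x 1 = 9-block tiling, so 12 requested beads leave 3 extras
  v <- array(1, c(6, 6, 2))
  m <- normalizeDensity(DensityMap(v + seq_along(v) * 1e-3, voxelSize = 1))
  p <- partitionBlocks(m, nBeads = 12)
  expect_equal(p$M, 9)
  seeds <- convolveMaxpool(p)
  expect_equal(nrow(seeds), 9)
  extras <- assignExtraCenters(p, 12 - nrow(seeds), seeds)
  expect_equal(nrow(extras), 3)
  # extras land in the 3 top-scoring blocks, at voxels not already seeds
  score <- tapply(p$h, p$blockId, max)
  top3 <- as.integer(names(sort(score, decreasing = TRUE)))[1:3]
  expect_setequal(extras$blockId, top3)
  expect_false(any(extras$voxel %in% seeds$voxel))
})

test_that("max-pooling picks the kernel-weighted density argmax per block", {
  # uniform density: the kernel peak (block center) wins
  v <- array(1, c(8, 8, 8))
  m <- normalizeDensity(DensityMap(v + array(seq_along(v), dim(v)) * 1e-9, 1))
  p <- partitionBlocks(m, nBeads = 1)
  s <- convolveMaxpool(p)
  expect_lt(max(abs(as.numeric(s[, c("x", "y", "z")]) - 4)), 1)

  # single blob: the blob's center voxel wins for any kernel width
  blob <- normalizeDensity(makeToyDensity("single_blob", gridDim = 9L))
  pb <- partitionBlocks(blob, nBeads = 1)
  sb <- convolveMaxpool(pb)
  brute <- which.max(pb$h)
  expect_equal(sb$voxel, pb$idx[brute])
  expect_equal(as.numeric(sb[, c("x", "y", "z")]), c(4.5, 4.5, 4.5))

  # rank check for extras: the higher-score block receives the extra
  expect_equal(assignExtraCenters(pb, 0, sb), sb[0, ])
})

test_that("weighted Lloyd iterations are monotone and stop at fixed points", {
  twob <- normalizeDensity(makeToyDensity("two_blobs", gridDim = c(11L, 11L, 25L)))
  vc <- voxelCenters(twob)
  # centers already at the two weighted centroids: 1-iteration fixed point
  b0 <- coarseGrain(twob, nBeads = 2)
  b1 <- kmeansRefine(twob, beadPositions(b0))
  expect_lte(b1@nIterations, 2)
  expect_equal(b1@objective, b0@objective, tolerance = 1e-12)
  expect_equal(beadPositions(b1), beadPositions(b0), tolerance = 1e-9)
  # objective trace never increases, on several random starts
  for (s in 1:5) {
    set.seed(s)
    C <- vc$xyz[sample(nrow(vc$xyz), 3), ]
    bs <- kmeansRefine(twob, C)
    expect_true(all(diff(bs@objectiveTrace) <= 1e-9 * bs@objectiveTrace[1]))
  }
})

test_that("CK-CG matches a brute-force oracle on a tiny map", {
  map <- tinyBlobMap()
  expect_lte(sum(retainedMask(map)), 200)
  vc <- voxelCenters(map)
  ck <- coarseGrain(map, nBeads = 3, method = "ckcg")
  best <- Inf
  set.seed(99)
  for (r in 1:1000) {
    C0 <- vc$xyz[sample(nrow(vc$xyz), 3), , drop = FALSE]
    o <- bruteForceWeightedKmeans(vc$xyz, vc$w, C0)
    best <- min(best, o$objective)
  }
  expect_lte(ck@objective, best * (1 + 1e-9))
})

test_that("coarse graining honours the mass bookkeeping and its contracts", {
  map <- tubeMap()
  total <- massScale(map) * sum(densityValues(map)[retainedMask(map)])
  beads <- tubeBeads()
  expect_equal(nrow(beadPositions(beads)), round(total / 22))
  expect_equal(sum(beadMasses(beads)), total, tolerance = 1e-9 * total)
  # every retained voxel assigned, no empty bead
  expect_equal(length(beads@assignment), sum(retainedMask(map)))
  expect_equal(sort(unique(beads@assignment)),
               seq_len(nrow(beadPositions(beads))))
  # positions are the density-weighted centroids of their voxels
  vc <- voxelCenters(map)
  k <- which.max(beadMasses(beads))
  sel <- beads@assignment == k
  ctr <- colSums(vc$xyz[sel, , drop = FALSE] * vc$w[sel]) / sum(vc$w[sel])
  expect_equal(as.numeric(beadPositions(beads)[k, ]), as.numeric(ctr),
               tolerance = 1e-9)
  expect_error(coarseGrain(map, nBeads = sum(retainedMask(map)) + 1),
               "retained voxels")
})

test_that("the CK-CG path is deterministic and beats the random-init median", {
  map <- tinyBlobMap()
  a <- coarseGrain(map, nBeads = 3, method = "ckcg")
  b <- coarseGrain(map, nBeads = 3, method = "ckcg")
  expect_identical(beadPositions(a), beadPositions(b))
  expect_identical(a@objective, b@objective)
  objs <- vapply(1:100, function(s)
    coarseGrain(map, nBeads = 3, method = "kmeans_random", seed = s)@objective,
    numeric(1))
  expect_lte(a@objective, stats::median(objs) * (1 + 1e-9))
})

test_that("minimal-model beads split into groove and crest radial populations", {
  r <- beadRadii(tubeBeads())
  km <- stats::kmeans(r, centers = c(min(r), max(r)))
  sep <- abs(diff(sort(km$centers)))
  pooled <- sqrt(sum(km$withinss) / length(r))
  expect_gt(sep / pooled, 2)                     # clearly separated modes
  expect_true(all(km$size / length(r) > 0.2))    # both populations substantial
})
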