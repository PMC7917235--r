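test_that("MRC round trip preserves grid, voxel sizes and origin", {
  m <- makeToyDensity("two_blobs", gridDim = c(10L, 12L, 14L),
                      voxelSize = 0.8)
  m@voxelSize <- c(0.5, 0.8, 1.1)       # anisotropic voxels
  m@origin <- c(1.5, -2.0, 3.25)
  f <- tempfile(fileext = ".mrc")
  writeDensity(m, f)
  r1 <- readDensity(f)
  expect_equal(voxelSize(r1), m@voxelSize, tolerance = 1e-6)
  expect_equal(mapOrigin(r1), m@origin, tolerance = 1e-6)
  expect_equal(dim(densityValues(r1)), dim(densityValues(m)))
  # float32 storage: values agree to single precision on first write,
  # and a second round trip is bitwise identical
  expect_equal(densityValues(r1), densityValues(m), tolerance = 1e-6)
  f2 <- tempfile(fileext = ".mrc")
  writeDensity(r1, f2)
  r2 <- readDensity(f2)
  expect_identical(densityValues(r2), densityValues(r1))
})

test_that("MRC header carries recomputed min/max and reads back via gemmi", {
  m <- normalizeDensity(makeToyDensity("single_blob"))
  f <- tempfile(fileext = ".mrc")
  writeDensity(m, f)
  con <- file(f, "rb")
  seek(con, 4 * 19)
  dstats <- readBin(con, "numeric", n = 2, size = 4, endian = "little")
  close(con)
  expect_equal(dstats, c(0, 1), tolerance = 1e-6)
  # independent format oracle: gemmi must agree on the grid geometry
  out <- suppressWarnings(system2("python", c("-c", shQuote(sprintf(
    "import gemmi; g = gemmi.read_ccp4_map('%s').grid; print(g.nu, g.nv, g.nw, round(g.spacing[0], 4))",
    f))), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (is.null(status) || status == 0)
    expect_equal(out[length(out)], "21 21 21 10.0")
  else succeed("gemmi oracle unavailable; geometry checked by the reader itself")
})

test_that("unreadable or truncated files raise format errors naming the field", {
  f <- tempfile()
  writeBin(raw(32), f)
  expect_error(readDensity(f), "header")
  m <- makeToyDensity("single_blob", gridDim = 8L)
  g <- tempfile(fileext = ".mrc")
  writeDensity(m, g)
  full <- readBin(g, "raw", n = file.size(g))
  writeBin(full[1:1200], g)            # cut the data block short
  expect_error(readDensity(g), "truncated")
})

test_that("axial replication tiles the grid and scales length and density", {
  spec <- microtubuleSpec(length = 32, voxelSize = 1.2)
  m <- makeMicrotubuleDensity(spec)
  expect_identical(replicateAxial(m, 1), m)
  m2 <- replicateAxial(m, 2)
  expect_equal(physicalExtent(m2)[3], 2 * physicalExtent(m)[3])
  expect_equal(dim(densityValues(m2))[3], 2 * dim(densityValues(m))[3])
  m31 <- replicateAxial(m, 31)
  expect_equal(sum(densityValues(m31)), 31 * sum(densityValues(m)),
               tolerance = 1e-12)
  # associativity of tiling
  expect_equal(densityValues(replicateAxial(replicateAxial(m, 2), 3)),
               densityValues(replicateAxial(m, 6)))
  expect_error(replicateAxial(m, 0), "positive")
})

test_that("a 32 nm synthetic map reports a 32 nm axial extent", {
  spec <- microtubuleSpec(length = 32, voxelSize = 0.925)
  m <- makeMicrotubuleDensity(spec)
  expect_lt(abs(physicalExtent(m)[symmetryAxis(m)] - 32), 0.925)
})

test_that("solvent removal masks background and keeps the main component", {
  u <- DensityMap(array(2, c(4, 4, 4)), voxelSize = 1)
  expect_equal(densityValues(removeSolvent(u, 0.5)), densityValues(u))

  m <- makeToyDensity("two_blobs", gridDim = 17L)
  bg <- 0.05 * max(densityValues(m))
  raw <- densityValues(m) + bg
  mb <- DensityMap(raw, voxelSize = 1)
  cleaned <- removeSolvent(mb, 0.1, keepLargestComponent = FALSE)
  expect_identical(sum(retainedMask(cleaned)),
                   sum(raw > 0.1 * max(raw)))
  expect_true(all(densityValues(cleaned)[retainedMask(cleaned)] > 0))
  expect_true(all(densityValues(cleaned) <= raw))  # never increases a voxel

  # two disconnected blobs: the smaller one is dropped
  v <- array(0, c(20, 5, 5))
  v[2:11, 2:4, 2:4] <- 1          # 90 voxels
  v[16:17, 2:3, 2:3] <- 1         # 8 voxels, disconnected
  md <- removeSolvent(DensityMap(v, voxelSize = 1), 0.5)
  expect_equal(sum(retainedMask(md)), 90)
  expect_error(removeSolvent(DensityMap(array(0, c(3, 3, 3)), 1), 0.5),
               "empty|removed all", ignore.case = TRUE)
})

test_that("normalization is an order-preserving affine map onto [0,1]", {
  v <- array(0, c(3, 1, 1)); v[] <- c(2, 4, 6)
  m <- normalizeDensity(DensityMap(v, 1))
  expect_equal(as.numeric(densityValues(m)), c(0, 0.5, 1))
  expect_equal(densityValues(normalizeDensity(m)), densityValues(m))

  set.seed(7)
  r <- DensityMap(array(runif(125, 0.1, 9), c(5, 5, 5)), 1)
  rn <- normalizeDensity(r)
  expect_equal(min(densityValues(rn)), 0)
  expect_equal(max(densityValues(rn)), 1)
  expect_identical(order(densityValues(rn)), order(densityValues(r)))
  expect_error(normalizeDensity(DensityMap(array(3, c(2, 2, 2)), 1)),
               "degenerate|constant")
})

test_that("mass calibration sets the scale so total mass is exact", {
  v <- array(1, c(5, 5, 4))
  m <- normalizeDensity(DensityMap(v * seq_len(100) / 100, 1))
  s <- sum(densityValues(m))
  cal <- calibrateMass(m, 167398)
  expect_equal(massScale(cal), 167398 / s)
  cal2 <- calibrateMass(m, 2 * 167398)
  expect_equal(massScale(cal2), 2 * massScale(cal))  # linearity
  expect_error(calibrateMass(m, -5), "positive")
})
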