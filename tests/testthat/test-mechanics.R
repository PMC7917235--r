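# a straight chain of n identical springs along z; analytically solvable
chainModel <- function(n = 10, gamma = 2.5, mass = 1, spacing = 1) {
  pos <- cbind(0, 0, spacing * (0:n))
  m <- buildNetwork(BeadSet(pos, masses = rep(mass, n + 1)),
                    cutoff = spacing, A = 1)
  m@bonds$gamma <- rep(gamma, nrow(m@bonds))
  m
}

test_that("configuration validation catches bad parameters", {
  expect_error(simulationConfig(timestep = 0), "positive")
  expect_error(simulationConfig(dampingTime = -1), "positive")
  expect_error(forceClampSetup(integer(), 2L, 1), "nonempty")
  expect_error(forceClampSetup(1L, 1L, 1), "disjoint")
})

test_that("dynamics at T = 0 with no force stays at the reference", {
  m <- chainModel()
  cfg <- simulationConfig(temperature = 0, timestep = 0.01, nSteps = 500L,
                          recordEvery = 100L, seed = 1L)
  tr <- langevinRun(m, cfg)
  expect_lt(max(abs(sweep(trajectoryFrames(tr), 2:3,
                          beadPositions(m))[])), 1e-12)
})

test_that("runs are reproducible for a fixed seed", {
  m <- chainModel()
  cfg <- simulationConfig(timestep = 0.02, nSteps = 2000L, recordEvery = 500L,
                          seed = 7L)
  t1 <- langevinRun(m, cfg)
  t2 <- langevinRun(m, cfg)
  expect_identical(trajectoryFrames(t1), trajectoryFrames(t2))
  t3 <- langevinRun(m, simulationConfig(timestep = 0.02, nSteps = 2000L,
                                        recordEvery = 500L, seed = 8L))
  expect_false(identical(trajectoryFrames(t1), trajectoryFrames(t3)))
})

test_that("a stiff single bond equilibrates to the harmonic length variance", {
  b <- BeadSet(rbind(c(0, 0, 0), c(0, 0, 1)), masses = c(0.022, 0.022))
  m <- buildNetwork(b, cutoff = 1.5, A = 1)
  m@bonds$gamma <- 500
  per <- ucgtube:::.minBondPeriod(m)
  cfg <- simulationConfig(temperature = 300, timestep = 0.02 * per,
                          dampingTime = per, nSteps = 400000L,
                          recordEvery = 10L, seed = 3L)
  tr <- langevinRun(m, cfg)
  fr <- trajectoryFrames(tr)
  d <- sqrt(rowSums((fr[, 1, ] - fr[, 2, ])^2))
  kBT <- 0.008314462618 * 300
  expect_equal(var(d[-(1:2000)]), kBT / (2 * 500), tolerance = 0.05)
})

test_that("static minimization solves the serial-chain closed form", {
  n <- 10; gam <- 2.5
  m <- chainModel(n, gam)
  s <- forceClampSetup(1L, n + 1L, totalForce = 0.001)
  X <- minimizeUnderForce(m, s)
  dL <- measureDisplacement(X, s, beadPositions(m))
  Fk <- 0.001 * 602.214076                  # nN -> kJ/mol/nm
  expect_equal(dL, n * Fk / (2 * gam), tolerance = 1e-6)
  # zero force: reference returned unchanged
  s0 <- forceClampSetup(1L, n + 1L, totalForce = 0)
  expect_identical(minimizeUnderForce(m, s0), beadPositions(m))
})

test_that("static displacement is linear in F and inversely proportional to A", {
  # the straight chain pulled along its axis is exactly linear
  n <- 8
  mk <- function(A) {
    pos <- cbind(0, 0, (0:n) * 1.0)
    buildNetwork(BeadSet(pos, masses = rep(3, n + 1)), cutoff = 1, R = 10,
                 A = A)
  }
  s1 <- forceClampSetup(1L, n + 1L, totalForce = 0.004)
  s2 <- forceClampSetup(1L, n + 1L, totalForce = 0.008)
  d1 <- measureDisplacement(minimizeUnderForce(mk(1), s1), s1,
                            beadPositions(mk(1)))
  d2 <- measureDisplacement(minimizeUnderForce(mk(1), s2), s2,
                            beadPositions(mk(1)))
  expect_equal(d2 / d1, 2, tolerance = 1e-6)
  dA <- measureDisplacement(minimizeUnderForce(mk(2), s1), s1,
                            beadPositions(mk(2)))
  expect_equal(d1 / dA, 2, tolerance = 1e-6)
})

test_that("displacement measurement matches a rigid translation and flags bad windows", {
  b <- tubeBeads()
  ends <- selectTerminalBeads(b)
  s <- forceClampSetup(ends$low, ends$high, totalForce = 1)
  X <- beadPositions(b)
  X[ends$high, 3] <- X[ends$high, 3] + 13.0
  expect_equal(measureDisplacement(X, s, beadPositions(b)), 13.0)
  m <- chainModel()
  cfg <- simulationConfig(timestep = 0.01, nSteps = 100L, recordEvery = 10L)
  tr <- langevinRun(m, cfg)
  sBad <- forceClampSetup(1L, 11L, totalForce = 0, window = c(5, 6)) # ns
  expect_error(measureDisplacement(tr, sBad, beadPositions(m)), "window")
})

test_that("Young's modulus estimators are consistent and unit-correct", {
  expect_equal(youngsModulus(2.36, 100, 13.0, 181.5), 100, tolerance = 1e-3)
  expect_equal(youngsModulus(4.72, 100, 13.0, 181.5),
               2 * youngsModulus(2.36, 100, 13.0, 181.5))
  expect_error(youngsModulus(2.36, 100, 0), "stiffness")
  # perfect linear data: slope estimator equals the single-point value
  fs <- c(1.04, 1.37, 1.7, 2.03, 2.36)
  dl <- fs * 13.0 / 2.36
  est <- youngsModulusFromSeries(fs, dl, length0 = 100, area = 181.5)
  expect_equal(est$E, youngsModulus(2.36, 100, 13.0, 181.5), tolerance = 1e-9)
  expect_equal(est$r.squared, 1, tolerance = 1e-12)
  # noisy data: estimate unbiased within 2 SE over 100 seeded replicates
  Es <- vapply(1:100, function(s) {
    set.seed(s)
    youngsModulusFromSeries(fs, dl + rnorm(5, sd = 0.3), 100, 181.5)$E
  }, numeric(1))
  expect_lt(abs(mean(Es) - 100), 2 * sd(Es) / sqrt(100))
  expect_error(youngsModulusFromSeries(c(1, 1), c(2, 2), 100), "distinct")
})

test_that("force-scale calibration inverts a known compliance", {
  n <- 8
  builder <- function(A) {
    pos <- cbind(0, 0, (0:n) * 1.0)
    buildNetwork(BeadSet(pos, masses = rep(3, n + 1)), cutoff = 1, R = 10,
                 A = A)
  }
  s <- forceClampSetup(1L, n + 1L, totalForce = 0.01)
  # analytic: dL = n F / (2 gamma), with gamma proportional to A
  g1 <- bondTable(builder(1))$gamma[1]
  target <- n * 0.01 * 602.214076 / (2 * g1 * 2)   # displacement of A = 2
  cal <- calibrateForceScale(builder, s, target, candidateAs = c(0.5, 1, 4))
  expect_equal(cal$A, 2, tolerance = 0.01)
  expect_equal(cal$displacement, target, tolerance = 1e-4)
})

test_that("stability diagnostics accept frozen tubes and flag collapses", {
  b <- tubeBeads()
  P <- beadPositions(b)
  frames <- array(0, c(3, nrow(P), 3))
  for (k in 1:3) frames[k, , ] <- P
  frozen <- new("Trajectory", frames = frames, frameInterval = 1,
                config = list(), potentialEnergy = numeric(3))
  expect_true(stabilityCheck(frozen, P)$stable)
  collapsed <- frames
  ctr <- colMeans(P[, 1:2])
  collapsed[3, , 1:2] <- sweep(sweep(P[, 1:2], 2, ctr) * 0.5, 2, ctr, "+")
  trC <- new("Trajectory", frames = collapsed, frameInterval = 1,
             config = list(), potentialEnergy = numeric(3))
  expect_false(stabilityCheck(trC, P)$stable)
})
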