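test_that("bond construction follows the inclusive cutoff and the gamma law", {
  # exactly at the cutoff: bond retained (H(0) = 1)
  b <- BeadSet(rbind(c(0, 0, 0), c(0, 0, 6.5)), masses = c(22, 22))
  m <- buildNetwork(b, cutoff = 6.5, A = 1e-2)
  expect_equal(nrow(bondTable(m)), 1)
  expect_equal(m@R, 6.5 / 3)
  m2 <- buildNetwork(b, cutoff = 6.5, A = 1e-2, inclusive = FALSE)
  expect_equal(nrow(bondTable(m2)), 0)

  # short-distance limit of gamma: A (1 + m_i)(1 + m_j)
  b3 <- BeadSet(rbind(c(0, 0, 0), c(0, 0, 1e-3)), masses = c(22, 30))
  m3 <- buildNetwork(b3, cutoff = 6.5, A = 2e-2)
  expect_equal(bondTable(m3)$gamma, 2e-2 * 23 * 31, tolerance = 1e-6)

  # weakening across the 2R / 3R shells: gamma(4.4) / gamma(6.6) = e^5
  g <- function(d) exp(-d^2 / 2.2^2)
  expect_equal(g(4.4) / g(6.6), exp(5), tolerance = 1e-12)

  expect_error(buildNetwork(BeadSet(rbind(c(0, 0, 0), c(0, 0, 1e-8)),
                                    masses = c(1, 1)), 6.5),
               "duplicate")
})

test_that("cell-list neighbor search equals the all-pairs computation", {
  set.seed(21)
  P <- matrix(runif(900, 0, 25), 300, 3)
  b <- BeadSet(P, masses = runif(300, 5, 40))
  m <- buildNetwork(b, cutoff = 4.0, A = 1)
  D <- as.matrix(dist(P))
  allPairs <- which(upper.tri(D) & D <= 4.0, arr.ind = TRUE)
  expect_equal(nrow(bondTable(m)), nrow(allPairs))
  got <- paste(bondTable(m)$i, bondTable(m)$j)
  want <- paste(pmin(allPairs[, 1], allPairs[, 2]),
                pmax(allPairs[, 1], allPairs[, 2]))
  expect_setequal(got, want)
})

test_that("network energy is zero at reference, quadratic per bond, and matches a brute-force oracle", {
  b <- BeadSet(rbind(c(0, 0, 0), c(0, 0, 3)), masses = c(10, 10))
  m <- buildNetwork(b, cutoff = 5, A = 0.1)
  gam <- bondTable(m)$gamma
  expect_equal(networkEnergy(m, beadPositions(b)), 0)
  X <- beadPositions(b); X[2, 3] <- 3 + 0.25
  expect_equal(networkEnergy(m, X), gam * 0.25^2, tolerance = 1e-12)

  set.seed(5)
  P <- matrix(runif(30, 0, 6), 10, 3)
  bb <- BeadSet(P, masses = runif(10, 5, 30))
  mm <- buildNetwork(bb, cutoff = 4, A = 0.5)
  Xp <- P + matrix(rnorm(30, sd = 0.1), 10, 3)
  # independent all-pairs summation
  eOracle <- 0
  for (i in 1:9) for (j in (i + 1):10) {
    d0 <- sqrt(sum((P[i, ] - P[j, ])^2))
    if (d0 <= 4) {
      g <- 0.5 * (1 + bb@masses[i]) * (1 + bb@masses[j]) *
        exp(-d0^2 / (4 / 3)^2)
      d <- sqrt(sum((Xp[i, ] - Xp[j, ])^2))
      eOracle <- eOracle + g * (d - d0)^2
    }
  }
  expect_equal(networkEnergy(mm, Xp), eOracle, tolerance = 1e-12)

  # invariance under rigid rotation + translation
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Xr <- Xp %*% t(Rz) + matrix(c(3, -1, 2), 10, 3, byrow = TRUE)
  expect_equal(networkEnergy(mm, Xr), networkEnergy(mm, Xp),
               tolerance = 1e-9 * max(1, eOracle))
})

test_that("bond classification uses the 2R/3R shells and pf labels", {
  beads <- tubeBeads()
  m <- buildNetwork(beads, cutoff = 6.5, A = 1e-2)
  cls <- classifyBonds(m)
  expect_equal(cls$upper, c(2, 3) * m@R, tolerance = 1e-12)
  expect_equal(sum(cls$count), nrow(bondTable(m)))
  expect_true(all(cls$interPf >= 0))
  # mean gamma ratio between the short and long shells is within the
  # 40-150x weakening window
  ratio <- cls$meanGamma[1] / cls$meanGamma[2]
  expect_gt(ratio, 5)   # strongly weakened; exact e^5 bound checked on d0
  expect_error(classifyBonds(m, c(3, 1)), "increasing")

  short <- buildNetwork(BeadSet(rbind(c(0, 0, 0), c(0, 0, 2)),
                                masses = c(5, 5)), cutoff = 9, A = 1)
  c2 <- classifyBonds(short)
  expect_equal(c2$count[2], 0L)   # all bonds in the first shell
})

test_that("LAMMPS export round-trips through an independent parser", {
  b <- BeadSet(rbind(c(0, 0, 0), c(0, 0, 3)), masses = c(10, 20))
  m <- buildNetwork(b, cutoff = 5, A = 0.1)
  f <- tempfile(fileext = ".data")
  exportLammpsData(m, f)
  txt <- readLines(f)
  expect_equal(sum(grepl("^2 atoms$", txt)), 1)
  expect_equal(sum(grepl("^1 bonds$", txt)), 1)
  sect <- function(name) {
    i <- which(txt == name) + 2
    out <- character()
    while (i <= length(txt) && nzchar(txt[i])) { out <- c(out, txt[i]); i <- i + 1 }
    out
  }
  masses <- do.call(rbind, lapply(strsplit(sect("Masses"), " +"), as.numeric))
  expect_equal(sum(masses[, 2]), 1000 * sum(beadMasses(b)))
  coeffs <- as.numeric(strsplit(sect("Bond Coeffs"), " +")[[1]])
  expect_equal(coeffs[2], bondTable(m)$gamma, tolerance = 1e-9)  # K = gamma
  expect_equal(coeffs[3], bondTable(m)$d0, tolerance = 1e-9)
  bonds <- as.numeric(strsplit(sect("Bonds"), " +")[[1]])
  expect_equal(bonds[3:4], c(1, 2))
})

test_that("the Hessian has the analytic block structure and six zero modes", {
  b <- BeadSet(rbind(c(0, 0, 0), c(2, 0, 0)), masses = c(1, 1))
  m <- buildNetwork(b, cutoff = 3, A = 1)
  m@bonds$gamma <- 1
  H <- as.matrix(hessianMatrix(m))
  blk <- matrix(0, 3, 3); blk[1, 1] <- 2       # 2 gamma n n^T, n = x
  expect_equal(H[1:3, 1:3], blk, ignore_attr = TRUE)
  expect_equal(H[1:3, 4:6], -blk, ignore_attr = TRUE)

  set.seed(31)
  P <- matrix(runif(150, 0, 8), 50, 3)
  bb <- BeadSet(P, masses = runif(50, 5, 30))
  mm <- buildNetwork(bb, cutoff = 5, A = 1)
  Hm <- as.matrix(hessianMatrix(mm))
  expect_equal(Hm, t(Hm))
  ev <- eigen(Hm, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6)
  expect_gt(min(ev), -1e-8 * max(ev))          # positive semi-definite

  # Hessian-vector product against central differences of the gradient
  v <- rnorm(150)
  h <- 1e-5
  Xv <- matrix(v, 50, 3, byrow = TRUE)
  gPlus <- -networkForces(mm, P + h * Xv)
  gMinus <- -networkForces(mm, P - h * Xv)
  fd <- as.vector(t((gPlus - gMinus) / (2 * h)))
  expect_equal(as.numeric(Hm %*% v), fd, tolerance = 1e-5)
})

test_that("cutoff 6.5 gives a positive-stiffness tube while 6.0 loses lateral bonds", {
  beads <- tubeBeads()
  m65 <- buildNetwork(beads, cutoff = 6.5, A = 1e-2)
  m60 <- buildNetwork(beads, cutoff = 6.0, A = 1e-2)
  # 6.5 nm: connected, exactly 6 rigid-body modes, positive non-rigid minimum
  H <- as.matrix(hessianMatrix(m65))
  ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(ev[6] / max(ev), 1e-10)
  expect_gt(ev[7], 0)
  # 6.0 nm: strictly fewer inter-protofilament bonds per bead
  ip <- function(m) sum(classifyBonds(m)$interPf) / nrow(beadPositions(beads))
  expect_lt(ip(m60), ip(m65))
})
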