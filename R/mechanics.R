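#' Simulation configuration for Langevin dynamics
#'
#' Defaults follow the standard protocol for these networks: 300 K, a
#' 10 fs timestep for force-clamp runs (persistence-length runs can afford
#' ~3 ps because the lightest beads are thousands of times heavier than
#' atoms), and a Langevin damping time of 10 ps with per-bead friction
#' mass / dampingTime.
#'
#' @param temperature K; default 300.
#' @param timestep ps; default 0.01 (10 fs).
#' @param dampingTime ps; default 10.
#' @param nSteps number of integration steps.
#' @param recordEvery store a frame every this many steps; default 1.
#' @param seed RNG seed.
#' @param massScaling factor applied to all masses in the equations of
#'   motion only; default 1. The configurational Boltzmann distribution is
#'   independent of the masses, so scaling them down accelerates
#'   convergence of equilibrium structural averages without changing them
#'   (kinetic time scales are of course distorted).
#' @return list of class "SimulationConfig".
#' @export
simulationConfig <- function(temperature = 300, timestep = 0.01,
                             dampingTime = 10, nSteps = 1000L,
                             recordEvery = 1L, seed = 1L, massScaling = 1) {
  if (timestep <= 0) stop("timestep must be positive")
  if (dampingTime <= 0) stop("dampingTime must be positive")
  if (temperature < 0) stop("temperature must be >= 0")
  if (massScaling <= 0) stop("massScaling must be positive")
  structure(list(temperature = temperature, timestep = timestep,
                 dampingTime = dampingTime, nSteps = as.integer(nSteps),
                 recordEvery = as.integer(recordEvery),
                 seed = as.integer(seed), massScaling = massScaling),
            class = "SimulationConfig")
}

#' Force-clamp setup: fixed and pulled terminal bead sets
#'
#' One terminal of the filament is held fixed while the other is pulled by a
#' constant total force along the tube axis, split equally over the pulled
#' beads.
#'
#' @param fixedBeads indices of immobilized beads.
#' @param pulledBeads indices of pulled beads (disjoint from fixed).
#' @param totalForce total pulling force in nN (may be 0).
#' @param axis axis index the force acts along; default 3.
#' @param window averaging window c(start, end) in ns for trajectory
#'   displacement means; default NULL (second half of the run).
#' @return list of class "ForceClampSetup".
#' @export
forceClampSetup <- function(fixedBeads, pulledBeads, totalForce = 0,
                            axis = 3L, window = NULL) {
  fixedBeads <- as.integer(fixedBeads); pulledBeads <- as.integer(pulledBeads)
  if (!length(fixedBeads) || !length(pulledBeads))
    stop("fixed and pulled bead sets must be nonempty")
  if (length(intersect(fixedBeads, pulledBeads)))
    stop("fixed and pulled bead sets must be disjoint")
  structure(list(fixedBeads = fixedBeads, pulledBeads = pulledBeads,
                 totalForce = totalForce, axis = as.integer(axis),
                 window = window),
            class = "ForceClampSetup")
}

#' Select terminal bead sets along the tube axis
#'
#' @param x a \code{BeadSet} or \code{UCGModel}.
#' @param axis axis index; default 3.
#' @param width terminal slab thickness in nm; default 5.
#' @return list(low = indices, high = indices).
#' @export
selectTerminalBeads <- function(x, axis = 3L, width = 5) {
  P <- beadPositions(x)
  z <- P[, axis]
  list(low = which(z <= min(z) + width), high = which(z >= max(z) - width))
}

# shortest harmonic bond period of a model, ps (masses g/mol internally)
.minBondPeriod <- function(model) {
  b <- model@bonds
  if (!nrow(b)) return(Inf)
  mg <- 1000 * model@beads@masses
  mu <- mg[b$i] * mg[b$j] / (mg[b$i] + mg[b$j])
  min(2 * pi * sqrt(mu / (2 * b$gamma)))
}

# external constant force matrix (N x 3, kJ/mol/nm) for a setup
.externalForce <- function(N, setup) {
  Fext <- matrix(0, N, 3)
  if (!is.null(setup) && setup$totalForce != 0) {
    perBead <- setup$totalForce * .NN_TO_KJMOLNM / length(setup$pulledBeads)
    Fext[setup$pulledBeads, setup$axis] <- perBead
  }
  Fext
}

#' Langevin dynamics of a UCG network
#'
#' BAOAB discretization of Langevin dynamics at the configured temperature,
#' with per-bead friction coefficient mass / dampingTime (so the velocity
#' autocorrelation decays with the damping time, the LAMMPS "damp"
#' convention). Fixed beads are immobilized; the clamp force is divided
#' equally over the pulled beads. Fully reproducible for a given seed.
#' Initial velocities are drawn from the Maxwell-Boltzmann distribution
#' (exactly zero at T = 0).
#'
#' @param model a \code{UCGModel}.
#' @param config a \code{\link{simulationConfig}}.
#' @param setup optional \code{\link{forceClampSetup}}.
#' @param start optional N x 3 starting coordinates; default the reference.
#' @return a \code{\link{Trajectory}} (frame 1 is the start configuration).
#' @export
langevinRun <- function(model, config, setup = NULL, start = NULL) {
  P0 <- model@beads@positions
  N <- nrow(P0)
  b <- model@bonds
  if (!.isConnected(N, b)) warning("network is not connected")
  ms <- if (is.null(config$massScaling)) 1 else config$massScaling
  per <- .minBondPeriod(model) * sqrt(ms)
  if (config$timestep > 0.1 * per)
    warning(sprintf("timestep %.3g ps exceeds 0.1 x shortest bond period (%.3g ps)",
                    config$timestep, per))
  X <- if (is.null(start)) P0 else as.matrix(start)
  mg <- 1000 * model@beads@masses * ms      # g/mol: consistent kJ/mol-nm-ps
  dt <- config$timestep
  kT <- .kB * config$temperature
  c1 <- exp(-dt / config$dampingTime)
  Fext <- .externalForce(N, setup)
  fixed <- if (is.null(setup)) integer(0) else setup$fixedBeads
  fixedMask <- logical(N)
  fixedMask[fixed] <- TRUE
  res <- .withSeed(config$seed,
    cpp_langevin_baoab(X, as.integer(b$i) - 1L, as.integer(b$j) - 1L,
                       b$gamma, b$d0, mg, dt, c1, sqrt(kT / mg),
                       Fext, fixedMask, config$nSteps, config$recordEvery, kT))
  if (res$divergedAt > 0)
    stop("simulation diverged at step ", res$divergedAt)
  nf <- res$nFrames
  # frames come back as [xyz, bead, frame] (fastest first); reorder
  fr <- aperm(array(res$frames[seq_len(nf * N * 3)], dim = c(3, N, nf)),
              c(3, 2, 1))
  new("Trajectory", frames = fr, frameInterval = dt * config$recordEvery,
      config = unclass(config), potentialEnergy = res$epot[seq_len(nf)])
}

.isConnected <- function(N, bonds) {
  if (N <= 1) return(TRUE)
  if (!nrow(bonds)) return(FALSE)
  adj <- split(c(bonds$j, bonds$i), c(bonds$i, bonds$j))
  visited <- logical(N)
  visited[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {      # BFS over the bond graph
    nb <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nb <- nb[!visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  all(visited)
}

# instantaneous Hessian of the (geometrically nonlinear) network energy
.energyHessianAt <- function(model, X) {
  b <- model@bonds
  N <- nrow(X)
  dv <- X[b$i, , drop = FALSE] - X[b$j, , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  n <- dv / d
  kpar <- 2 * b$gamma
  kperp <- 2 * b$gamma * (d - b$d0) / d
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (a in 1:3) for (cc in 1:3) {
    blk <- (kpar - kperp) * n[, a] * n[, cc] + ifelse(a == cc, kperp, 0)
    ia <- 3 * (b$i - 1L) + a; ic <- 3 * (b$i - 1L) + cc
    ja <- 3 * (b$j - 1L) + a; jc <- 3 * (b$j - 1L) + cc
    rows <- c(rows, ia, ja, ia, ja)
    cols <- c(cols, ic, jc, jc, ic)
    vals <- c(vals, blk, blk, -blk, -blk)
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(3 * N, 3 * N))
}

#' Static equilibrium under a constant clamp force
#'
#' Minimizes the network energy minus the work of the external force over
#' the free beads (fixed beads stay at the reference), by Newton iterations
#' with the exact sparse Hessian and step halving. For a harmonic network
#' the Langevin time-average of the force-clamp displacement equals this
#' static minimum, which makes it the cheap oracle for the long-time mean.
#'
#' @param model a \code{UCGModel}.
#' @param setup a \code{\link{forceClampSetup}}.
#' @param gradTol convergence threshold on the max gradient component,
#'   relative to the typical applied force (absolute when no force);
#'   default 1e-9.
#' @param maxIter Newton iteration cap; default 60.
#' @param start optional N x 3 starting coordinates (e.g. the solution at a
#'   nearby force level, for continuation along a force series).
#' @return N x 3 matrix of equilibrium coordinates.
#' @export
minimizeUnderForce <- function(model, setup, gradTol = 1e-9, maxIter = 60L,
                               start = NULL) {
  P0 <- model@beads@positions
  N <- nrow(P0)
  Fext <- .externalForce(N, setup)
  if (all(Fext == 0)) return(P0)
  fixed <- setup$fixedBeads
  freeBeads <- setdiff(seq_len(N), fixed)
  freeDof <- as.vector(vapply(freeBeads, function(i) 3L * (i - 1L) + 1:3,
                              integer(3)))
  scale <- max(abs(Fext))
  X <- if (is.null(start)) P0 else as.matrix(start)
  X[fixed, ] <- P0[fixed, ]
  phi <- function(X) {
    e <- networkEnergy(model, X) - sum(Fext * X)
    if (!is.finite(e)) Inf else e
  }
  f0 <- phi(X)
  maxStep <- 5 + 0.2 * diff(range(P0[, setup$axis]))   # trust-region cap, nm
  lam <- 0                            # Levenberg-Marquardt damping
  for (it in seq_len(2 * maxIter)) {
    G <- -(networkForces(model, X) + Fext)       # gradient of phi
    gvec <- as.vector(t(G))[freeDof]
    if (!all(is.finite(gvec))) stop("minimization diverged (overlapping beads)")
    if (max(abs(gvec)) < gradTol * scale) break
    H <- .energyHessianAt(model, X)[freeDof, freeDof]
    hScale <- max(abs(H@x))
    accepted <- FALSE
    for (try in 1:30) {               # damped Newton with adaptive ridge
      step <- tryCatch(
        as.numeric(Matrix::solve(H + Matrix::Diagonal(length(freeDof),
                                                      lam * hScale), -gvec)),
        error = function(e) NULL)
      if (is.null(step)) { lam <- max(lam * 10, 1e-10); next }
      big <- max(abs(step))
      if (big > maxStep) step <- step * (maxStep / big)
      U <- as.vector(t(X))
      U[freeDof] <- U[freeDof] + step
      Xn <- matrix(U, N, 3, byrow = TRUE)
      fn <- phi(Xn)
      if (fn <= f0 + 1e-12 * abs(f0)) {
        accepted <- TRUE
        lam <- lam / 10
        if (lam < 1e-12) lam <- 0
        break
      }
      lam <- max(lam * 10, 1e-10)
    }
    if (!accepted) break              # no descent direction left
    X <- Xn; f0 <- fn
  }
  if (max(abs(gvec)) > 2e-2 * scale)
    warning("force-clamp minimization did not fully converge ",
            "(max residual force ", signif(max(abs(gvec)), 3),
            " vs applied ", signif(scale, 3),
            "); the model may have floppy mechanism modes")
  X
}

#' Axial end-to-end displacement under a force clamp
#'
#' Delta L = (mean axial coordinate of the pulled set minus the fixed set),
#' relative to the same quantity at the reference structure. For a
#' \code{Trajectory} the displacement is averaged over the equilibration
#' window (\code{setup$window} in ns, defaulting to the second half of the
#' run), with the per-frame standard deviation reported.
#'
#' @param x a \code{Trajectory} or an N x 3 coordinate matrix.
#' @param setup a \code{\link{forceClampSetup}}.
#' @param reference reference coordinates (N x 3).
#' @return for matrices, the displacement (nm); for trajectories, a list
#'   with \code{displacement}, \code{sd}, \code{se}, \code{nFrames} and the
#'   per-frame \code{trace}.
#' @export
measureDisplacement <- function(x, setup, reference) {
  ax <- setup$axis
  refGap <- mean(reference[setup$pulledBeads, ax]) -
    mean(reference[setup$fixedBeads, ax])
  gapOf <- function(M) mean(M[setup$pulledBeads, ax]) -
    mean(M[setup$fixedBeads, ax])
  if (is.matrix(x)) return(gapOf(x) - refGap)
  stopifnot(is(x, "Trajectory"))
  fr <- x@frames
  tps <- (seq_len(dim(fr)[1]) - 1L) * x@frameInterval
  win <- setup$window
  if (is.null(win)) win <- c(max(tps) / 2, max(tps)) / 1000
  sel <- which(tps >= win[1] * 1000 & tps <= win[2] * 1000)
  if (!length(sel)) stop("averaging window outside the trajectory span")
  trace <- vapply(sel, function(k) gapOf(fr[k, , ]) - refGap, numeric(1))
  ess <- max(1, length(trace) / (2 * max(1, .intAutocorrTime(trace))))
  list(displacement = mean(trace), sd = sd(trace),
       se = sd(trace) / sqrt(ess), nFrames = length(trace), trace = trace)
}

# crude integrated autocorrelation time (frames), for effective sample size
.intAutocorrTime <- function(x, maxLag = min(200L, length(x) %/% 3L)) {
  if (length(x) < 10 || sd(x) == 0) return(1)
  ac <- stats::acf(x, lag.max = maxLag, plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  if (length(pos)) ac <- ac[seq_len(pos[1])]
  max(1, 0.5 + sum(ac))
}

#' Young's modulus from a single force-displacement pair
#'
#' E = (F / A) / (Delta L / L), converted to MPa (F in nN, lengths in nm,
#' area in nm^2; 1 nN/nm^2 = 1 GPa).
#'
#' @param force nN.
#' @param length0 filament length L, nm.
#' @param displacement Delta L, nm.
#' @param area cross-section area, nm^2; default 181.5 (annulus with outer
#'   radius 12.5 nm and ~2.6 nm wall).
#' @return Young's modulus in MPa.
#' @export
youngsModulus <- function(force, length0, displacement, area = 181.5) {
  if (force <= 0 || length0 <= 0 || area <= 0) stop("inputs must be positive")
  if (displacement == 0) stop("zero displacement: infinite stiffness")
  1000 * (force / area) / (displacement / length0)
}

#' Young's modulus from a force series (slope estimator)
#'
#' Least-squares fit of displacement against force (through the origin by
#' default); E follows from the fitted compliance slope.
#'
#' @param forces nN (>= 2 distinct values).
#' @param displacements nm.
#' @param length0 nm.
#' @param area nm^2.
#' @param throughOrigin force the fit through zero; default TRUE.
#' @return list(E, slope, r.squared, fit).
#' @export
youngsModulusFromSeries <- function(forces, displacements, length0,
                                    area = 181.5, throughOrigin = TRUE) {
  if (length(unique(forces)) < 2) stop("need at least 2 distinct forces")
  fit <- if (throughOrigin) lm(displacements ~ forces + 0)
         else lm(displacements ~ forces)
  slope <- unname(coef(fit)[["forces"]])
  r2 <- 1 - sum(resid(fit)^2) /
    sum((displacements - if (throughOrigin) 0 else mean(displacements))^2)
  list(E = 1000 * length0 / (area * slope), slope = slope,
       r.squared = r2, fit = fit)
}

#' Calibrate the force-constant scale A against a target displacement
#'
#' Evaluates the static clamp displacement for each candidate A (each
#' candidate's model is built by \code{modelBuilder}), then exploits the
#' harmonic scaling Delta L ~ 1/A for a one-step inverse update, polished by
#' secant iterations on log A until the static displacement matches the
#' target.
#'
#' @param modelBuilder function(A) returning a \code{UCGModel}.
#' @param setup a \code{\link{forceClampSetup}} with nonzero force.
#' @param targetDisplacement nm.
#' @param candidateAs numeric vector of candidate A values (>= 2).
#' @param tol relative displacement tolerance; default 1e-4.
#' @return list(A, displacement, candidates = data.frame(A, displacement)).
#' @export
calibrateForceScale <- function(modelBuilder, setup, targetDisplacement,
                                candidateAs, tol = 1e-4) {
  if (length(candidateAs) < 2) stop("need at least 2 candidate A values")
  dispOf <- function(A) {
    m <- modelBuilder(A)
    measureDisplacement(minimizeUnderForce(m, setup), setup,
                        m@beads@positions)
  }
  cand <- data.frame(A = sort(candidateAs))
  # the scan only brackets the target; rough minimizations suffice there
  cand$displacement <- suppressWarnings(vapply(cand$A, dispOf, numeric(1)))
  if (targetDisplacement > max(cand$displacement) ||
      targetDisplacement < min(cand$displacement))
    warning("target displacement outside the span of the candidates; extrapolating")
  best <- which.min(abs(cand$displacement - targetDisplacement))
  A0 <- cand$A[best]; d0 <- cand$displacement[best]
  A1 <- A0 * d0 / targetDisplacement          # one-step inverse scaling
  d1 <- dispOf(A1)
  for (it in 1:20) {
    if (abs(d1 - targetDisplacement) <= tol * targetDisplacement) break
    # secant on log A vs log displacement
    sl <- (log(d1) - log(d0)) / (log(A1) - log(A0))
    A2 <- exp(log(A1) + (log(targetDisplacement) - log(d1)) / sl)
    A0 <- A1; d0 <- d1
    A1 <- A2; d1 <- dispOf(A1)
  }
  list(A = A1, displacement = d1, candidates = cand)
}

#' Structural stability diagnostics of a trajectory
#'
#' A tube is judged stable when its mean cross-section radius stays within
#' \code{radiusTol} of the reference at every frame and the radius of
#' gyration drifts by less than \code{rgTol}. The cross-section radius is
#' measured per axial slice (beads grouped by their reference axial
#' coordinate; per frame, the mean distance of each slice's beads from the
#' slice centroid), which makes the diagnostic insensitive to rigid motion
#' and to thermal bending of long tubes while remaining sensitive to
#' radial collapse or splaying of an underbonded wall.
#'
#' @param traj a \code{Trajectory}.
#' @param reference reference coordinates.
#' @param axis tube axis; default 3.
#' @param radiusTol relative tolerance on the mean radius; default 0.2.
#' @param rgTol relative tolerance on the radius of gyration; default 0.2.
#' @param sliceWidth axial slice thickness in nm; default 8 (the dimer
#'   repeat).
#' @return list(stable, radiusTrace, rgTrace, refRadius, refRg).
#' @export
stabilityCheck <- function(traj, reference, axis = 3L, radiusTol = 0.2,
                           rgTol = 0.2, sliceWidth = 8) {
  z <- reference[, axis]
  slice <- pmin(floor((z - min(z)) / sliceWidth) + 1L,
                max(1L, floor(diff(range(z)) / sliceWidth)))
  meanRadius <- function(M) {
    rad <- 0; nsl <- 0
    for (s in unique(slice)) {
      sel <- slice == s
      if (sum(sel) < 3) next
      ctr <- colMeans(M[sel, , drop = FALSE])
      rad <- rad + mean(sqrt(rowSums(sweep(M[sel, , drop = FALSE], 2, ctr)^2)))
      nsl <- nsl + 1
    }
    rad / nsl
  }
  rgOf <- function(M) sqrt(mean(rowSums(sweep(M, 2, colMeans(M))^2)))
  r0 <- meanRadius(reference); g0 <- rgOf(reference)
  fr <- traj@frames
  rr <- vapply(seq_len(dim(fr)[1]), function(k) meanRadius(fr[k, , ]), numeric(1))
  gg <- vapply(seq_len(dim(fr)[1]), function(k) rgOf(fr[k, , ]), numeric(1))
  stable <- all(abs(rr / r0 - 1) < radiusTol) && all(abs(gg / g0 - 1) < rgTol)
  list(stable = stable, radiusTrace = rr, rgTrace = gg,
       refRadius = r0, refRg = g0)
}
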