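# Shared fixtures, built once per test run and cached for the session.
.fx <- new.env(parent = emptyenv())

# 32 nm synthetic microtubule map, preprocessed and mass-calibrated.
tubeMap <- function() {
  if (is.null(.fx$map)) {
    spec <- microtubuleSpec(length = 32)
    map <- makeMicrotubuleDensity(spec, seed = 1)
    map <- removeSolvent(map, 0.1)
    map <- normalizeDensity(map)
    .fx$nMonomers <- nrow(microtubuleLattice(spec))
    .fx$map <- calibrateMass(map, .fx$nMonomers * 55)
  }
  .fx$map
}

tubeMonomerCount <- function() { tubeMap(); .fx$nMonomers }

# CK-CG minimal-model beads (22 kg/mol average) on the 32 nm tube,
# labeled by protofilament.
tubeBeads <- function() {
  if (is.null(.fx$beads))
    .fx$beads <- labelProtofilaments(coarseGrain(tubeMap(), targetAvgMass = 22))
  .fx$beads
}

# Force-scale A calibrated so the 32 nm tube reproduces E = 100 MPa under
# a 2.36 nN clamp (cross-section 181.5 nm^2).
tubeCalibration <- function() {
  if (is.null(.fx$cal)) {
    b <- tubeBeads()
    ends <- selectTerminalBeads(b)
    setup <- forceClampSetup(ends$low, ends$high, totalForce = 2.36)
    L <- physicalExtent(tubeMap())[symmetryAxis(tubeMap())]
    target <- 1000 * 2.36 * L / (181.5 * 100)
    .fx$cal <- calibrateForceScale(function(A) buildNetwork(b, 6.5, A = A),
                                   setup, target, candidateAs = c(1, 2, 4))
    .fx$cal$setup <- setup
    .fx$cal$targetDisplacement <- target
    .fx$cal$length <- L
  }
  .fx$cal
}

# Tiny (<= 200 voxel) three-blob map for brute-force clustering oracles.
tinyBlobMap <- function() {
  if (is.null(.fx$tiny)) {
    d <- c(12L, 4L, 4L)
    ax <- lapply(d, function(n) seq_len(n) - 0.5)
    centers <- list(c(2, 2, 2), c(6, 2, 2), c(10, 2, 2))
    v <- array(0, d)
    for (ct in centers)
      v <- v + exp(-(ax[[1]] - ct[1])^2) %o% exp(-(ax[[2]] - ct[2])^2) %o%
        exp(-(ax[[3]] - ct[3])^2)
    .fx$tiny <- normalizeDensity(removeSolvent(DensityMap(v, voxelSize = 1),
                                               0.01))
  }
  .fx$tiny
}

# Independent brute-force density-weighted Lloyd oracle (deliberately
# written differently from the package implementation: plain loops).
bruteForceWeightedKmeans <- function(X, w, C, maxIter = 100) {
  K <- nrow(C)
  obj <- Inf
  for (it in seq_len(maxIter)) {
    assign <- integer(nrow(X))
    for (p in seq_len(nrow(X))) {
      dd <- colSums((t(C) - X[p, ])^2)
      assign[p] <- which.min(dd)
    }
    newObj <- 0
    for (k in seq_len(K)) {
      sel <- assign == k
      if (!any(sel)) next
      C[k, ] <- colSums(X[sel, , drop = FALSE] * w[sel]) / sum(w[sel])
    }
    for (p in seq_len(nrow(X)))
      newObj <- newObj + w[p] * sum((X[p, ] - C[assign[p], ])^2)
    if (is.finite(obj) && abs(obj - newObj) < 1e-12 * obj) break
    obj <- newObj
  }
  list(objective = newObj, centers = C, assign = assign)
}
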