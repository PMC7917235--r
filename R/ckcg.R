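#' Partition the retained density into axis-aligned blocks
#'
#' Tiles the bounding box of the retained voxels with cubic blocks of edge
#' \code{blockEdge}. In auto mode the edge is the smallest multiple of the
#' largest voxel dimension whose nonempty-block count M does not exceed
#' \code{nBeads} (the finest cubic tiling with M <= N), since the CK-CG
#' initializer needs one seed per block plus N - M extras.
#'
#' @param map a preprocessed \code{DensityMap}.
#' @param nBeads number of UCG beads the partition will seed (>= 1).
#' @param blockEdge block edge in nm, or NULL for auto selection.
#' @return an object of class "BlockPartition": a list with voxel
#'   coordinates \code{xyz} (nm), weights \code{w}, linear voxel indices
#'   \code{idx}, per-voxel \code{blockId}, block count \code{M},
#'   the Hadamard scores \code{h} (density x Gaussian kernel, kernel sigma =
#'   blockEdge/4 centered on the block content), and \code{blockEdge}.
#' @export
partitionBlocks <- function(map, nBeads, blockEdge = NULL) {
  nBeads <- as.integer(nBeads)
  if (nBeads < 1L) stop("nBeads must be >= 1")
  vc <- voxelCenters(map)
  if (!nrow(vc$xyz)) stop("map has no retained voxels")
  lo <- apply(vc$xyz, 2, min)
  hi <- apply(vc$xyz, 2, max)
  maxVox <- max(map@voxelSize)
  countBlocks <- function(edge) {
    bid <- .blockIds(vc$xyz, lo, edge)
    length(unique(bid$key))
  }
  if (is.null(blockEdge)) {
    span <- max(hi - lo) + maxVox
    edge <- maxVox
    while (countBlocks(edge) > nBeads && edge < 2 * span)
      edge <- edge + maxVox
    blockEdge <- edge
  } else {
    if (blockEdge < maxVox) stop("blockEdge smaller than one voxel")
    if (countBlocks(blockEdge) > nBeads)
      stop("blockEdge yields more blocks than beads (M > N)")
  }
  bid <- .blockIds(vc$xyz, lo, blockEdge)
  keys <- sort(unique(bid$key))
  blockId <- match(bid$key, keys)
  M <- length(keys)
  # Gaussian kernel centered on each block's content (midpoint of the
  # block's retained voxels), sigma = blockEdge / 4; content centering
  # keeps edge blocks unbiased and makes symmetric maps seed symmetrically
  ctr <- matrix(0, M, 3)
  for (c in 1:3) {
    mn <- tapply(vc$xyz[, c], blockId, min)
    mx <- tapply(vc$xyz[, c], blockId, max)
    ctr[, c] <- (mn + mx) / 2
  }
  sigma <- blockEdge / 4
  dc2 <- rowSums((vc$xyz - ctr[blockId, , drop = FALSE])^2)
  h <- vc$w * exp(-dc2 / (2 * sigma^2))
  structure(list(xyz = vc$xyz, w = vc$w, idx = vc$idx, blockId = blockId,
                 M = M, h = h, blockEdge = blockEdge, nBeads = nBeads),
            class = "BlockPartition")
}

# integer block coordinates and a collision-free key
.blockIds <- function(xyz, lo, edge) {
  ijk <- floor(sweep(xyz, 2, lo, "-") / edge)
  key <- ijk[, 1] + 1e4 * ijk[, 2] + 1e8 * ijk[, 3]
  list(ijk = ijk, key = key)
}

#' @export
print.BlockPartition <- function(x, ...) {
  cat("BlockPartition:", x$M, "blocks of edge", signif(x$blockEdge, 4),
      "nm over", length(x$w), "retained voxels\n")
  invisible(x)
}

#' Initial bead positions by per-block convolution and max-pooling
#'
#' For every block the Hadamard product h = density x Gaussian kernel is
#' max-pooled: the voxel with the largest h becomes that block's initial
#' center. Ties break to the lexicographically smallest voxel index. Blocks
#' whose retained density is entirely zero are skipped with a message.
#'
#' @param partition a \code{\link{partitionBlocks}} result.
#' @return data.frame(blockId, voxel, x, y, z, h) with one row per seeded
#'   block, ordered by blockId.
#' @export
convolveMaxpool <- function(partition) {
  p <- partition
  ord <- order(p$blockId, -p$h, p$idx)  # per block: best h first, ties by idx
  first <- !duplicated(p$blockId[ord])
  sel <- ord[first]
  out <- data.frame(blockId = p$blockId[sel], voxel = p$idx[sel],
                    x = p$xyz[sel, 1], y = p$xyz[sel, 2], z = p$xyz[sel, 3],
                    h = p$h[sel])
  empty <- out$h <= 0
  if (any(empty)) {
    message(sum(empty), " block(s) with zero retained density skipped")
    out <- out[!empty, , drop = FALSE]
  }
  out[order(out$blockId), , drop = FALSE]
}

#' Place extra centers in the highest-scoring blocks
#'
#' When the requested bead count N exceeds the block count M, the N - M
#' extra seeds go to the blocks with the largest Hadamard scores, one per
#' block in rank order (cycling if nExtra > M); within a block each extra
#' takes the largest-h voxel not already used as a center.
#'
#' @param partition a \code{\link{partitionBlocks}} result.
#' @param nExtra number of extra centers (>= 0).
#' @param centers the \code{\link{convolveMaxpool}} seed table.
#' @return data.frame in the same layout as \code{convolveMaxpool} (zero
#'   rows when nExtra = 0).
#' @export
assignExtraCenters <- function(partition, nExtra, centers) {
  nExtra <- as.integer(nExtra)
  empty <- centers[0, , drop = FALSE]
  if (nExtra == 0L) return(empty)
  p <- partition
  used <- centers$voxel
  blockScore <- tapply(p$h, p$blockId, max)
  rank <- as.integer(names(sort(blockScore, decreasing = TRUE)))
  rank <- rank[rank %in% centers$blockId]      # only seedable blocks
  picks <- list()
  takenPerBlock <- new.env()
  i <- 0L
  while (length(picks) < nExtra) {
    b <- rank[(i %% length(rank)) + 1L]
    i <- i + 1L
    inb <- which(p$blockId == b)
    ord <- inb[order(-p$h[inb], p$idx[inb])]
    avail <- ord[!(p$idx[ord] %in% used)]
    if (!length(avail)) next
    v <- avail[1]
    used <- c(used, p$idx[v])
    picks[[length(picks) + 1L]] <-
      data.frame(blockId = b, voxel = p$idx[v], x = p$xyz[v, 1],
                 y = p$xyz[v, 2], z = p$xyz[v, 3], h = p$h[v])
    if (i > nExtra * length(rank) + length(rank)) break  # nothing left anywhere
  }
  if (length(picks)) do.call(rbind, picks) else empty
}

#' Density-weighted K-means refinement (Lloyd iterations)
#'
#' Assigns every retained voxel to its nearest center (Euclidean distance in
#' physical nm; ties to the lowest center index) and moves each center to
#' the density-weighted centroid of its voxels, iterating until assignments
#' are stable or the relative change of the weighted within-cluster sum of
#' squares falls below \code{tol}. The objective is non-increasing by
#' construction. A cluster whose total weight drops to zero is reseeded at
#' the voxel contributing most to the objective (logged via message). Bead
#' masses follow the density-to-mass rule: massScale x summed voxel density
#' (raw density sums when the map is uncalibrated).
#'
#' @param map a preprocessed \code{DensityMap}.
#' @param centers initial center positions, K x 3 matrix (nm).
#' @param tol relative objective-change convergence threshold; default 1e-8.
#' @param maxIter maximum Lloyd iterations; default 500.
#' @param method label recorded on the result.
#' @return a \code{\link{BeadSet}}.
#' @export
kmeansRefine <- function(map, centers, tol = 1e-8, maxIter = 500L,
                         method = "ckcg") {
  C <- as.matrix(centers)
  if (!nrow(C)) stop("need at least one center")
  vc <- voxelCenters(map)
  X <- vc$xyz; w <- vc$w
  K <- nrow(C)
  if (K > nrow(X)) stop("more centers than retained voxels")
  prevAssign <- NULL
  trace <- numeric()
  for (it in seq_len(maxIter)) {
    a <- .assignNearest(X, w, C)
    # reseed empty (zero-weight) clusters at the worst-fit voxel
    wsum <- rowsum(w, a$assign)
    present <- as.integer(rownames(wsum))
    emptyK <- setdiff(seq_len(K), present[wsum > 0])
    if (length(emptyK)) {
      for (k in emptyK) {
        v <- which.max(w * a$dist2)
        C[k, ] <- X[v, ]
        message("reseeded empty cluster ", k, " at voxel ", vc$idx[v])
      }
      a <- .assignNearest(X, w, C)
    }
    trace <- c(trace, a$objective)
    if (!is.null(prevAssign) && identical(a$assign, prevAssign)) break
    relChange <- if (length(trace) > 1)
      abs(diff(tail(trace, 2))) / max(trace[length(trace) - 1], .Machine$double.eps)
      else Inf
    prevAssign <- a$assign
    # weighted centroid update
    ws <- as.numeric(rowsum(w, a$assign))
    Cnew <- rowsum(X * w, a$assign) / ws
    C[sort(unique(a$assign)), ] <- Cnew
    if (relChange < tol && length(trace) > 1) break
  }
  a <- .assignNearest(X, w, C)
  for (guard in 1:10) {   # ensure no empty bead in the final assignment
    missing <- setdiff(seq_len(K), unique(a$assign))
    if (!length(missing)) break
    for (k in missing) {
      v <- which.max(w * a$dist2)
      C[k, ] <- X[v, ]
      message("reseeded empty cluster ", k, " at voxel ", vc$idx[v])
      a <- .assignNearest(X, w, C)
    }
  }
  # final positions are the density-weighted centroids of the assignment
  ws <- as.numeric(rowsum(w, a$assign)[as.character(seq_len(K)), 1])
  C <- rowsum(X * w, a$assign)[as.character(seq_len(K)), , drop = FALSE] / ws
  obj <- sum(w * rowSums((X - C[a$assign, , drop = FALSE])^2))
  masses <- if (!is.na(map@massScale)) map@massScale * ws else ws
  BeadSet(positions = unname(C), masses = masses, assignment = a$assign,
          objective = obj, objectiveTrace = trace,
          nIterations = length(trace), method = method)
}

#' Coarse-grain a density map into UCG beads
#'
#' Full CK-CG pipeline: block partition, per-block Gaussian convolution and
#' max-pooling, extra-seed assignment to the highest-scoring blocks when
#' N > M, and density-weighted K-means refinement. The bead count is either
#' given directly or derived from a target average bead mass as
#' N = round(total calibrated mass / targetAvgMass). The \code{ckcg} method
#' is fully deterministic (no RNG anywhere on that path); the
#' \code{kmeans_random} baseline seeds K-means at \code{nBeads} voxels drawn
#' uniformly from the retained set with the given seed.
#'
#' @param map a preprocessed (and, for mass targets, calibrated)
#'   \code{DensityMap}.
#' @param targetAvgMass target average bead mass in kg/mol (requires a
#'   calibrated map); give either this or nBeads.
#' @param nBeads explicit bead count.
#' @param method "ckcg" (deterministic) or "kmeans_random" (seeded baseline).
#' @param seed RNG seed for the random baseline.
#' @param blockEdge block edge in nm or NULL for auto.
#' @param tol,maxIter convergence controls for \code{\link{kmeansRefine}}.
#' @return a \code{\link{BeadSet}}.
#' @export
coarseGrain <- function(map, targetAvgMass = NULL, nBeads = NULL,
                        method = c("ckcg", "kmeans_random"), seed = 1L,
                        blockEdge = NULL, tol = 1e-8, maxIter = 500L) {
  method <- match.arg(method)
  if (is.null(nBeads)) {
    if (is.null(targetAvgMass)) stop("give targetAvgMass or nBeads")
    if (is.na(map@massScale)) stop("targetAvgMass requires a calibrated map")
    total <- map@massScale * sum(map@values[map@mask])
    nBeads <- round(total / targetAvgMass)
  }
  nBeads <- as.integer(nBeads)
  nRetained <- sum(map@mask)
  if (nBeads > nRetained)
    stop("requested ", nBeads, " beads but only ", nRetained, " retained voxels")
  if (method == "ckcg") {
    part <- partitionBlocks(map, nBeads, blockEdge)
    seeds <- convolveMaxpool(part)
    extra <- assignExtraCenters(part, nBeads - nrow(seeds), seeds)
    C <- rbind(as.matrix(seeds[, c("x", "y", "z")]),
               as.matrix(extra[, c("x", "y", "z")]))
    kmeansRefine(map, C, tol = tol, maxIter = maxIter, method = "ckcg")
  } else {
    vc <- voxelCenters(map)
    pick <- .withSeed(seed, sample.int(nrow(vc$xyz), nBeads))
    kmeansRefine(map, vc$xyz[pick, , drop = FALSE], tol = tol,
                 maxIter = maxIter, method = "kmeans_random")
  }
}

#' Label beads by protofilament from their azimuthal position
#'
#' Assigns each bead the protofilament whose azimuthal sector it falls in
#' (sectors of width 2 pi / nPf centered on the protofilament angles of the
#' synthetic lattice). Intended for synthetic maps where the protofilament
#' geometry is known; used to count inter-protofilament bonds.
#'
#' @param beads a \code{BeadSet}.
#' @param nPf number of protofilaments.
#' @param axis long-axis index (default 3).
#' @return the \code{BeadSet} with the \code{labels} slot filled.
#' @export
labelProtofilaments <- function(beads, nPf = 13L, axis = 3L) {
  P <- beads@positions
  perp <- setdiff(1:3, axis)
  ctr <- colMeans(P[, perp, drop = FALSE])
  ang <- atan2(P[, perp[2]] - ctr[2], P[, perp[1]] - ctr[1])
  lab <- (round(ang / (2 * pi / nPf)) %% nPf) + 1L
  beads@labels <- as.integer(lab)
  beads
}

#' Radial bead distances from the tube axis
#'
#' @param beads a \code{BeadSet}.
#' @param axis long-axis index (default 3).
#' @return numeric vector of distances (nm) from the mean axis.
#' @export
beadRadii <- function(beads, axis = 3L) {
  P <- beads@positions
  perp <- setdiff(1:3, axis)
  ctr <- colMeans(P[, perp, drop = FALSE])
  sqrt((P[, perp[1]] - ctr[1])^2 + (P[, perp[2]] - ctr[2])^2)
}
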