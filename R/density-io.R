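#' Read an MRC/CCP4 density map
#'
#' Reads a mode-2 (32-bit float) MRC2014/CCP4 map. Header lengths are in
#' Angstrom and are converted to nm at this boundary; the rest of the package
#' works in nm. The grid is stored with the fastest-varying file axis first
#' (the standard column/row/section order with mapc,mapr,maps = 1,2,3).
#' The symmetry axis defaults to the longest physical axis. When the MRC
#' ORIGIN record is zero but the start indices (nxstart...) are not, the
#' origin is reconstructed from the start indices.
#'
#' @param path path to an MRC/CCP4 file.
#' @return a \code{\link{DensityMap}}.
#' @export
readDensity <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  if (length(ints) < 10)
    stop("MRC format error: truncated header (nx/ny/nz block)")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  nstart <- ints[5:7]
  mxyz <- ints[8:10]
  if (any(c(nx, ny, nz) <= 0) || any(c(nx, ny, nz) > 1e5))
    stop("MRC format error: implausible grid dimensions in header field nx/ny/nz")
  if (mode != 2)
    stop("MRC format error: unsupported mode in header field 'mode' (need 2, got ",
         mode, ")")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  if (!identical(mapcrs, 1:3))
    stop("MRC format error: unsupported axis order in header field mapc/mapr/maps")
  dstats <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  ispg <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (!length(nsymbt) || is.na(nsymbt) || nsymbt < 0)
    stop("MRC format error: bad header field nsymbt")
  extra <- readBin(con, "integer", n = 25, size = 4, endian = "little")
  # words 50-52 are the MRC2014 ORIGIN record (Angstrom floats)
  seek(con, 4 * 49)
  originA <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  nvox <- as.numeric(nx) * ny * nz
  vals <- readBin(con, "numeric", n = nvox, size = 4, endian = "little")
  if (length(vals) < nvox)
    stop("MRC format error: data block truncated (expected ", nvox,
         " voxels, got ", length(vals), ")")
  mxyz[mxyz <= 0] <- c(nx, ny, nz)[mxyz <= 0]
  voxA <- cella / mxyz
  if (any(voxA <= 0))
    stop("MRC format error: non-positive cell in header field cella")
  origin <- if (all(originA == 0) && any(nstart != 0)) nstart * voxA else originA
  DensityMap(array(vals, dim = c(nx, ny, nz)),
             voxelSize = voxA / 10, origin = origin / 10)
}

#' Write a DensityMap as an MRC/CCP4 file
#'
#' Writes a mode-2 little-endian MRC2014 map (nm converted back to Angstrom).
#' The min/max/mean/rms statistics are recomputed from the grid.
#'
#' @param map a \code{DensityMap}.
#' @param path output path.
#' @export
writeDensity <- function(map, path) {
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  v <- map@values
  d <- dim(v)
  wI <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wF <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wI(d); wI(2)            # nx ny nz, mode
  wI(c(0, 0, 0))          # nstart
  wI(d)                   # mx my mz
  wF(d * map@voxelSize * 10)  # cella in Angstrom
  wF(c(90, 90, 90))       # cellb
  wI(1:3)                 # mapc mapr maps
  wF(c(min(v), max(v), mean(v)))
  wI(c(1, 0))             # ispg, nsymbt
  wI(rep(0L, 25))         # extra; words 50-52 rewritten below as ORIGIN
  seek(con, 4 * 49)
  wF(map@origin * 10)     # ORIGIN in Angstrom
  seek(con, 4 * 52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian machine stamp
  wF(sd(as.numeric(v)))
  wI(0)                   # nlabl
  writeBin(raw(800), con) # labels
  wF(as.numeric(v))
  invisible(NULL)
}

#' Replicate a map along its symmetry axis
#'
#' Tiles the grid \code{nCopies} times along the long axis, multiplying the
#' physical length and the total summed density by \code{nCopies}. Copies
#' abut with no blending: the seed is assumed to be an exact lattice repeat
#' (for the microtubule, 4 x 8 nm dimer rise in 32 nm); a non-periodic seed
#' would create density seams at the junctions.
#'
#' @param map a \code{DensityMap}.
#' @param nCopies integer >= 1.
#' @return the replicated \code{DensityMap}.
#' @export
replicateAxial <- function(map, nCopies) {
  nCopies <- as.integer(nCopies)
  if (is.na(nCopies) || nCopies < 1L) stop("nCopies must be a positive integer")
  if (nCopies == 1L) return(map)
  a <- map@axis
  d <- dim(map@values)
  idx <- rep(seq_len(d[a]), times = nCopies)
  sel <- list(quote(expr =), quote(expr =), quote(expr =))
  sel[[a]] <- idx
  vals <- do.call(`[`, c(list(map@values), sel, list(drop = FALSE)))
  mask <- do.call(`[`, c(list(map@mask), sel, list(drop = FALSE)))
  out <- map
  out@values <- vals
  out@mask <- mask
  validObject(out)
  out
}

# Largest 6-connected component of a logical 3D array (BFS with vectorized
# frontier expansion on linear indices).
.largestComponent <- function(mask) {
  d <- dim(mask)
  n <- prod(d)
  lin <- which(mask)
  if (!length(lin)) return(mask)
  comp <- integer(n)           # 0 = unvisited / not in mask
  inMask <- logical(n); inMask[lin] <- TRUE
  ai <- arrayInd(lin, d)
  ix <- integer(n); iy <- integer(n); iz <- integer(n)
  ix[lin] <- ai[, 1]; iy[lin] <- ai[, 2]; iz[lin] <- ai[, 3]
  strides <- c(1L, d[1], d[1] * d[2])
  compId <- 0L
  sizes <- integer(0)
  remaining <- lin
  while (length(remaining)) {
    compId <- compId + 1L
    seedv <- remaining[1]
    comp[seedv] <- compId
    frontier <- seedv
    size <- 1L
    while (length(frontier)) {
      nb <- c(
        frontier[ix[frontier] > 1] - strides[1],
        frontier[ix[frontier] < d[1]] + strides[1],
        frontier[iy[frontier] > 1] - strides[2],
        frontier[iy[frontier] < d[2]] + strides[2],
        frontier[iz[frontier] > 1] - strides[3],
        frontier[iz[frontier] < d[3]] + strides[3]
      )
      nb <- unique(nb[inMask[nb] & comp[nb] == 0L])
      comp[nb] <- compId
      size <- size + length(nb)
      frontier <- nb
    }
    sizes[compId] <- size
    remaining <- remaining[comp[remaining] == 0L]
  }
  best <- which.max(sizes)
  array(comp == best, d)
}

#' Remove solvent density by relative thresholding
#'
#' Zeroes every voxel whose value is at most
#' \code{thresholdFraction * max(values)} and, optionally, keeps only the
#' largest 6-connected component of the surviving voxels (disconnected
#' density specks are solvent artifacts, not filament). Retained voxels are
#' strictly positive afterwards and are the only ones seen by clustering.
#'
#' @param map a \code{DensityMap} (not yet normalized).
#' @param thresholdFraction fraction of the maximum density in (0,1);
#'   default 0.1.
#' @param keepLargestComponent logical; default TRUE.
#' @return the masked \code{DensityMap}.
#' @export
removeSolvent <- function(map, thresholdFraction = 0.1,
                          keepLargestComponent = TRUE) {
  if (map@normalized) stop("removeSolvent must run before normalization")
  if (thresholdFraction <= 0 || thresholdFraction >= 1)
    stop("thresholdFraction must be in (0,1)")
  v <- map@values
  thr <- thresholdFraction * max(v)
  keep <- map@mask & (v > thr)
  if (!any(keep)) stop("threshold removed all voxels (empty map)")
  if (keepLargestComponent) keep <- .largestComponent(keep)
  v[!keep] <- 0
  out <- map
  out@values <- v
  out@mask <- keep
  out@solventRemoved <- TRUE
  validObject(out)
  out
}

#' Min-max normalize retained density to [0, 1]
#'
#' Applies mu_s(r) = (mu(r) - mu_min) / (mu_max - mu_min) over the retained
#' voxels; solvent-zeroed voxels stay zero and remain excluded via the mask.
#' Idempotent on an already normalized map.
#'
#' @param map a \code{DensityMap}.
#' @return the normalized \code{DensityMap}.
#' @export
normalizeDensity <- function(map) {
  v <- map@values
  r <- v[map@mask]
  lo <- min(r); hi <- max(r)
  if (hi <= lo) stop("degenerate density range: map is constant over retained voxels")
  v[map@mask] <- (r - lo) / (hi - lo)
  v[!map@mask] <- 0
  out <- map
  out@values <- v
  out@normalized <- TRUE
  validObject(out)
  out
}

#' Calibrate the density-to-mass scale
#'
#' Sets \code{massScale} so that \code{massScale * sum(retained density)}
#' equals the given total molar mass. Downstream, a bead's mass is
#' \code{massScale} times the summed normalized density of its voxels, which
#' conserves the total exactly over any clustering.
#'
#' @param map a normalized \code{DensityMap}.
#' @param totalMolarMass total molar mass represented by the map, kg/mol.
#' @return the calibrated \code{DensityMap}.
#' @export
calibrateMass <- function(map, totalMolarMass) {
  if (!map@normalized) stop("calibrateMass requires a normalized map")
  if (totalMolarMass <= 0) stop("totalMolarMass must be positive")
  s <- sum(map@values[map@mask])
  if (s <= 0) stop("zero total retained density; cannot calibrate")
  out <- map
  out@massScale <- totalMolarMass / s
  out
}
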