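#' @import methods
#' @importFrom Matrix sparseMatrix Cholesky solve crossprod t
#' @importFrom stats rnorm runif sd lm coef resid fitted quantile setNames kmeans
#' @importFrom utils head tail write.csv read.csv
#' @importFrom Rcpp evalCpp
#' @useDynLib ucgtube, .registration = TRUE
NULL

#' DensityMap: a 3D density grid with physical metadata
#'
#' Container for a cryo-EM style volumetric density map. Values live on a
#' regular grid; \code{voxelSize} gives the edge length of a voxel along each
#' grid axis in nm, \code{mapOrigin} the position of the corner of voxel
#' (1,1,1) in nm. Voxel centers sit at \code{origin + (index - 0.5) * voxelSize}.
#' The \code{mask} flags voxels retained for coarse-graining (solvent voxels
#' are zeroed and unmasked by \code{\link{removeSolvent}}). After
#' \code{\link{calibrateMass}}, \code{massScale} converts summed normalized
#' density to molar mass (kg/mol per density unit).
#'
#' @slot values 3D numeric array of densities.
#' @slot voxelSize numeric(3), nm per voxel edge.
#' @slot origin numeric(3), nm position of the grid corner.
#' @slot axis integer(1), grid axis treated as the filament long axis.
#' @slot massScale numeric(1), kg/mol per unit summed density (NA before
#'   calibration).
#' @slot mask logical array, TRUE for retained voxels.
#' @slot normalized logical(1), TRUE after min-max normalization.
#' @slot solventRemoved logical(1), TRUE after solvent removal.
#' @export
setClass("DensityMap",
  representation(
    values = "array",
    voxelSize = "numeric",
    origin = "numeric",
    axis = "integer",
    massScale = "numeric",
    mask = "array",
    normalized = "logical",
    solventRemoved = "logical"
  )
)

setValidity("DensityMap", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L) msg <- c(msg, "values must be a 3D array")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive finite numbers")
  if (length(object@origin) != 3L) msg <- c(msg, "origin must have length 3")
  if (!(object@axis %in% 1:3)) msg <- c(msg, "axis must be 1, 2 or 3")
  if (!identical(dim(object@mask), d)) msg <- c(msg, "mask must match values")
  if (object@solventRemoved &&
      any(object@values[object@mask] < 0))
    msg <- c(msg, "retained voxels must be non-negative after solvent removal")
  if (length(msg)) msg else TRUE
})

#' Construct a DensityMap
#'
#' @param values 3D numeric array.
#' @param voxelSize numeric(3) or scalar, nm per voxel edge.
#' @param origin numeric(3), nm; default zeros.
#' @param axis symmetry axis index; default the longest physical extent.
#' @param massScale kg/mol per density unit; NA until calibrated.
#' @param mask logical array of retained voxels; default all TRUE.
#' @return A \code{DensityMap}.
#' @export
DensityMap <- function(values, voxelSize, origin = c(0, 0, 0), axis = NULL,
                       massScale = NA_real_, mask = NULL) {
  values <- as.array(values)
  storage.mode(values) <- "double"
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  if (is.null(axis)) axis <- which.max(dim(values) * voxelSize)
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  new("DensityMap", values = values, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin), axis = as.integer(axis),
      massScale = as.numeric(massScale), mask = mask,
      normalized = FALSE, solventRemoved = FALSE)
}

#' BeadSet: UCG bead positions and masses from clustering a DensityMap
#'
#' @slot positions N x 3 matrix, bead coordinates in nm.
#' @slot masses numeric(N), kg/mol (density units when the source map was not
#'   mass-calibrated).
#' @slot assignment integer vector mapping retained voxels (in the order of
#'   \code{which(mask)}) to bead indices; may be empty.
#' @slot objective final density-weighted within-cluster sum of squares
#'   (nm^2 x density units).
#' @slot objectiveTrace per-iteration objective values.
#' @slot nIterations integer, Lloyd iterations to convergence.
#' @slot method "ckcg" or "kmeans_random".
#' @slot labels optional integer protofilament labels per bead (may be empty).
#' @export
setClass("BeadSet",
  representation(
    positions = "matrix",
    masses = "numeric",
    assignment = "integer",
    objective = "numeric",
    objectiveTrace = "numeric",
    nIterations = "integer",
    method = "character",
    labels = "integer"
  )
)

setValidity("BeadSet", function(object) {
  msg <- character()
  n <- nrow(object@positions)
  if (ncol(object@positions) != 3L) msg <- c(msg, "positions must be N x 3")
  if (length(object@masses) != n) msg <- c(msg, "one mass per bead required")
  if (n > 0 && any(!is.finite(object@positions)))
    msg <- c(msg, "positions must be finite")
  if (length(object@assignment) &&
      (min(object@assignment) < 1L || max(object@assignment) > n))
    msg <- c(msg, "assignment indices out of range")
  if (length(object@assignment) &&
      length(unique(object@assignment)) < n)
    msg <- c(msg, "empty bead: every bead must own at least one voxel")
  if (length(msg)) msg else TRUE
})

#' @export
BeadSet <- function(positions, masses, assignment = integer(),
                    objective = NA_real_, objectiveTrace = numeric(),
                    nIterations = 0L, method = "ckcg", labels = integer()) {
  new("BeadSet", positions = as.matrix(positions), masses = as.numeric(masses),
      assignment = as.integer(assignment), objective = as.numeric(objective),
      objectiveTrace = as.numeric(objectiveTrace),
      nIterations = as.integer(nIterations), method = method,
      labels = as.integer(labels))
}

#' UCGModel: a heterogeneous harmonic (MVP-ANM) network on a BeadSet
#'
#' Bonds connect bead pairs whose equilibrium separation d0 does not exceed
#' the cutoff dc; each carries a force constant
#' gamma = A (1 + m_i)(1 + m_j) exp(-d0^2 / R^2) in kJ/mol/nm^2, where m are
#' the bead molar masses in kg/mol and R defaults to dc/3. The bond energy is
#' gamma (d - d0)^2 (no factor 1/2).
#'
#' @slot beads a \code{BeadSet}.
#' @slot bonds data.frame with columns i, j (i < j), d0 (nm), gamma
#'   (kJ/mol/nm^2).
#' @slot cutoff nm, the Heaviside cutoff dc.
#' @slot R nm, range parameter of the distance Gaussian.
#' @slot A scaling factor (kJ/mol/nm^2 per unit mass product).
#' @export
setClass("UCGModel",
  representation(
    beads = "BeadSet",
    bonds = "data.frame",
    cutoff = "numeric",
    R = "numeric",
    A = "numeric"
  )
)

setValidity("UCGModel", function(object) {
  msg <- character()
  b <- object@bonds
  need <- c("i", "j", "d0", "gamma")
  if (!all(need %in% names(b))) {
    msg <- c(msg, "bonds must have columns i, j, d0, gamma")
  } else if (nrow(b)) {
    if (any(b$i >= b$j)) msg <- c(msg, "bonds must satisfy i < j")
    if (anyDuplicated(paste(b$i, b$j))) msg <- c(msg, "duplicate bond pair")
    if (any(b$d0 > object@cutoff + 1e-12))
      msg <- c(msg, "bond beyond cutoff (Heaviside violated)")
    if (any(b$gamma <= 0)) msg <- c(msg, "gamma must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Trajectory: time-ordered bead coordinate frames from Langevin dynamics
#'
#' @slot frames array [nFrames, N, 3] in nm (frame 1 is the initial state).
#' @slot frameInterval ps between stored frames.
#' @slot config echo of the \code{simulationConfig} used.
#' @slot potentialEnergy per-frame bonded potential energy, kJ/mol.
#' @export
setClass("Trajectory",
  representation(
    frames = "array",
    frameInterval = "numeric",
    config = "list",
    potentialEnergy = "numeric"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L || dim(object@frames)[3] != 3L)
    msg <- c(msg, "frames must be [nFrames, N, 3]")
  if (any(!is.finite(object@frames))) msg <- c(msg, "frames must be finite")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (length(msg)) msg else TRUE
})

## ---- show methods ----

setMethod("show", "DensityMap", function(object) {
  d <- dim(object@values)
  ext <- d * object@voxelSize
  cat("DensityMap:", paste(d, collapse = " x "), "voxels, ",
      sprintf("extent %.1f x %.1f x %.1f nm", ext[1], ext[2], ext[3]), "\n")
  cat("  voxel size (nm):", paste(signif(object@voxelSize, 4), collapse = ", "),
      " axis:", object@axis, "\n")
  cat("  retained voxels:", sum(object@mask), "of", length(object@mask),
      if (object@normalized) " [normalized]" else "",
      if (object@solventRemoved) " [solvent removed]" else "", "\n")
  if (!is.na(object@massScale))
    cat("  mass scale:", signif(object@massScale, 6), "kg/mol per density unit\n")
})

setMethod("show", "BeadSet", function(object) {
  cat("BeadSet:", nrow(object@positions), "beads (method:", object@method, ")\n")
  if (length(object@masses))
    cat("  mass range (kg/mol):", signif(min(object@masses), 4), "-",
        signif(max(object@masses), 4),
        " total:", signif(sum(object@masses), 6), "\n")
  if (!is.na(object@objective))
    cat("  objective:", signif(object@objective, 6), "after",
        object@nIterations, "iterations\n")
})

setMethod("show", "UCGModel", function(object) {
  cat("UCGModel:", nrow(object@beads@positions), "beads,",
      nrow(object@bonds), "bonds\n")
  cat("  cutoff dc:", object@cutoff, "nm, R:", signif(object@R, 4),
      "nm, A:", signif(object@A, 6), "\n")
  if (nrow(object@bonds))
    cat("  d0 range (nm):", signif(min(object@bonds$d0), 4), "-",
        signif(max(object@bonds$d0), 4), "\n")
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@frames)
  cat("Trajectory:", d[1], "frames of", d[2], "beads; frame interval",
      object@frameInterval, "ps\n")
})

## ---- accessors ----

#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))
#' @export
setMethod("densityValues", "DensityMap", function(x) x@values)

#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @export
setMethod("voxelSize", "DensityMap", function(x) x@voxelSize)

#' @export
setGeneric("mapOrigin", function(x) standardGeneric("mapOrigin"))
#' @export
setMethod("mapOrigin", "DensityMap", function(x) x@origin)

#' @export
setGeneric("symmetryAxis", function(x) standardGeneric("symmetryAxis"))
#' @export
setMethod("symmetryAxis", "DensityMap", function(x) x@axis)

#' @export
setGeneric("massScale", function(x) standardGeneric("massScale"))
#' @export
setMethod("massScale", "DensityMap", function(x) x@massScale)

#' @export
setGeneric("retainedMask", function(x) standardGeneric("retainedMask"))
#' @export
setMethod("retainedMask", "DensityMap", function(x) x@mask)

#' Physical extent of the map along each grid axis (nm)
#' @param x a DensityMap
#' @export
setGeneric("physicalExtent", function(x) standardGeneric("physicalExtent"))
#' @export
setMethod("physicalExtent", "DensityMap",
          function(x) dim(x@values) * x@voxelSize)

#' @export
setGeneric("beadPositions", function(x) standardGeneric("beadPositions"))
#' @export
setMethod("beadPositions", "BeadSet", function(x) x@positions)
#' @export
setMethod("beadPositions", "UCGModel", function(x) x@beads@positions)

#' @export
setGeneric("beadMasses", function(x) standardGeneric("beadMasses"))
#' @export
setMethod("beadMasses", "BeadSet", function(x) x@masses)
#' @export
setMethod("beadMasses", "UCGModel", function(x) x@beads@masses)

#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))
#' @export
setMethod("bondTable", "UCGModel", function(x) x@bonds)

#' @export
setGeneric("trajectoryFrames", function(x) standardGeneric("trajectoryFrames"))
#' @export
setMethod("trajectoryFrames", "Trajectory", function(x) x@frames)

#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @export
setMethod("frameInterval", "Trajectory", function(x) x@frameInterval)

#' Centers of retained voxels, in nm
#'
#' @param map a DensityMap
#' @return list with \code{xyz} (n x 3 matrix of retained voxel centers),
#'   \code{w} (their density values) and \code{idx} (linear voxel indices).
#' @export
voxelCenters <- function(map) {
  idx <- which(map@mask)
  ai <- arrayInd(idx, dim(map@values))
  xyz <- sweep(sweep(ai - 0.5, 2, map@voxelSize, "*"), 2, map@origin, "+")
  list(xyz = xyz, w = map@values[idx], idx = idx)
}
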