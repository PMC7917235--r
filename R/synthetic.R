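#' Parameter set for a synthetic microtubule density map
#'
#' Describes an idealized 13-protofilament microtubule as a helical lattice
#' of Gaussian monomer blobs on a hollow cylinder. The default geometry is a
#' B-lattice 3-start helix (per-protofilament axial stagger of
#' 3 x monomerRise / nProtofilaments, i.e. ~0.92 nm for 13 protofilaments);
#' the lattice seam is ignored -- all protofilaments are identical. The axial
#' monomer rise is 4 nm (8 nm dimer repeat) and each monomer carries
#' 55 kg/mol, the average tubulin molar mass. The default voxel size,
#' 0.925 nm, is half of the 18.5 A resolution typical of the cryo-EM maps
#' this generator emulates, which keeps the longitudinal grooves resolvable
#' on a desk-scale grid.
#'
#' @param nProtofilaments number of protofilaments (>= 3); default 13.
#' @param radius mid-wall radius in nm; default 12.5.
#' @param monomerRise axial rise per monomer along a protofilament, nm;
#'   default 4.
#' @param helicalRise axial stagger between adjacent protofilaments, nm;
#'   default 3 * monomerRise / nProtofilaments (3-start lattice).
#' @param monomerSigma Gaussian blob width, nm; default 2.
#' @param monomerMass molar mass per monomer, kg/mol; default 55.
#' @param length axial length, nm (>= 2 x monomerRise).
#' @param voxelSize grid spacing, nm (< monomerSigma); default 0.925.
#' @param backgroundLevel uniform solvent background as a fraction of the
#'   peak blob density; default 0.
#' @param noiseSd Gaussian noise s.d. as a fraction of the peak; default 0.
#' @return a list of class "MicrotubuleSpec".
#' @export
microtubuleSpec <- function(nProtofilaments = 13L, radius = 12.5,
                            monomerRise = 4.0,
                            helicalRise = 3 * monomerRise / nProtofilaments,
                            monomerSigma = 2.0, monomerMass = 55,
                            length = 64, voxelSize = 0.925,
                            backgroundLevel = 0, noiseSd = 0) {
  if (nProtofilaments < 3) stop("need at least 3 protofilaments")
  if (length < 2 * monomerRise) stop("length must be >= 2 x monomerRise")
  if (voxelSize >= monomerSigma)
    stop("voxelSize must be smaller than monomerSigma")
  structure(list(nProtofilaments = as.integer(nProtofilaments),
                 radius = radius, monomerRise = monomerRise,
                 helicalRise = helicalRise, monomerSigma = monomerSigma,
                 monomerMass = monomerMass, length = length,
                 voxelSize = voxelSize, backgroundLevel = backgroundLevel,
                 noiseSd = noiseSd),
            class = "MicrotubuleSpec")
}

#' Monomer lattice positions of a MicrotubuleSpec
#'
#' @param spec a \code{microtubuleSpec}.
#' @return data.frame with columns x, y, z (nm, z along the axis, wrapped
#'   into [0, length)) and pf (protofilament index, 1-based).
#' @export
microtubuleLattice <- function(spec) {
  nPerPf <- max(1L, floor(spec$length / spec$monomerRise))
  pf <- rep(seq_len(spec$nProtofilaments), each = nPerPf)
  k <- rep(seq_len(nPerPf) - 1L, times = spec$nProtofilaments)
  ang <- 2 * pi * (pf - 1L) / spec$nProtofilaments
  z <- ((pf - 1L) * spec$helicalRise + k * spec$monomerRise) %% spec$length
  data.frame(x = spec$radius * cos(ang), y = spec$radius * sin(ang),
             z = z, pf = pf)
}

#' Generate a synthetic microtubule density map
#'
#' Sums one Gaussian blob per tubulin monomer on the helical lattice of the
#' spec, producing a hollow cylinder with \code{nProtofilaments} azimuthal
#' density crests and longitudinal grooves between them. Blobs wrap
#' periodically along the axis so the map is an exact lattice repeat and can
#' be tiled seamlessly by \code{\link{replicateAxial}}. Optional uniform
#' background and seeded Gaussian noise are added relative to the peak blob
#' density. Deterministic given (spec, seed).
#'
#' @param spec a \code{microtubuleSpec}.
#' @param seed RNG seed for the noise (irrelevant when noiseSd = 0).
#' @param maxVoxels guard on the grid size; default 2e7.
#' @return a \code{DensityMap} (axis = 3).
#' @export
makeMicrotubuleDensity <- function(spec, seed = 1L, maxVoxels = 2e7) {
  halfW <- spec$radius + 3 * spec$monomerSigma + spec$voxelSize
  nxy <- ceiling(2 * halfW / spec$voxelSize)
  nz <- max(1L, round(spec$length / spec$voxelSize))
  if (as.numeric(nxy)^2 * nz > maxVoxels)
    stop("grid of ", nxy, "x", nxy, "x", nz, " voxels exceeds the size budget; ",
         "increase voxelSize to >= ",
         signif(spec$voxelSize * ((as.numeric(nxy)^2 * nz) / maxVoxels)^(1 / 3), 3),
         " nm")
  vox <- spec$voxelSize
  # voxel-center coordinates, grid centered on the tube axis in x,y
  x0 <- -nxy * vox / 2
  xs <- x0 + (seq_len(nxy) - 0.5) * vox
  zs <- (seq_len(nz) - 0.5) * vox
  vals <- array(0, dim = c(nxy, nxy, nz))
  lat <- microtubuleLattice(spec)
  s2 <- spec$monomerSigma^2
  rad <- 3 * spec$monomerSigma
  nrad <- ceiling(rad / vox)
  Lz <- nz * vox
  for (m in seq_len(nrow(lat))) {
    cx <- lat$x[m]; cy <- lat$y[m]; cz <- lat$z[m]
    ixr <- which(abs(xs - cx) <= rad)
    iyr <- which(abs(xs - cy) <= rad)
    # axial window with periodic wrap
    izc <- round(cz / vox)
    izr <- ((izc - nrad):(izc + nrad)) %% nz + 1L
    izr <- unique(.clamp(izr, 1L, nz))
    dz <- zs[izr] - cz
    dz <- dz - Lz * round(dz / Lz)   # minimum-image along the axis
    gx <- exp(-(xs[ixr] - cx)^2 / (2 * s2))
    gy <- exp(-(xs[iyr] - cy)^2 / (2 * s2))
    gz <- exp(-dz^2 / (2 * s2))
    blob <- spec$monomerMass * (gx %o% gy %o% gz)
    vals[ixr, iyr, izr] <- vals[ixr, iyr, izr] + blob
  }
  peak <- max(vals)
  if (spec$backgroundLevel > 0) vals <- vals + spec$backgroundLevel * peak
  if (spec$noiseSd > 0) {
    noise <- .withSeed(seed,
      array(rnorm(length(vals), sd = spec$noiseSd * peak), dim(vals)))
    vals <- pmax(vals + noise, 0)
  }
  DensityMap(vals, voxelSize = vox,
             origin = c(x0, x0, 0), axis = 3L)
}

#' Toy density maps with analytically known optima
#'
#' \itemize{
#'   \item \code{single_blob}: one isotropic Gaussian; its density centroid
#'     is the blob center.
#'   \item \code{two_blobs}: two Gaussians (equal mass by default); a 2-bead
#'     clustering must place beads at the two centers with equal masses.
#'   \item \code{uniform_rod}: a uniform-density rectangular rod along z; a
#'     2-bead clustering splits it at the midplane.
#' }
#'
#' @param kind one of "single_blob", "two_blobs", "uniform_rod".
#' @param gridDim grid size (scalar or length-3); default 21.
#' @param voxelSize nm; default 1.
#' @param sigma blob width in nm (blob kinds); default 2.
#' @param separation center-to-center distance in nm (two_blobs); default 10.
#' @param massRatio mass of blob 2 relative to blob 1 (two_blobs); default 1.
#' @return a \code{DensityMap}.
#' @export
makeToyDensity <- function(kind = c("single_blob", "two_blobs", "uniform_rod"),
                           gridDim = 21L, voxelSize = 1, sigma = 2,
                           separation = 10, massRatio = 1) {
  kind <- match.arg(kind)
  if (length(gridDim) == 1L) gridDim <- rep(as.integer(gridDim), 3L)
  d <- as.integer(gridDim)
  ax <- lapply(d, function(n) (seq_len(n) - 0.5) * voxelSize)
  ctr <- d * voxelSize / 2
  gauss <- function(center, amp = 1) {
    gx <- exp(-(ax[[1]] - center[1])^2 / (2 * sigma^2))
    gy <- exp(-(ax[[2]] - center[2])^2 / (2 * sigma^2))
    gz <- exp(-(ax[[3]] - center[3])^2 / (2 * sigma^2))
    amp * (gx %o% gy %o% gz)
  }
  vals <- switch(kind,
    single_blob = gauss(ctr),
    two_blobs = gauss(ctr - c(0, 0, separation / 2)) +
                gauss(ctr + c(0, 0, separation / 2), amp = massRatio),
    uniform_rod = {
      v <- array(0, d)
      ix <- which(abs(ax[[1]] - ctr[1]) <= 1.5 * voxelSize)
      iy <- which(abs(ax[[2]] - ctr[2]) <= 1.5 * voxelSize)
      v[ix, iy, ] <- 1
      v
    })
  DensityMap(vals, voxelSize = voxelSize, axis = 3L)
}

#' Sample discrete worm-like-chain conformations
#'
#' Fixed-segment-length chains whose tangent direction receives independent
#' Gaussian bending increments of variance (segmentLength / lpTrue) per
#' transverse direction at every joint, giving tangent correlations that
#' decay as exp(-s / lpTrue). Used as the ground-truth oracle for the
#' end-tangent persistence-length estimator.
#'
#' @param contourLength chain length (same unit as lpTrue).
#' @param lpTrue true persistence length (> 0).
#' @param nSegments number of segments (>= 10).
#' @param seed RNG seed.
#' @param nChains number of independent chains; default 1.
#' @return if nChains == 1, an (nSegments+1) x 3 coordinate matrix; otherwise
#'   an array [nChains, nSegments+1, 3].
#' @export
sampleWlcChain <- function(contourLength, lpTrue, nSegments, seed = 1L,
                           nChains = 1L) {
  if (lpTrue <= 0) stop("lpTrue must be positive")
  if (nSegments < 10) stop("nSegments must be >= 10")
  ds <- contourLength / nSegments
  sdb <- sqrt(ds / lpTrue)
  nc <- as.integer(nChains)
  .withSeed(seed, {
    X <- array(0, dim = c(nc, nSegments + 1L, 3L))
    t_ <- cbind(rep(0, nc), rep(0, nc), rep(1, nc))
    for (s in seq_len(nSegments)) {
      X[, s + 1L, ] <- X[, s, ] + ds * t_
      if (s == nSegments) break
      # orthonormal frame perpendicular to the current tangent
      aligned <- abs(t_[, 1]) > 0.9
      e1 <- cbind(ifelse(aligned, 0, 1), ifelse(aligned, 1, 0), 0)
      e1 <- e1 - rowSums(e1 * t_) * t_
      e1 <- e1 / sqrt(rowSums(e1^2))
      e2 <- cbind(t_[, 2] * e1[, 3] - t_[, 3] * e1[, 2],
                  t_[, 3] * e1[, 1] - t_[, 1] * e1[, 3],
                  t_[, 1] * e1[, 2] - t_[, 2] * e1[, 1])
      t_ <- t_ + rnorm(nc, sd = sdb) * e1 + rnorm(nc, sd = sdb) * e2
      t_ <- t_ / sqrt(rowSums(t_^2))
    }
    if (nc == 1L) X[1, , ] else X
  })
}

#' Generate a length-dependent persistence-length dataset
#'
#' Evaluates the anisotropic-rod relationship
#' l_p(L) = l_p_inf / (1 + 3 E I / (G k A L^2)) at the given contour lengths
#' and applies multiplicative lognormal noise. Constants default to the
#' standard microtubule values: E = 100 MPa, I = 16670 nm^4, k = 0.72,
#' A = 25 nm^2.
#'
#' @param lpInf asymptotic persistence length, mm (> 0).
#' @param G transverse shear modulus, Pa (> 0).
#' @param lengths contour lengths, micrometers.
#' @param noiseFraction lognormal sdlog of the multiplicative noise;
#'   default 0.
#' @param seed RNG seed.
#' @param E Young's modulus, MPa.
#' @param I area moment of the cross section, nm^4.
#' @param k dimensionless shear geometric factor.
#' @param A cross-section area, nm^2.
#' @return data.frame(length_um, lp_um).
#' @export
makeLpDataset <- function(lpInf, G, lengths, noiseFraction = 0, seed = 1L,
                          E = 100, I = 16670, k = 0.72, A = 25) {
  if (lpInf <= 0 || G <= 0) stop("lpInf and G must be positive")
  lp <- lpLengthModel(lengths, lpInf, G, E = E, I = I, k = k, A = A)
  if (noiseFraction > 0)
    lp <- .withSeed(seed,
      lp * exp(rnorm(length(lp), sd = noiseFraction)))
  data.frame(length_um = lengths, lp_um = lp)
}

#' Predicted persistence length at contour length L (anisotropic rod model)
#'
#' @param L contour lengths, micrometers.
#' @param lpInf asymptotic persistence length, mm.
#' @param G shear modulus, Pa.
#' @inheritParams makeLpDataset
#' @return persistence lengths in micrometers.
#' @export
lpLengthModel <- function(L, lpInf, G, E = 100, I = 16670, k = 0.72, A = 25) {
  E_SI <- E * 1e6          # Pa
  I_SI <- I * 1e-36        # m^4
  A_SI <- A * 1e-18        # m^2
  L_SI <- L * 1e-6         # m
  lpInf_SI <- lpInf * 1e-3 # m
  lp_SI <- lpInf_SI / (1 + 3 * E_SI * I_SI / (G * k * A_SI * L_SI^2))
  lp_SI * 1e6              # micrometers
}

#' Threshold length sqrt(3EI/(GkA)) of the anisotropic rod model, micrometers
#' @inheritParams lpLengthModel
#' @export
lpThresholdLength <- function(G, E = 100, I = 16670, k = 0.72, A = 25) {
  sqrt(3 * (E * 1e6) * (I * 1e-36) / (G * k * (A * 1e-18))) * 1e6
}
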