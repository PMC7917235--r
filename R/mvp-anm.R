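#' Build a heterogeneous harmonic (MVP-ANM) network on a BeadSet
#'
#' Connects every bead pair whose equilibrium separation d0 is within the
#' cutoff dc (inclusive at the boundary: the Heaviside step is taken as
#' H(0) = 1) with a harmonic spring of energy gamma (d - d0)^2 and force
#' constant
#'   gamma_ij = A (1 + m_i)(1 + m_j) exp(-d0_ij^2 / R^2),
#' where m are bead molar masses in kg/mol and R defaults to dc / 3 (gamma
#' decays to insignificance past 3R, which motivates tying R to the cutoff).
#' gamma is evaluated at the equilibrium distance, so springs are constant
#' force constants and the network is a fixed-topology harmonic model.
#' Neighbor search uses cell lists with cell edge = cutoff and is exact
#' (identical bond set to the all-pairs computation).
#'
#' @param beads a \code{BeadSet} (>= 2 beads).
#' @param cutoff cutoff distance dc in nm (> 0).
#' @param R range parameter in nm, or NULL for dc / 3.
#' @param A force-constant scale in kJ/mol/nm^2 per unit mass product;
#'   see \code{\link{calibrateForceScale}}.
#' @param inclusive include bonds at exactly d0 = dc; default TRUE.
#' @return a \code{\link{UCGModel}}.
#' @export
buildNetwork <- function(beads, cutoff, R = NULL, A = 1e-2, inclusive = TRUE) {
  P <- beads@positions
  N <- nrow(P)
  if (N < 2) stop("need at least 2 beads")
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is.null(R)) R <- cutoff / 3
  pr <- .cellListPairs(P, cutoff, inclusive)
  if (nrow(pr) && any(pr$d < 1e-6))
    stop("duplicate beads: pair closer than 1e-6 nm")
  m <- beads@masses
  gamma <- A * (1 + m[pr$i]) * (1 + m[pr$j]) * exp(-pr$d^2 / R^2)
  bonds <- data.frame(i = pr$i, j = pr$j, d0 = pr$d, gamma = gamma)
  new("UCGModel", beads = beads, bonds = bonds, cutoff = cutoff,
      R = R, A = A)
}

# Exact neighbor pairs within cutoff using cell lists (cell edge = cutoff).
.cellListPairs <- function(P, cutoff, inclusive = TRUE) {
  N <- nrow(P)
  lo <- apply(P, 2, min)
  cell <- floor(sweep(P, 2, lo, "-") / cutoff)
  dims <- apply(cell, 2, max) + 1L
  key <- cell[, 1] + dims[1] * (cell[, 2] + dims[2] * cell[, 3])
  byCell <- split(seq_len(N), key)
  keys <- as.numeric(names(byCell))
  keyIndex <- seq_along(keys)
  names(keyIndex) <- names(byCell)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ii <- integer(0); jj <- integer(0)
  for (kk in seq_along(byCell)) {
    a <- byCell[[kk]]
    k <- keys[kk]
    kz <- floor(k / (dims[1] * dims[2]))
    ky <- floor((k - kz * dims[1] * dims[2]) / dims[1])
    kx <- k - dims[1] * (ky + dims[2] * kz)
    for (o in seq_len(nrow(offs))) {
      nx <- kx + offs$dx[o]; ny <- ky + offs$dy[o]; nz <- kz + offs$dz[o]
      if (nx < 0 || ny < 0 || nz < 0 ||
          nx >= dims[1] || ny >= dims[2] || nz >= dims[3]) next
      nkey <- nx + dims[1] * (ny + dims[2] * nz)
      if (nkey < k) next                     # visit each cell pair once
      b <- byCell[[as.character(nkey)]]
      if (is.null(b)) next
      if (nkey == k) {
        if (length(a) > 1) {
          cmb <- utils::combn(a, 2)
          ii <- c(ii, cmb[1, ]); jj <- c(jj, cmb[2, ])
        }
      } else {
        g <- expand.grid(a = a, b = b)
        ii <- c(ii, pmin(g$a, g$b)); jj <- c(jj, pmax(g$a, g$b))
      }
    }
  }
  if (!length(ii)) return(data.frame(i = integer(), j = integer(), d = numeric()))
  d <- sqrt(rowSums((P[ii, , drop = FALSE] - P[jj, , drop = FALSE])^2))
  keep <- if (inclusive) d <= cutoff + 1e-12 else d < cutoff
  data.frame(i = ii[keep], j = jj[keep], d = d[keep])
}

#' MVP-ANM potential energy of a configuration
#'
#' E = sum over bonds of gamma (d - d0)^2 (note: no factor 1/2); zero at the
#' reference structure and invariant under rigid rotations/translations.
#'
#' @param model a \code{UCGModel}.
#' @param coordinates N x 3 matrix in nm.
#' @return energy in kJ/mol.
#' @export
setGeneric("networkEnergy", function(model, coordinates)
  standardGeneric("networkEnergy"))

#' @export
setMethod("networkEnergy", "UCGModel", function(model, coordinates) {
  X <- as.matrix(coordinates)
  if (any(!is.finite(X))) stop("coordinates must be finite")
  b <- model@bonds
  if (!nrow(b)) return(0)
  dv <- X[b$i, , drop = FALSE] - X[b$j, , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  sum(b$gamma * (d - b$d0)^2)
})

#' Per-bead forces (negative gradient) of the MVP-ANM energy, kJ/mol/nm
#' @param model a \code{UCGModel}.
#' @param coordinates N x 3 matrix in nm.
#' @return N x 3 force matrix.
#' @export
networkForces <- function(model, coordinates) {
  X <- as.matrix(coordinates)
  b <- model@bonds
  N <- nrow(X)
  if (!nrow(b)) return(matrix(0, N, 3))
  dv <- X[b$i, , drop = FALSE] - X[b$j, , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  fac <- -2 * b$gamma * (d - b$d0) / d      # force on i along +dv
  Fb <- dv * fac
  acc <- rowsum(rbind(Fb, -Fb), group = c(b$i, b$j))
  F <- matrix(0, N, 3)
  F[as.integer(rownames(acc)), ] <- acc
  F
}

#' Classify bonds into distance classes
#'
#' Histograms the equilibrium bond lengths over distance classes (defaults
#' [0, 2R] and (2R, 3R]) and reports count and mean force constant per
#' class. With R = 2.2 nm the default classes are the short "bonded"
#' interactions below 4.4 nm and the weaker 4.4-6.6 nm shell. If the beads
#' carry protofilament labels, the inter-protofilament bond count per class
#' is included.
#'
#' @param model a \code{UCGModel}.
#' @param classEdges increasing breakpoints in nm; default
#'   c(0, 2R, 3R).
#' @return data.frame(class, lower, upper, count, meanGamma and, when labels
#'   exist, interPf).
#' @export
classifyBonds <- function(model, classEdges = NULL) {
  if (is.null(classEdges)) classEdges <- c(0, 2 * model@R, 3 * model@R)
  if (is.unsorted(classEdges, strictly = TRUE))
    stop("classEdges must be strictly increasing")
  b <- model@bonds
  cls <- cut(b$d0, breaks = classEdges, include.lowest = TRUE, right = TRUE)
  lev <- levels(cls)
  count <- as.integer(table(cls))
  meanGamma <- as.numeric(tapply(b$gamma, cls, mean))
  out <- data.frame(class = lev,
                    lower = head(classEdges, -1), upper = tail(classEdges, -1),
                    count = count, meanGamma = meanGamma)
  lab <- model@beads@labels
  if (length(lab)) {
    inter <- lab[b$i] != lab[b$j]
    out$interPf <- as.integer(tapply(inter, cls, sum))
    out$interPf[is.na(out$interPf)] <- 0L
  }
  out
}

#' Export a UCGModel as a LAMMPS data file
#'
#' Writes a LAMMPS data file (atom_style molecular) with one atom type per
#' bead and one bond type per bond. The energy convention matches directly:
#' the model's bond energy gamma (d - d0)^2 has no factor 1/2, and LAMMPS
#' \code{bond_style harmonic} is K (r - r0)^2, so K = gamma as-is. Units in
#' the file: distances nm, masses g/mol (1000 x kg/mol), K in kJ/mol/nm^2;
#' the header comment records the conversions.
#'
#' @param model a \code{UCGModel}.
#' @param path output path.
#' @export
exportLammpsData <- function(model, path) {
  P <- model@beads@positions
  m <- model@beads@masses
  b <- model@bonds
  N <- nrow(P); nb <- nrow(b)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("LAMMPS data file: MVP-ANM network.",
    " Units: x,y,z in nm; mass in g/mol (= 1000 x kg/mol);",
    " bond K in kJ/mol/nm^2 with E = K (r - r0)^2 (no 1/2).")
  w("")
  w(N, " atoms")
  w(nb, " bonds")
  w(N, " atom types")
  w(nb, " bond types")
  w("")
  pad <- 2 * model@cutoff
  w(sprintf("%.6f %.6f xlo xhi", min(P[, 1]) - pad, max(P[, 1]) + pad))
  w(sprintf("%.6f %.6f ylo yhi", min(P[, 2]) - pad, max(P[, 2]) + pad))
  w(sprintf("%.6f %.6f zlo zhi", min(P[, 3]) - pad, max(P[, 3]) + pad))
  w("")
  w("Masses")
  w("")
  for (i in seq_len(N)) w(sprintf("%d %.8f", i, 1000 * m[i]))
  w("")
  w("Bond Coeffs")
  w("")
  for (k in seq_len(nb)) w(sprintf("%d %.10g %.10g", k, b$gamma[k], b$d0[k]))
  w("")
  w("Atoms")
  w("")
  for (i in seq_len(N))
    w(sprintf("%d 1 %d %.8f %.8f %.8f", i, i, P[i, 1], P[i, 2], P[i, 3]))
  w("")
  w("Bonds")
  w("")
  for (k in seq_len(nb)) w(sprintf("%d %d %d %d", k, k, b$i[k], b$j[k]))
  invisible(NULL)
}

#' Sparse Hessian of the MVP-ANM energy at the reference structure
#'
#' Standard ANM second derivative: each bond contributes the 3x3 block
#' 2 gamma n n^T (n the unit bond vector at the reference) added to the
#' (i,i) and (j,j) diagonal blocks and subtracted from (i,j)/(j,i). The
#' result is symmetric positive semi-definite with exactly six zero modes
#' for a connected 3D network.
#'
#' @param model a \code{UCGModel}.
#' @return a sparse symmetric 3N x 3N \code{Matrix}.
#' @export
hessianMatrix <- function(model) {
  P <- model@beads@positions
  b <- model@bonds
  N <- nrow(P)
  if (!nrow(b)) return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                            x = numeric(), dims = c(3 * N, 3 * N)))
  dv <- P[b$i, , drop = FALSE] - P[b$j, , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  n <- dv / d
  nb <- nrow(b)
  # 9 entries of 2 gamma n n^T per bond
  comp <- expand.grid(a = 1:3, c = 1:3)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (q in seq_len(nrow(comp))) {
    a <- comp$a[q]; cc <- comp$c[q]
    v <- 2 * b$gamma * n[, a] * n[, cc]
    ia <- 3 * (b$i - 1L) + a; ic <- 3 * (b$i - 1L) + cc
    ja <- 3 * (b$j - 1L) + a; jc <- 3 * (b$j - 1L) + cc
    rows <- c(rows, ia, ja, ia, ja)
    cols <- c(cols, ic, jc, jc, ic)
    vals <- c(vals, v, v, -v, -v)
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(3 * N, 3 * N))
}
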