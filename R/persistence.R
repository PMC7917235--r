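#' Terminal tangent of an axially ordered bead chain
#'
#' Total-least-squares 3D line fit (first principal component) through the
#' terminal segment of the chain, oriented along increasing bead order
#' (minus end to plus end) so that head and tail tangents of a straight
#' filament coincide.
#'
#' @param frame N x 3 coordinate matrix with beads in axial order.
#' @param end "head" (first beads) or "tail" (last beads).
#' @param segmentFraction fraction of the chain entering the fit; default
#'   0.1 (at least 3 beads).
#' @param minBeads lower bound on the number of fitted beads; default 3.
#' @return unit tangent (length-3), or NULL with a warning when the segment
#'   is degenerate (all beads coincident).
#' @export
terminalTangent <- function(frame, end = c("head", "tail"),
                            segmentFraction = 0.1, minBeads = 3L) {
  end <- match.arg(end)
  N <- nrow(frame)
  k <- max(minBeads, ceiling(segmentFraction * N))
  k <- min(k, N)
  idx <- if (end == "head") seq_len(k) else (N - k + 1L):N
  seg <- frame[idx, , drop = FALSE]
  ctr <- colMeans(seg)
  Xc <- sweep(seg, 2, ctr)
  if (all(abs(Xc) < 1e-12)) {
    warning("degenerate terminal segment: undefined tangent")
    return(NULL)
  }
  v <- svd(Xc, nu = 0, nv = 1)$v[, 1]
  # orient along increasing bead order
  ord <- seq_along(idx) - mean(seq_along(idx))
  if (sum(ord * (Xc %*% v)) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Head-tail intersection angle of one frame
#'
#' theta = arccos(t_head . t_tail) with both tangents oriented along the
#' bead order; angles beyond pi/2 are clamped to pi/2 (the estimator's
#' stated domain) and the clamping is flagged in the attribute "clamped".
#'
#' @inheritParams terminalTangent
#' @return angle in radians in [0, pi/2] (attribute "clamped" TRUE/FALSE),
#'   or NA when a tangent is undefined.
#' @export
frameAngle <- function(frame, segmentFraction = 0.1, minBeads = 3L) {
  th <- suppressWarnings(terminalTangent(frame, "head", segmentFraction, minBeads))
  tt <- suppressWarnings(terminalTangent(frame, "tail", segmentFraction, minBeads))
  if (is.null(th) || is.null(tt)) return(NA_real_)
  ang <- acos(.clamp(sum(th * tt), -1, 1))
  clamped <- ang > pi / 2
  structure(min(ang, pi / 2), clamped = clamped)
}

#' Angle series for a trajectory of an axially ordered filament
#'
#' The total-least-squares tangent of a terminal segment is the average
#' tangent over that segment, i.e. it effectively probes the filament at
#' the segment centroid. The head and tail tangents are therefore separated
#' by (1 - segmentFraction) x contourLength along the chain, and that
#' effective length is the one stored for the exponential-decay inversion
#' (set \code{effectiveLength = FALSE} to store the raw contour length).
#'
#' @param traj a \code{Trajectory} whose beads are in axial order (use
#'   \code{\link{axialOrder}} first if needed), or an array
#'   [nFrames, N, 3].
#' @param contourLength contour length L in micrometers.
#' @param segmentFraction terminal fraction for the tangent fits.
#' @param effectiveLength correct L for the tangent-averaging geometry;
#'   default TRUE.
#' @return list of class "AngleSeries" with \code{theta} (radians, NA
#'   frames dropped), \code{L} (um, effective), \code{frameInterval} (ps),
#'   \code{nClamped} and \code{nDropped}.
#' @export
angleSeries <- function(traj, contourLength, segmentFraction = 0.1,
                        effectiveLength = TRUE) {
  fr <- if (is(traj, "Trajectory")) traj@frames else traj
  nf <- dim(fr)[1]
  th <- numeric(nf); cl <- logical(nf)
  for (k in seq_len(nf)) {
    a <- frameAngle(fr[k, , ], segmentFraction)
    th[k] <- as.numeric(a)
    cl[k] <- isTRUE(attr(a, "clamped"))
  }
  drop <- is.na(th)
  L <- if (effectiveLength) contourLength * (1 - segmentFraction)
       else contourLength
  structure(list(theta = th[!drop], L = L,
                 frameInterval = if (is(traj, "Trajectory"))
                   traj@frameInterval else NA_real_,
                 nClamped = sum(cl), nDropped = sum(drop)),
            class = "AngleSeries")
}

#' Build an AngleSeries from raw angles
#' @param theta radians in [0, pi/2].
#' @param contourLength micrometers.
#' @param frameInterval ps; default NA.
#' @export
asAngleSeries <- function(theta, contourLength, frameInterval = NA_real_) {
  if (any(theta < 0 | theta > pi / 2 + 1e-12))
    stop("angles must lie in [0, pi/2]")
  structure(list(theta = theta, L = contourLength,
                 frameInterval = frameInterval, nClamped = 0L, nDropped = 0L),
            class = "AngleSeries")
}

#' Persistence length from the mean end-tangent cosine
#'
#' Inverts <cos theta> = exp(-L / l_p): l_p = -L / log(mean(cos(theta))).
#' A mean cosine indistinguishable from 1 returns Inf with the flag
#' \code{rigid = TRUE}; a mean cosine <= 0 is outside the estimator's
#' domain and errors. The confidence interval comes from a block bootstrap
#' over frames (blocks of consecutive frames, since successive frames are
#' correlated).
#'
#' @param angles an "AngleSeries".
#' @param minFrames minimum usable frames; default 100.
#' @param nBoot bootstrap replicates; default 200.
#' @param blockLength frames per block; default length/50 (>= 1).
#' @param seed bootstrap seed; default 1.
#' @return list(lp, ci, rigid, meanCos, nFrames, clampedFraction).
#' @export
persistenceLength <- function(angles, minFrames = 100L, nBoot = 200L,
                              blockLength = NULL, seed = 1L) {
  th <- angles$theta
  n <- length(th)
  if (n < minFrames)
    stop("need at least ", minFrames, " usable frames (got ", n, ")")
  mc <- mean(cos(th))
  if (mc <= 1e-9)
    stop("mean cosine <= 0: filament far too flexible for the end-tangent estimator")
  if (mc >= 1 - 1e-12)
    return(list(lp = Inf, ci = c(Inf, Inf), rigid = TRUE, meanCos = mc,
                nFrames = n, clampedFraction = angles$nClamped / n))
  lpOf <- function(m) -angles$L / log(m)
  if (is.null(blockLength)) blockLength <- max(1L, n %/% 50L)
  nBlocks <- ceiling(n / blockLength)
  starts <- (seq_len(nBlocks) - 1L) * blockLength + 1L
  boot <- .withSeed(seed, vapply(seq_len(nBoot), function(r) {
    pick <- sample(starts, nBlocks, replace = TRUE)
    idx <- unlist(lapply(pick, function(s) s:min(n, s + blockLength - 1L)))
    m <- mean(cos(th[idx]))
    if (m <= 0 || m >= 1) NA_real_ else lpOf(m)
  }, numeric(1)))
  list(lp = lpOf(mc),
       ci = unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE)),
       rigid = FALSE, meanCos = mc, nFrames = n,
       clampedFraction = angles$nClamped / n)
}

#' Flexural rigidity from persistence length
#'
#' kappa = l_p k_B T in SI units.
#'
#' @param lp persistence length in micrometers (finite, positive).
#' @param temperature K; default 300.
#' @return kappa in N m^2.
#' @export
flexuralRigidity <- function(lp, temperature = 300) {
  if (!is.finite(lp) || lp <= 0) stop("lp must be finite and positive")
  (lp * 1e-6) * .kB_SI * temperature
}

#' Fit the length-dependent persistence-length model
#'
#' Nonlinear least squares of l_p(L) = l_p_inf / (1 + 3 E I / (G k A L^2))
#' over (l_p_inf, G), with a fixed multi-start grid over G (deterministic).
#' The threshold length sqrt(3 E I / (G k A)) separating the short, shear-
#' dominated regime from the asymptote is computed from the fit.
#'
#' @param lengths contour lengths, micrometers (>= 3 values spanning a
#'   factor >= 2).
#' @param lps persistence lengths, micrometers.
#' @param E Young's modulus, MPa; default 100.
#' @param I area moment, nm^4; default 16670.
#' @param k shear geometric factor; default 0.72.
#' @param A cross-section area for this model, nm^2; default 25 (a distinct
#'   constant from the force-clamp cross-section).
#' @param weights optional fit weights.
#' @return list of class "LpFitResult": lp_inf_mm, G_Pa, threshold_um,
#'   constants, residuals, fitted.
#' @export
fitLpModel <- function(lengths, lps, E = 100, I = 16670, k = 0.72, A = 25,
                       weights = NULL) {
  if (length(lengths) < 3) stop("need at least 3 (L, lp) points")
  if (max(lengths) / min(lengths) < 2)
    stop("lengths must span at least a factor of 2")
  if (diff(range(lengths)) == 0) stop("all lengths equal: not identifiable")
  df <- data.frame(L = lengths, lp = lps)
  if (is.null(weights)) weights <- rep(1, nrow(df))
  best <- NULL
  for (G0 in 10^seq(0, 6, by = 1)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        lp ~ lpLengthModel(L, lpInf, G, E = E, I = I, k = k, A = A),
        data = df, weights = weights,
        start = list(lpInf = max(lps) * 1e-3 * 2, G = G0),
        lower = c(1e-12, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("persistence-length model fit failed to converge")
  co <- coef(best$fit)
  structure(list(lp_inf_mm = unname(co["lpInf"]), G_Pa = unname(co["G"]),
                 threshold_um = lpThresholdLength(unname(co["G"]), E, I, k, A),
                 constants = list(E_MPa = E, I_nm4 = I, k = k, A_nm2 = A),
                 residuals = resid(best$fit),
                 fitted = fitted(best$fit)),
            class = "LpFitResult")
}

#' @export
print.LpFitResult <- function(x, ...) {
  cat("Length-dependent persistence-length fit\n")
  cat(sprintf("  lp_inf: %.4g mm   G: %.4g Pa   threshold length: %.4g um\n",
              x$lp_inf_mm, x$G_Pa, x$threshold_um))
  invisible(x)
}

#' Order beads of a tube model along its axis
#'
#' @param beads a \code{BeadSet} or coordinate matrix.
#' @param axis axis index; default 3.
#' @return integer permutation ordering beads by axial coordinate.
#' @export
axialOrder <- function(beads, axis = 3L) {
  P <- if (is.matrix(beads)) beads else beadPositions(beads)
  order(P[, axis])
}
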