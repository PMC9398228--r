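#' @include constructors.R utils.R
NULL

#' Machined marker positions of the 3D fiducial-grid phantom
#'
#' Seven flat plates 55 mm apart, each carrying markers on a 25 mm
#' half-offset square lattice cut at `plateRadiusMm`; the defaults give
#' exactly 276 markers per plate and 1932 in total, with the central plate
#' at isocenter.
#'
#' @param spec a [PhantomSpec-class] of kind `"fiducial3d"`.
#' @return n x 3 matrix of marker coordinates (mm, isocenter origin)
#' @examples
#' nrow(fiducialGridPositions(phantomSpec("fiducial3d")))  # 1932
#' @export
fiducialGridPositions <- function(spec = phantomSpec("fiducial3d")) {
  g <- spec@geometry
  s <- g$gridSpacingMm
  half <- ceiling(g$plateRadiusMm / s) + 1L
  lat <- expand.grid(i = -half:half, j = -half:half)
  x <- (lat$i + 0.5) * s
  y <- (lat$j + 0.5) * s
  keep <- x^2 + y^2 <= g$plateRadiusMm^2
  x <- x[keep]; y <- y[keep]
  zPlates <- (seq_len(g$nPlates) - (g$nPlates + 1) / 2) * g$plateSpacingMm
  out <- cbind(x = rep(x, g$nPlates), y = rep(y, g$nPlates),
               z = rep(zPlates, each = length(x)))
  out[order(out[, 3], out[, 2], out[, 1]), , drop = FALSE]
}

#' Generate a fiducial-grid phantom volume with known marker positions
#'
#' Markers are rendered as compact Gaussian blobs (anti-aliased, so the
#' intensity centroid is defined to sub-voxel precision) at the machined
#' position plus the geometric-distortion field evaluated there. The
#' returned `markers` are the *undistorted* machine coordinates.
#'
#' @param spec a [PhantomSpec-class] of kind `"fiducial3d"`.
#' @param truth a [GroundTruth-class]; `distortionFieldMm`, `noiseSd` and
#'   `seed` are honored.
#' @param voxelSizeMm rendering voxel size (mm).
#' @param marginMm padding beyond the marker envelope (mm).
#' @param dropIds optional integer ids of markers to omit from the image
#'   (but not from the returned known set), for dropout studies.
#' @return list with `volume` (an [ImageVolume-class]) and `markers`
#'   (a [MarkerSet-class] whose measured slot holds the true distorted
#'   positions, for reference).
#' @export
generateFiducialVolume <- function(spec = phantomSpec("fiducial3d"),
                                   truth = groundTruth(),
                                   voxelSizeMm = c(2.5, 2.5, 2.5),
                                   marginMm = 15, dropIds = integer()) {
  if (spec@kind != "fiducial3d") stop("spec.kind must be 'fiducial3d'")
  known <- fiducialGridPositions(spec)
  disp <- truth@distortionFieldMm(known)
  maxDisp <- sqrt(max(rowSums(disp^2)))
  minSpacing <- min(spec@geometry$gridSpacingMm, spec@geometry$plateSpacingMm)
  if (maxDisp > minSpacing / 2)
    stop(sprintf(paste("ambiguous matching: distortion magnitude %.2f mm",
                       "exceeds half the marker spacing (%.1f mm);",
                       "refusing to simulate"), maxDisp, minSpacing / 2))
  true <- known + disp

  g <- spec@geometry
  ext <- c(g$plateRadiusMm + marginMm, g$plateRadiusMm + marginMm,
           (g$nPlates - 1) / 2 * g$plateSpacingMm + marginMm)
  d <- as.integer(ceiling(2 * ext / voxelSizeMm))
  org <- -(d - 1) / 2 * voxelSizeMm
  co <- gridCoords(d, voxelSizeMm, org)

  sigma <- g$markerDiameterMm / 4
  supp <- ceiling(4 * sigma / voxelSizeMm)
  vox <- array(spec@backgroundSignal, dim = d)
  render <- seq_len(nrow(true))
  if (length(dropIds)) render <- setdiff(render, dropIds)
  for (m in render) {
    p <- true[m, ]
    i0 <- pmax(1L, pmin(d, round((p - org) / voxelSizeMm) + 1L))
    ii <- max(1L, i0[1] - supp[1]):min(d[1], i0[1] + supp[1])
    jj <- max(1L, i0[2] - supp[2]):min(d[2], i0[2] + supp[2])
    kk <- max(1L, i0[3] - supp[3]):min(d[3], i0[3] + supp[3])
    gx <- exp(-(co$x[ii] - p[1])^2 / (2 * sigma^2))
    gy <- exp(-(co$y[jj] - p[2])^2 / (2 * sigma^2))
    gz <- exp(-(co$z[kk] - p[3])^2 / (2 * sigma^2))
    blob <- spec@objectSignal * outer(outer(gx, gy), gz)
    vox[ii, jj, kk] <- vox[ii, jj, kk] + blob
  }
  set.seed(truth@seed)
  vox <- addRicianNoise(vox, truth@noiseSd)
  vol <- imageVolume(vox, spacingMm = voxelSizeMm, originMm = org,
                     meta = acquisitionSpec(voxelSizeMm = voxelSizeMm,
                                            matrixSize = d,
                                            trMs = 10, teMs = 2),
                     annotations = list(phantom = "fiducial3d"))
  list(volume = vol,
       markers = markerSet(knownMm = known, measuredMm = true))
}
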