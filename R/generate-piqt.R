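#' @include constructors.R utils.R
NULL

# anti-aliased disk coverage: 1 inside, 0 outside, linear ramp one voxel wide
# across the rim, as a function of distance from the rim. Radially symmetric,
# so the intensity-weighted centroid of a rendered disk is its center.
diskCoverage <- function(dist2, radius, rampMm) {
  d <- sqrt(dist2)
  pmin(1, pmax(0, (radius - d) / rampMm + 0.5))
}

# positions of the 45 hole centers of the image-quality grid section:
# a 7 x 7 lattice at `spacing` mm minus the four corners, centered on (0,0)
piqtGridHoleCenters <- function(spacingMm = 25) {
  g <- expand.grid(i = -3:3, j = -3:3)
  g <- g[!(abs(g$i) == 3 & abs(g$j) == 3), ]
  cbind(x = g$i * spacingMm, y = g$j * spacingMm)
}

# slice-sensitivity profile p(z) in [0, 1]; rectangular profiles take a
# rampWidth (through-plane extent of one in-plane voxel under the wedge
# slope) so the sampled edge is anti-aliased rather than quantized
sliceProfileFn <- function(geom, rampWidth = 0) {
  shape <- geom$profileShape
  if (is.null(shape)) shape <- "rect"
  th <- geom$sliceThicknessMm
  if (shape == "rect") {
    if (rampWidth <= 0) function(z) as.numeric(abs(z) <= th / 2)
    else function(z) pmin(1, pmax(0, (th / 2 - abs(z)) / rampWidth + 0.5))
  } else if (shape == "gaussian") {
    sigma <- geom$profileSigmaMm
    function(z) exp(-z^2 / (2 * sigma^2))
  } else stop("unknown profileShape: ", shape)
}

# in-plane wedge-pair regions: wedge A above the x axis (slope +s), wedge B
# below (slope -s); each wedgeWidthMm wide in y, wedgeLengthMm long in x
wedgeRegions <- function(geom) {
  w <- geom$wedgeWidthMm; gap <- geom$wedgeGapMm
  list(
    A = list(yLo = gap / 2, yHi = gap / 2 + w, slope = geom$wedgeSlope),
    B = list(yLo = -gap / 2 - w, yHi = -gap / 2, slope = -geom$wedgeSlope)
  )
}

#' Generate synthetic image-quality phantom images
#'
#' Renders one magnitude image of the requested image-quality phantom
#' section with the stated object/background signal levels, sub-voxel
#' (area-weighted) edges, the geometric-distortion field of `truth`
#' applied to the hole-grid section, and Rician magnitude noise.
#'
#' Sections: `"piqt_grid"` renders the 45-hole lattice used for spatial
#' linearity; `"piqt_wedge"` renders an opposing wedge pair whose in-plane
#' profile encodes the slice profile (projected FWHM =
#' slice thickness / wedge slope); `"piqt_edge"` renders a uniform block
#' whose edges yield the line-spread function. Edge positions snap to
#' voxel boundaries by default (`geometry$snapToGrid = FALSE` disables),
#' matching the aligned physical phantom and keeping the discrete
#' line-spread function free of sampling-phase ambiguity.
#'
#' @param spec a [PhantomSpec-class] of kind `piqt_grid`, `piqt_wedge`
#'   or `piqt_edge`.
#' @param acq an [AcquisitionSpec-class]; `matrixSize` and `voxelSizeMm`
#'   set the grid.
#' @param truth a [GroundTruth-class]; `noiseSd`, `seed` and (for the
#'   grid) `distortionFieldMm` are honored.
#' @return an [ImageVolume-class]
#' @examples
#' img <- generatePiqtImages(phantomSpec("piqt_grid"), acquisitionSpec(
#'   voxelSizeMm = c(1.2, 1.2, 5), matrixSize = c(192, 192, 1)),
#'   groundTruth())
#' @export
generatePiqtImages <- function(spec, acq, truth = groundTruth()) {
  if (!(spec@kind %in% c("piqt_grid", "piqt_wedge", "piqt_edge")))
    stop("spec.kind must be piqt_grid, piqt_wedge or piqt_edge")
  if (any(acq@matrixSize < 1) || any(acq@voxelSizeMm <= 0))
    stop("invalid spec: non-positive matrix or voxel size")
  d <- as.integer(acq@matrixSize)
  sp <- acq@voxelSizeMm
  org <- -(d - 1) / 2 * sp
  co <- gridCoords(d, sp, org)
  geom <- spec@geometry
  bg <- spec@backgroundSignal
  obj <- spec@objectSignal
  img <- matrix(bg, d[1], d[2])

  if (spec@kind == "piqt_grid") {
    ctr <- piqtGridHoleCenters(geom$gridSpacingMm)
    disp <- truth@distortionFieldMm(cbind(ctr, 0))
    ctr <- ctr + disp[, 1:2, drop = FALSE]
    ramp <- min(sp[1:2])
    for (h in seq_len(nrow(ctr))) {
      d2 <- outer((co$x - ctr[h, 1])^2, (co$y - ctr[h, 2])^2, "+")
      cov <- diskCoverage(d2, geom$holeDiameterMm / 2, ramp)
      img <- img + (obj - bg) * cov
    }
  } else if (spec@kind == "piqt_wedge") {
    # ramp two in-plane samples wide: the half-maximum crossing then falls
    # between two samples on the same linear segment, so interpolated
    # FWHM is exact for the rectangular profile
    p <- sliceProfileFn(geom, rampWidth = 2 * geom$wedgeSlope * sp[1])
    regs <- wedgeRegions(geom)
    halfLen <- geom$wedgeLengthMm / 2
    for (rg in regs) {
      iny <- co$y >= rg$yLo & co$y <= rg$yHi
      inx <- abs(co$x) <= halfLen
      z <- rg$slope * co$x        # through-plane position sampled by wedge
      prof <- ifelse(inx, p(z), 0)
      img[, iny] <- img[, iny] + (obj - bg) * prof
    }
  } else { # piqt_edge
    half <- geom$edgeSizeMm / 2
    snap <- !isTRUE(geom$snapToGrid == FALSE)
    edgePos <- function(target, cc, dx) {
      if (!snap) return(target)
      bnd <- cc - dx / 2                       # voxel boundaries
      bnd[which.min(abs(bnd - target))]
    }
    x1 <- edgePos(-half, co$x, sp[1]); x2 <- edgePos(half, co$x, sp[1])
    y1 <- edgePos(-half, co$y, sp[2]); y2 <- edgePos(half, co$y, sp[2])
    covAxis <- function(cc, lo, hi, dx)
      pmin(1, pmax(0, (pmin(hi - cc, cc - lo) / dx + 0.5)))
    cov <- outer(covAxis(co$x, x1, x2, sp[1]),
                 covAxis(co$y, y1, y2, sp[2]), pmin)
    if (!is.null(geom$edgeBlurMm) && geom$edgeBlurMm > 0)
      cov <- gaussSmooth2d(cov, geom$edgeBlurMm / sp[1])
    img <- img + (obj - bg) * cov
  }

  set.seed(truth@seed)
  vox <- addRicianNoise(array(img, dim = d), truth@noiseSd)
  imageVolume(vox, spacingMm = sp, originMm = org, meta = acq,
              annotations = list(phantom = spec@kind))
}

#' Generate a uniform-cylinder magnitude image
#'
#' A homogeneous disk of the stated diameter (default 40 cm) at
#' `objectSignal`, optionally modulated by a smooth in-plane shading
#' function, with Rician noise. Used for SNR and uniformity measurements
#' and as the magnitude counterpart of the field-mapping series.
#'
#' @param spec a [PhantomSpec-class] of kind `"cylinder"`.
#' @param acq an [AcquisitionSpec-class].
#' @param truth a [GroundTruth-class] (noise + seed).
#' @param shading optional function `(x, y)` returning a multiplicative
#'   intensity modulation (1 = none), evaluated inside the phantom only.
#' @return an [ImageVolume-class]
#' @export
generateCylinderImage <- function(spec, acq, truth = groundTruth(),
                                  shading = NULL) {
  if (spec@kind != "cylinder") stop("spec.kind must be 'cylinder'")
  d <- as.integer(acq@matrixSize)
  sp <- acq@voxelSizeMm
  org <- -(d - 1) / 2 * sp
  co <- gridCoords(d, sp, org)
  R <- spec@geometry$cylinderDiameterMm / 2
  d2 <- outer(co$x^2, co$y^2, "+")
  cov <- diskCoverage(d2, R, min(sp[1:2]))
  img <- spec@backgroundSignal + (spec@objectSignal - spec@backgroundSignal) * cov
  if (!is.null(shading)) {
    mod <- outer(co$x, co$y, function(x, y) shading(x, y))
    img <- img * ifelse(cov > 0, mod, 1)
  }
  set.seed(truth@seed)
  vox <- addRicianNoise(array(img, dim = d), truth@noiseSd)
  imageVolume(vox, spacingMm = sp, originMm = org, meta = acq,
              annotations = list(phantom = "cylinder"))
}
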