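#' @include constructors.R utils.R generate-piqt.R
NULL

#' Slice profile measurement
#'
#' @slot fwhmMm full width at half maximum (through-plane mm).
#' @slot integralMm equivalent width, sum(profile)/max(profile) x spacing
#'   (through-plane mm).
#' @slot profile data.frame with `positionMm` (through-plane) and `value`.
#' @export
setClass("SliceProfileResult",
  representation(fwhmMm = "numeric", integralMm = "numeric",
                 profile = "data.frame")
)

setValidity("SliceProfileResult", function(object) {
  if (object@fwhmMm <= 0 || object@integralMm <= 0)
    "fwhmMm and integralMm must be positive" else TRUE
})

setMethod("show", "SliceProfileResult", function(object) {
  cat(sprintf("SliceProfileResult: FWHM %.3f mm, integral %.3f mm\n",
              object@fwhmMm, object@integralMm))
})

#' Signal-to-noise ratio of a phantom image
#'
#' SNR = mean signal in the phantom ROI divided by the noise estimate from
#' a background ROI. The background of a magnitude image is Rayleigh
#' distributed, so with `rayleighCorrect = TRUE` (default, single-image
#' NEMA practice) the background SD is divided by 0.655 to estimate the
#' underlying Gaussian noise SD; with `FALSE` the raw background SD is
#' used. The choice is recorded in the result's attributes.
#'
#' @param img an [ImageVolume-class] (magnitude).
#' @param signalRoi [RoiSpec-class] inside the phantom.
#' @param noiseRoi [RoiSpec-class] in signal-free background; must not
#'   overlap `signalRoi`.
#' @param rayleighCorrect apply the 0.655 Rayleigh correction (default).
#' @return SNR (scalar, > 0) with attributes `noiseSd` and
#'   `rayleighCorrect`.
#' @export
computeSNR <- function(img, signalRoi, noiseRoi, rayleighCorrect = TRUE) {
  mS <- roiMask(img, signalRoi)
  mN <- roiMask(img, noiseRoi)
  if (any(mS & mN)) stop("signal and noise ROIs must be disjoint")
  sdBg <- stats::sd(img@voxels[mN])
  if (!is.finite(sdBg) || sdBg == 0)
    stop("undefined SNR: background SD is zero")
  noise <- if (rayleighCorrect) sdBg / 0.655 else sdBg
  out <- mean(img@voxels[mS]) / noise
  attr(out, "noiseSd") <- noise
  attr(out, "rayleighCorrect") <- rayleighCorrect
  out
}

#' Image uniformity, (max - min)/(max + min) x 100%
#'
#' Evaluated over the ROI slice after an optional in-plane Gaussian
#' low-pass (default FWHM of one voxel) that suppresses single-voxel
#' noise from dominating the extrema.
#'
#' @param img an [ImageVolume-class].
#' @param roi [RoiSpec-class] inside the phantom body.
#' @param smoothingMm Gaussian FWHM of the pre-filter in mm; `NULL`
#'   (default) uses one voxel, `0` disables smoothing.
#' @return uniformity in percent, in [0, 100]
#' @export
computeUniformity <- function(img, roi, smoothingMm = NULL) {
  if (is.null(smoothingMm)) smoothingMm <- min(img@spacingMm[1:2])
  mask <- roiMask(img, roi)
  kSlice <- which(apply(mask, 3, any))
  if (length(kSlice) != 1L)
    stop("uniformity ROI must lie on a single slice")
  slice <- img@voxels[, , kSlice]
  if (smoothingMm > 0)
    slice <- gaussSmooth2d(slice, smoothingMm / img@spacingMm[1])
  vals <- slice[mask[, , kSlice]]
  hi <- max(vals); lo <- min(vals)
  if (hi + lo == 0) stop("undefined uniformity: max + min = 0")
  (hi - lo) / (hi + lo) * 100
}

# detect bright blob centroids on a 2D slice: Otsu threshold, connected
# components (8-connectivity), intensity-weighted centroids in mm
detectBlobs2d <- function(slice, xCoords, yCoords, minVoxels = 3L) {
  thr <- otsuThreshold(as.numeric(slice))
  mask <- slice > thr
  idx <- which(mask)
  if (!length(idx)) stop("detection failure: no features above threshold")
  nx <- nrow(slice)
  ii <- (idx - 1L) %% nx + 1L
  jj <- (idx - 1L) %/% nx + 1L
  key <- idx
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    ni <- ii + off[1]; nj <- jj + off[2]
    ok <- ni >= 1 & ni <= nx & nj >= 1 & nj <= ncol(slice)
    nkey <- (nj - 1L) * nx + ni
    hit <- ok & !is.na(match(nkey, key))
    if (any(hit))
      edges <- c(edges, rbind(match(key[hit], key), match(nkey[hit], key)))
  }
  gr <- igraph::make_graph(edges, n = length(key), directed = FALSE)
  comp <- igraph::components(gr)$membership
  # centroid over the padded bounding box of each component (background is
  # ~0 there), not only the above-threshold core: thresholding truncates
  # the blob asymmetrically and would bias sub-voxel centroids
  cent <- t(vapply(seq_len(max(comp)), function(cc) {
    sel <- idx[comp == cc]
    if (length(sel) < minVoxels) return(c(NA_real_, NA_real_))
    si <- (sel - 1L) %% nx + 1L
    sj <- (sel - 1L) %/% nx + 1L
    ri <- max(1L, min(si) - 2L):min(nx, max(si) + 2L)
    rj <- max(1L, min(sj) - 2L):min(ncol(slice), max(sj) + 2L)
    w <- slice[ri, rj, drop = FALSE]
    c(sum(rowSums(w) * xCoords[ri]), sum(colSums(w) * yCoords[rj])) / sum(w)
  }, numeric(2)))
  cent[stats::complete.cases(cent), , drop = FALSE]
}

#' Spatial linearity from the hole-grid phantom image
#'
#' Detects the hole centroids, pairs them to the machined 45-node grid,
#' and measures the phantom extent along the eight compass directions
#' through the grid center (center node to the outermost node on each
#' exact ray). Linearity per direction is
#' (measured - actual)/actual x 100%.
#'
#' @param img an [ImageVolume-class] of the grid section.
#' @param grid the [PhantomSpec-class] (kind `"piqt_grid"`) that describes
#'   the machined geometry.
#' @return list with `perDirection` (named numeric, percent, directions
#'   N, NE, E, SE, S, SW, W, NW), `meanPercent`, `sdPercent`,
#'   `maxAbsPercent`.
#' @export
computeLinearity <- function(img, grid) {
  if (grid@kind != "piqt_grid") stop("grid spec must be of kind 'piqt_grid'")
  s <- grid@geometry$gridSpacingMm
  d <- dim(img@voxels)
  co <- gridCoords(d, img@spacingMm, img@originMm)
  kSlice <- (d[3] + 1L) %/% 2L
  cent <- detectBlobs2d(img@voxels[, , kSlice], co$x, co$y)
  expected <- piqtGridHoleCenters(s)
  # translation estimate: both point sets are symmetric about their mean
  shift <- colMeans(cent) - colMeans(expected)
  expShift <- sweep(expected, 2, -shift)
  pair <- rep(NA_integer_, nrow(expected))
  for (e in seq_len(nrow(expected))) {
    dd <- (cent[, 1] - expShift[e, 1])^2 + (cent[, 2] - expShift[e, 2])^2
    j <- which.min(dd)
    if (dd[j] <= (s / 2)^2) pair[e] <- j
  }
  if (anyNA(pair)) {
    miss <- which(is.na(pair))
    stop("detection failure: missing grid nodes at (",
         paste(apply(expected[miss, , drop = FALSE], 1, paste,
                     collapse = ","), collapse = "); ("), ") mm")
  }
  dirs <- rbind(N = c(0, 1), NE = c(1, 1) / sqrt(2), E = c(1, 0),
                SE = c(1, -1) / sqrt(2), S = c(0, -1), SW = c(-1, -1) / sqrt(2),
                W = c(-1, 0), NW = c(-1, 1) / sqrt(2))
  centerIdx <- which(expected[, 1] == 0 & expected[, 2] == 0)
  cCenter <- cent[pair[centerIdx], ]
  perDir <- apply(dirs, 1, function(u) {
    proj <- expected %*% u
    onRay <- abs(expected[, 1] - proj * u[1]) < 1e-6 &
             abs(expected[, 2] - proj * u[2]) < 1e-6 & proj > 1e-6
    kOut <- which(onRay)[which.max(proj[onRay])]
    dMeas <- sqrt(sum((cent[pair[kOut], ] - cCenter)^2))
    dAct <- proj[kOut]
    (dMeas - dAct) / dAct * 100
  })
  list(perDirection = perDir, meanPercent = mean(perDir),
       sdPercent = stats::sd(perDir), maxAbsPercent = max(abs(perDir)))
}

#' Slice profile from the opposing wedge pair
#'
#' Extracts the line profile along each wedge (averaged across the wedge
#' width), converts the in-plane position to through-plane millimetres
#' via the wedge slope, and reports the FWHM (linear interpolation at
#' half maximum) and the slice integral (equivalent width,
#' sum(profile)/max(profile) x sample spacing).
#'
#' @param img an [ImageVolume-class] of the wedge section.
#' @param wedge the [PhantomSpec-class] (kind `"piqt_wedge"`).
#' @return list of two [SliceProfileResult-class] (`wedgeA`, `wedgeB`).
#' @export
computeSliceProfile <- function(img, wedge) {
  if (wedge@kind != "piqt_wedge") stop("wedge spec must be of kind 'piqt_wedge'")
  geom <- wedge@geometry
  d <- dim(img@voxels)
  co <- gridCoords(d, img@spacingMm, img@originMm)
  kSlice <- (d[3] + 1L) %/% 2L
  slice <- img@voxels[, , kSlice]
  regs <- wedgeRegions(geom)
  out <- lapply(regs, function(rg) {
    iny <- co$y >= rg$yLo & co$y <= rg$yHi
    inx <- abs(co$x) <= geom$wedgeLengthMm / 2
    prof <- rowMeans(slice[, iny, drop = FALSE])[inx]
    xs <- co$x[inx]
    if (max(prof) - min(prof) <= 1e-12 * max(abs(prof), 1))
      stop("low contrast: profile maximum indistinguishable from background")
    zs <- abs(rg$slope) * xs                 # through-plane mm
    fwhm <- interpWidth(zs, prof, 0.5)
    dz <- abs(rg$slope) * img@spacingMm[1]
    integral <- sum(prof - min(prof)) / (max(prof) - min(prof)) * dz
    new("SliceProfileResult", fwhmMm = fwhm, integralMm = integral,
        profile = data.frame(positionMm = zs, value = prof))
  })
  names(out) <- c("wedgeA", "wedgeB")
  out
}

#' Pixel size from the edge-spread function
#'
#' Differentiates the edge-spread function across the block edges into a
#' line-spread function and reports its FWHM (linear interpolation) in mm
#' per axis: horizontal (frequency-encode) from a row across a vertical
#' edge, vertical (phase-encode) from a column across a horizontal edge.
#'
#' @param img an [ImageVolume-class] of the edge section.
#' @param edge the [PhantomSpec-class] (kind `"piqt_edge"`).
#' @return named numeric: `horizontalMm`, `verticalMm`, with attribute
#'   `convention = "LSF FWHM"`.
#' @export
computePixelSize <- function(img, edge) {
  if (edge@kind != "piqt_edge") stop("edge spec must be of kind 'piqt_edge'")
  d <- dim(img@voxels)
  co <- gridCoords(d, img@spacingMm, img@originMm)
  kSlice <- (d[3] + 1L) %/% 2L
  slice <- img@voxels[, , kSlice]
  lsfFwhm <- function(esf, coords) {
    lsf <- abs(diff(esf))
    if (max(lsf) == 0) stop("detection error: no edge found")
    xm <- (coords[-1] + coords[-length(coords)]) / 2
    iPk <- which.max(lsf)   # rising (left/bottom) edge of the block
    win <- max(1, iPk - 8):min(length(lsf), iPk + 8)
    interpWidth(xm[win], lsf[win], 0.5)
  }
  iRow <- which.min(abs(co$y))   # central row: profile along x
  iCol <- which.min(abs(co$x))   # central column: profile along y
  c(horizontalMm = lsfFwhm(slice[, iRow], co$x),
    verticalMm = lsfFwhm(slice[iCol, ], co$y)) |>
    structure(convention = "LSF FWHM")
}

#' Central-frequency deviation from nominal
#'
#' Nominal frequency is gamma x B0 from the acquisition spec; the measured
#' frequency is compared as a percent and ppm deviation.
#'
#' @param acq an [AcquisitionSpec-class] (fieldT, gammaMHzPerT).
#' @param measuredF0MHz measured resonance frequency (MHz).
#' @return list with `nominalMHz`, `measuredMHz`, `deviationPercent`,
#'   `deviationPpm`.
#' @export
centralFrequencyCheck <- function(acq, measuredF0MHz) {
  nominal <- nominalFrequencyMHz(acq)
  dev <- (measuredF0MHz - nominal) / nominal
  list(nominalMHz = nominal, measuredMHz = measuredF0MHz,
       deviationPercent = dev * 100, deviationPpm = dev * 1e6)
}
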