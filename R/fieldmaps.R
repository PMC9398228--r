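#' @include constructors.R utils.R
NULL

defaultFieldRoi <- function() roiSpec("circle", c(0, 0), diameterMm = 350)

#' Reconstruct a B0 map from a dual-echo phase pair
#'
#' f_Hz = wrap(phi2 - phi1) / (2 pi dTE); the unambiguous range is
#' +/- 1/(2 dTE) (+/- 333.3 Hz at dTE = 1.5 ms). No unwrapping is applied:
#' QA fields are expected inside the range, and a wrap flag is propagated
#' from the inputs or raised when reconstructed values sit at the range
#' boundary.
#'
#' @param echo1,echo2 phase [ImageVolume-class] (radians, wrapped), or
#'   magnitude/phase pairs from [generateFieldSeries()].
#' @param te1Ms,te2Ms echo times (ms); taken from the volumes'
#'   annotations when omitted.
#' @param roi analysis region, default a 35-cm-diameter circle at the
#'   phantom center.
#' @return a [FieldMap-class] of kind `"b0"` (values in Hz; ppm via
#'   [ppmValues()])
#' @export
reconstructB0 <- function(echo1, echo2, te1Ms = NULL, te2Ms = NULL,
                          roi = defaultFieldRoi()) {
  if (is.null(te1Ms)) te1Ms <- echo1@annotations$teMs
  if (is.null(te2Ms)) te2Ms <- echo2@annotations$teMs
  if (is.null(te1Ms) || is.null(te2Ms))
    stop("invalid acquisition: echo times missing")
  dTEs <- (te2Ms - te1Ms) / 1000
  if (dTEs == 0) stop("invalid acquisition: dTE = 0")
  if (!echo1@isPhase || !echo2@isPhase)
    stop("reconstructB0 expects phase volumes")
  f <- wrapPhase(echo2@voxels - echo1@voxels) / (2 * pi * dTEs)
  lim <- 1 / (2 * abs(dTEs))
  wrapped <- isTRUE(echo1@annotations$wrapped) ||
    isTRUE(echo2@annotations$wrapped) ||
    any(abs(f) >= lim * 0.999)
  new("FieldMap", values = f, kind = "b0", spacingMm = echo1@spacingMm,
      originMm = echo1@originMm,
      gantryAngleDeg = echo1@meta@gantryAngleDeg, roi = roi,
      meta = echo1@meta, maskedVoxels = 0L, wrapped = wrapped)
}

#' Reconstruct a B1 map from a dual-TR magnitude pair
#'
#' Inverts the long-T1 dual-TR steady-state ratio: with r = S(TR2)/S(TR1)
#' and n = TR2/TR1, the actual flip angle is
#' alpha = arccos((r n - 1)/(n - r)), and the map is 100 x alpha/nominal.
#' Voxels with r outside the model domain (1/n, 1) are masked (NA) and
#' counted.
#'
#' @param sTr1,sTr2 magnitude [ImageVolume-class] at the short/long TR.
#' @param tr1Ms,tr2Ms repetition times (ms); 0 < tr1 < tr2. Taken from
#'   annotations when omitted.
#' @param nominalFaDeg prescribed flip angle (degrees).
#' @param roi analysis region (default 35-cm circle).
#' @return a [FieldMap-class] of kind `"b1"` (percent of nominal)
#' @export
reconstructB1 <- function(sTr1, sTr2, tr1Ms = NULL, tr2Ms = NULL,
                          nominalFaDeg = 60, roi = defaultFieldRoi()) {
  if (is.null(tr1Ms)) tr1Ms <- sTr1@annotations$trMs
  if (is.null(tr2Ms)) tr2Ms <- sTr2@annotations$trMs
  if (is.null(tr1Ms) || is.null(tr2Ms) || !(tr2Ms > tr1Ms && tr1Ms > 0))
    stop("invalid acquisition: need tr2 > tr1 > 0")
  n <- tr2Ms / tr1Ms
  r <- sTr2@voxels / sTr1@voxels
  valid <- is.finite(r) & r > 1 / n & r < 1
  cosA <- (r * n - 1) / (n - r)
  alpha <- array(NA_real_, dim = dim(r))
  alpha[valid] <- acos(pmin(1, pmax(-1, cosA[valid]))) * 180 / pi
  new("FieldMap", values = alpha / nominalFaDeg * 100, kind = "b1",
      spacingMm = sTr1@spacingMm, originMm = sTr1@originMm,
      gantryAngleDeg = sTr1@meta@gantryAngleDeg, roi = roi,
      meta = sTr1@meta, maskedVoxels = sum(!valid), wrapped = FALSE)
}

# in-plane ROI mask for a FieldMap, eroded by `erodeVoxels` voxels
fieldRoiMask <- function(map, erodeVoxels = 1L) {
  d <- dim(map@values)
  co <- gridCoords(d, map@spacingMm, map@originMm)
  R <- map@roi@diameterMm / 2 - erodeVoxels * max(map@spacingMm[1:2])
  ctr <- map@roi@centerMm
  inn <- outer((co$x - ctr[1])^2, (co$y - ctr[2])^2, "+") <= R^2
  array(inn, dim = d)
}

#' Gantry-angle dependence of B0 or B1 uniformity
#'
#' B0 mode: the voxelwise mean map across all gantry angles is subtracted
#' from each map to remove the static field contribution; per angle the
#' peak-to-peak difference (range of values inside the ROI) is reported
#' for both the mean-subtracted and the raw map, in Hz and ppm. B1 mode:
#' per angle the mean absolute deviation from 100% of nominal inside the
#' ROI, plus the across-angle grand mean and SD.
#'
#' @param maps list of [FieldMap-class] on a common grid, one per angle.
#' @param mode `"b0"` or `"b1"`; default from the maps.
#' @param erodeVoxels ROI erosion (voxels) to avoid edge effects.
#' @param percentiles peak-to-peak percentiles, default `c(0, 1)` (the
#'   literal range); `c(0.01, 0.99)` gives a robust variant.
#' @return a [GantrySweep-class]
#' @export
analyzeGantrySweep <- function(maps, mode = NULL, erodeVoxels = 1L,
                               percentiles = c(0, 1)) {
  if (length(maps) < 2) stop("need maps from >= 2 gantry angles")
  if (is.null(mode)) mode <- maps[[1]]@kind
  dims <- lapply(maps, function(m) dim(m@values))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("alignment error: maps must share a common grid")
  angles <- vapply(maps, function(m) m@gantryAngleDeg, numeric(1))
  mask <- fieldRoiMask(maps[[1]], erodeVoxels)
  p2p <- function(v) {
    q <- stats::quantile(v, percentiles, na.rm = TRUE, names = FALSE)
    q[2] - q[1]
  }
  if (mode == "b0") {
    d <- dim(maps[[1]]@values)
    stack <- vapply(maps, function(m) m@values, maps[[1]]@values)
    meanMap <- array(rowMeans(matrix(stack, prod(d), length(maps))), d)
    f0MHz <- nominalFrequencyMHz(maps[[1]]@meta)
    stats <- data.frame(
      angle_deg = angles,
      p2p_raw_hz = vapply(maps, function(m) p2p(m@values[mask]), numeric(1)),
      p2p_resid_hz = vapply(maps, function(m)
        p2p((m@values - meanMap)[mask]), numeric(1)))
    stats$p2p_raw_ppm <- stats$p2p_raw_hz / f0MHz
    stats$p2p_resid_ppm <- stats$p2p_resid_hz / f0MHz
    new("GantrySweep", mode = "b0", anglesDeg = angles, maps = maps,
        meanMap = meanMap, stats = stats,
        grandMean = NA_real_, grandSd = NA_real_)
  } else {
    dev <- vapply(maps, function(m)
      mean(abs(m@values[mask] - 100), na.rm = TRUE), numeric(1))
    stats <- data.frame(angle_deg = angles, mean_abs_dev_percent = dev)
    new("GantrySweep", mode = "b1", anglesDeg = angles, maps = maps,
        meanMap = array(0, dim(maps[[1]]@values)), stats = stats,
        grandMean = mean(dev), grandSd = stats::sd(dev))
  }
}

#' Worst-case geometric displacement caused by B0 inhomogeneity
#'
#' A field offset dB0 read out under gradient G_read displaces signal by
#' dB0/G_read: (ppm x 1e-6 x B0_T)/(G x 1e-3 T/m), returned in mm.
#'
#' @param deltaB0Ppm field inhomogeneity (ppm, >= 0).
#' @param fieldT static field (T).
#' @param gReadmTPerM readout gradient strength (mT/m, > 0).
#' @return displacement in mm
#' @examples
#' b0DistortionEstimate(3, 1.5, 15)  # 0.30 mm
#' @export
b0DistortionEstimate <- function(deltaB0Ppm, fieldT, gReadmTPerM) {
  if (gReadmTPerM <= 0) stop("division error: readout gradient must be > 0")
  if (fieldT <= 0) stop("fieldT must be > 0")
  if (deltaB0Ppm < 0) stop("deltaB0Ppm must be >= 0")
  (deltaB0Ppm * 1e-6 * fieldT) / (gReadmTPerM * 1e-3) * 1000
}
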