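#' @import methods
NULL

# Coordinate convention used throughout: machine (patient) coordinates in mm
# with the origin at isocenter. A voxel with 1-based array index (i, j, k)
# has its *center* at origin_mm + (index - 1) * spacing_mm. Generators place
# the volume so that its geometric center coincides with isocenter.

#' Acquisition parameters
#'
#' Container for the acquisition metadata that travels with every image
#' volume: repetition time, echo times, flip angles, diffusion b-values,
#' voxel geometry, gantry angle and the nominal field.
#'
#' @slot trMs repetition time (ms); for dual-TR series, the first TR.
#' @slot tr2Ms second repetition time (ms) of a dual-TR series, or `NA`.
#' @slot teMs numeric vector of echo times (ms).
#' @slot flipAnglesDeg numeric vector of flip angles (degrees).
#' @slot bValues diffusion weightings (s/mm^2).
#' @slot voxelSizeMm voxel size (mm), length 3.
#' @slot matrixSize acquisition matrix, length 3 (counts).
#' @slot gantryAngleDeg gantry angle (degrees).
#' @slot fieldT nominal static field (tesla), default 1.5.
#' @slot gammaMHzPerT proton gyromagnetic ratio (MHz/T).
#' @export
setClass("AcquisitionSpec",
  representation(
    trMs = "numeric", tr2Ms = "numeric", teMs = "numeric",
    flipAnglesDeg = "numeric", bValues = "numeric",
    voxelSizeMm = "numeric", matrixSize = "numeric",
    gantryAngleDeg = "numeric", fieldT = "numeric", gammaMHzPerT = "numeric"
  )
)

setValidity("AcquisitionSpec", function(object) {
  msg <- character()
  if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
    msg <- c(msg, "voxelSizeMm must be 3 strictly positive values")
  if (length(object@matrixSize) != 3L || any(object@matrixSize < 1))
    msg <- c(msg, "matrixSize must be 3 positive counts")
  if (length(object@teMs) && !is.na(object@trMs) &&
      object@trMs <= max(object@teMs))
    msg <- c(msg, "trMs must exceed every echo time")
  if (length(object@bValues) && any(object@bValues < 0))
    msg <- c(msg, "b-values must be non-negative")
  if (length(object@flipAnglesDeg) &&
      (any(object@flipAnglesDeg <= 0) || any(object@flipAnglesDeg > 90)))
    msg <- c(msg, "flip angles must lie in (0, 90] degrees")
  if (object@fieldT <= 0) msg <- c(msg, "fieldT must be positive")
  if (length(msg)) msg else TRUE
})

#' Phantom geometry specification
#'
#' Describes one of the physical QA phantoms the synthetic generator can
#' render: the image-quality phantom sections (hole grid, wedge pair, edge
#' block), the 3D fiducial-grid distortion phantom, the uniform field
#' cylinder, and the quantitative vial arrays.
#'
#' @slot kind one of `"piqt_grid"`, `"piqt_wedge"`, `"piqt_edge"`,
#'   `"fiducial3d"`, `"cylinder"`, `"vial_array"`.
#' @slot geometry named list of dimensions in mm (see [phantomSpec()]).
#' @slot backgroundSignal signal level outside the object (a.u.).
#' @slot objectSignal signal level of the object (a.u.).
#' @export
setClass("PhantomSpec",
  representation(kind = "character", geometry = "list",
                 backgroundSignal = "numeric", objectSignal = "numeric")
)

setValidity("PhantomSpec", function(object) {
  kinds <- c("piqt_grid", "piqt_wedge", "piqt_edge", "fiducial3d",
             "cylinder", "vial_array")
  msg <- character()
  if (!(object@kind %in% kinds))
    msg <- c(msg, paste("kind must be one of:", paste(kinds, collapse = ", ")))
  num <- unlist(Filter(is.numeric, object@geometry))
  if (length(num) && any(!is.finite(num)))
    msg <- c(msg, "geometry values must be finite")
  dims <- object@geometry[names(object@geometry) %in%
    c("gridSpacingMm", "holeDiameterMm", "gridSizeMm", "bodyDiameterMm",
      "plateSpacingMm", "plateRadiusMm", "markerDiameterMm",
      "cylinderDiameterMm", "vialDiameterMm", "wedgeSlope",
      "sliceThicknessMm", "edgeSizeMm")]
  if (length(dims) && any(unlist(dims) <= 0))
    msg <- c(msg, "all phantom dimensions must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Ground truth for synthetic phantom generation
#'
#' Holds everything the generator knows that a scanner never reports: the
#' per-vial relaxation/diffusion values, the B0 and B1 fields as functions
#' of position (and gantry angle for B0), the geometric-distortion field,
#' the complex-noise level and the random seed.
#'
#' @slot t1Ms,t2Ms,adc per-vial nominal values (`adc` in mm^2/s).
#' @slot b0FieldHz function `(x, y, z, gantryAngleDeg)` returning Hz.
#' @slot b1Fraction function `(x, y, z)` returning the actual/nominal flip
#'   angle ratio (1 = nominal).
#' @slot distortionFieldMm function `(xyz matrix)` returning an n x 3 matrix
#'   of displacements in mm.
#' @slot noiseSd standard deviation of the complex Gaussian noise per
#'   channel (a.u.); magnitude images therefore carry Rician noise.
#' @slot seed integer random seed.
#' @export
setClass("GroundTruth",
  representation(t1Ms = "numeric", t2Ms = "numeric", adc = "numeric",
                 b0FieldHz = "function", b1Fraction = "function",
                 distortionFieldMm = "function",
                 noiseSd = "numeric", seed = "integer")
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  n <- length(object@t1Ms)
  if (n && length(object@t2Ms) == n) {
    if (any(object@t2Ms <= 0) || any(object@t1Ms <= object@t2Ms))
      msg <- c(msg, "each vial needs t1 > t2 > 0")
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Image volume
#'
#' The universal carrier of image data: a 3D voxel grid with spacing,
#' origin and acquisition metadata. Phase volumes are flagged and must be
#' wrapped to (-pi, pi].
#'
#' @slot voxels 3D numeric array (magnitude in a.u., or phase in radians).
#' @slot spacingMm voxel spacing (mm), length 3.
#' @slot originMm machine coordinate (mm) of the center of voxel (1,1,1).
#' @slot isPhase logical flag; `TRUE` for phase data.
#' @slot meta [AcquisitionSpec-class] plus free-form annotations.
#' @slot annotations list of per-volume labels (echo index, flip angle,
#'   b-value, gantry angle, dummy-echo flag, wrap warning, ...).
#' @export
setClass("ImageVolume",
  representation(voxels = "array", spacingMm = "numeric", originMm = "numeric",
                 isPhase = "logical", meta = "AcquisitionSpec",
                 annotations = "list")
)

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    msg <- c(msg, "spacingMm must be 3 strictly positive values")
  if (length(object@originMm) != 3L)
    msg <- c(msg, "originMm must have length 3")
  if (isTRUE(object@isPhase)) {
    v <- object@voxels
    if (any(v <= -pi - 1e-9 | v > pi + 1e-9, na.rm = TRUE))
      msg <- c(msg, "phase volumes must be wrapped to (-pi, pi]")
  }
  if (length(msg)) msg else TRUE
})

#' Region of interest
#'
#' A circular or rectangular region, given in machine coordinates (mm).
#' Circles are evaluated in-plane (x, y) on a stated slice.
#'
#' @slot shape `"circle"` or `"rectangle"`.
#' @slot centerMm region center (mm), length 2 or 3.
#' @slot diameterMm circle diameter (mm).
#' @slot extentsMm rectangle edge lengths (mm), length 2 or 3.
#' @export
setClass("RoiSpec",
  representation(shape = "character", centerMm = "numeric",
                 diameterMm = "numeric", extentsMm = "numeric")
)

setValidity("RoiSpec", function(object) {
  msg <- character()
  if (!(object@shape %in% c("circle", "rectangle")))
    msg <- c(msg, "shape must be 'circle' or 'rectangle'")
  if (object@shape == "circle" &&
      (length(object@diameterMm) != 1L || object@diameterMm <= 0))
    msg <- c(msg, "circle needs a positive diameterMm")
  if (object@shape == "rectangle" && any(object@extentsMm <= 0))
    msg <- c(msg, "rectangle needs positive extentsMm")
  if (length(msg)) msg else TRUE
})

#' Paired fiducial marker set
#'
#' Known (machined) and measured marker coordinates, paired one-to-one;
#' the distortion vector at each marker is measured - known.
#'
#' @slot knownMm n x 3 matrix of machined positions (mm, isocenter origin).
#' @slot measuredMm n x 3 matrix of detected centroids (mm).
#' @slot ids integer grid identifiers.
#' @slot unpairedKnownMm m x 3 matrix of expected markers with no detection.
#' @export
setClass("MarkerSet",
  representation(knownMm = "matrix", measuredMm = "matrix",
                 ids = "integer", unpairedKnownMm = "matrix")
)

setValidity("MarkerSet", function(object) {
  msg <- character()
  if (nrow(object@knownMm) != nrow(object@measuredMm))
    msg <- c(msg, "knownMm and measuredMm must pair row-for-row")
  if (ncol(object@knownMm) != 3L || ncol(object@measuredMm) != 3L)
    msg <- c(msg, "coordinates must have 3 columns")
  if (length(object@ids) != nrow(object@knownMm))
    msg <- c(msg, "ids must match the number of pairs")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "pairing must be bijective (duplicate ids)")
  if (!all(is.finite(object@measuredMm - object@knownMm)))
    msg <- c(msg, "distortion vectors must be finite")
  if (length(msg)) msg else TRUE
})

#' Distortion summary per diameter of spherical volume
#'
#' @slot table data.frame with columns `dsv_cm`, `max_distortion_mm`,
#'   `n_markers`, `tolerance_mm`, `pass`.
#' @export
setClass("DsvSummary", representation(table = "data.frame"))

setValidity("DsvSummary", function(object) {
  tb <- object@table
  need <- c("dsv_cm", "max_distortion_mm", "n_markers", "tolerance_mm", "pass")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  o <- order(tb$dsv_cm)
  if (is.unsorted(tb$max_distortion_mm[o]))
    return("max distortion must be non-decreasing with DSV")
  if (!all(tb$pass == (tb$max_distortion_mm <= tb$tolerance_mm)))
    return("pass flags inconsistent with tolerances")
  TRUE
})

#' Field map (B0 or B1)
#'
#' Per-voxel B0 offset (Hz, with a derived ppm channel) or B1 (percent of
#' the nominal flip angle), with the gantry angle at which it was acquired
#' and the analysis region.
#'
#' @slot values 3D array; Hz for B0, percent of nominal for B1.
#' @slot kind `"b0"` or `"b1"`.
#' @slot spacingMm,originMm grid geometry as in [ImageVolume-class].
#' @slot gantryAngleDeg gantry angle (degrees).
#' @slot roi [RoiSpec-class] over which statistics are computed.
#' @slot meta [AcquisitionSpec-class].
#' @slot maskedVoxels count of voxels excluded by the reconstruction.
#' @slot wrapped logical; `TRUE` if phase wrapping was detected.
#' @export
setClass("FieldMap",
  representation(values = "array", kind = "character",
                 spacingMm = "numeric", originMm = "numeric",
                 gantryAngleDeg = "numeric", roi = "RoiSpec",
                 meta = "AcquisitionSpec", maskedVoxels = "integer",
                 wrapped = "logical")
)

setValidity("FieldMap", function(object) {
  msg <- character()
  if (!(object@kind %in% c("b0", "b1"))) msg <- c(msg, "kind must be b0 or b1")
  if (object@kind == "b1" && any(object@values <= 0, na.rm = TRUE))
    msg <- c(msg, "B1 percent values must be positive")
  if (length(msg)) msg else TRUE
})

#' Gantry sweep analysis
#'
#' @slot mode `"b0"` or `"b1"`.
#' @slot anglesDeg gantry angles.
#' @slot maps list of [FieldMap-class], one per angle.
#' @slot meanMap voxelwise mean across angles (B0 only).
#' @slot stats per-angle statistics: for B0, raw and mean-subtracted
#'   peak-to-peak in Hz and ppm; for B1, mean absolute deviation from 100%.
#' @slot grandMean,grandSd across-angle summary of the B1 deviation.
#' @export
setClass("GantrySweep",
  representation(mode = "character", anglesDeg = "numeric", maps = "list",
                 meanMap = "array", stats = "data.frame",
                 grandMean = "numeric", grandSd = "numeric")
)

setValidity("GantrySweep", function(object) {
  p2p <- unlist(object@stats[grep("^p2p", names(object@stats))])
  if (length(p2p) && any(p2p < -1e-12, na.rm = TRUE))
    return("peak-to-peak values must be >= 0")
  TRUE
})

#' Quantitative MRI fit result
#'
#' Per-voxel parameter map from a linearized mono-exponential fit, with
#' the S0 map, goodness of fit and validity mask. Invalid voxels are `NA`
#' in the parameter map and `FALSE` in the mask, never silently zero.
#'
#' @slot parameter `"T1"`, `"T2"` or `"ADC"`.
#' @slot units `"ms"` or `"mm^2/s"`.
#' @slot map 3D array of fitted values (`NA` where masked).
#' @slot s0 3D array of fitted S0 (a.u.).
#' @slot r2 3D array of per-voxel R^2 of the linearized fit.
#' @slot mask logical 3D array of valid voxels.
#' @slot spacingMm,originMm grid geometry.
#' @export
setClass("QMRIFitResult",
  representation(parameter = "character", units = "character",
                 map = "array", s0 = "array", r2 = "array", mask = "array",
                 spacingMm = "numeric", originMm = "numeric")
)

setValidity("QMRIFitResult", function(object) {
  msg <- character()
  if (!(object@parameter %in% c("T1", "T2", "ADC")))
    msg <- c(msg, "parameter must be T1, T2 or ADC")
  ok <- object@map[object@mask]
  if (length(ok) && any(!is.finite(ok) | ok <= 0))
    msg <- c(msg, "valid voxels must carry finite positive values")
  bad <- object@map[!object@mask]
  if (length(bad) && any(!is.na(bad)))
    msg <- c(msg, "masked voxels must be NA, never silently zero")
  if (length(msg)) msg else TRUE
})

#' Per-vial bias and reproducibility report
#'
#' @slot perSession data.frame: one row per vial per session (vial, session,
#'   roi mean, roi sd, n voxels).
#' @slot perVial data.frame: one row per vial (nominal, mean-of-session
#'   means, bias percent, COV percent across sessions).
#' @slot summary named list: medians and ranges of bias and COV across vials.
#' @slot parameter which biomarker the report covers.
#' @slot nSessions number of sessions.
#' @export
setClass("VialReport",
  representation(perSession = "data.frame", perVial = "data.frame",
                 summary = "list", parameter = "character",
                 nSessions = "integer")
)

setValidity("VialReport", function(object) {
  cov <- object@perVial$cov_percent
  if (length(cov) && any(cov < 0, na.rm = TRUE)) "COV must be >= 0" else TRUE
})

#' Longitudinal trend result
#'
#' @slot slopePerDay OLS slope in metric units (or percent of baseline,
#'   if normalized) per day.
#' @slot slopePerYear slope annualized by 365.25.
#' @slot intercept fitted value at the first date.
#' @slot covPercent coefficient of variation of the series (percent).
#' @slot normalized whether the fit was on percent-of-baseline values.
#' @slot changePoints dates where a sustained shift beyond the CUSUM
#'   threshold begins.
#' @export
setClass("TrendResult",
  representation(slopePerDay = "numeric", slopePerYear = "numeric",
                 intercept = "numeric", covPercent = "numeric",
                 normalized = "logical", changePoints = "ANY")
)

setValidity("TrendResult", function(object) {
  if (length(object@covPercent) && object@covPercent < 0)
    "covPercent must be >= 0" else TRUE
})
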