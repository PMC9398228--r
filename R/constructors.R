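#' @include AllClasses.R
NULL

#' Create an acquisition specification
#'
#' @param trMs repetition time in ms (first TR for dual-TR series).
#' @param tr2Ms second TR in ms for dual-TR B1 mapping (default `NA`).
#' @param teMs echo time(s) in ms.
#' @param flipAnglesDeg flip angle(s) in degrees.
#' @param bValues diffusion b-values in s/mm^2.
#' @param voxelSizeMm voxel size in mm (length 3).
#' @param matrixSize acquisition matrix (length 3).
#' @param gantryAngleDeg gantry angle in degrees.
#' @param fieldT nominal static field in tesla.
#' @param gammaMHzPerT proton gyromagnetic ratio in MHz/T.
#' @return an [AcquisitionSpec-class]
#' @examples
#' acquisitionSpec(trMs = 20, teMs = 2.3, flipAnglesDeg = c(4, 22))
#' @export
acquisitionSpec <- function(trMs = NA_real_, tr2Ms = NA_real_,
                            teMs = numeric(), flipAnglesDeg = numeric(),
                            bValues = numeric(),
                            voxelSizeMm = c(2, 2, 3),
                            matrixSize = c(160, 160, 1),
                            gantryAngleDeg = 0, fieldT = 1.5,
                            gammaMHzPerT = 42.577478518) {
  new("AcquisitionSpec", trMs = as.numeric(trMs), tr2Ms = as.numeric(tr2Ms),
      teMs = as.numeric(teMs), flipAnglesDeg = as.numeric(flipAnglesDeg),
      bValues = as.numeric(bValues), voxelSizeMm = as.numeric(voxelSizeMm),
      matrixSize = as.numeric(matrixSize),
      gantryAngleDeg = as.numeric(gantryAngleDeg),
      fieldT = as.numeric(fieldT), gammaMHzPerT = as.numeric(gammaMHzPerT))
}

#' Nominal resonance frequency in MHz
#' @param acq an [AcquisitionSpec-class]
#' @return gamma * B0 in MHz
#' @export
nominalFrequencyMHz <- function(acq) acq@gammaMHzPerT * acq@fieldT

#' Create a phantom specification
#'
#' Geometry defaults follow the physical QA phantoms: the image-quality
#' grid section has 45 holes of 5 mm diameter on a 25 mm lattice spanning
#' 150 x 150 mm^2 (a 7 x 7 grid minus the four corners); the fiducial
#' phantom has 7 plates 55 mm apart carrying 1932 markers on a 25 mm
#' in-plane lattice; the field cylinder is 40 cm in diameter.
#'
#' @param kind phantom kind: `"piqt_grid"`, `"piqt_wedge"`, `"piqt_edge"`,
#'   `"fiducial3d"`, `"cylinder"` or `"vial_array"`.
#' @param geometry named list overriding the per-kind defaults, in mm
#'   (except `wedgeSlope`, a unitless through-plane/in-plane ratio).
#' @param backgroundSignal,objectSignal signal levels in arbitrary units.
#' @return a [PhantomSpec-class]
#' @examples
#' phantomSpec("piqt_grid")
#' phantomSpec("cylinder", geometry = list(cylinderDiameterMm = 400))
#' @export
phantomSpec <- function(kind, geometry = list(),
                        backgroundSignal = 0, objectSignal = 100) {
  defaults <- switch(kind,
    piqt_grid = list(gridSpacingMm = 25, holeDiameterMm = 5,
                     gridSizeMm = 150, bodyDiameterMm = 190),
    piqt_wedge = list(wedgeSlope = 0.2, sliceThicknessMm = 5,
                      wedgeLengthMm = 80, wedgeWidthMm = 30,
                      wedgeGapMm = 10),
    piqt_edge = list(edgeSizeMm = 100, edgeBlurMm = 0),
    fiducial3d = list(gridSpacingMm = 25, plateSpacingMm = 55,
                      nPlates = 7, plateRadiusMm = 235,
                      markerDiameterMm = 8),
    cylinder = list(cylinderDiameterMm = 400),
    vial_array = list(vialDiameterMm = 20, bodyDiameterMm = 180,
                      layout = "relaxometry"),
    stop("unknown phantom kind: ", kind)
  )
  geometry <- utils::modifyList(defaults, geometry)
  new("PhantomSpec", kind = kind, geometry = geometry,
      backgroundSignal = as.numeric(backgroundSignal),
      objectSignal = as.numeric(objectSignal))
}

#' Create a ground-truth object for simulation
#'
#' @param t1Ms,t2Ms,adc per-vial nominal values (ms, ms, mm^2/s).
#' @param b0FieldHz function `(x, y, z, gantryAngleDeg)` -> Hz. Default 0.
#' @param b1Fraction function `(x, y, z)` -> actual/nominal flip-angle
#'   fraction. Default 1 everywhere.
#' @param distortionFieldMm function taking an n x 3 coordinate matrix (mm)
#'   and returning an n x 3 displacement matrix (mm). Default zero field.
#' @param noiseSd complex Gaussian noise SD per channel (a.u.).
#' @param seed integer random seed; identical seeds give bit-identical
#'   volumes.
#' @return a [GroundTruth-class]
#' @export
groundTruth <- function(t1Ms = numeric(), t2Ms = numeric(), adc = numeric(),
                        b0FieldHz = function(x, y, z, gantryAngleDeg = 0)
                          rep(0, length(x)),
                        b1Fraction = function(x, y, z) rep(1, length(x)),
                        distortionFieldMm = zeroField(),
                        noiseSd = 0, seed = 1L) {
  new("GroundTruth", t1Ms = as.numeric(t1Ms), t2Ms = as.numeric(t2Ms),
      adc = as.numeric(adc), b0FieldHz = b0FieldHz, b1Fraction = b1Fraction,
      distortionFieldMm = distortionFieldMm, noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

#' Construct an image volume
#'
#' @param voxels 3D numeric array (a 2D matrix is promoted to one slice).
#' @param spacingMm voxel spacing in mm (length 3).
#' @param originMm machine coordinate of the center of voxel (1,1,1); by
#'   default the grid is centered on isocenter.
#' @param isPhase `TRUE` for phase data (radians, wrapped to (-pi, pi]).
#' @param meta an [AcquisitionSpec-class].
#' @param annotations free-form list of per-volume labels.
#' @return an [ImageVolume-class]
#' @export
imageVolume <- function(voxels, spacingMm = c(1, 1, 1), originMm = NULL,
                        isPhase = FALSE, meta = acquisitionSpec(),
                        annotations = list()) {
  if (length(dim(voxels)) == 2L)
    voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (is.null(originMm))
    originMm <- -(dim(voxels) - 1) / 2 * spacingMm
  new("ImageVolume", voxels = voxels, spacingMm = as.numeric(spacingMm),
      originMm = as.numeric(originMm), isPhase = isPhase, meta = meta,
      annotations = annotations)
}

#' Define a region of interest
#'
#' @param shape `"circle"` (in-plane) or `"rectangle"`.
#' @param centerMm region center in machine coordinates (mm); length 2
#'   places the region on the central slice.
#' @param diameterMm circle diameter (mm).
#' @param extentsMm rectangle edge lengths (mm).
#' @return an [RoiSpec-class]
#' @export
roiSpec <- function(shape = c("circle", "rectangle"), centerMm = c(0, 0),
                    diameterMm = NA_real_, extentsMm = NA_real_) {
  shape <- match.arg(shape)
  new("RoiSpec", shape = shape, centerMm = as.numeric(centerMm),
      diameterMm = as.numeric(diameterMm), extentsMm = as.numeric(extentsMm))
}

#' Construct a paired marker set
#'
#' @param knownMm,measuredMm n x 3 coordinate matrices (mm).
#' @param ids integer identifiers (default sequence).
#' @param unpairedKnownMm expected markers without a detection.
#' @return a [MarkerSet-class]
#' @export
markerSet <- function(knownMm, measuredMm, ids = seq_len(nrow(knownMm)),
                      unpairedKnownMm = matrix(numeric(), 0, 3)) {
  new("MarkerSet", knownMm = as.matrix(knownMm),
      measuredMm = as.matrix(measuredMm), ids = as.integer(ids),
      unpairedKnownMm = as.matrix(unpairedKnownMm))
}
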