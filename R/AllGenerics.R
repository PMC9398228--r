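#' @include AllClasses.R
NULL

#' Extract the voxel array
#' @param x an object carrying voxel data
#' @return a 3D numeric array
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Voxel spacing in mm
#' @param x an object on a voxel grid
#' @return numeric length-3 vector (mm)
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Machine coordinate (mm) of the center of voxel (1,1,1)
#' @param x an object on a voxel grid
#' @return numeric length-3 vector (mm)
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' Acquisition metadata
#' @param x an object carrying acquisition metadata
#' @return an [AcquisitionSpec-class]
#' @export
setGeneric("acqSpec", function(x) standardGeneric("acqSpec"))

#' Known (machined) marker coordinates
#' @param x a [MarkerSet-class]
#' @return n x 3 matrix (mm)
#' @export
setGeneric("knownPositions", function(x) standardGeneric("knownPositions"))

#' Measured marker coordinates
#' @param x a [MarkerSet-class]
#' @return n x 3 matrix (mm)
#' @export
setGeneric("measuredPositions", function(x) standardGeneric("measuredPositions"))

#' Distortion vectors (measured - known)
#' @param x a [MarkerSet-class]
#' @return n x 3 matrix (mm)
#' @export
setGeneric("distortionVectors", function(x) standardGeneric("distortionVectors"))

#' Per-voxel ppm channel of a B0 field map
#'
#' Converts the Hz values to parts-per-million of the nominal resonance
#' frequency, ppm = f_Hz / (gamma_MHz_per_T * B0_T).
#' @param x a [FieldMap-class] of kind `"b0"`
#' @return 3D array in ppm
#' @export
setGeneric("ppmValues", function(x) standardGeneric("ppmValues"))

#' Fitted parameter map
#' @param x a [QMRIFitResult-class]
#' @return 3D array, `NA` at masked voxels
#' @export
setGeneric("parameterMap", function(x) standardGeneric("parameterMap"))

#' Validity mask of a fit
#' @param x a [QMRIFitResult-class]
#' @return logical 3D array
#' @export
setGeneric("fitMask", function(x) standardGeneric("fitMask"))

#' Summary table of a DSV or sweep analysis
#' @param x a [DsvSummary-class], [GantrySweep-class] or [VialReport-class]
#' @return a data.frame
#' @export
setGeneric("summaryTable", function(x) standardGeneric("summaryTable"))
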