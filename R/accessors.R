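#' @include AllGenerics.R
NULL

#' @rdname voxelData
#' @export
setMethod("voxelData", "ImageVolume", function(x) x@voxels)

#' @rdname voxelData
#' @export
setMethod("voxelData", "FieldMap", function(x) x@values)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacingMm)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "FieldMap", function(x) x@spacingMm)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "QMRIFitResult", function(x) x@spacingMm)

#' @rdname voxelOrigin
#' @export
setMethod("voxelOrigin", "ImageVolume", function(x) x@originMm)

#' @rdname voxelOrigin
#' @export
setMethod("voxelOrigin", "FieldMap", function(x) x@originMm)

#' @rdname voxelOrigin
#' @export
setMethod("voxelOrigin", "QMRIFitResult", function(x) x@originMm)

#' @rdname acqSpec
#' @export
setMethod("acqSpec", "ImageVolume", function(x) x@meta)

#' @rdname acqSpec
#' @export
setMethod("acqSpec", "FieldMap", function(x) x@meta)

#' @rdname knownPositions
#' @export
setMethod("knownPositions", "MarkerSet", function(x) x@knownMm)

#' @rdname measuredPositions
#' @export
setMethod("measuredPositions", "MarkerSet", function(x) x@measuredMm)

#' @rdname distortionVectors
#' @export
setMethod("distortionVectors", "MarkerSet",
          function(x) x@measuredMm - x@knownMm)

#' @rdname ppmValues
#' @export
setMethod("ppmValues", "FieldMap", function(x) {
  if (x@kind != "b0")
    stop("ppm conversion applies to B0 maps only")
  f0MHz <- x@meta@gammaMHzPerT * x@meta@fieldT
  x@values / f0MHz  # Hz / MHz = 1e-6 = ppm
})

#' @rdname parameterMap
#' @export
setMethod("parameterMap", "QMRIFitResult", function(x) x@map)

#' @rdname fitMask
#' @export
setMethod("fitMask", "QMRIFitResult", function(x) x@mask)

#' @rdname summaryTable
#' @export
setMethod("summaryTable", "DsvSummary", function(x) x@table)

#' @rdname summaryTable
#' @export
setMethod("summaryTable", "GantrySweep", function(x) x@stats)

#' @rdname summaryTable
#' @export
setMethod("summaryTable", "VialReport", function(x) x@perVial)

# -- show methods -------------------------------------------------------------

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume: %d x %d x %d %s, spacing %s mm\n",
              d[1], d[2], d[3],
              if (object@isPhase) "(phase, rad)" else "(magnitude, a.u.)",
              paste(format(object@spacingMm, digits = 4), collapse = " x ")))
  ann <- object@annotations
  if (length(ann))
    cat("  annotations:", paste(names(ann), unlist(lapply(ann, format)),
                                sep = "=", collapse = ", "), "\n")
})

setMethod("show", "MarkerSet", function(object) {
  v <- sqrt(rowSums(distortionVectors(object)^2))
  cat(sprintf("MarkerSet: %d paired markers (%d expected unpaired)\n",
              nrow(object@knownMm), nrow(object@unpairedKnownMm)))
  if (length(v))
    cat(sprintf("  |distortion| median %.3f mm, max %.3f mm\n",
                stats::median(v), max(v)))
})

setMethod("show", "DsvSummary", function(object) {
  cat("DSV distortion summary:\n")
  print(object@table, row.names = FALSE)
})

setMethod("show", "FieldMap", function(object) {
  cat(sprintf("FieldMap (%s) at gantry %g deg, %s\n",
              toupper(object@kind), object@gantryAngleDeg,
              if (object@kind == "b0") "values in Hz" else
                "values in % of nominal flip angle"))
  if (object@maskedVoxels > 0L)
    cat("  masked voxels:", object@maskedVoxels, "\n")
  if (isTRUE(object@wrapped))
    cat("  warning: phase wrapping detected\n")
})

setMethod("show", "GantrySweep", function(object) {
  cat(sprintf("GantrySweep (%s) over %d angles\n",
              toupper(object@mode), length(object@anglesDeg)))
  print(object@stats, row.names = FALSE)
  if (object@mode == "b1")
    cat(sprintf("  grand mean deviation %.2f +/- %.2f %%\n",
                object@grandMean, object@grandSd))
})

setMethod("show", "QMRIFitResult", function(object) {
  ok <- object@map[object@mask]
  cat(sprintf("QMRIFitResult: %s (%s), %d/%d voxels valid\n",
              object@parameter, object@units, sum(object@mask),
              length(object@mask)))
  if (length(ok))
    cat(sprintf("  valid-voxel range: %.4g .. %.4g\n", min(ok), max(ok)))
})

setMethod("show", "VialReport", function(object) {
  cat(sprintf("VialReport: %s, %d vials, %d session(s)\n",
              object@parameter, nrow(object@perVial), object@nSessions))
  print(object@perVial, row.names = FALSE)
})

setMethod("show", "TrendResult", function(object) {
  cat(sprintf("TrendResult: slope %.4g per day (%.4g per year%s), COV %.3g%%\n",
              object@slopePerDay, object@slopePerYear,
              if (object@normalized) ", % of baseline" else "",
              object@covPercent))
  if (length(object@changePoints))
    cat("  change points:", paste(object@changePoints, collapse = ", "), "\n")
})
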