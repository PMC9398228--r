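#' @include constructors.R
NULL

#' Write an image volume to NIfTI with a JSON sidecar
#'
#' The voxel data and spacing go into the NIfTI file; the sidecar
#' (`<path without .nii>.json`) is authoritative for the origin, phase
#' flag, acquisition spec and annotations, all of which
#' [readImageVolume()] restores.
#'
#' @param vol an [ImageVolume-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return invisibly, the path
#' @export
writeImageVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@voxels)
  RNifti::pixdim(img) <- vol@spacingMm
  RNifti::writeNifti(img, path)
  acq <- vol@meta
  sidecar <- list(
    spacingMm = vol@spacingMm, originMm = vol@originMm,
    isPhase = vol@isPhase, annotations = vol@annotations,
    acquisition = list(
      trMs = acq@trMs, tr2Ms = acq@tr2Ms, teMs = acq@teMs,
      flipAnglesDeg = acq@flipAnglesDeg, bValues = acq@bValues,
      voxelSizeMm = acq@voxelSizeMm, matrixSize = acq@matrixSize,
      gantryAngleDeg = acq@gantryAngleDeg, fieldT = acq@fieldT,
      gammaMHzPerT = acq@gammaMHzPerT))
  jsonlite::write_json(sidecar, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

sidecarPath <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' Read an image volume written by [writeImageVolume()]
#'
#' Plain NIfTI files (no sidecar) are read with geometry from the header
#' and default metadata.
#'
#' @param path NIfTI file path.
#' @return an [ImageVolume-class]
#' @export
readImageVolume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vox)) == 2L) vox <- array(vox, c(dim(vox), 1L))
  sc <- sidecarPath(path)
  if (file.exists(sc)) {
    side <- jsonlite::fromJSON(sc, simplifyVector = TRUE)
    a <- side$acquisition
    nodef <- function(x, d) if (is.null(x) || !length(x)) d else x
    meta <- acquisitionSpec(
      trMs = nodef(a$trMs, NA_real_), tr2Ms = nodef(a$tr2Ms, NA_real_),
      teMs = nodef(a$teMs, numeric()),
      flipAnglesDeg = nodef(a$flipAnglesDeg, numeric()),
      bValues = nodef(a$bValues, numeric()),
      voxelSizeMm = a$voxelSizeMm, matrixSize = a$matrixSize,
      gantryAngleDeg = a$gantryAngleDeg, fieldT = a$fieldT,
      gammaMHzPerT = a$gammaMHzPerT)
    ann <- side$annotations
    imageVolume(vox, spacingMm = side$spacingMm, originMm = side$originMm,
                isPhase = isTRUE(side$isPhase), meta = meta,
                annotations = if (is.null(ann)) list() else as.list(ann))
  } else {
    sp <- RNifti::pixdim(img)[1:3]
    imageVolume(vox, spacingMm = sp)
  }
}

#' Write a series of volumes (one file per member) with sidecars
#'
#' @param series named list of [ImageVolume-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the written paths
#' @export
writeImageSeries <- function(series, dir, prefix = "vol") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- names(series)
  if (is.null(nm)) nm <- sprintf("%03d", seq_along(series))
  paths <- file.path(dir, paste0(prefix, "_", nm, ".nii"))
  for (i in seq_along(series)) writeImageVolume(series[[i]], paths[i])
  invisible(paths)
}
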