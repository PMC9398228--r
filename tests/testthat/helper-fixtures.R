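# shared fixture builders; everything is generated in code at test time

# a bare magnitude volume from a matrix or array
mkVol <- function(values, spacingMm = c(1, 1, 1), isPhase = FALSE,
                  meta = acquisitionSpec(), annotations = list()) {
  imageVolume(if (is.matrix(values)) array(values, c(dim(values), 1L))
              else values,
              spacingMm = spacingMm, isPhase = isPhase, meta = meta,
              annotations = annotations)
}

# uniform field map on a small grid
mkFieldMap <- function(values, kind = "b0", gantry = 0, dims = c(20, 20, 1),
                       spacingMm = c(10, 10, 10), roiDiameterMm = 150,
                       acq = acquisitionSpec(trMs = 30, teMs = c(5.4, 6.9),
                                             flipAnglesDeg = 20)) {
  if (length(values) == 1) values <- array(values, dims)
  new("FieldMap", values = values, kind = kind,
      spacingMm = spacingMm, originMm = -(dims - 1) / 2 * spacingMm,
      gantryAngleDeg = gantry,
      roi = roiSpec("circle", c(0, 0), roiDiameterMm),
      meta = acq, maskedVoxels = 0L, wrapped = FALSE)
}

# anisotropic/isotropic scaling as a distortion field
scalingField <- function(s) {
  s <- rep(s, length.out = 3)
  function(xyz) xyz %*% diag(s - 1)
}

# voxel-center coordinates of an isocenter-centered axis
gridCoordsOracle <- function(n, dx) (seq_len(n) - (n + 1) / 2) * dx

# acquisition specs used throughout
piqtAcq <- function(matrix = c(192, 192, 1))
  acquisitionSpec(trMs = 1000, teMs = 30, voxelSizeMm = c(1.2, 1.2, 5),
                  matrixSize = matrix)

vfaAcq <- function(fa = c(4, 22))
  acquisitionSpec(trMs = 20, teMs = 2.3, flipAnglesDeg = fa,
                  voxelSizeMm = c(2, 2, 3), matrixSize = c(160, 160, 1))

meseAcq <- function()
  acquisitionSpec(trMs = 4000, teMs = seq(22, 99, by = 11),
                  voxelSizeMm = c(2, 2, 3), matrixSize = c(160, 160, 1))

dwiAcq <- function()
  acquisitionSpec(trMs = 15000, teMs = 149, bValues = c(0, 500, 900, 2000),
                  voxelSizeMm = c(1.5625, 1.5625, 4),
                  matrixSize = c(128, 128, 1))

b0Acq <- function(te = c(5.4, 6.9), gantry = 0)
  acquisitionSpec(trMs = 30, teMs = te, flipAnglesDeg = 20,
                  voxelSizeMm = c(3, 3, 10), matrixSize = c(150, 150, 1),
                  gantryAngleDeg = gantry)

b1Acq <- function()
  acquisitionSpec(trMs = 30, tr2Ms = 150, teMs = 2, flipAnglesDeg = 60,
                  voxelSizeMm = c(4, 4, 12), matrixSize = c(100, 100, 1))

# small fiducial phantom (3 plates, reduced radius) for fast tests
smallFiducialSpec <- function()
  phantomSpec("fiducial3d", geometry = list(nPlates = 3, plateRadiusMm = 80))

# session fits for the Monte-Carlo envelope checks
mcSessionFits <- function(spec, truth, acq, mode, fitfun, noiseSd, nSessions,
                          seed0 = 1000L) {
  lapply(seq_len(nSessions), function(s) {
    tr <- truth
    tr@noiseSd <- noiseSd
    tr@seed <- seed0 + s
    fitfun(generateQmriSeries(spec, acq, tr, mode))
  })
}
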