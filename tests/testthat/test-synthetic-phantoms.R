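test_that("noiseless generation is exact: background, object and signal equations", {
  # grid section: background exactly 0, hole interiors exactly 100
  g <- phantomSpec("piqt_grid")
  img <- generatePiqtImages(g, piqtAcq(), groundTruth())
  v <- voxelData(img)
  expect_equal(min(v), 0)
  expect_equal(max(v), 100)
  # a voxel at a hole center is fully covered; far corner is background
  d <- dim(v)
  ctr <- (d[1:2] + 1) / 2
  expect_equal(v[ctr[1], ctr[2], 1], 100)
  expect_equal(v[2, 2, 1], 0)

  # vial series reproduce the signal equations literally (independent
  # scalar evaluation, frozen):
  #   spoiled GRE  T1 = 1000 ms, TR = 20 ms, a = 22 deg, S0 = 1000 -> 81.3563
  #   spin echo    T2 = 100 ms, TE = 100 ms, S0 = 500       -> 183.9397
  #   diffusion    ADC = 1.1e-3, b = 900, S0 = 1000          -> 371.5767
  expect_equal(spgrSignal(1000, 22, 20, 1000), 81.3562647113, tolerance = 1e-9)
  expect_equal(meseSignal(500, 100, 100), 183.939720586, tolerance = 1e-9)
  expect_equal(dwiSignal(1000, 900, 1.1e-3), 371.576691022, tolerance = 1e-9)

  spec <- phantomSpec("vial_array", objectSignal = 1000)
  truth <- groundTruth(t1Ms = rep(1000, 14), t2Ms = rep(100, 14))
  ser <- generateQmriSeries(spec, vfaAcq(c(4, 22)), truth, "vfa")
  ctrs <- vialCenters(spec)
  co <- seq(-159, 159, by = 2)  # voxel centers at 2 mm spacing, 160 matrix
  i <- which.min(abs(co - ctrs$x[1])); j <- which.min(abs(co - ctrs$y[1]))
  expect_equal(voxelData(ser[[2]])[i, j, 1], 81.3562647113, tolerance = 1e-9)
})

test_that("wedge image encodes the slice profile via the wedge slope", {
  # slope 0.2 projects a 5 mm slab onto 25 mm in-plane: at 1 mm pixels the
  # projected profile is 25 pixels wide at half maximum (ray-trace oracle)
  acq <- acquisitionSpec(trMs = 1000, teMs = 30, voxelSizeMm = c(1, 1, 5),
                         matrixSize = c(200, 200, 1))
  w <- phantomSpec("piqt_wedge")
  img <- generatePiqtImages(w, acq, groundTruth())
  v <- voxelData(img)[, , 1]
  co <- gridCoordsOracle(200, 1)
  iny <- co >= 5 & co <= 35
  prof <- rowMeans(v[, iny])
  # in-plane width at half maximum in pixels
  above <- which(prof >= max(prof) / 2)
  widthPx <- diff(range(above))
  expect_equal(widthPx, 25, tolerance = 0.08)  # within one interpolation px
  sp <- computeSliceProfile(img, w)
  expect_equal(sp$wedgeA@fwhmMm, 5, tolerance = 1e-6)
})

test_that("undistorted grid hole centroids sit on the 25 mm lattice", {
  g <- phantomSpec("piqt_grid")
  img <- generatePiqtImages(g, piqtAcq(), groundTruth())
  d <- dim(voxelData(img))
  xs <- (seq_len(d[1]) - (d[1] + 1) / 2) * 1.2
  cent <- mrlqa:::detectBlobs2d(voxelData(img)[, , 1], xs, xs)
  expect_equal(nrow(cent), 45L)
  # nearest-neighbour spacing of the recovered lattice is 25 mm
  nn <- apply(as.matrix(dist(cent)) + diag(Inf, 45), 1, min)
  expect_equal(unname(nn), rep(25, 45), tolerance = 2e-3)
})

test_that("fiducial phantom has 1932 markers on 7 plates 55 mm apart", {
  known <- fiducialGridPositions(phantomSpec("fiducial3d"))
  expect_equal(nrow(known), 1932L)
  plates <- sort(unique(known[, 3]))
  expect_length(plates, 7L)
  expect_equal(diff(plates), rep(55, 6))
  expect_equal(plates[4], 0)  # central plate at isocenter
})

test_that("rendered marker centroids match known + field positions", {
  # identity field: every centroid within 0.05 voxel of its known position
  spec <- smallFiducialSpec()
  gen <- generateFiducialVolume(spec, groundTruth())
  det <- detectMarkers(gen$volume, knownPositions(gen$markers), align = FALSE)
  expect_equal(nrow(det@unpairedKnownMm), 0L)
  err <- sqrt(rowSums(distortionVectors(det)^2))
  expect_lt(max(err), 0.05 * 2.5)

  # radial r^3 field: centroid displacement equals the analytic field at
  # each marker within 0.1 voxel
  k <- 2 / 250^3
  truth <- groundTruth(distortionFieldMm = radialCubicField(k))
  gen2 <- generateFiducialVolume(spec, truth)
  det2 <- detectMarkers(gen2$volume, knownPositions(gen2$markers),
                        align = FALSE)
  analytic <- radialCubicField(k)(knownPositions(det2))
  err2 <- sqrt(rowSums((distortionVectors(det2) - analytic)^2))
  expect_lt(max(err2), 0.1 * 2.5)
})

test_that("excessive distortion is refused as ambiguous matching", {
  expect_error(
    generateFiducialVolume(smallFiducialSpec(),
                           groundTruth(distortionFieldMm = constantField(c(14, 0, 0)))),
    "ambiguous matching")
})

test_that("B0 series carries the closed-form phase difference and wrap flag", {
  cyl <- phantomSpec("cylinder")
  tr50 <- groundTruth(b0FieldHz = function(x, y, z, g = 0) rep(50, length(x)))
  ser <- generateFieldSeries(cyl, b0Acq(), tr50, "b0_dual_echo")
  dphi <- mrlqa:::wrapPhase(voxelData(ser$phase2) - voxelData(ser$phase1))
  # 2 pi * 50 Hz * 1.5 ms = 0.4712389 rad, everywhere
  expect_equal(range(dphi), rep(0.471238898038, 2), tolerance = 1e-9)
  expect_false(isTRUE(ser$phase1@annotations$wrapped))

  tr400 <- groundTruth(b0FieldHz = function(x, y, z, g = 0) rep(400, length(x)))
  expect_warning(ser2 <- generateFieldSeries(cyl, b0Acq(), tr400,
                                             "b0_dual_echo"),
                 "wrapping")
  expect_true(ser2$phase1@annotations$wrapped)
})

test_that("dual-TR series encodes the actual flip angle in the magnitude ratio", {
  cyl <- phantomSpec("cylinder")
  # b1_fraction = 1: ratio equals the nominal-angle model
  ser <- generateFieldSeries(cyl, b1Acq(),
                             groundTruth(b1Fraction = function(x, y, z)
                               rep(1, length(x))), "b1_dual_tr")
  b1 <- reconstructB1(ser$trShort, ser$trLong, nominalFaDeg = 60)
  vals <- voxelData(b1)[!is.na(voxelData(b1))]
  expect_equal(range(vals), c(100, 100), tolerance = 1e-9)

  # b1_fraction = 0.9 at nominal 60: ratio equals the model at 54 degrees
  ser2 <- generateFieldSeries(cyl, b1Acq(),
                              groundTruth(b1Fraction = function(x, y, z)
                                rep(0.9, length(x))), "b1_dual_tr")
  i <- 50; j <- 50
  r <- voxelData(ser2$trLong)[i, j, 1] / voxelData(ser2$trShort)[i, j, 1]
  expect_equal(r, 0.704917258559, tolerance = 1e-9)  # (1+5cos54)/(5+cos54)
})

test_that("magnitude background noise is Rayleigh (mean/SD ~ 1.913)", {
  set.seed(11)
  bg <- addRicianNoise(array(0, c(150, 150, 1)), sd = 3)
  expect_equal(mean(bg) / sd(bg), sqrt(pi / 2) / sqrt(2 - pi / 2),
               tolerance = 0.02)
})

test_that("identical seeds give bit-identical volumes; different seeds differ", {
  g <- phantomSpec("piqt_grid")
  a <- generatePiqtImages(g, piqtAcq(), groundTruth(noiseSd = 2, seed = 5L))
  b <- generatePiqtImages(g, piqtAcq(), groundTruth(noiseSd = 2, seed = 5L))
  c <- generatePiqtImages(g, piqtAcq(), groundTruth(noiseSd = 2, seed = 6L))
  expect_identical(voxelData(a), voxelData(b))
  expect_false(identical(voxelData(a), voxelData(c)))
})

test_that("invalid specifications are rejected", {
  expect_error(generatePiqtImages(phantomSpec("piqt_grid"),
    acquisitionSpec(matrixSize = c(0, 10, 1)), groundTruth()))
  expect_error(phantomSpec("piqt_grid", geometry = list(holeDiameterMm = -1)))
  expect_error(groundTruth(t1Ms = c(100, 200), t2Ms = c(150, 100)),
               "t1 > t2")
  expect_error(acquisitionSpec(trMs = 10, teMs = c(20, 30)))
  expect_error(generateQmriSeries(phantomSpec("vial_array"),
    vfaAcq(fa = 22), defaultVialTruth("relaxometry"), "vfa"),
    "2 distinct flip angles|flip")
})

test_that("noiseless forward generation + estimator recovers every vial exactly", {
  # exactness of the forward/inverse pair, all three biomarkers
  specR <- phantomSpec("vial_array", geometry = list(layout = "relaxometry"))
  truthR <- defaultVialTruth("relaxometry")
  ctrR <- vialCenters(specR)

  fitT1 <- fitT1Vfa(generateQmriSeries(specR, vfaAcq(), truthR, "vfa"))
  repT1 <- vialReport(list(fitT1), truthR@t1Ms, ctrR)
  expect_lt(max(abs(summaryTable(repT1)$bias_percent)), 1e-4 * 0.01)

  fitT2 <- fitT2Mese(generateQmriSeries(specR, meseAcq(), truthR, "mese"))
  repT2 <- vialReport(list(fitT2), truthR@t2Ms, ctrR)
  expect_lt(max(abs(summaryTable(repT2)$bias_percent)), 1e-4 * 0.01)

  specD <- phantomSpec("vial_array", geometry = list(layout = "diffusion"))
  truthD <- defaultVialTruth("diffusion")
  fitD <- fitAdc(generateQmriSeries(specD, dwiAcq(), truthD, "dwi"))
  repD <- vialReport(list(fitD), truthD@adc, vialCenters(specD))
  expect_lt(max(abs(summaryTable(repD)$bias_percent)), 1e-4 * 0.01)
})

test_that("volumes round-trip through NIfTI + sidecar", {
  acq <- vfaAcq()
  vol <- imageVolume(array(rnorm(60), c(5, 4, 3)), spacingMm = c(2, 2, 3),
                     meta = acq, annotations = list(flipDeg = 4))
  f <- tempfile(fileext = ".nii")
  writeImageVolume(vol, f)
  back <- readImageVolume(f)
  expect_equal(voxelData(back), voxelData(vol))
  expect_equal(voxelSpacing(back), voxelSpacing(vol))
  expect_equal(voxelOrigin(back), voxelOrigin(vol))
  expect_equal(back@meta@flipAnglesDeg, c(4, 22))
  expect_equal(back@annotations$flipDeg, 4)
  unlink(c(f, mrlqa:::sidecarPath(f)))
})
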