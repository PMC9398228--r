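test_that("SNR is the ROI mean over the background noise estimate", {
  v <- matrix(0, 60, 60)
  v[21:40, 21:40] <- 100
  set.seed(3)
  bgNoise <- rnorm(60 * 60, sd = 2)
  v[v == 0] <- abs(bgNoise[v == 0])
  img <- mkVol(v)
  sroi <- roiSpec("rectangle", c(0, 0), extentsMm = c(10, 10))
  nroi <- roiSpec("rectangle", c(-22, -22), extentsMm = c(12, 12))
  sdBg <- sd(voxelData(img)[mrlqa:::roiMask(img, nroi)])
  expect_equal(computeSNR(img, sroi, nroi, rayleighCorrect = FALSE),
               100 / sdBg, ignore_attr = TRUE)
  expect_equal(computeSNR(img, sroi, nroi, rayleighCorrect = TRUE),
               100 / (sdBg / 0.655), ignore_attr = TRUE)
  # noiseless image: undefined SNR
  flat <- mkVol(matrix(c(rep(100, 1800), rep(0, 1800)), 60, 60))
  expect_error(computeSNR(flat, sroi, nroi), "undefined SNR")
  # overlapping ROIs rejected
  expect_error(computeSNR(img, sroi, roiSpec("rectangle", c(2, 2),
                                             extentsMm = c(10, 10))),
               "disjoint")
})

test_that("Monte-Carlo SNR estimate recovers the generator truth", {
  # complex-noise SD set so the true SNR is 69.3; mean of 50 corrected
  # estimates within 3%
  cy <- phantomSpec("cylinder", geometry = list(cylinderDiameterMm = 300))
  acq <- b0Acq()
  sroi <- roiSpec("circle", c(0, 0), 100)
  nroi <- roiSpec("rectangle", c(185, 185), extentsMm = c(80, 80))
  est <- vapply(1:50, function(i) {
    img <- generateCylinderImage(cy, acq,
                                 groundTruth(noiseSd = 100 / 69.3, seed = i))
    computeSNR(img, sroi, nroi)
  }, numeric(1))
  expect_equal(mean(est), 69.3, tolerance = 0.03)
})

test_that("uniformity follows (max - min)/(max + min) x 100", {
  roi <- roiSpec("rectangle", c(0, 0), extentsMm = c(20, 20))
  expect_equal(computeUniformity(mkVol(matrix(5, 30, 30)), roi), 0)
  v <- matrix(1, 30, 30); v[15, 15] <- 2
  expect_equal(computeUniformity(mkVol(v), roi, smoothingMm = 0),
               (2 - 1) / (2 + 1) * 100, tolerance = 1e-12)
  # imposed linear shading with max = 1.25 min -> 11.11% (closed form);
  # the ROI covers the full shaded region so both extremes are sampled
  ramp <- matrix(rep(seq(1, 1.25, length.out = 30), each = 30), 30, 30)
  full <- roiSpec("rectangle", c(0, 0), extentsMm = c(29, 29))
  expect_equal(computeUniformity(mkVol(ramp), full, smoothingMm = 0),
               0.25 / 2.25 * 100, tolerance = 1e-9)
  expect_error(computeUniformity(mkVol(matrix(0, 30, 30)), roi,
                                 smoothingMm = 0), "undefined uniformity")
  # invariance to global intensity scaling
  expect_equal(computeUniformity(mkVol(3.7 * ramp), full, smoothingMm = 0),
               computeUniformity(mkVol(ramp), full, smoothingMm = 0))
})

test_that("linearity recovers imposed scalings along all eight directions", {
  g <- phantomSpec("piqt_grid")
  idn <- computeLinearity(generatePiqtImages(g, piqtAcq(), groundTruth()), g)
  expect_lt(idn$maxAbsPercent, 0.05)

  iso <- computeLinearity(generatePiqtImages(g, piqtAcq(),
    groundTruth(distortionFieldMm = scalingField(c(1.005, 1.005, 1)))), g)
  expect_equal(unname(iso$perDirection), rep(0.5, 8), tolerance = 0.05)

  an <- computeLinearity(generatePiqtImages(g, piqtAcq(),
    groundTruth(distortionFieldMm = scalingField(c(1.003, 0.999, 1)))), g)
  diag <- 100 * (sqrt((1.003^2 + 0.999^2) / 2) - 1)
  want <- c(N = -0.1, NE = diag, E = 0.3, SE = diag,
            S = -0.1, SW = diag, W = 0.3, NW = diag)
  expect_lt(max(abs(an$perDirection[names(want)] - want)), 0.05)
  # translation insensitivity
  shift <- computeLinearity(generatePiqtImages(g, piqtAcq(),
    groundTruth(distortionFieldMm = constantField(c(4, -3, 0)))), g)
  expect_lt(shift$maxAbsPercent, 0.05)
})

test_that("missing grid holes raise a detection failure naming the nodes", {
  g <- phantomSpec("piqt_grid")
  img <- generatePiqtImages(g, piqtAcq(), groundTruth())
  v <- voxelData(img)
  # blank the hole at (+75, +50) mm
  xs <- gridCoordsOracle(192, 1.2)
  sel <- abs(xs - 75) < 5
  sel2 <- abs(xs - 50) < 5
  v[sel, sel2, 1] <- 0
  expect_error(computeLinearity(mkVol(v[, , 1], spacingMm = c(1.2, 1.2, 5)), g),
               "missing grid nodes.*75")
})

test_that("slice profile FWHM and integral match closed forms", {
  w <- phantomSpec("piqt_wedge")
  sp <- computeSliceProfile(generatePiqtImages(w, piqtAcq(), groundTruth()), w)
  expect_equal(sp$wedgeA@fwhmMm, 5, tolerance = 1e-6)
  expect_equal(sp$wedgeA@integralMm, 5, tolerance = 2e-3)
  expect_equal(sp$wedgeB@fwhmMm, 5, tolerance = 1e-6)

  # Gaussian slab of SD sigma: FWHM = 2.355 sigma, integral = 2.507 sigma
  sigma <- 2
  wg <- phantomSpec("piqt_wedge",
                    geometry = list(profileShape = "gaussian",
                                    profileSigmaMm = sigma))
  spg <- computeSliceProfile(generatePiqtImages(wg, piqtAcq(), groundTruth()),
                             wg)
  expect_equal(spg$wedgeA@fwhmMm, 2 * sqrt(2 * log(2)) * sigma,
               tolerance = 0.01)
  expect_equal(spg$wedgeA@integralMm, sqrt(2 * pi) * sigma, tolerance = 0.01)

  # a simulated 4.93 mm slab lands inside the published window 4.65-5.15
  w493 <- phantomSpec("piqt_wedge", geometry = list(sliceThicknessMm = 4.93))
  sp493 <- computeSliceProfile(generatePiqtImages(w493, piqtAcq(),
                                                  groundTruth()), w493)
  expect_true(sp493$wedgeA@fwhmMm >= 4.65 && sp493$wedgeA@fwhmMm <= 5.15)

  expect_error(computeSliceProfile(mkVol(matrix(1, 192, 192),
                                         spacingMm = c(1.2, 1.2, 5)), w),
               "low contrast")
})

test_that("pixel size is the LSF FWHM and tracks discrete blur exactly", {
  e <- phantomSpec("piqt_edge")
  px <- computePixelSize(generatePiqtImages(e, piqtAcq(), groundTruth()), e)
  expect_equal(unname(px["horizontalMm"]), 1.2, tolerance = 1e-9)
  expect_equal(unname(px["verticalMm"]), 1.2, tolerance = 1e-9)
  expect_lt(px[["horizontalMm"]], 1.3)  # published echo-1 tolerance

  # edge blurred by a 1-pixel boxcar: FWHM grows by exactly one sample
  n <- 100
  step <- c(rep(0, 49), rep(1, 51))
  blurred <- stats::filter(c(0, step), rep(0.5, 2), sides = 1)[-1]
  v <- matrix(rep(blurred, n), n, n) * 100
  v <- v * t(v) / 100  # same edge along both axes
  img <- mkVol(v, spacingMm = c(1.2, 1.2, 5))
  px2 <- computePixelSize(img, e)
  expect_equal(unname(px2["horizontalMm"]), 2 * 1.2, tolerance = 1e-9)

  expect_error(computePixelSize(mkVol(matrix(1, n, n)), e), "no edge")
})

test_that("central-frequency deviation is reported in percent and ppm", {
  acq <- acquisitionSpec()
  nominal <- nominalFrequencyMHz(acq)
  expect_equal(nominal, 42.577478518 * 1.5)
  expect_equal(centralFrequencyCheck(acq, nominal)$deviationPercent, 0)
  lowered <- centralFrequencyCheck(acq, nominal * (1 - 0.018 / 100))
  expect_equal(lowered$deviationPercent, -0.018, tolerance = 1e-9)
  expect_equal(centralFrequencyCheck(acq, nominal * (1 - 5e-6))$deviationPpm,
               -5, tolerance = 1e-9)
})

test_that("SNR is invariant to joint signal/noise scaling", {
  set.seed(9)
  v <- matrix(abs(rnorm(3600, sd = 2)), 60, 60)
  v[21:40, 21:40] <- 100
  img1 <- mkVol(v); img2 <- mkVol(7 * v)
  sroi <- roiSpec("rectangle", c(0, 0), extentsMm = c(10, 10))
  nroi <- roiSpec("rectangle", c(-22, -22), extentsMm = c(12, 12))
  expect_equal(computeSNR(img1, sroi, nroi), computeSNR(img2, sroi, nroi),
               ignore_attr = TRUE)
})

test_that("daily metrics reproduce within the stated COV envelope at SNR 50", {
  acq <- piqtAcq()
  cy <- phantomSpec("cylinder", geometry = list(cylinderDiameterMm = 300))
  acqc <- b0Acq()
  w <- phantomSpec("piqt_wedge"); e <- phantomSpec("piqt_edge")
  sroi <- roiSpec("circle", c(0, 0), 100)
  nroi <- roiSpec("rectangle", c(185, 185), extentsMm = c(80, 80))
  uroi <- roiSpec("circle", c(0, 0), 0.75 * 300)
  res <- vapply(1:100, function(i) {
    tr <- groundTruth(noiseSd = 2, seed = i)  # object 100 -> SNR 50
    ci <- generateCylinderImage(cy, acqc, tr)
    sp <- computeSliceProfile(generatePiqtImages(w, acq, tr), w)$wedgeA
    px <- computePixelSize(generatePiqtImages(e, acq, tr), e)
    c(snr = computeSNR(ci, sroi, nroi),
      unif = computeUniformity(ci, uroi),
      fwhm = sp@fwhmMm, integ = sp@integralMm, px = px[["horizontalMm"]])
  }, numeric(5))
  cv <- apply(res, 1, function(x) sd(x) / mean(x) * 100)
  expect_lt(cv[["snr"]], 5)
  expect_lt(cv[["unif"]], 6)
  expect_lt(cv[["fwhm"]], 0.6)
  expect_lt(cv[["integ"]], 1)
  expect_lt(cv[["px"]], 4)
})
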