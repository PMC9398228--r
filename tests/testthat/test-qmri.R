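test_that("two noiseless flip angles determine T1 exactly", {
  acq <- vfaAcq(c(4, 22))
  s <- vapply(c(4, 22), function(fa) spgrSignal(1000, fa, 20, 1000),
              numeric(1))
  series <- lapply(seq_along(s), function(i)
    mkVol(matrix(s[i], 8, 8), meta = acq, annotations = list(flipDeg = c(4, 22)[i])))
  fit <- fitT1Vfa(series)
  expect_true(all(fitMask(fit)))
  expect_equal(unique(as.numeric(parameterMap(fit))), 1000, tolerance = 1e-9)
  expect_equal(unique(as.numeric(fit@s0)), 1000, tolerance = 1e-9)
})

test_that("degenerate VFA inputs are masked or rejected", {
  acq <- vfaAcq(c(4, 13, 22))
  const <- lapply(c(4, 13, 22), function(fa)
    mkVol(matrix(50, 6, 6), meta = acq, annotations = list(flipDeg = fa)))
  fit <- fitT1Vfa(const)
  expect_false(any(fitMask(fit)))
  expect_true(all(is.na(parameterMap(fit))))

  same <- lapply(c(10, 10), function(fa)
    mkVol(matrix(50, 6, 6), meta = acq, annotations = list(flipDeg = fa)))
  expect_error(fitT1Vfa(same), "distinct flip angles")
})

test_that("scaling all signals rescales S0 and leaves parameters unchanged", {
  spec <- phantomSpec("vial_array", geometry = list(layout = "relaxometry"))
  truth <- defaultVialTruth("relaxometry")
  ser <- generateQmriSeries(spec, vfaAcq(), truth, "vfa")
  ser10 <- lapply(ser, function(v) {
    v@voxels <- v@voxels * 10
    v
  })
  f1 <- fitT1Vfa(ser); f10 <- fitT1Vfa(ser10)
  m <- fitMask(f1)
  expect_equal(parameterMap(f10)[m], parameterMap(f1)[m], tolerance = 1e-9)
  expect_equal(f10@s0[m], 10 * f1@s0[m], tolerance = 1e-9)
})

test_that("optimal VFA pair matches a dense grid search and its limits", {
  # TR = 20 ms over the 1000-2000 ms design range: rounds to {4, 22}
  pair <- optimalVfaAngles(c(1000, 2000), trMs = 20)
  expect_equal(round(as.numeric(pair)), c(4, 22))

  # grid-search verification at 0.01 deg for 20 (T1, TR) pairs
  set.seed(4)
  t1s <- round(runif(20, 300, 3000))
  trs <- round(runif(20, 5, 50), 1)
  for (i in seq_along(t1s)) {
    root <- optimalVfaAngles(t1s[i], trs[i])
    e1 <- exp(-trs[i] / t1s[i])
    grid <- seq(0.01, 90, by = 0.01)
    sig <- sin(grid * pi / 180) * (1 - e1) / (1 - cos(grid * pi / 180) * e1)
    ernst <- acos(e1) * 180 / pi
    target <- 0.71 * max(sig)
    lo <- grid[grid < ernst][which.min(abs(sig[grid < ernst] - target))]
    hi <- grid[grid > ernst][which.min(abs(sig[grid > ernst] - target))]
    expect_lt(abs(root[["lowDeg"]] - lo), 0.011)
    expect_lt(abs(root[["highDeg"]] - hi), 0.011)
  }

  # fraction -> 1: both roots converge to the Ernst angle
  p1 <- optimalVfaAngles(1500, 20, signalFraction = 0.999999)
  ernst <- attr(p1, "ernstDeg")
  expect_lt(abs(p1[["lowDeg"]] - ernst), 0.05)
  expect_lt(abs(p1[["highDeg"]] - ernst), 0.05)

  # both roots strictly decrease as T1 grows at fixed TR
  pa <- optimalVfaAngles(1000, 20); pb <- optimalVfaAngles(2000, 20)
  expect_true(all(pb < pa))
})

test_that("MESE fit is exact and the dummy-echo discard is consequential", {
  spec <- phantomSpec("vial_array", objectSignal = 500)
  truth <- groundTruth(t1Ms = rep(500, 14), t2Ms = rep(100, 14))
  ser <- generateQmriSeries(spec, meseAcq(), truth, "mese")
  expect_length(ser, 9L)  # dummy + 8 analysis echoes
  expect_true(ser[[1]]@annotations$dummy)

  fitOn <- fitT2Mese(ser, discardFirst = TRUE)
  rep1 <- vialReport(list(fitOn), truth@t2Ms, vialCenters(spec))
  expect_lt(max(abs(summaryTable(rep1)$bias_percent)), 1e-6)

  # keeping the (stimulated-echo attenuated) dummy echo overestimates T2
  fitOff <- fitT2Mese(ser, discardFirst = FALSE)
  rep0 <- vialReport(list(fitOff), truth@t2Ms, vialCenters(spec))
  expect_true(all(summaryTable(rep0)$bias_percent > 0.5))

  expect_error(fitT2Mese(ser[1:2], discardFirst = TRUE), "2 usable echoes")
})

test_that("ADC fit matches closed forms", {
  spec <- phantomSpec("vial_array", geometry = list(layout = "diffusion"))
  truth <- defaultVialTruth("diffusion")
  ser <- generateQmriSeries(spec, dwiAcq(), truth, "dwi")
  fit <- fitAdc(ser)
  rep1 <- vialReport(list(fit), truth@adc, vialCenters(spec))
  expect_lt(max(abs(summaryTable(rep1)$bias_percent)), 1e-6)

  # two-point closed form: S(1000)/S(0) = e^-1 -> ADC = 1.0e-3
  acq <- acquisitionSpec(trMs = 15000, teMs = 100, bValues = c(0, 1000),
                         voxelSizeMm = c(2, 2, 4), matrixSize = c(6, 6, 1))
  two <- list(mkVol(matrix(200, 6, 6), meta = acq,
                    annotations = list(bValue = 0)),
              mkVol(matrix(200 * exp(-1), 6, 6), meta = acq,
                    annotations = list(bValue = 1000)))
  f2 <- fitAdc(two)
  expect_equal(unique(as.numeric(parameterMap(f2))), 1.0e-3, tolerance = 1e-12)
})

test_that("vial report computes bias and COV per their definitions", {
  mkFit <- function(value) new("QMRIFitResult", parameter = "T1",
    units = "ms", map = array(value, c(20, 20, 1)),
    s0 = array(1, c(20, 20, 1)), r2 = array(1, c(20, 20, 1)),
    mask = array(TRUE, c(20, 20, 1)), spacingMm = c(2, 2, 3),
    originMm = c(-19, -19, 0))
  centers <- cbind(x = c(-8, 8), y = c(0, 0))

  # measured = nominal: all biases zero
  repEq <- vialReport(list(mkFit(100)), c(100, 100), centers)
  expect_equal(summaryTable(repEq)$bias_percent, c(0, 0))
  expect_equal(repEq@summary$median_bias_percent, 0)
  # single session: COV undefined, not zero
  expect_true(all(is.na(summaryTable(repEq)$cov_percent)))

  # session means {100, 101, 99}: COV = sqrt(2/3)/100 x 100 = 0.8165%
  rep3 <- vialReport(list(mkFit(100), mkFit(101), mkFit(99)),
                     c(100, 100), centers)
  expect_equal(summaryTable(rep3)$cov_percent, rep(sqrt(2 / 3), 2),
               tolerance = 1e-9)
  # sample-SD variant gives 1%
  rep3s <- vialReport(list(mkFit(100), mkFit(101), mkFit(99)),
                      c(100, 100), centers, sampleSd = TRUE)
  expect_equal(summaryTable(rep3s)$cov_percent, rep(1, 2), tolerance = 1e-9)
  # bias definition: (measured - nominal)/nominal x 100
  expect_equal(summaryTable(rep3)$bias_percent,
               rep((100 - 100) / 100 * 100, 2))
  repB <- vialReport(list(mkFit(110)), c(100, 100), centers)
  expect_equal(summaryTable(repB)$bias_percent, rep(10, 2))

  expect_error(vialReport(list(mkFit(100)), c(100, 100),
                          cbind(x = c(500, 0), y = c(0, 0))),
               "placement error")
})

test_that("Spearman tests use average ranks and exact permutation p-values", {
  up <- spearmanExact(1:6, c(2, 4, 6, 8, 10, 12))
  expect_equal(up$rho, 1)
  dn <- spearmanExact(1:6, c(9, 7, 5, 4, 2, 1))
  expect_equal(dn$rho, -1)
  expect_equal(dn$pValue, 2 / 720, tolerance = 1e-12)  # 6! orderings
  expect_warning(deg <- spearmanExact(1:6, rep(3, 6)), "degenerate")
  expect_true(is.na(deg$rho))

  # cross-check the permutation route against the reference implementation
  set.seed(8)
  x <- rnorm(7); y <- rnorm(7)
  ours <- spearmanExact(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$pValue, ref$p.value, tolerance = 1e-9)
})

test_that("rank dependence of COV on value carries the expected sign", {
  tb <- data.frame(vial = 1:6, nominal = 1:6,
                   measured_mean = c(0.4, 0.55, 0.7, 0.84, 0.97, 1.1) * 1e-3,
                   bias_percent = c(0.1, -0.2, 0.15, 0.02, -0.1, 0.05),
                   cov_percent = c(2.2, 1.8, 1.3, 1.1, 0.8, 0.5))
  rep1 <- new("VialReport", perSession = tb[0, 0], perVial = tb,
              summary = list(), parameter = "ADC", nSessions = 4L)
  rk <- rankDependenceTests(rep1)
  expect_equal(rk$rho[rk$statistic == "cov"], -1)
  expect_lt(rk$p_value[rk$statistic == "cov"], 0.05)
})
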