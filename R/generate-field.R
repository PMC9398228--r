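#' @include constructors.R utils.R
NULL

#' Default ground truth for the field-mapping cylinder
#'
#' A smooth static B0 field plus a gantry-angle-dependent perturbation
#' peaking at gantry 180 degrees, calibrated so that the raw (no
#' mean-subtraction) peak-to-peak inhomogeneity over the 35-cm analysis
#' region at gantry 180 degrees equals `rawP2pPpmAt180` ppm, with the
#' gantry-induced component an order of magnitude smaller; and a smooth
#' B1 profile whose mean absolute deviation from nominal over the region
#' is `b1MeanDevPercent` percent.
#'
#' @param rawP2pPpmAt180 worst-case raw peak-to-peak B0 inhomogeneity
#'   (ppm), reached at gantry 180 degrees.
#' @param gantryP2pHz peak-to-peak amplitude of the gantry-induced B0
#'   component (Hz) at gantry 180 degrees.
#' @param b1MeanDevPercent mean absolute B1 deviation from nominal (%).
#' @param roiDiameterMm diameter of the analysis region (mm).
#' @param fieldT,gammaMHzPerT nominal field and gyromagnetic ratio, used
#'   to convert ppm to Hz.
#' @param noiseSd,seed noise level and seed passed through.
#' @return a [GroundTruth-class]
#' @export
defaultCylinderTruth <- function(rawP2pPpmAt180 = 3.05, gantryP2pHz = 18,
                                 b1MeanDevPercent = 1.2,
                                 roiDiameterMm = 350, fieldT = 1.5,
                                 gammaMHzPerT = 42.577478518,
                                 noiseSd = 0, seed = 1L) {
  f0MHz <- gammaMHzPerT * fieldT
  Rroi <- roiDiameterMm / 2
  p2pHzAt180 <- rawP2pPpmAt180 * f0MHz    # ppm * MHz = Hz
  staticP2pHz <- p2pHzAt180 - gantryP2pHz
  s0 <- staticP2pHz / 2                   # static: s0 * x/Rroi, range 2*s0
  p0 <- gantryP2pHz / 2                   # gantry: w(theta) * p0 * x/Rroi
  b0 <- function(x, y, z, gantryAngleDeg = 0) {
    w <- (1 - cos(gantryAngleDeg * pi / 180)) / 2   # 0 at 0 deg, 1 at 180 deg
    (s0 + w * p0) * x / Rroi
  }
  dev <- b1MeanDevPercent / 100
  b1 <- function(x, y, z) 1 - dev + 0.1 * dev * x / Rroi
  groundTruth(b0FieldHz = b0, b1Fraction = b1, noiseSd = noiseSd, seed = seed)
}

#' Generate a dual-echo (B0) or dual-TR (B1) field-mapping series
#'
#' `b0_dual_echo` returns the magnitude image and one wrapped phase image
#' per echo, with per-voxel phase 2*pi*f*TE for the ground-truth offset f;
#' if |f| exceeds the unambiguous range 1/(2*dTE) anywhere inside the
#' phantom, the outputs carry a `wrapped = TRUE` annotation.
#' `b1_dual_tr` returns two magnitude images following the long-T1
#' dual-TR (actual flip angle) steady-state pair
#' S1 = S0 sin(a) (n + cos a)/(1 + n), S2 = S0 sin(a) (1 + n cos a)/(1 + n)
#' with n = TR2/TR1 and a = b1Fraction x nominal flip angle, the exact
#' forward model of the ratio inversion in [reconstructB1()].
#'
#' @param spec a [PhantomSpec-class] of kind `"cylinder"`.
#' @param acq an [AcquisitionSpec-class]; B0 mode needs two `teMs`
#'   (default 5.4/6.9 ms), B1 mode needs `trMs`/`tr2Ms` (default 30/150 ms)
#'   and one nominal flip angle (default 60 degrees).
#' @param truth a [GroundTruth-class]; see [defaultCylinderTruth()].
#' @param mode `"b0_dual_echo"` or `"b1_dual_tr"`.
#' @return named list of [ImageVolume-class]: `magnitude`, `phase1`,
#'   `phase2` (B0 mode) or `trShort`, `trLong` (B1 mode).
#' @export
generateFieldSeries <- function(spec, acq, truth = defaultCylinderTruth(),
                                mode = c("b0_dual_echo", "b1_dual_tr")) {
  mode <- match.arg(mode)
  if (spec@kind != "cylinder") stop("spec.kind must be 'cylinder'")
  d <- as.integer(acq@matrixSize)
  sp <- acq@voxelSizeMm
  org <- -(d - 1) / 2 * sp
  co <- gridCoords(d, sp, org)
  R <- spec@geometry$cylinderDiameterMm / 2
  d2 <- outer(co$x^2, co$y^2, "+")
  inside <- diskCoverage(d2, R, min(sp[1:2]))
  mag2d <- spec@backgroundSignal +
    (spec@objectSignal - spec@backgroundSignal) * inside
  X <- matrix(co$x, d[1], d[2])
  Y <- matrix(co$y, d[1], d[2], byrow = TRUE)
  set.seed(truth@seed)

  asVol <- function(m, isPhase = FALSE, ann = list()) {
    imageVolume(array(m, dim = d), spacingMm = sp, originMm = org,
                isPhase = isPhase, meta = acq,
                annotations = c(list(phantom = "cylinder",
                                     gantryAngleDeg = acq@gantryAngleDeg), ann))
  }

  if (mode == "b0_dual_echo") {
    te <- acq@teMs
    if (length(te) < 2) stop("B0 mode needs two echo times")
    fHz <- truth@b0FieldHz(X, Y, 0 * X, acq@gantryAngleDeg)
    dTEs <- (te[2] - te[1]) / 1000
    wrapped <- any(abs(fHz[inside > 0.5]) > 1 / (2 * dTEs))
    if (wrapped)
      warning("true field exceeds the unambiguous range 1/(2*dTE); ",
              "wrapping present")
    vols <- list(magnitude = NULL, phase1 = NULL, phase2 = NULL)
    phases <- lapply(te[1:2], function(t) wrapPhase(2 * pi * fHz * t / 1000))
    if (truth@noiseSd > 0) {
      # complex noise applied to each echo, magnitude taken from echo 1
      noisy <- lapply(phases, function(ph) {
        re <- mag2d * cos(ph) + stats::rnorm(length(ph), sd = truth@noiseSd)
        im <- mag2d * sin(ph) + stats::rnorm(length(ph), sd = truth@noiseSd)
        list(mag = sqrt(re^2 + im^2),
             ph = matrix(atan2(im, re), d[1], d[2]))
      })
      mag2d <- noisy[[1]]$mag
      phases <- lapply(noisy, `[[`, "ph")
    }
    list(magnitude = asVol(mag2d, ann = list(wrapped = wrapped)),
         phase1 = asVol(phases[[1]], isPhase = TRUE,
                        ann = list(teMs = te[1], wrapped = wrapped)),
         phase2 = asVol(phases[[2]], isPhase = TRUE,
                        ann = list(teMs = te[2], wrapped = wrapped)))
  } else {
    if (is.na(acq@trMs) || is.na(acq@tr2Ms)) stop("B1 mode needs trMs and tr2Ms")
    if (length(acq@flipAnglesDeg) != 1) stop("B1 mode needs one nominal flip angle")
    n <- acq@tr2Ms / acq@trMs
    alpha <- truth@b1Fraction(X, Y, 0 * X) * acq@flipAnglesDeg * pi / 180
    s1 <- mag2d * sin(alpha) * (n + cos(alpha)) / (1 + n)
    s2 <- mag2d * sin(alpha) * (1 + n * cos(alpha)) / (1 + n)
    s1 <- addRicianNoise(s1, truth@noiseSd)
    s2 <- addRicianNoise(s2, truth@noiseSd)
    list(trShort = asVol(s1, ann = list(trMs = acq@trMs)),
         trLong = asVol(s2, ann = list(trMs = acq@tr2Ms)))
  }
}

#' Generate a full gantry sweep of field-mapping series
#'
#' Calls [generateFieldSeries()] once per gantry angle (default 0 to 330
#' degrees in steps of 30) with the angle recorded in the metadata.
#'
#' @inheritParams generateFieldSeries
#' @param anglesDeg gantry angles (degrees).
#' @return named list (one element per angle) of series lists.
#' @export
generateGantrySeries <- function(spec, acq, truth = defaultCylinderTruth(),
                                 mode = c("b0_dual_echo", "b1_dual_tr"),
                                 anglesDeg = seq(0, 330, by = 30)) {
  mode <- match.arg(mode)
  out <- lapply(anglesDeg, function(a) {
    acqA <- acq
    acqA@gantryAngleDeg <- a
    tr <- truth
    tr@seed <- truth@seed + as.integer(a)
    generateFieldSeries(spec, acqA, tr, mode)
  })
  names(out) <- paste0("gantry", anglesDeg)
  out
}
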