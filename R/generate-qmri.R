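#' @include constructors.R utils.R
NULL

#' Vial center layout of a quantitative phantom
#'
#' `"relaxometry"`: 14 spherical vials equally spaced on a 60-mm-radius
#' ring (one plane of the two-plate relaxometry phantom).
#' `"diffusion"`: 13 cylindrical vials, one at center plus two concentric
#' rings of six (radii 30 and 65 mm), each ring spanning the full
#' concentration range; the center vial is counted in the inner ring.
#'
#' @param spec a [PhantomSpec-class] of kind `"vial_array"` whose
#'   `geometry$layout` is `"relaxometry"` or `"diffusion"`.
#' @return data.frame with columns `vial`, `x`, `y` (mm) and `ring`
#'   (`"inner"`/`"outer"`).
#' @export
vialCenters <- function(spec) {
  if (spec@kind != "vial_array") stop("spec.kind must be 'vial_array'")
  layout <- spec@geometry$layout
  if (layout == "relaxometry") {
    n <- 14L
    th <- 2 * pi * (seq_len(n) - 1) / n
    data.frame(vial = seq_len(n), x = 60 * cos(th), y = 60 * sin(th),
               ring = "inner", stringsAsFactors = FALSE)
  } else if (layout == "diffusion") {
    th <- 2 * pi * (0:5) / 6
    data.frame(vial = 1:13,
               x = c(0, 30 * cos(th), 65 * cos(th + pi / 6)),
               y = c(0, 30 * sin(th), 65 * sin(th + pi / 6)),
               ring = c("inner", rep("inner", 6), rep("outer", 6)),
               stringsAsFactors = FALSE)
  } else stop("unknown vial layout: ", layout)
}

#' Default synthetic vial ground truth
#'
#' Synthetic stand-ins for the (user-supplied) nominal vial values of the
#' physical phantoms: 14 relaxometry vials with T1 log-spaced over
#' 500-2000 ms and T2 = T1/5 (so t1 > t2 always), and 13 diffusion vials
#' spanning ADC 0.4e-3 to 1.1e-3 mm^2/s with the full range in each ring.
#'
#' @param layout `"relaxometry"` or `"diffusion"`.
#' @param noiseSd,seed noise level and seed passed through.
#' @return a [GroundTruth-class]
#' @export
defaultVialTruth <- function(layout = c("relaxometry", "diffusion"),
                             noiseSd = 0, seed = 1L) {
  layout <- match.arg(layout)
  if (layout == "relaxometry") {
    t1 <- exp(seq(log(500), log(2000), length.out = 14))
    groundTruth(t1Ms = t1, t2Ms = t1 / 5, noiseSd = noiseSd, seed = seed)
  } else {
    adcRange <- seq(0.4e-3, 1.1e-3, length.out = 6)
    groundTruth(adc = c(1.1e-3, adcRange, adcRange),
                noiseSd = noiseSd, seed = seed)
  }
}

# signal equations -------------------------------------------------------------

#' Spoiled steady-state gradient-echo signal
#'
#' S = S0 sin(a) (1 - E1) / (1 - cos(a) E1), E1 = exp(-TR/T1).
#' @param s0 equilibrium signal (a.u.).
#' @param flipDeg flip angle (degrees).
#' @param trMs repetition time (ms).
#' @param t1Ms longitudinal relaxation time (ms).
#' @return signal (a.u.)
#' @export
spgrSignal <- function(s0, flipDeg, trMs, t1Ms) {
  a <- flipDeg * pi / 180
  e1 <- exp(-trMs / t1Ms)
  s0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Mono-exponential spin-echo decay, S = S0 exp(-TE/T2)
#' @param s0 signal at TE = 0; @param teMs echo time (ms);
#' @param t2Ms transverse relaxation time (ms).
#' @return signal (a.u.)
#' @export
meseSignal <- function(s0, teMs, t2Ms) s0 * exp(-teMs / t2Ms)

#' Mono-exponential diffusion decay, S = S0 exp(-b ADC)
#' @param s0 signal at b = 0; @param b diffusion weighting (s/mm^2);
#' @param adc apparent diffusion coefficient (mm^2/s).
#' @return signal (a.u.)
#' @export
dwiSignal <- function(s0, b, adc) s0 * exp(-b * adc)

#' Noise level giving a target image SNR for a qMRI series
#'
#' The complex-noise SD that makes the generated images carry the stated
#' SNR: the mean noiseless vial signal across all vials and all members
#' of the series (flip angles / echoes / b-values), divided by the target
#' SNR. Spoiled gradient-echo and strongly weighted diffusion images have
#' signals far below the equilibrium S0, so referencing noise to the
#' *image* signal, not S0, is what "image SNR" means on a scanner.
#'
#' @inheritParams generateQmriSeries
#' @param imageSnr target image signal-to-noise ratio.
#' @param roiDiameterMm ROI used to sample the vial signal (mm).
#' @return noise SD (a.u.) to place in [groundTruth()]
#' @export
qmriNoiseSd <- function(spec, acq, truth, mode, imageSnr,
                        roiDiameterMm = 10) {
  tr0 <- truth
  tr0@noiseSd <- 0
  ser <- generateQmriSeries(spec, acq, tr0, mode)
  ctr <- vialCenters(spec)
  d <- dim(ser[[1]]@voxels)
  co <- gridCoords(d, ser[[1]]@spacingMm, ser[[1]]@originMm)
  kSlice <- (d[3] + 1L) %/% 2L
  masks <- lapply(seq_len(nrow(ctr)), function(v)
    outer((co$x - ctr$x[v])^2, (co$y - ctr$y[v])^2, "+") <=
      (roiDiameterMm / 2)^2)
  ref <- mean(vapply(ser, function(vol) {
    sl <- vol@voxels[, , kSlice]
    mean(vapply(masks, function(m) mean(sl[m]), numeric(1)))
  }, numeric(1)))
  ref / imageSnr
}

#' Generate a quantitative-MRI image series from a vial phantom
#'
#' Per-voxel signals follow the stated signal equation exactly before
#' Rician noise is applied. In `"mese"` mode one dummy echo (one echo
#' spacing before the first analysis echo) is prepended, annotated
#' `dummy = TRUE`, and carries a stimulated-echo-like relative attenuation
#' so that the discard rule is consequential.
#'
#' @param spec a [PhantomSpec-class] of kind `"vial_array"`.
#' @param acq an [AcquisitionSpec-class]: `flipAnglesDeg` + `trMs` for
#'   `"vfa"`, `teMs` for `"mese"`, `bValues` for `"dwi"`.
#' @param truth a [GroundTruth-class] with per-vial `t1Ms`/`t2Ms`/`adc`.
#' @param mode `"vfa"`, `"mese"` or `"dwi"`.
#' @param dummyEchoBias multiplicative bias on the dummy echo (mese only).
#'   The default 0.95 leaves the dummy echo 5% below the mono-exponential
#'   train, emulating the stimulated-echo elevation that all echoes after
#'   the first acquire in a multi-echo train; fitting without discarding
#'   it therefore overestimates T2.
#' @return list of [ImageVolume-class], one per flip angle / echo /
#'   b-value, annotated with the varying parameter.
#' @export
generateQmriSeries <- function(spec, acq, truth, mode = c("vfa", "mese", "dwi"),
                               dummyEchoBias = 0.95) {
  mode <- match.arg(mode)
  if (spec@kind != "vial_array") stop("spec.kind must be 'vial_array'")
  centers <- vialCenters(spec)
  nV <- nrow(centers)
  vialR <- spec@geometry$vialDiameterMm / 2
  bodyR <- spec@geometry$bodyDiameterMm / 2
  if (any(sqrt(centers$x^2 + centers$y^2) + vialR > bodyR))
    stop("vial centers must lie inside the phantom body")

  d <- as.integer(acq@matrixSize)
  sp <- acq@voxelSizeMm
  org <- -(d - 1) / 2 * sp
  co <- gridCoords(d, sp, org)
  ramp <- min(sp[1:2])
  cov <- lapply(seq_len(nV), function(v) {
    d2 <- outer((co$x - centers$x[v])^2, (co$y - centers$y[v])^2, "+")
    diskCoverage(d2, vialR, ramp)
  })

  vialValues <- switch(mode,
    vfa = {
      if (length(truth@t1Ms) != nV) stop("need one t1Ms per vial")
      if (length(unique(acq@flipAnglesDeg)) < 2)
        stop("insufficient series: need >= 2 distinct flip angles")
      list(param = truth@t1Ms, vary = acq@flipAnglesDeg, key = "flipDeg")
    },
    mese = {
      if (length(truth@t2Ms) != nV) stop("need one t2Ms per vial")
      if (length(acq@teMs) < 2)
        stop("insufficient series: need >= 2 echoes")
      list(param = truth@t2Ms, vary = acq@teMs, key = "teMs")
    },
    dwi = {
      if (length(truth@adc) != nV) stop("need one adc per vial")
      if (length(acq@bValues) < 2)
        stop("insufficient series: need >= 2 b-values")
      list(param = truth@adc, vary = acq@bValues, key = "bValue")
    })

  vary <- vialValues$vary
  dummy <- logical(length(vary))
  bias <- rep(1, length(vary))
  if (mode == "mese") {
    dTE <- if (length(vary) >= 2) vary[2] - vary[1] else vary[1] / 2
    vary <- c(vary[1] - dTE, vary)
    dummy <- c(TRUE, logical(length(vary) - 1))
    bias <- c(dummyEchoBias, rep(1, length(vary) - 1))
  }

  s0 <- spec@objectSignal
  set.seed(truth@seed)
  vols <- vector("list", length(vary))
  for (j in seq_along(vary)) {
    img <- matrix(spec@backgroundSignal, d[1], d[2])
    for (v in seq_len(nV)) {
      sig <- switch(mode,
        vfa = spgrSignal(s0, vary[j], acq@trMs, vialValues$param[v]),
        mese = meseSignal(s0, vary[j], vialValues$param[v]) * bias[j],
        dwi = dwiSignal(s0, vary[j], vialValues$param[v]))
      img <- img + sig * cov[[v]]
    }
    vox <- addRicianNoise(array(img, dim = d), truth@noiseSd)
    ann <- list(phantom = "vial_array", mode = mode, dummy = dummy[j])
    ann[[vialValues$key]] <- vary[j]
    vols[[j]] <- imageVolume(vox, spacingMm = sp, originMm = org, meta = acq,
                             annotations = ann)
  }
  names(vols) <- paste0(vialValues$key, "_", signif(vary, 6))
  vols
}
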