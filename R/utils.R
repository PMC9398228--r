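#' @include AllClasses.R
NULL

# world coordinate of each voxel center along one axis
axisCoords <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing

# list(x=, y=, z=) of per-axis voxel-center coordinates for a volume-like
# object given dim/spacing/origin
gridCoords <- function(dims, spacingMm, originMm) {
  list(x = axisCoords(dims[1], spacingMm[1], originMm[1]),
       y = axisCoords(dims[2], spacingMm[2], originMm[2]),
       z = axisCoords(dims[3], spacingMm[3], originMm[3]))
}

# wrap phase to (-pi, pi]
wrapPhase <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Add Rician magnitude noise to a noiseless signal
#'
#' Independent Gaussian noise of standard deviation `sd` is added to the
#' real and imaginary channel of the (real-valued) noiseless signal and
#' the magnitude is taken, giving Rician-distributed magnitude data and a
#' Rayleigh-distributed background where the signal is zero.
#'
#' @param signal numeric array of noiseless signal values.
#' @param sd per-channel Gaussian noise SD; `0` returns the input.
#' @return array of the same shape with Rician noise applied.
#' @export
addRicianNoise <- function(signal, sd) {
  if (sd == 0) return(signal)
  n <- length(signal)
  re <- signal + stats::rnorm(n, sd = sd)
  im <- stats::rnorm(n, sd = sd)
  out <- sqrt(re^2 + im^2)
  dim(out) <- dim(signal)
  out
}

#' Zero geometric-distortion field
#' @return a field function returning zero displacement everywhere
#' @export
zeroField <- function() {
  function(xyz) matrix(0, nrow(xyz), 3)
}

#' Radial cubic distortion field
#'
#' Displacement grows as the cube of the distance from isocenter along the
#' outward radial direction, the leading behaviour of gradient
#' nonlinearity; zero at isocenter by construction.
#'
#' @param k coefficient in mm per mm^3, i.e. |v|(r) = k * r^3.
#' @return a field function for [groundTruth()]
#' @examples
#' # 3.1 mm displacement at r = 250 mm:
#' f <- radialCubicField(3.1 / 250^3)
#' @export
radialCubicField <- function(k) {
  function(xyz) {
    r <- sqrt(rowSums(xyz^2))
    mag <- k * r^3
    u <- xyz / ifelse(r > 0, r, 1)
    u * mag
  }
}

#' Constant (rigid-shift) distortion field
#' @param shiftMm length-3 displacement applied everywhere (mm).
#' @return a field function for [groundTruth()]
#' @export
constantField <- function(shiftMm) {
  shiftMm <- as.numeric(shiftMm)
  function(xyz) matrix(shiftMm, nrow(xyz), 3, byrow = TRUE)
}

# Otsu threshold on a numeric vector (256-bin histogram)
otsuThreshold <- function(x, nbins = 256L) {
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- 0
  mids[which.max(sigmaB)]
}

# logical mask for an RoiSpec over a volume grid; circles are in-plane on
# the slice nearest centerMm[3] (central slice when length 2)
roiMask <- function(vol, roi) {
  d <- dim(vol@voxels)
  co <- gridCoords(d, vol@spacingMm, vol@originMm)
  ctr <- roi@centerMm
  if (length(ctr) == 2L) ctr <- c(ctr, co$z[(d[3] + 1L) %/% 2L])
  mask <- array(FALSE, d)
  kSlice <- which.min(abs(co$z - ctr[3]))
  if (roi@shape == "circle") {
    dx <- outer(co$x - ctr[1], co$y - ctr[2],
                function(a, b) a^2 + b^2)
    inn <- dx <= (roi@diameterMm / 2)^2
    mask[, , kSlice] <- inn
  } else {
    ext <- roi@extentsMm
    inx <- abs(co$x - ctr[1]) <= ext[1] / 2
    iny <- abs(co$y - ctr[2]) <= ext[2] / 2
    if (length(ext) >= 3 && !is.na(ext[3])) {
      inz <- abs(co$z - ctr[3]) <= ext[3] / 2
      mask <- outer(outer(inx, iny, "&"), inz, "&")
    } else {
      mask[, , kSlice] <- outer(inx, iny, "&")
    }
  }
  if (!any(mask)) stop("ROI lies outside the image volume")
  mask
}

# smooth a 2D matrix with a separable Gaussian of given FWHM (in samples)
gaussSmooth2d <- function(m, fwhmSamples) {
  if (fwhmSamples <= 0) return(m)
  sigma <- fwhmSamples / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad <- function(v) c(rep(v[1], half), v, rep(v[length(v)], half))
  conv1 <- function(v) stats::filter(pad(v), k, sides = 2)[(half + 1):(half + length(v))]
  m2 <- apply(m, 2, conv1)
  t(apply(t(m2), 2, conv1))
}

# linear-interpolated full width at `frac` of max for a sampled profile;
# x are sample positions (must be increasing)
interpWidth <- function(x, y, frac = 0.5) {
  ymax <- max(y)
  if (ymax <= 0) stop("profile maximum indistinguishable from background")
  half <- frac * ymax
  iMax <- which.max(y)
  cross <- function(idx) {
    # idx: indices moving away from the peak; find first crossing below half
    for (j in seq_along(idx)[-1]) {
      i1 <- idx[j - 1]; i2 <- idx[j]
      if ((y[i1] - half) * (y[i2] - half) <= 0 && y[i1] != y[i2])
        return(x[i1] + (half - y[i1]) / (y[i2] - y[i1]) * (x[i2] - x[i1]))
    }
    # no crossing: extrapolate half a sample beyond the last index
    x[idx[length(idx)]]
  }
  left <- cross(iMax:1)
  right <- cross(iMax:length(y))
  abs(right - left)
}
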