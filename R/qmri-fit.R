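#' @include constructors.R utils.R generate-qmri.R
NULL

# stack a series of ImageVolumes into (nVoxel x nVolume) matrix
stackSeries <- function(series) {
  d <- dim(series[[1]]@voxels)
  for (v in series)
    if (!identical(dim(v@voxels), d)) stop("series volumes must share a grid")
  vapply(series, function(v) as.numeric(v@voxels), numeric(prod(d)))
}

# per-voxel simple linear regression of Y on X (both nVoxel x n matrices or
# X a length-n vector); returns slope, intercept, r2
voxelwiseOls <- function(X, Y) {
  n <- ncol(Y)
  if (is.null(dim(X))) X <- matrix(X, nrow(Y), n, byrow = TRUE)
  sx <- rowSums(X); sy <- rowSums(Y)
  sxx <- rowSums(X^2); syy <- rowSums(Y^2); sxy <- rowSums(X * Y)
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  cxy <- sxy - sx * sy / n
  slope <- cxy / vx
  intercept <- (sy - slope * sx) / n
  r2 <- ifelse(vy > 0, cxy^2 / (vx * vy), ifelse(abs(cxy) > 0, 0, 1))
  list(slope = slope, intercept = intercept, r2 = r2)
}

fitResult <- function(parameter, units, vals, s0, r2, mask, d, template) {
  toArr <- function(x) array(x, dim = d)
  vals[!mask] <- NA_real_
  new("QMRIFitResult", parameter = parameter, units = units,
      map = toArr(vals), s0 = toArr(s0), r2 = toArr(r2),
      mask = toArr(mask), spacingMm = template@spacingMm,
      originMm = template@originMm)
}

#' Variable-flip-angle T1 fit
#'
#' Linearizes the spoiled steady-state signal equation: per voxel,
#' ordinary least squares of y_i = S_i/sin(a_i) on x_i = S_i/tan(a_i)
#' gives slope m = E1 = exp(-TR/T1) and intercept b = S0 (1 - E1), so
#' T1 = -TR/ln(m) and S0 = b/(1 - m). Voxels with m outside (0, 1),
#' non-positive signal, or linearized R^2 below `r2Min` are masked.
#'
#' @param series list of magnitude [ImageVolume-class], one per flip angle.
#' @param flipAnglesDeg flip angles (degrees); from annotations if omitted.
#' @param trMs repetition time (ms); from metadata if omitted.
#' @param r2Min goodness-of-fit mask threshold (ignored for 2-point fits,
#'   which are exact).
#' @return a [QMRIFitResult-class] (`parameter = "T1"`, ms)
#' @export
fitT1Vfa <- function(series, flipAnglesDeg = NULL, trMs = NULL, r2Min = 0.95) {
  if (is.null(flipAnglesDeg))
    flipAnglesDeg <- vapply(series, function(v)
      as.numeric(v@annotations$flipDeg), numeric(1))
  if (is.null(trMs)) trMs <- series[[1]]@meta@trMs
  if (length(series) < 2 || length(unique(flipAnglesDeg)) < 2)
    stop("invalid series: need >= 2 distinct flip angles")
  S <- stackSeries(series)
  a <- flipAnglesDeg * pi / 180
  Y <- sweep(S, 2, sin(a), "/")
  X <- sweep(S, 2, tan(a), "/")
  fit <- voxelwiseOls(X, Y)
  m <- fit$slope
  posSignal <- rowSums(S > 0) == ncol(S)
  # a signal that does not vary with flip angle carries no E1 information
  # (the apparent slope is a linearization artifact), so mask it
  sMin <- do.call(pmin, asplit(S, 2))
  sMax <- do.call(pmax, asplit(S, 2))
  varies <- (sMax - sMin) > 1e-9 * pmax(sMax, .Machine$double.eps)
  mask <- is.finite(m) & m > 0 & m < 1 & posSignal & varies
  if (length(series) > 2) mask <- mask & fit$r2 >= r2Min
  t1 <- rep(NA_real_, length(m))
  t1[mask] <- -trMs / log(m[mask])
  s0 <- fit$intercept / ifelse(m == 1, NA_real_, 1 - m)
  fitResult("T1", "ms", t1, s0, fit$r2, mask,
            dim(series[[1]]@voxels), series[[1]])
}

#' Optimal flip-angle pair for VFA T1 mapping
#'
#' The Ernst angle arccos(exp(-TR/T1)) maximizes the spoiled steady-state
#' signal; the optimal acquisition pair consists of the two flip angles at
#' which the signal falls to `signalFraction` (default 0.71) of the Ernst
#' signal, found by bracketed root-finding on either side of the Ernst
#' angle. For a T1 range, `t1Handling = "midpoint"` (default) computes the
#' pair at the range midpoint; `"average"` averages the per-bound pairs.
#'
#' @param t1Ms target T1 (ms), scalar or range.
#' @param trMs repetition time (ms).
#' @param signalFraction fraction of the Ernst-angle signal, in (0, 1].
#' @param t1Handling how to reduce a T1 range to one angle pair.
#' @return named numeric `c(lowDeg, highDeg)` with attribute `ernstDeg`
#' @examples
#' round(optimalVfaAngles(c(1000, 2000), trMs = 20))  # 4, 22
#' @export
optimalVfaAngles <- function(t1Ms, trMs, signalFraction = 0.71,
                             t1Handling = c("midpoint", "average")) {
  t1Handling <- match.arg(t1Handling)
  stopifnot(all(t1Ms > 0), trMs > 0,
            signalFraction > 0, signalFraction <= 1)
  onePair <- function(t1) {
    e1 <- exp(-trMs / t1)
    ernst <- acos(e1)
    sig <- function(a) sin(a) * (1 - e1) / (1 - cos(a) * e1)
    target <- signalFraction * sig(ernst)
    if (signalFraction == 1) return(rep(ernst, 2) * 180 / pi)
    f <- function(a) sig(a) - target
    if (f(1e-8) > 0 || f(pi / 2) > 0)
      stop("numerical failure: no bracketing sign change")
    lo <- stats::uniroot(f, c(1e-8, ernst), tol = 1e-12)$root
    hi <- stats::uniroot(f, c(ernst, pi / 2), tol = 1e-12)$root
    c(lo, hi) * 180 / pi
  }
  if (length(t1Ms) > 1) {
    if (t1Handling == "midpoint") {
      out <- onePair(mean(range(t1Ms)))
    } else {
      pairs <- vapply(range(t1Ms), onePair, numeric(2))
      out <- rowMeans(pairs)
    }
    ernst <- acos(exp(-trMs / mean(range(t1Ms)))) * 180 / pi
  } else {
    out <- onePair(t1Ms)
    ernst <- acos(exp(-trMs / t1Ms)) * 180 / pi
  }
  structure(c(lowDeg = out[1], highDeg = out[2]), ernstDeg = ernst)
}

#' Multi-echo spin-echo T2 fit
#'
#' Per voxel, least squares of ln S on TE; T2 = -1/slope. Echoes annotated
#' `dummy = TRUE` (or, failing that, the first echo) are discarded by
#' default, reflecting the acquisition rule that a stimulated-echo-biased
#' dummy echo precedes the analysis train. Voxels with any non-positive
#' signal are masked.
#'
#' @param series list of magnitude [ImageVolume-class], one per echo.
#' @param teMsList echo times (ms); from annotations if omitted.
#' @param discardFirst discard the dummy echo (default TRUE).
#' @param r2Min goodness-of-fit mask threshold (2-point fits exempt).
#' @return a [QMRIFitResult-class] (`parameter = "T2"`, ms)
#' @export
fitT2Mese <- function(series, teMsList = NULL, discardFirst = TRUE,
                      r2Min = 0.95) {
  if (is.null(teMsList))
    teMsList <- vapply(series, function(v)
      as.numeric(v@annotations$teMs), numeric(1))
  if (discardFirst) {
    dum <- vapply(series, function(v)
      isTRUE(v@annotations$dummy), logical(1))
    drop <- if (any(dum)) which(dum) else 1L
    series <- series[-drop]
    teMsList <- teMsList[-drop]
  }
  if (length(series) < 2) stop("invalid series: need >= 2 usable echoes")
  fitLogLinear(series, teMsList, "T2", "ms", r2Min,
               transform = function(slope) -1 / slope)
}

#' Apparent-diffusion-coefficient fit
#'
#' Per voxel, least squares of ln S on b; ADC = -slope (mm^2/s). Voxels
#' with non-positive signal are masked.
#'
#' @param series list of magnitude [ImageVolume-class], one per b-value.
#' @param bValues diffusion weightings (s/mm^2); from annotations if
#'   omitted.
#' @param r2Min goodness-of-fit mask threshold (2-point fits exempt).
#' @return a [QMRIFitResult-class] (`parameter = "ADC"`, mm^2/s)
#' @export
fitAdc <- function(series, bValues = NULL, r2Min = 0.95) {
  if (is.null(bValues))
    bValues <- vapply(series, function(v)
      as.numeric(v@annotations$bValue), numeric(1))
  if (length(series) < 2) stop("invalid series: need >= 2 b-values")
  fitLogLinear(series, bValues, "ADC", "mm^2/s", r2Min,
               transform = function(slope) -slope)
}

fitLogLinear <- function(series, x, parameter, units, r2Min, transform) {
  S <- stackSeries(series)
  pos <- rowSums(S > 0) == ncol(S)
  logS <- log(pmax(S, .Machine$double.xmin))
  fit <- voxelwiseOls(x, logS)
  val <- transform(fit$slope)
  mask <- pos & is.finite(val) & val > 0
  if (length(series) > 2) mask <- mask & fit$r2 >= r2Min
  fitResult(parameter, units, val, exp(fit$intercept), fit$r2, mask,
            dim(series[[1]]@voxels), series[[1]])
}

#' Per-vial bias and reproducibility across sessions
#'
#' For each vial, the mean and SD of the parameter map inside a circular
#' ROI (default 1 cm diameter) centered on the vial are computed per
#' session; bias (percent) compares the across-session mean of the ROI
#' means to the nominal value, and COV (percent) is the SD of the session
#' means over their mean. With a single session the COV is undefined (NA),
#' never 0. By default the SD uses the population (n) denominator;
#' `sampleSd = TRUE` switches to n - 1.
#'
#' @param results list of [QMRIFitResult-class], one per session.
#' @param nominals per-vial nominal values (same units as the fit).
#' @param roiCenters data.frame or matrix with vial center x, y (mm); a
#'   [vialCenters()] data.frame works directly.
#' @param roiDiameterMm ROI diameter (mm), default 10.
#' @param sampleSd use the n - 1 denominator for the across-session SD.
#' @return a [VialReport-class]
#' @export
vialReport <- function(results, nominals, roiCenters, roiDiameterMm = 10,
                       sampleSd = FALSE) {
  if (!length(results)) stop("need >= 1 session")
  if (is.data.frame(roiCenters))
    roiCenters <- as.matrix(roiCenters[, c("x", "y")])
  nV <- nrow(roiCenters)
  if (length(nominals) != nV) stop("one nominal value per vial required")
  sdFun <- if (sampleSd) stats::sd else
    function(x) sqrt(mean((x - mean(x))^2))
  perSession <- do.call(rbind, lapply(seq_along(results), function(s) {
    res <- results[[s]]
    d <- dim(res@map)
    co <- gridCoords(d, res@spacingMm, res@originMm)
    kSlice <- (d[3] + 1L) %/% 2L
    do.call(rbind, lapply(seq_len(nV), function(v) {
      inn <- outer((co$x - roiCenters[v, 1])^2,
                   (co$y - roiCenters[v, 2])^2, "+") <= (roiDiameterMm / 2)^2
      if (!any(inn)) stop("placement error: ROI outside map for vial ", v)
      vals <- res@map[, , kSlice][inn & res@mask[, , kSlice]]
      if (!length(vals)) stop("empty fit: all ROI voxels masked for vial ", v)
      data.frame(vial = v, session = s, mean = mean(vals),
                 sd = sdFun(vals), nVoxels = length(vals))
    }))
  }))
  perVial <- do.call(rbind, lapply(seq_len(nV), function(v) {
    m <- perSession$mean[perSession$vial == v]
    mu <- mean(m)
    cov <- if (length(m) >= 2) sdFun(m) / mu * 100 else NA_real_
    data.frame(vial = v, nominal = nominals[v], measured_mean = mu,
               bias_percent = (mu - nominals[v]) / nominals[v] * 100,
               cov_percent = cov)
  }))
  summary <- list(
    median_bias_percent = stats::median(perVial$bias_percent),
    range_bias_percent = range(perVial$bias_percent),
    median_cov_percent = stats::median(perVial$cov_percent),
    range_cov_percent = if (all(is.na(perVial$cov_percent)))
      c(NA_real_, NA_real_) else range(perVial$cov_percent, na.rm = TRUE))
  new("VialReport", perSession = perSession, perVial = perVial,
      summary = summary, parameter = results[[1]]@parameter,
      nSessions = length(results))
}

# all permutations of 1..n (n <= 8) in lexicographic order
allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank correlation with exact permutation p-value
#'
#' Rank correlation of y against x with average ranks for ties; the
#' two-sided p-value is computed by exhaustive permutation for n <= 8 and
#' by the large-sample t approximation otherwise. Degenerate (constant)
#' ranks give rho = NA with a warning.
#'
#' @param x,y numeric vectors (n >= 4).
#' @return list with `rho`, `pValue`, `method`
#' @export
spearmanExact <- function(x, y) {
  n <- length(x)
  if (n < 4) stop("need >= 4 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("degenerate ranks: rho undefined")
    return(list(rho = NA_real_, pValue = NA_real_, method = "degenerate"))
  }
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- allPermutations(n)
    rhoPerm <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhoPerm) >= abs(rho) - 1e-12)
    list(rho = rho, pValue = p, method = "exact permutation")
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    list(rho = rho, pValue = p, method = "t approximation")
  }
}

#' Rank dependence of bias and COV on the measured value
#'
#' Spearman tests of per-vial bias and COV against the measured vial
#' means, asking whether accuracy or reproducibility depends on the
#' magnitude of the biomarker.
#'
#' @param report a [VialReport-class] (>= 4 vials).
#' @return data.frame with one row per statistic (`bias`, `cov`):
#'   `rho`, `p_value`, `method`
#' @export
rankDependenceTests <- function(report) {
  tb <- report@perVial
  if (nrow(tb) < 4) stop("need >= 4 vials")
  rows <- lapply(c(bias = "bias_percent", cov = "cov_percent"), function(col) {
    keep <- !is.na(tb[[col]])
    if (sum(keep) < 4)
      return(data.frame(rho = NA_real_, p_value = NA_real_,
                        method = "insufficient data"))
    r <- spearmanExact(tb$measured_mean[keep], tb[[col]][keep])
    data.frame(rho = r$rho, p_value = r$pValue, method = r$method)
  })
  out <- do.call(rbind, rows)
  out$statistic <- names(rows)
  out[, c("statistic", "rho", "p_value", "method")]
}
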