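#' @include constructors.R utils.R
NULL

# 3D connected components of a logical mask via the 6-neighbour voxel graph
labelComponents3d <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) stop("no voxels above threshold")
  nx <- d[1]; nxy <- d[1] * d[2]
  ii <- (idx - 1L) %% nx + 1L
  jj <- ((idx - 1L) %/% nx) %% d[2] + 1L
  kk <- (idx - 1L) %/% nxy + 1L
  pos <- match(idx, idx)  # identity, placeholder for clarity
  edges <- integer(0)
  for (off in list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))) {
    ni <- ii + off[1]; nj <- jj + off[2]; nk <- kk + off[3]
    ok <- ni <= d[1] & nj <= d[2] & nk <= d[3]
    nidx <- (nk - 1L) * nxy + (nj - 1L) * nx + ni
    m <- match(nidx, idx)
    hit <- ok & !is.na(m)
    if (any(hit)) edges <- c(edges, rbind(which(hit), m[hit]))
  }
  gr <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  list(idx = idx, membership = igraph::components(gr)$membership, dims = d)
}

# rigid (rotation + translation) least-squares alignment of P onto Q
# (Kabsch); returns the transformed P
rigidAlignPoints <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  R <- sv$v %*% diag(c(1, 1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
  sweep(sweep(P, 2, cp) %*% t(R), 2, -cq)
}

#' Detect fiducial markers and pair them to the machined grid
#'
#' Thresholds the volume (Otsu), labels 3D connected components, computes
#' intensity-weighted centroids over each component's padded bounding box,
#' optionally removes phantom setup error by rigid (translation +
#' rotation) least-squares alignment of the measured onto the known
#' positions, and pairs each centroid to the nearest expected marker
#' within half the grid spacing. Expected markers with no detection are
#' reported as unpaired; more than `maxUnpairedFraction` unpaired (or any
#' duplicate assignment) is a matching failure.
#'
#' @param vol an [ImageVolume-class] of the fiducial phantom.
#' @param expected n x 3 matrix of machined marker positions (mm), e.g.
#'   [fiducialGridPositions()].
#' @param align remove setup error by rigid pre-alignment (default TRUE).
#' @param pairingRadiusMm pairing radius; default half the minimum
#'   nearest-neighbour spacing of `expected`.
#' @param maxUnpairedFraction tolerated fraction of missing markers.
#' @return a [MarkerSet-class]
#' @export
detectMarkers <- function(vol, expected, align = TRUE,
                          pairingRadiusMm = NULL,
                          maxUnpairedFraction = 0.01) {
  v <- vol@voxels
  thr <- otsuThreshold(as.numeric(v))
  lab <- labelComponents3d(v > thr)
  d <- lab$dims
  nx <- d[1]; nxy <- d[1] * d[2]
  co <- gridCoords(d, vol@spacingMm, vol@originMm)
  nComp <- max(lab$membership)
  cent <- matrix(NA_real_, nComp, 3)
  for (cc in seq_len(nComp)) {
    sel <- lab$idx[lab$membership == cc]
    ii <- (sel - 1L) %% nx + 1L
    jj <- ((sel - 1L) %/% nx) %% d[2] + 1L
    kk <- (sel - 1L) %/% nxy + 1L
    # pad the bounding box so the centroid uses the full blob, not only
    # the thresholded core (removes threshold-truncation bias). The local
    # background median (0 for noiseless volumes, the Rayleigh level
    # otherwise) is subtracted so the background mean does not pull the
    # centroid toward the box center; the remainder stays symmetric about
    # the blob center.
    ri <- max(1L, min(ii) - 2L):min(d[1], max(ii) + 2L)
    rj <- max(1L, min(jj) - 2L):min(d[2], max(jj) + 2L)
    rk <- max(1L, min(kk) - 2L):min(d[3], max(kk) + 2L)
    box <- v[ri, rj, rk, drop = FALSE]
    w <- pmax(box - stats::median(box), 0)
    tot <- sum(w)
    cent[cc, ] <- c(sum(apply(w, 1, sum) * co$x[ri]),
                    sum(apply(w, 2, sum) * co$y[rj]),
                    sum(apply(w, 3, sum) * co$z[rk])) / tot
  }
  expected <- as.matrix(expected)
  if (is.null(pairingRadiusMm)) {
    dd <- as.matrix(stats::dist(expected[seq_len(min(200L, nrow(expected))), ,
                                         drop = FALSE]))
    diag(dd) <- Inf
    pairingRadiusMm <- min(dd) / 2
  }
  meas <- if (align && nrow(cent) >= 3) rigidAlignPoints(cent, closestSubset(cent, expected)) else cent
  pair <- rep(NA_integer_, nrow(expected))
  used <- logical(nrow(meas))
  for (e in seq_len(nrow(expected))) {
    dd <- (meas[, 1] - expected[e, 1])^2 + (meas[, 2] - expected[e, 2])^2 +
          (meas[, 3] - expected[e, 3])^2
    j <- which.min(dd)
    if (dd[j] <= pairingRadiusMm^2) {
      if (used[j])
        stop("matching failure: duplicate assignment of one detection ",
             "to multiple expected markers")
      pair[e] <- j
      used[j] <- TRUE
    }
  }
  nMiss <- sum(is.na(pair))
  if (nMiss > maxUnpairedFraction * nrow(expected))
    stop(sprintf("matching failure: %d of %d expected markers unpaired",
                 nMiss, nrow(expected)))
  ok <- !is.na(pair)
  markerSet(knownMm = expected[ok, , drop = FALSE],
            measuredMm = meas[pair[ok], , drop = FALSE],
            ids = which(ok),
            unpairedKnownMm = expected[!ok, , drop = FALSE])
}

# for pre-alignment we need correspondence: nearest expected position for
# each detection (adequate for setup errors well below the grid spacing)
closestSubset <- function(cent, expected) {
  t(apply(cent, 1, function(p) {
    dd <- (expected[, 1] - p[1])^2 + (expected[, 2] - p[2])^2 +
          (expected[, 3] - p[3])^2
    expected[which.min(dd), ]
  }))
}

#' Maximum distortion per diameter of spherical volume
#'
#' For each DSV the maximum Euclidean distortion-vector norm over markers
#' whose *known* position lies inside the sphere (|known| <= DSV/2,
#' isocenter-centered) is compared to its tolerance.
#'
#' @param markers a [MarkerSet-class].
#' @param dsvCm sphere diameters in cm (default 20, 30, 40, 50).
#' @param toleranceMm tolerances (default 1, 2, 4, 20 mm).
#' @return a [DsvSummary-class]
#' @export
summarizeByDsv <- function(markers, dsvCm = c(20, 30, 40, 50),
                           toleranceMm = c(1, 2, 4, 20)) {
  stopifnot(length(dsvCm) == length(toleranceMm))
  r <- sqrt(rowSums(knownPositions(markers)^2))
  vn <- sqrt(rowSums(distortionVectors(markers)^2))
  tb <- do.call(rbind, lapply(seq_along(dsvCm), function(i) {
    sel <- r <= dsvCm[i] * 10 / 2
    if (!any(sel))
      stop("empty region: no markers inside DSV ", dsvCm[i], " cm")
    data.frame(dsv_cm = dsvCm[i], max_distortion_mm = max(vn[sel]),
               n_markers = sum(sel), tolerance_mm = toleranceMm[i])
  }))
  tb$pass <- tb$max_distortion_mm <= tb$tolerance_mm
  new("DsvSummary", table = tb[order(tb$dsv_cm), ])
}

#' Render the distortion magnitude of one plate as a gridded heatmap
#'
#' Scatter-to-grid rendering of |distortion| over the markers of one
#' plate, for qualitative comparison against baseline maps.
#'
#' @param markers a [MarkerSet-class].
#' @param plateZMm z coordinate (mm) of the plate to render; default the
#'   plate nearest isocenter.
#' @return matrix of |vector| (mm) with `xMm`/`yMm` coordinate attributes
#'   and NA off the marker lattice.
#' @export
renderHeatmap <- function(markers, plateZMm = NULL) {
  known <- knownPositions(markers)
  vn <- sqrt(rowSums(distortionVectors(markers)^2))
  zs <- sort(unique(round(known[, 3], 6)))
  if (is.null(plateZMm)) plateZMm <- zs[which.min(abs(zs))]
  sel <- abs(known[, 3] - plateZMm) < 1e-6
  if (!any(sel)) stop("no markers on plate z = ", plateZMm, " mm")
  xs <- sort(unique(known[sel, 1])); ys <- sort(unique(known[sel, 2]))
  hm <- matrix(NA_real_, length(xs), length(ys))
  hm[cbind(match(known[sel, 1], xs), match(known[sel, 2], ys))] <- vn[sel]
  structure(hm, xMm = xs, yMm = ys, plateZMm = plateZMm)
}

#' Save a rendered heatmap grid to CSV (deterministic)
#'
#' @param heatmap output of [renderHeatmap()].
#' @param path file to write.
#' @return invisibly, the path
#' @export
saveHeatmap <- function(heatmap, path) {
  df <- data.frame(xMm = rep(attr(heatmap, "xMm"), ncol(heatmap)),
                   yMm = rep(attr(heatmap, "yMm"), each = nrow(heatmap)),
                   distortionMm = as.numeric(heatmap))
  utils::write.csv(format(df, digits = 10, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
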