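# Reduction of detector frames to 1D traces: cake/sector integration in
# (q, chi), azimuthal profiles over a q band, GISAXS line cuts, and local
# background subtraction.

# nearest-bin-center assignment; returns NA outside the grid's outer edges
.assignBins <- function(values, centers) {
  n <- length(centers)
  if (n < 2L) stop("need at least 2 bin centers")
  edges <- c(centers[1] - diff(centers[1:2]) / 2,
             centers[-n] + diff(centers) / 2,
             centers[n] + diff(centers[(n - 1):n]) / 2)
  idx <- findInterval(values, edges)
  idx[idx < 1L | idx > n] <- NA_integer_
  idx
}

# per-bin mean / Poisson sigma / pixel count
.binStats <- function(bin, y, varY, nbins) {
  ok <- !is.na(bin)
  bin <- bin[ok]; y <- y[ok]; varY <- varY[ok]
  n <- tabulate(bin, nbins)
  sumY <- numeric(nbins); sumV <- numeric(nbins)
  if (length(bin)) {
    t1 <- rowsum(y, bin); sumY[as.integer(rownames(t1))] <- t1
    t2 <- rowsum(varY, bin); sumV[as.integer(rownames(t2))] <- t2
  }
  intensity <- ifelse(n > 0L, sumY / n, NA_real_)
  sigma <- ifelse(n > 0L, sqrt(sumV) / n, NA_real_)
  list(intensity = intensity, sigma = sigma, n = as.integer(n),
       sumY = sumY)
}

.pixelIntensity <- function(frame, map, applySolidAngle) {
  if (applySolidAngle) {
    w <- solidAngleWeight(map)
    list(y = frame / w, varY = frame / w^2)
  } else list(y = frame, varY = frame)
}

#' Sector-averaged radial profile I(q)
#'
#' Mean per-pixel intensity in each q bin, over masked pixels whose polar
#' angle lies in `chiRange` (optionally also the mirrored `-chiRange` lobe).
#' The defaults reproduce the out-of-plane reduction sector (-17 to +17
#' degrees about the substrate normal); use `chiRange = c(78, 88)` with
#' `bothLobes = TRUE` for the in-plane sector.
#'
#' @param frame counts matrix matching the map.
#' @param map a [QChiMap-class].
#' @param chiRange numeric (lo, hi) polar sector in degrees, within
#'   `[-90, 90]`.
#' @param qGrid strictly increasing q bin centers (A^-1).
#' @param bothLobes logical; include the sign-mirrored sector too.
#' @param applySolidAngle logical; divide counts by the per-pixel
#'   solid-angle weight (default TRUE).
#' @return A [Profile1D-class] over q.
#' @export
sectorProfile <- function(frame, map, chiRange = c(-17, 17), qGrid,
                          bothLobes = FALSE, applySolidAngle = TRUE) {
  stopifnot(is(map, "QChiMap"), identical(dim(frame), dim(qValues(map))))
  if (length(chiRange) != 2L || chiRange[1] >= chiRange[2] ||
      any(abs(chiRange) > 90))
    stop("'chiRange' must be (lo, hi) within [-90, 90]")
  chi <- chiValues(map)
  sel <- validMask(map) & chi >= chiRange[1] & chi <= chiRange[2]
  if (bothLobes)
    sel <- sel | (validMask(map) & chi >= -chiRange[2] & chi <= -chiRange[1])
  if (!any(sel))
    stop(sprintf("empty sector: no valid pixels in chi [%g, %g]",
                 chiRange[1], chiRange[2]))
  px <- .pixelIntensity(frame, map, applySolidAngle)
  bin <- .assignBins(qValues(map)[sel], qGrid)
  st <- .binStats(bin, px$y[sel], px$varY[sel], length(qGrid))
  .profile1D("q", qGrid, st$intensity, st$sigma, st$n,
             meta = list(kind = "sector_profile", chiRange = chiRange,
                         bothLobes = bothLobes,
                         applySolidAngle = applySolidAngle))
}

#' Azimuthal profile I(chi) over a q band
#'
#' Intensity per chi bin over the annulus `qBand[1] <= q <= qBand[2]`.
#' The annulus is first regrouped into `qCells` radial sub-cells per chi
#' bin (per-cell mean pixel intensity); the cells are then averaged with
#' equal weight. This two-step collapse gives every chi bin the same
#' effective q weighting, so the azimuthal shape is not distorted where
#' the pixel grid samples the annulus unevenly (worst on the vertical
#' axis, where the ring runs tangent to the pixel rows). `qCells = 1`
#' falls back to a plain per-pixel mean. Bins that no valid pixel reaches
#' (the grazing-incidence missing wedge) are flagged with `nPixels = 0`
#' and NA intensity, not zero-filled.
#'
#' @inheritParams sectorProfile
#' @param qBand numeric (lo, hi) in A^-1; default `c(0.99, 1.31)`, i.e.
#'   1.15 +/- 0.16, the cellulose 110-family band.
#' @param chiGrid strictly increasing chi bin centers in degrees.
#' @param fold logical; average the +/- chi lobes onto `|chi|` (grid must
#'   then be non-negative).
#' @param qCells number of radial sub-cells per chi bin (default 8).
#' @return A [Profile1D-class] over chi.
#' @export
azimuthalProfile <- function(frame, map, qBand = c(0.99, 1.31), chiGrid,
                             fold = FALSE, applySolidAngle = TRUE,
                             qCells = 8L) {
  stopifnot(is(map, "QChiMap"), identical(dim(frame), dim(qValues(map))))
  if (length(qBand) != 2L || qBand[1] >= qBand[2])
    stop("'qBand' must be (lo, hi) with lo < hi")
  q <- qValues(map)
  sel <- validMask(map) & q >= qBand[1] & q <= qBand[2]
  if (!any(sel))
    stop(sprintf("q band [%g, %g] A^-1 lies outside the detector",
                 qBand[1], qBand[2]))
  chi <- chiValues(map)[sel]
  if (fold) chi <- abs(chi)
  px <- .pixelIntensity(frame, map, applySolidAngle)
  bin <- .assignBins(chi, chiGrid)
  nchi <- length(chiGrid)
  qCells <- max(1L, as.integer(qCells))
  if (qCells > 1L) {
    qEdges <- seq(qBand[1], qBand[2], length.out = qCells + 1L)
    cell <- pmin(pmax(findInterval(q[sel], qEdges), 1L), qCells)
    flat <- (bin - 1L) * qCells + cell
    st <- .binStats(flat, px$y[sel], px$varY[sel], nchi * qCells)
    im <- matrix(st$intensity, qCells, nchi)
    sm <- matrix(st$sigma, qCells, nchi)
    nm <- matrix(st$n, qCells, nchi)
    nCellsUsed <- colSums(!is.na(im))
    intensity <- ifelse(nCellsUsed > 0L, colMeans(im, na.rm = TRUE),
                        NA_real_)
    sigma <- ifelse(nCellsUsed > 0L,
                    sqrt(colSums(sm^2, na.rm = TRUE)) / pmax(nCellsUsed, 1L),
                    NA_real_)
    n <- colSums(nm)
  } else {
    st <- .binStats(bin, px$y[sel], px$varY[sel], nchi)
    intensity <- st$intensity; sigma <- st$sigma; n <- st$n
  }
  .profile1D("chi", chiGrid, intensity, sigma, as.integer(n),
             meta = list(kind = "azimuthal_profile", qBand = qBand,
                         fold = fold, applySolidAngle = applySolidAngle,
                         qCells = qCells))
}

#' Full cake integration over (q, chi)
#'
#' Bins every valid pixel by nearest (q, chi) bin center and returns the
#' per-bin mean intensity and pixel count. With `applySolidAngle = FALSE`
#' the cake conserves counts: `sum(intensity * nPixels)` equals the summed
#' counts of all masked pixels inside the grid coverage.
#'
#' @inheritParams sectorProfile
#' @param chiGrid strictly increasing chi bin centers (degrees).
#' @return list with `intensity` (nq x nchi matrix), `nPixels`,
#'   `qGrid`, `chiGrid`, `totalBinnedCounts`.
#' @export
cakeIntegrate <- function(frame, map, qGrid, chiGrid,
                          applySolidAngle = FALSE) {
  stopifnot(is(map, "QChiMap"), identical(dim(frame), dim(qValues(map))))
  sel <- validMask(map)
  px <- .pixelIntensity(frame, map, applySolidAngle)
  qb <- .assignBins(qValues(map)[sel], qGrid)
  cb <- .assignBins(chiValues(map)[sel], chiGrid)
  nq <- length(qGrid); nchi <- length(chiGrid)
  flat <- (cb - 1L) * nq + qb        # NA propagates
  st <- .binStats(flat, px$y[sel], px$varY[sel], nq * nchi)
  intensity <- matrix(st$intensity, nq, nchi)
  n <- matrix(st$n, nq, nchi)
  list(intensity = intensity, nPixels = n, qGrid = qGrid, chiGrid = chiGrid,
       totalBinnedCounts = sum(st$sumY))
}

#' GISAXS line cuts
#'
#' Vertical cut: intensity vs q_z inside `|q_y - center| <= width/2`
#' (defaults q_y = 0.012, width 0.005 A^-1). Horizontal cut: intensity vs
#' q_y inside `|q_z - center| <= width/2` (defaults q_z = 0.03, width
#' 0.005 A^-1). The in-plane and normal components are taken from the map
#' as `q_y = q sin(chi)`, `q_z = q cos(chi)`.
#'
#' @inheritParams sectorProfile
#' @param direction `"vertical"` or `"horizontal"`.
#' @param center cut center in A^-1 (default 0.012 vertical / 0.03
#'   horizontal).
#' @param width cut width in A^-1 (default 0.005).
#' @param grid bin centers along the cut; default: steps of `width` over
#'   the covered range.
#' @return A [Profile1D-class] over q (the cut axis), with the cut
#'   parameters in `profileMeta()`.
#' @export
gisaxsLineCut <- function(frame, map,
                          direction = c("vertical", "horizontal"),
                          center = NULL, width = 0.005, grid = NULL,
                          applySolidAngle = TRUE) {
  stopifnot(is(map, "QChiMap"), identical(dim(frame), dim(qValues(map))))
  direction <- match.arg(direction)
  if (is.null(center)) center <- if (direction == "vertical") 0.012 else 0.03
  chiRad <- .deg2rad(chiValues(map))
  qy <- qValues(map) * sin(chiRad)
  qz <- qValues(map) * cos(chiRad)
  if (direction == "vertical") { across <- qy; along <- qz }
  else { across <- qz; along <- qy }
  sel <- validMask(map) & abs(across - center) <= width / 2
  if (!any(sel))
    stop(sprintf("%s cut at %g A^-1 lies outside the detector",
                 direction, center))
  if (is.null(grid)) {
    rng <- range(along[sel])
    grid <- seq(rng[1], rng[2], by = width)
    if (length(grid) < 2L) stop("cut covers fewer than 2 bins")
  }
  px <- .pixelIntensity(frame, map, applySolidAngle)
  bin <- .assignBins(along[sel], grid)
  st <- .binStats(bin, px$y[sel], px$varY[sel], length(grid))
  .profile1D("q", grid, st$intensity, st$sigma, st$n,
             meta = list(kind = "gisaxs_line_cut", direction = direction,
                         center = center, width = width))
}

#' Local background subtraction for azimuthal traces
#'
#' Pointwise subtraction of a background azimuthal profile (taken over a
#' q band outside the reflection) from the signal profile at the same
#' polar angles. Uncertainties add in quadrature. Negative differences are
#' retained (clipping would bias the estimator); their count is recorded in
#' `profileMeta()$nNegative` and reported via [message()].
#'
#' @param signal,background [Profile1D-class] traces on identical chi
#'   grids.
#' @return A background-corrected [Profile1D-class].
#' @export
localBackgroundSubtract <- function(signal, background) {
  stopifnot(is(signal, "Profile1D"), is(background, "Profile1D"))
  if (signal@axis != background@axis ||
      length(profileGrid(signal)) != length(profileGrid(background)) ||
      any(abs(profileGrid(signal) - profileGrid(background)) > 1e-9))
    stop("signal and background grids differ")
  i <- intensity(signal) - intensity(background)
  s <- sqrt(uncertainty(signal)^2 + uncertainty(background)^2)
  n <- pmin(nPixels(signal), nPixels(background))
  i[n == 0L] <- NA_real_; s[n == 0L] <- NA_real_
  nNeg <- sum(i < 0, na.rm = TRUE)
  if (nNeg > 0)
    message(nNeg, " bin(s) went negative after background subtraction")
  meta <- profileMeta(signal)
  meta$background <- profileMeta(background)
  meta$nNegative <- nNeg
  .profile1D(signal@axis, profileGrid(signal), i, s, n, meta = meta)
}

#' Background-band registry
#'
#' Named local-background q bands (A^-1): for GIWAXS azimuthal traces,
#' onion `[0.5, 0.6]`, Arabidopsis and moss `[0.6, 0.7]`; for rocking-scan
#' traces, onion `[2.0, 2.2]`, Arabidopsis `[1.8, 1.9]`, moss `[0.7, 0.8]`.
#'
#' @param specimen `"onion"`, `"arabidopsis"` or `"moss"`.
#' @param kind `"giwaxs"` or `"rocking"`.
#' @return numeric (lo, hi) q band in A^-1.
#' @examples
#' backgroundBand("onion", "giwaxs")
#' @export
backgroundBand <- function(specimen = c("onion", "arabidopsis", "moss"),
                           kind = c("giwaxs", "rocking")) {
  specimen <- match.arg(specimen); kind <- match.arg(kind)
  bands <- list(
    giwaxs = list(onion = c(0.5, 0.6), arabidopsis = c(0.6, 0.7),
                  moss = c(0.6, 0.7)),
    rocking = list(onion = c(2.0, 2.2), arabidopsis = c(1.8, 1.9),
                   moss = c(0.7, 0.8)))
  bands[[kind]][[specimen]]
}
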