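# chi-pole-figure assembly: GIWAXS branch (|chi| >= 7.5 deg) stitched with
# the rocking-scan branch (|chi| < 30 deg) via a scale factor matched at
# chi = +/-7.5 deg, plus texture and crystallinity metrics.

#' GIWAXS branch of a chi-pole figure
#'
#' Background-corrected azimuthal profile of a GIWAXS frame over the
#' reflection band (default 1.15 +/- 0.16 A^-1, the cellulose 110-family
#' band), restricted to `|chi| >= matchChi` (default 7.5 degrees): polar
#' angles closer to the substrate normal fall in the missing wedge and are
#' flagged missing, to be filled by the rocking branch.
#'
#' @param frame GIWAXS counts matrix.
#' @param map the grazing [QChiMap-class] for the frame.
#' @param qBand reflection band (lo, hi) in A^-1, default `c(0.99, 1.31)`.
#' @param chiGrid chi bin centers in degrees.
#' @param bgBand local-background q band, default
#'   `backgroundBand("onion", "giwaxs")` = `[0.5, 0.6]` A^-1.
#' @param matchChi smallest |chi| retained (degrees, default 7.5).
#' @return A [Profile1D-class] over chi (NA inside `|chi| < matchChi`).
#' @export
giwaxsBranch <- function(frame, map, qBand = c(0.99, 1.31), chiGrid,
                         bgBand = backgroundBand("onion", "giwaxs"),
                         matchChi = 7.5) {
  sig <- azimuthalProfile(frame, map, qBand = qBand, chiGrid = chiGrid)
  bg <- azimuthalProfile(frame, map, qBand = bgBand, chiGrid = chiGrid)
  out <- localBackgroundSubtract(sig, bg)
  drop <- abs(profileGrid(out)) < matchChi
  i <- intensity(out); s <- uncertainty(out); n <- nPixels(out)
  i[drop] <- NA_real_; s[drop] <- NA_real_; n[drop] <- 0L
  meta <- profileMeta(out)
  meta$kind <- "giwaxs_branch"; meta$qBand <- qBand; meta$bgBand <- bgBand
  meta$matchChi <- matchChi
  .profile1D("chi", profileGrid(out), i, s, n, meta = meta)
}

#' Rocking-scan branch of a chi-pole figure
#'
#' Sums the rocking frames over sample angles, takes the azimuthal profile
#' of the summed image over the reflection band within `|chi| < chiMax`
#' (default 30 degrees, the validity range of the small-tilt mapping), and
#' subtracts the local background band. Bins outside `|chi| < chiMax` are
#' flagged missing.
#'
#' @param series a [RockingSeries-class].
#' @param chiGrid chi bin centers in degrees.
#' @param qBand reflection band; default: the series' target band.
#' @param bgBand local-background q band, default
#'   `backgroundBand("onion", "rocking")` = `[2.0, 2.2]` A^-1.
#' @param chiMax largest |chi| retained (degrees, default 30).
#' @return A [Profile1D-class] over chi.
#' @export
rockingBranch <- function(series, chiGrid, qBand = NULL,
                          bgBand = backgroundBand("onion", "rocking"),
                          chiMax = 30) {
  stopifnot(is(series, "RockingSeries"))
  if (!length(frames(series))) stop("empty rocking series")
  if (is.null(qBand)) qBand <- qBand(series)
  summed <- Reduce(`+`, frames(series))
  map <- buildQChiMap(series@geometry, series@beam, mode = "transmission")
  sig <- azimuthalProfile(summed, map, qBand = qBand, chiGrid = chiGrid)
  bg <- azimuthalProfile(summed, map, qBand = bgBand, chiGrid = chiGrid)
  out <- localBackgroundSubtract(sig, bg)
  drop <- abs(profileGrid(out)) >= chiMax
  i <- intensity(out); s <- uncertainty(out); n <- nPixels(out)
  i[drop] <- NA_real_; s[drop] <- NA_real_; n[drop] <- 0L
  meta <- profileMeta(out)
  meta$kind <- "rocking_branch"; meta$qBand <- qBand; meta$bgBand <- bgBand
  meta$chiMax <- chiMax
  meta$sampleAngles <- range(sampleAngles(series))
  .profile1D("chi", profileGrid(out), i, s, n, meta = meta)
}

.sigmaAsIntensity <- function(p) {
  s <- uncertainty(p)
  s[nPixels(p) == 0L] <- NA_real_
  .profile1D(p@axis, profileGrid(p), s, s, nPixels(p))
}

# value of a branch at +/- matchChi: mean of the nearest populated bin on
# each side (not a fit)
.matchValue <- function(profile, matchChi) {
  g <- profileGrid(profile); i <- intensity(profile)
  ok <- nPixels(profile) > 0L & !is.na(i)
  vals <- vapply(c(-matchChi, matchChi), function(x0) {
    cand <- which(ok)
    if (!length(cand)) return(NA_real_)
    i[cand[which.min(abs(g[cand] - x0))]]
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Stitch GIWAXS and rocking branches into a full pole figure
#'
#' The GIWAXS branch is multiplied by
#' `s = mean(rocking at +/-matchChi) / mean(giwaxs at +/-matchChi)` (bin
#' values at the two match angles averaged, not a fit) so the two branches
#' agree at the match angle; the composite uses the rocking branch for
#' `|chi| < matchChi` and the scaled GIWAXS branch elsewhere (GIWAXS has
#' the better statistics off-specular, so it wins in the 7.5-30 degree
#' overlap). The grid is trimmed to bins where the chosen branch has data.
#'
#' @param giwaxs [Profile1D-class] from [giwaxsBranch()].
#' @param rocking [Profile1D-class] from [rockingBranch()].
#' @param matchChi match angle in degrees (default 7.5).
#' @param qBand reflection band recorded in the result (default from the
#'   GIWAXS branch metadata).
#' @return A [PoleFigure-class].
#' @export
stitchPoleFigure <- function(giwaxs, rocking, matchChi = 7.5,
                             qBand = NULL) {
  stopifnot(is(giwaxs, "Profile1D"), is(rocking, "Profile1D"))
  g1 <- profileGrid(giwaxs); g2 <- profileGrid(rocking)
  if (length(g1) != length(g2) || any(abs(g1 - g2) > 1e-9))
    stop("branches must share one chi grid")
  mg <- .matchValue(giwaxs, matchChi)
  mr <- .matchValue(rocking, matchChi)
  if (!is.finite(mg) || !is.finite(mr) || mg <= 0 || mr <= 0)
    stop("cannot scale: non-positive branch intensity at the match angle")
  s <- mr / mg
  # relative variance of s from the match-bin uncertainties; carried so
  # that downstream integrals can count the shared-scale noise of the
  # GIWAXS branch, which per-bin sigmas alone miss
  sg2 <- .matchValue(.sigmaAsIntensity(giwaxs), matchChi)
  sr2 <- .matchValue(.sigmaAsIntensity(rocking), matchChi)
  scaleRelVar <- (sg2 / mg)^2 / 2 + (sr2 / mr)^2 / 2
  useRock <- abs(g1) < matchChi
  i <- ifelse(useRock, intensity(rocking), s * intensity(giwaxs))
  sg <- ifelse(useRock, uncertainty(rocking), s * uncertainty(giwaxs))
  branch <- ifelse(useRock, "rocking", "giwaxs")
  # fall back to the other branch where the chosen one is missing
  swap <- is.na(i) & useRock & !is.na(intensity(giwaxs))
  i[swap] <- s * intensity(giwaxs)[swap]
  sg[swap] <- s * uncertainty(giwaxs)[swap]; branch[swap] <- "giwaxs"
  swap <- is.na(i) & !useRock & !is.na(intensity(rocking))
  i[swap] <- intensity(rocking)[swap]
  sg[swap] <- uncertainty(rocking)[swap]; branch[swap] <- "rocking"
  keep <- !is.na(i)
  if (!any(keep)) stop("no populated bins to stitch")
  if (is.null(qBand)) qBand <- profileMeta(giwaxs)$qBand %||% c(0.99, 1.31)
  new("PoleFigure", chiGrid = g1[keep], intensity = i[keep],
      sigma = ifelse(is.na(sg[keep]), 0, sg[keep]), branch = branch[keep],
      scaleFactor = s, qBand = as.numeric(qBand),
      meta = list(matchChi = matchChi, scaleRelVar = scaleRelVar,
                  giwaxs = profileMeta(giwaxs),
                  rocking = profileMeta(rocking)))
}

# fold a pole figure onto |chi|: grid of unique |chi| >= 0, averaging the
# two lobes where both exist; warns when the lobes are badly asymmetric
.foldPoleFigure <- function(pf, asymmetryTol = 0.2) {
  g <- profileGrid(pf); i <- intensity(pf); s <- uncertainty(pf)
  left <- g < 0; right <- g > 0
  if (any(left) && any(right)) {
    aL <- sum(i[left]); aR <- sum(i[right])
    denom <- max(abs(aL), abs(aR))
    if (denom > 0 && abs(aL - aR) / denom > asymmetryTol)
      warning(sprintf(
        "pole-figure left/right asymmetry %.0f%% exceeds %.0f%%",
        100 * abs(aL - aR) / denom, 100 * asymmetryTol))
  }
  fg <- sort(unique(round(abs(g), 9)))
  fi <- numeric(length(fg)); fs <- numeric(length(fg))
  gshare <- numeric(length(fg))
  for (j in seq_along(fg)) {
    sel <- abs(abs(g) - fg[j]) < 1e-8
    fi[j] <- mean(i[sel])
    fs[j] <- sqrt(sum(s[sel]^2)) / sum(sel)
    gshare[j] <- mean(pf@branch[sel] == "giwaxs")
  }
  list(chi = fg, intensity = fi, sigma = fs, gshare = gshare)
}

# exact integral of a binned trace times the weight over [0, upper] deg.
# Each bin value is the average of I over the bin's support (that is what
# the azimuthal histogram reduction delivers), so the trace is integrated
# as piecewise-constant over the bin supports, with the weight integrated
# in closed form per bin; returns d(integral)/d(f_j) coefficients too.
.integrateBinned <- function(chiDeg, f, weighting, upper) {
  x <- .deg2rad(chiDeg); u <- .deg2rad(upper)
  n <- length(x)
  lo <- c(max(0, x[1] - (x[2] - x[1]) / 2),
          (x[-n] + x[-1]) / 2)
  hiN <- x[n] + (x[n] - x[n - 1]) / 2
  hi <- c(lo[-1], hiN)
  lo <- pmin(pmax(lo, 0), u)
  hi <- pmin(pmax(hi, 0), u)
  coef <- if (weighting == "flat") hi - lo else cos(lo) - cos(hi)
  value <- sum(coef * f)
  # detector coverage often ends a fraction of a bin short of the
  # integration limit (chi = 90 itself is unreachable in grazing
  # incidence); fill a sub-bin-width sliver by extrapolating the local
  # linear trend of the last two bins rather than dropping that part of
  # the measure
  if (u > hiN && u - hiN <= x[n] - x[n - 1] && n >= 2L) {
    w <- if (weighting == "flat") u - hiN else cos(hiN) - cos(u)
    mid <- (hiN + u) / 2
    slope <- (f[n] - f[n - 1]) / (x[n] - x[n - 1])
    a_n <- 1 + (mid - x[n]) / (x[n] - x[n - 1])    # d f_ext / d f[n]
    a_n1 <- -(mid - x[n]) / (x[n] - x[n - 1])
    value <- value + w * (f[n] + slope * (mid - x[n]))
    coef[n] <- coef[n] + w * a_n
    coef[n - 1L] <- coef[n - 1L] + w * a_n1
  }
  list(value = value, coef = coef)
}

#' Fraction of plane normals within a polar cone
#'
#' `fraction = int_0^chi0 I(chi) w(chi) dchi / int_0^90 I(chi) w(chi)
#' dchi` on the folded `|chi|` pole figure, with `w = sin(chi)` (hemisphere
#' measure, default) or `w = 1`. The integrand is treated as
#' piecewise-linear and integrated in closed form per segment, so a uniform
#' pole figure reproduces `1 - cos(chi0)` (sin weighting) and `chi0/90`
#' (flat) to machine precision. A Poisson standard error is propagated from
#' the per-bin uncertainties and attached as `attr(, "se")`.
#'
#' If the folded grid stops short of 90 degrees (detector coverage), the
#' denominator integrates to the last covered angle; the integration limit
#' is recorded in `attr(, "upperLimit")`.
#'
#' @param pf a [PoleFigure-class].
#' @param chi0 cone half-angle in degrees, `0 < chi0 <= 90`.
#' @param weighting `"sin_chi"` or `"flat"`.
#' @return Fraction in `[0, 1]`, with attributes `se` and `upperLimit`.
#' @examples
#' # uniform pole figure: 1 - cos(34 deg) = 0.1710 under the sin measure
#' @export
orientedFraction <- function(pf, chi0, weighting = c("sin_chi", "flat")) {
  stopifnot(is(pf, "PoleFigure"))
  weighting <- match.arg(weighting)
  if (chi0 <= 0 || chi0 > 90) stop("'chi0' must lie in (0, 90] degrees")
  fold <- .foldPoleFigure(pf)
  if (fold$chi[1] > chi0)
    stop("no populated bins below chi0")
  n <- length(fold$chi)
  step <- fold$chi[n] - fold$chi[n - 1]
  edge <- fold$chi[n] + step / 2
  upper <- if (90 - edge <= step) 90 else min(90, edge)
  num <- .integrateBinned(fold$chi, fold$intensity, weighting, min(chi0, upper))
  den <- .integrateBinned(fold$chi, fold$intensity, weighting, upper)
  if (den$value <= 0) stop("non-positive pole-figure integral")
  frac <- num$value / den$value
  # delta-method SE over independent bins, plus the shared-scale noise of
  # the stitched GIWAXS branch (all its bins move together with s)
  dcoef <- (num$coef * den$value - den$coef * num$value) / den$value^2
  se2 <- sum((dcoef * fold$sigma)^2)
  relVarS <- profileMeta(pf)$scaleRelVar
  if (!is.null(relVarS) && is.finite(relVarS)) {
    gIn <- sum(num$coef * fold$intensity * fold$gshare)
    gAll <- sum(den$coef * fold$intensity * fold$gshare)
    dFds <- (gIn * den$value - gAll * num$value) / den$value^2
    se2 <- se2 + dFds^2 * relVarS
  }
  structure(frac, se = sqrt(se2), upperLimit = upper,
            weighting = weighting)
}

#' Full width at half maximum of the orientation distribution
#'
#' FWHM of the folded pole figure about its maximum, with linear
#' interpolation between bins. For a Gaussian texture of width sigma the
#' expected value is `2.355 * sigma`. When no half-maximum crossing exists
#' (isotropic or monotone traces) the result is `NA` with
#' `attr(, "flag") = "no width"` rather than an error.
#'
#' @param pf a [PoleFigure-class] with its maximum at `|chi| < 45` degrees.
#' @return FWHM in degrees (possibly NA, flagged).
#' @export
textureWidth <- function(pf) {
  stopifnot(is(pf, "PoleFigure"))
  fold <- .foldPoleFigure(pf)
  x <- fold$chi; y <- fold$intensity
  jmax <- which.max(y)
  if (x[jmax] >= 45)
    return(structure(NA_real_, flag = "maximum not out-of-plane"))
  half <- (y[jmax] + min(y)) / 2
  # half-maximum relative to the trace floor, robust to flat backgrounds
  crossRight <- NA_real_
  for (j in seq(jmax, length(x) - 1L)) {
    if ((y[j] - half) * (y[j + 1L] - half) <= 0 && y[j] != y[j + 1L]) {
      crossRight <- x[j] + (half - y[j]) * (x[j + 1L] - x[j]) /
        (y[j + 1L] - y[j])
      break
    }
  }
  if (!is.finite(crossRight))
    return(structure(NA_real_, flag = "no width"))
  # folded trace: the left half-width mirrors through chi = 0 when the
  # maximum sits at the origin
  crossLeft <- NA_real_
  if (jmax > 1L) for (j in seq(jmax, 2L)) {
    if ((y[j] - half) * (y[j - 1L] - half) <= 0 && y[j] != y[j - 1L]) {
      crossLeft <- x[j] + (half - y[j]) * (x[j - 1L] - x[j]) /
        (y[j - 1L] - y[j])
      break
    }
  }
  width <- if (is.finite(crossLeft)) crossRight - crossLeft
           else 2 * (crossRight - x[jmax])
  structure(width, flag = NA_character_)
}

#' Segal crystallinity index
#'
#' Height-based crystallinity proxy `CI = 100 * (I_200 - I_am) / I_200`
#' from a 1D diffraction profile, with `I_200` the maximum intensity in the
#' (200) window and `I_am` the minimum in the amorphous valley. The
#' windows are fixed in q (default `[1.40, 1.70]` and `[1.10, 1.40]`
#' A^-1), a wavelength-independent transcription of the classic Cu-K-alpha
#' two-theta points (22.6 and ~18.7 degrees).
#'
#' @param profile a [Profile1D-class] over q spanning `[1.0, 1.7]` A^-1.
#' @param crystallineWindow q window for the (200) maximum (A^-1).
#' @param amorphousWindow q window for the amorphous minimum (A^-1).
#' @return CI in percent (can be <= 0 for amorphous profiles).
#' @export
segalCI <- function(profile, crystallineWindow = c(1.40, 1.70),
                    amorphousWindow = c(1.10, 1.40)) {
  stopifnot(is(profile, "Profile1D"), profile@axis == "q")
  g <- profileGrid(profile); i <- intensity(profile)
  ok <- nPixels(profile) > 0L & !is.na(i)
  inC <- ok & g >= crystallineWindow[1] & g <= crystallineWindow[2]
  inA <- ok & g >= amorphousWindow[1] & g <= amorphousWindow[2]
  if (!any(inC) || !any(inA))
    stop("profile does not cover the Segal windows")
  i200 <- max(i[inC]); iam <- min(i[inA])
  if (i200 <= 0) stop("non-positive (200) window maximum")
  100 * (i200 - iam) / i200
}

#' Write a pole figure as CSV
#'
#' Columns `chi_deg, intensity, sigma, branch`; '#'-prefixed header lines
#' record the q band, match angle and scale factor.
#'
#' @param pf a [PoleFigure-class].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writePoleFigureCsv <- function(pf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# q_band_invA: %g %g", pf@qBand[1], pf@qBand[2]),
    sprintf("# match_chi_deg: %g", pf@meta$matchChi %||% NA),
    sprintf("# scale_factor: %.10g", pf@scaleFactor)), con)
  write.csv(data.frame(chi_deg = pf@chiGrid, intensity = pf@intensity,
                       sigma = pf@sigma, branch = pf@branch),
            con, row.names = FALSE)
  invisible(path)
}
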