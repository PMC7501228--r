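# Forward renderer: synthetic GIWAXS frames, rocking-scan series and
# transmission-WAXS frames from a generative Scene, so every downstream
# stage is testable without beamline data.

# Orientation density g(chi) with the sin(chi) hemisphere measure:
# integral_0^{pi/2} g(chi) sin(chi) dchi = 1. Evaluated at |chi| (fiber
# texture is even in chi).
.textureNormalization <- function(texture) {
  if (texture@kind == "isotropic") return(1)
  s <- .deg2rad(texture@sigmaChi)
  c0 <- .deg2rad(texture@centerChi)
  f <- function(x) exp(-(x - c0)^2 / (2 * s^2)) * sin(x)
  1 / integrate(f, 0, pi / 2, rel.tol = 1e-10)$value
}

#' Orientation density of a texture model
#'
#' Evaluates the plane-normal orientation density g(chi), normalized over
#' the hemisphere with the sin(chi) measure
#' (`integral_0^90 g sin(chi) dchi = 1`, chi in radians).
#'
#' @param texture a [TextureModel-class].
#' @param chi polar angle(s) in degrees (evaluated at `|chi|`).
#' @return Density values (unitless).
#' @export
orientationDensity <- function(texture, chi) {
  stopifnot(is(texture, "TextureModel"))
  chi <- abs(chi)
  if (texture@kind == "isotropic") return(rep(1, length(chi)))
  A <- .textureNormalization(texture)
  A * exp(-(chi - texture@centerChi)^2 / (2 * texture@sigmaChi^2))
}

#' Fraction of the orientation density within a polar cone
#'
#' Analytic (quadrature) fraction of plane normals with `|chi| <= chi0`
#' under the sin(chi) hemisphere measure, or flat in chi. This is the
#' ground-truth value a pole-figure analysis of a rendered scene should
#' recover.
#'
#' @param texture a [TextureModel-class].
#' @param chi0 cone half-angle in degrees, `0 < chi0 <= 90`.
#' @param weighting `"sin_chi"` (hemisphere measure, default) or `"flat"`.
#' @return Fraction in `[0, 1]`.
#' @export
textureFractionWithin <- function(texture, chi0,
                                  weighting = c("sin_chi", "flat")) {
  weighting <- match.arg(weighting)
  if (chi0 <= 0 || chi0 > 90) stop("'chi0' must lie in (0, 90] degrees")
  w <- if (weighting == "sin_chi") function(x) sin(x) else function(x) 1
  f <- function(x) orientationDensity(texture, .rad2deg(x)) * w(x)
  num <- integrate(f, 0, .deg2rad(chi0), rel.tol = 1e-10)$value
  den <- integrate(f, 0, pi / 2, rel.tol = 1e-10)$value
  num / den
}

# expected (noiseless) counts for a grazing or transmission frame
.expectedFrame <- function(scn, map, useTexture = TRUE, chiEff = NULL) {
  q <- qValues(map)
  mean <- matrix(0, nrow(q), ncol(q))
  chiFrame <- if (is.null(chiEff)) chiValues(map) else chiEff
  for (p in scn@phases) {
    radial <- .phaseRadial(p$phase, q)
    g <- if (useTexture) orientationDensity(p$texture, chiFrame) else 1
    mean <- mean + p$scale * radial * g
  }
  mean <- mean + .haloIntensity(scn@amorphousHalo, q) + scn@flatBackground
  mean <- scn@exposure * mean * solidAngleWeight(map)
  mean[!validMask(map)] <- 0
  mean
}

.poissonize <- function(meanFrame, seed, noiseless) {
  if (noiseless) return(meanFrame)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed))
    stop("'seed' must be a single integer")
  set.seed(as.integer(seed))
  matrix(as.numeric(rpois(length(meanFrame), lambda = meanFrame)),
         nrow(meanFrame), ncol(meanFrame))
}

#' Render a synthetic GIWAXS frame
#'
#' Expected counts per pixel:
#' `exposure * [sum_phases scale * radial(q) * g(chi)] + halo(q) + flat`,
#' multiplied by the solid-angle weight and zeroed outside the validity
#' mask (missing wedge, below-horizon). With `noiseless = FALSE` each pixel
#' draws an independent Poisson count with that mean.
#'
#' @param scn a [Scene-class].
#' @param geometry a [DetectorGeometry-class].
#' @param beam a [BeamSpec-class].
#' @param seed integer RNG seed (required unless noiseless).
#' @param noiseless logical; TRUE returns the expected-count frame itself.
#' @param map optional precomputed grazing [QChiMap-class] for this
#'   geometry/beam (saves recomputation in loops).
#' @return A counts matrix (rows x cols of the detector).
#' @examples
#' g <- defaultGeometry(rebin = 8L); b <- beamSpec(10, 0.15)
#' fr <- renderGiwaxs(scenePreset("unextracted"), g, b, seed = 1)
#' @export
renderGiwaxs <- function(scn, geometry, beam, seed = NULL,
                         noiseless = FALSE, map = NULL) {
  stopifnot(is(scn, "Scene"))
  if (is.null(map)) map <- buildQChiMap(geometry, beam, mode = "grazing")
  .poissonize(.expectedFrame(scn, map), seed, noiseless)
}

#' Render a synthetic transmission-WAXS frame
#'
#' Beam normal to the cell-wall plane: out-of-plane texture is invisible in
#' this projection, so every phase contributes its full radial profile
#' isotropically (in-plane isotropy of the wall). No missing wedge.
#'
#' @inheritParams renderGiwaxs
#' @return A counts matrix.
#' @export
renderTransmission <- function(scn, geometry, beam, seed = NULL,
                               noiseless = FALSE, map = NULL) {
  stopifnot(is(scn, "Scene"))
  if (is.null(map)) map <- buildQChiMap(geometry, beam,
                                        mode = "transmission")
  .poissonize(.expectedFrame(scn, map, useTexture = FALSE), seed, noiseless)
}

#' Render a specular rocking-scan series
#'
#' The sample is rocked through sample angles theta_s; at each angle the
#' crystallites satisfying the Bragg condition at a pixel have plane tilt
#' `chi = chi_det + (theta_s - theta_B(q))`, where chi_det is the apparent
#' detector polar offset and `theta_B(q) = asin(q/(2k))` (the specular q at
#' sample angle theta_s is `2k sin(theta_s)`, which sweeps the target band
#' as the sample rocks). The small-tilt mapping is valid for
#' `|chi| <= ~30` degrees, matching the rocking sector used downstream.
#'
#' A warning is issued if the rock range does not cross the Bragg angles of
#' the target band.
#'
#' @inheritParams renderGiwaxs
#' @param thetaRange numeric (lo, hi) sample angles in degrees, within
#'   (0, 20).
#' @param nFrames number of frames (>= 2), equally spaced over thetaRange.
#' @param qBandTarget the reflection band the scan targets, default
#'   `c(0.99, 1.31)` A^-1 (the cellulose 110-family band).
#' @return A [RockingSeries-class].
#' @export
renderRockingSeries <- function(scn, geometry, beam, thetaRange, nFrames,
                                seed = NULL, noiseless = FALSE,
                                qBandTarget = c(0.99, 1.31)) {
  stopifnot(is(scn, "Scene"), is(beam, "BeamSpec"))
  if (length(thetaRange) != 2L || any(thetaRange <= 0) ||
      any(thetaRange >= 20) || thetaRange[1] >= thetaRange[2])
    stop("'thetaRange' must be (lo, hi) within (0, 20) degrees")
  if (nFrames < 2) stop("'nFrames' must be >= 2")
  k <- 2 * pi / wavelength(beam)
  thetaB <- .rad2deg(asin(qBandTarget / (2 * k)))
  if (thetaB[1] > thetaRange[2] || thetaB[2] < thetaRange[1])
    warning(sprintf(
      "rock range [%.2f, %.2f] deg misses the Bragg angles [%.2f, %.2f] deg of the target band",
      thetaRange[1], thetaRange[2], thetaB[1], thetaB[2]))
  map <- buildQChiMap(geometry, beam, mode = "transmission")
  q <- qValues(map)
  thetaBq <- .rad2deg(asin(pmin(q / (2 * k), 1)))
  angles <- seq(thetaRange[1], thetaRange[2], length.out = nFrames)
  if (!noiseless) {
    if (is.null(seed)) stop("'seed' must be a single integer")
    set.seed(as.integer(seed))
    frameSeeds <- sample.int(.Machine$integer.max - 1L, nFrames)
  }
  frames <- vector("list", nFrames)
  for (i in seq_len(nFrames)) {
    chiEff <- chiValues(map) + (angles[i] - thetaBq)
    m <- .expectedFrame(scn, map, useTexture = TRUE, chiEff = chiEff)
    frames[[i]] <- if (noiseless) m else .poissonize(m, frameSeeds[i], FALSE)
  }
  new("RockingSeries", sampleAngles = angles, frames = frames,
      qBand = as.numeric(qBandTarget), geometry = geometry, beam = beam)
}

#' Scene presets mirroring the specimen preparations
#'
#' Named generative scenes emulating the phenomenology of differently
#' treated cell-wall specimens:
#' \describe{
#'   \item{unextracted}{out-of-plane-textured cellulose (Gaussian about the
#'     substrate normal) + in-plane lamellar wax + amorphous halo.}
#'   \item{driselase}{polysaccharides digested: wax + halo only, no
#'     cellulose phase.}
#'   \item{chloroform}{wax extracted: textured cellulose + halo, no wax.}
#'   \item{ground}{ground wall: isotropic cellulose + halo (orientation
#'     randomized, crystallinity retained).}
#'   \item{stem_segment}{as unextracted with a somewhat tighter texture.}
#' }
#'
#' The cellulose texture width defaults to sigma = 35 degrees, a realistic
#' moderate out-of-plane preference; the halo (center 1.4 A^-1, FWHM 0.7,
#' amplitude comparable to the Bragg peaks, as in real primary-wall
#' patterns where amorphous polysaccharides dominate) is a synthetic
#' stand-in for the amorphous wall background, not a fitted literature
#' parameterization.
#'
#' @param name preset name (see above).
#' @param sigmaChi Gaussian texture width in degrees for the cellulose
#'   phase (default 35).
#' @param exposure overall exposure scale (default 1).
#' @param waxScale scale of the wax phase where present (default 0.6).
#' @param celluloseScale scale of the cellulose phase where present
#'   (default 1).
#' @return A [Scene-class].
#' @examples
#' scenePreset("driselase")
#' @export
scenePreset <- function(name, sigmaChi = 35, exposure = 1, waxScale = 0.6,
                        celluloseScale = 1) {
  presets <- c("unextracted", "driselase", "chloroform", "ground",
               "stem_segment")
  if (!is.character(name) || length(name) != 1L || !name %in% presets)
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  halo <- c(1.4, 0.7, 20 * celluloseScale)
  cel <- function(sig) list(
    phase = celluloseIbetaPhase(crystalSize = 30),
    texture = textureModel("gaussian_out_of_plane", sigmaChi = sig,
                           centerChi = 0),
    scale = celluloseScale)
  celIso <- list(phase = celluloseIbetaPhase(crystalSize = 30),
                 texture = textureModel("isotropic"),
                 scale = celluloseScale)
  wax <- list(phase = waxPhase(), texture = textureModel("delta_in_plane"),
              scale = waxScale)
  phases <- switch(name,
    unextracted = list(cel(sigmaChi), wax),
    driselase = list(wax),
    chloroform = list(cel(sigmaChi)),
    ground = list(celIso),
    stem_segment = list(cel(max(sigmaChi - 10, 5)), wax))
  scene(phases = phases, amorphousHalo = halo, flatBackground = 0.02,
        exposure = exposure)
}
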