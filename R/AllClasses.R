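#' BeamSpec: X-ray beam description
#'
#' Holds the beam energy (keV), the derived wavelength (Angstrom) and the
#' grazing incidence angle alpha_i (degrees, 0 for transmission geometry).
#'
#' @slot energy numeric, photon energy in keV.
#' @slot wavelength numeric, wavelength in Angstrom, always `12.3984/energy`.
#' @slot incidence numeric, incidence angle alpha_i in degrees.
#' @exportClass BeamSpec
setClass("BeamSpec",
  representation(energy = "numeric", wavelength = "numeric",
                 incidence = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@energy) != 1L || !is.finite(object@energy) ||
        object@energy <= 0)
      msg <- c(msg, "energy must be a single positive number (keV)")
    else if (abs(object@wavelength - .hc_keV_A / object@energy) >
             1e-6 * object@wavelength)
      msg <- c(msg, "wavelength inconsistent with energy (hc = 12.3984 keV*A)")
    if (length(object@incidence) != 1L || !is.finite(object@incidence) ||
        object@incidence < 0 || object@incidence >= 5)
      msg <- c(msg, "incidence angle must be in [0, 5) degrees")
    if (length(msg)) msg else TRUE
  })

#' Construct a BeamSpec
#'
#' @param energy photon energy in keV.
#' @param incidence grazing incidence angle in degrees (default 0.15, the
#'   setting used with 10 keV beams on cell-wall samples).
#' @return A [BeamSpec-class] object.
#' @examples
#' beamSpec(10, incidence = 0.15)
#' @export
beamSpec <- function(energy, incidence = 0.15) {
  if (!is.numeric(energy) || length(energy) != 1L || !is.finite(energy) ||
      energy <= 0)
    stop("'energy' must be a single positive number (keV)")
  new("BeamSpec", energy = as.numeric(energy),
      wavelength = energyToWavelength(energy),
      incidence = as.numeric(incidence))
}

#' Material: elemental composition and mass density
#'
#' @slot massFractions named numeric vector, element symbol -> mass fraction;
#'   fractions are non-negative and sum to 1.
#' @slot density numeric, g/cm^3.
#' @exportClass Material
setClass("Material",
  representation(massFractions = "numeric", density = "numeric"),
  validity = function(object) {
    msg <- character()
    w <- object@massFractions
    if (is.null(names(w)) || any(!nzchar(names(w))))
      msg <- c(msg, "massFractions must be named by element symbol")
    if (any(w < 0)) msg <- c(msg, "mass fractions must be non-negative")
    if (abs(sum(w) - 1) > 1e-9)
      msg <- c(msg, "mass fractions must sum to 1 (+/- 1e-9)")
    if (length(object@density) != 1L || !is.finite(object@density) ||
        object@density <= 0)
      msg <- c(msg, "density must be a single positive number (g/cm^3)")
    if (length(msg)) msg else TRUE
  })

#' Construct a Material from a chemical formula or mass fractions
#'
#' @param formula either a named numeric vector of element counts
#'   (e.g. `c(C = 6, H = 10, O = 5)`) interpreted as a stoichiometric
#'   formula, or a named numeric vector of mass fractions when
#'   `byMass = TRUE`.
#' @param density mass density in g/cm^3.
#' @param byMass logical; if TRUE, `formula` already holds mass fractions.
#' @return A [Material-class] object.
#' @examples
#' anhydroglucose <- material(c(C = 6, H = 10, O = 5), density = 1.5)
#' @export
material <- function(formula, density, byMass = FALSE) {
  if (!is.numeric(formula) || is.null(names(formula)))
    stop("'formula' must be a named numeric vector")
  unknown <- setdiff(names(formula), names(.element_Z))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (byMass) {
    w <- formula / sum(formula)
  } else {
    m <- formula * .element_A[names(formula)]
    w <- m / sum(m)
  }
  new("Material", massFractions = w, density = as.numeric(density))
}

#' The model primary cell-wall material
#'
#' Dried plant primary cell wall modelled as anhydroglucose (C6H10O5) at
#' 1.5 g/cm^3: the wall is predominantly cellulose, pectin and hemicellulose,
#' all hexose/pentose polymers of near-identical composition and density.
#'
#' @param density mass density in g/cm^3 (default 1.5).
#' @return A [Material-class] object.
#' @export
cellWallMaterial <- function(density = 1.5)
  material(c(C = 6, H = 10, O = 5), density = density)

#' DetectorGeometry: flat area detector placement
#'
#' Ties pixel indices to scattering directions. Pixel centers sit at integer
#' (1-based) indices; `beamCenter` is the direct-beam position `(row, col)`
#' and may be fractional or lie outside the frame. The detector plane is
#' perpendicular to the incident beam at distance `distance`.
#'
#' @slot distance numeric, sample-to-detector distance in mm.
#' @slot pixelSize numeric, square pixel edge in mm.
#' @slot beamCenter numeric length-2, (row, col) of the direct beam.
#' @slot shape integer length-2, (rows, cols).
#' @slot orientation character, `"up_is_low_row"` (row 1 at the top of the
#'   image, away from the substrate; the default) or `"up_is_high_row"`.
#' @exportClass DetectorGeometry
setClass("DetectorGeometry",
  representation(distance = "numeric", pixelSize = "numeric",
                 beamCenter = "numeric", shape = "integer",
                 orientation = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@distance) != 1L || object@distance <= 0)
      msg <- c(msg, "distance must be a single positive number (mm)")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a single positive number (mm)")
    if (length(object@beamCenter) != 2L || any(!is.finite(object@beamCenter)))
      msg <- c(msg, "beamCenter must be (row, col)")
    if (length(object@shape) != 2L || any(object@shape < 1L))
      msg <- c(msg, "shape must be (rows, cols), both >= 1")
    if (!object@orientation %in% c("up_is_low_row", "up_is_high_row"))
      msg <- c(msg, "orientation must be 'up_is_low_row' or 'up_is_high_row'")
    if (length(msg)) msg else TRUE
  })

#' Construct a DetectorGeometry
#'
#' @param distance sample-to-detector distance in mm.
#' @param pixelSize pixel edge in mm.
#' @param beamCenter numeric (row, col) of the direct-beam position,
#'   fractional allowed, may lie outside the frame.
#' @param shape integer (rows, cols) of the frame.
#' @param orientation which image direction points away from the substrate;
#'   see [DetectorGeometry-class].
#' @return A [DetectorGeometry-class] object.
#' @examples
#' detectorGeometry(125, 0.172, beamCenter = c(508, 256.5), shape = c(512, 512))
#' @export
detectorGeometry <- function(distance, pixelSize, beamCenter, shape,
                             orientation = "up_is_low_row") {
  new("DetectorGeometry", distance = as.numeric(distance),
      pixelSize = as.numeric(pixelSize), beamCenter = as.numeric(beamCenter),
      shape = as.integer(shape), orientation = orientation)
}

#' Default detector geometries
#'
#' Desk-scale defaults: a 512 x 512 detector with 0.172 mm pixels at 125 mm,
#' which covers q up to about 3 A^-1 at 10 keV. For `kind = "giwaxs"` the
#' beam center sits near the bottom edge (sample horizon); for
#' `kind = "transmission"` it is at the frame center. `rebin` coarsens the
#' pixel grid while keeping the same physical aperture, convenient for fast
#' tests.
#'
#' @param kind `"giwaxs"` or `"transmission"`.
#' @param rebin integer >= 1; 1 gives 512 x 512, 4 gives 128 x 128 with
#'   0.688 mm pixels, etc.
#' @return A [DetectorGeometry-class] object.
#' @export
defaultGeometry <- function(kind = c("giwaxs", "transmission"), rebin = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(512 / rebin)
  px <- 0.172 * rebin
  center <- if (kind == "giwaxs") c(n - 2.5, (n + 1) / 2)
            else c((n + 1) / 2, (n + 1) / 2)
  detectorGeometry(125, px, center, c(n, n))
}

#' QChiMap: per-pixel reciprocal-space coordinates
#'
#' For each detector pixel: the scattering-vector magnitude q (A^-1), the
#' polar angle chi (degrees, 0 along the substrate normal, +/-90 in plane,
#' signed left/right), a relative solid-angle weight, and a validity mask
#' that is FALSE at the direct beam, below the sample horizon, and inside
#' the grazing-incidence missing wedge.
#'
#' @slot q numeric matrix, A^-1.
#' @slot chi numeric matrix, degrees in `[-90, 90]`.
#' @slot weight numeric matrix, relative solid angle in (0, 1].
#' @slot mask logical matrix.
#' @slot geometry the [DetectorGeometry-class] used.
#' @slot beam the [BeamSpec-class] used.
#' @slot mode `"grazing"` or `"transmission"`.
#' @exportClass QChiMap
setClass("QChiMap",
  representation(q = "matrix", chi = "matrix", weight = "matrix",
                 mask = "matrix", geometry = "DetectorGeometry",
                 beam = "BeamSpec", mode = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@q)
    if (!identical(d, dim(object@chi)) || !identical(d, dim(object@weight)) ||
        !identical(d, dim(object@mask)))
      msg <- c(msg, "q, chi, weight, mask must share dimensions")
    if (any(object@q < 0, na.rm = TRUE)) msg <- c(msg, "q must be >= 0")
    if (any(abs(object@chi) > 90 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "chi must lie in [-90, 90] degrees")
    if (!object@mode %in% c("grazing", "transmission"))
      msg <- c(msg, "mode must be 'grazing' or 'transmission'")
    if (length(msg)) msg else TRUE
  })

#' Profile1D: a 1D reduced trace with counting uncertainties
#'
#' @slot axis `"q"` (A^-1) or `"chi"` (degrees).
#' @slot grid numeric, strictly increasing bin centers.
#' @slot intensity numeric, mean (solid-angle-normalized) counts per bin;
#'   NA where no pixel contributed.
#' @slot sigma numeric, Poisson standard error of the bin mean.
#' @slot nPixels integer, contributing pixels per bin (0 marks missing bins).
#' @slot meta list of provenance (sector bounds, q band, geometry notes).
#' @exportClass Profile1D
setClass("Profile1D",
  representation(axis = "character", grid = "numeric", intensity = "numeric",
                 sigma = "numeric", nPixels = "integer", meta = "list"),
  validity = function(object) {
    msg <- character()
    n <- length(object@grid)
    if (length(object@intensity) != n || length(object@sigma) != n ||
        length(object@nPixels) != n)
      msg <- c(msg, "grid, intensity, sigma, nPixels must have equal length")
    if (n > 1 && any(diff(object@grid) <= 0))
      msg <- c(msg, "grid must be strictly increasing")
    if (!object@axis %in% c("q", "chi"))
      msg <- c(msg, "axis must be 'q' or 'chi'")
    if (any(object@sigma < 0, na.rm = TRUE))
      msg <- c(msg, "sigma must be >= 0")
    if (any(object@nPixels == 0L & !is.na(object@intensity)))
      msg <- c(msg, "bins with nPixels = 0 must have NA intensity")
    if (length(msg)) msg else TRUE
  })

.profile1D <- function(axis, grid, intensity, sigma, nPixels, meta = list())
  new("Profile1D", axis = axis, grid = as.numeric(grid),
      intensity = as.numeric(intensity), sigma = as.numeric(sigma),
      nPixels = as.integer(nPixels), meta = meta)

#' PoleFigure: stitched chi-pole figure
#'
#' Background-corrected, stitched orientation-distribution trace I(chi) on
#' chi in `[-90, 90]` degrees, with per-bin provenance (`"giwaxs"`,
#' `"rocking"`) and the GIWAXS-to-rocking scale factor applied.
#'
#' @slot chiGrid numeric, degrees, strictly increasing.
#' @slot intensity numeric, finite everywhere on the grid.
#' @slot sigma numeric, propagated Poisson uncertainty.
#' @slot branch character, per-bin source label.
#' @slot scaleFactor numeric, factor applied to the GIWAXS branch.
#' @slot qBand numeric length-2, the reflection band integrated (A^-1).
#' @slot meta list (match angle, weighting, background bands).
#' @exportClass PoleFigure
setClass("PoleFigure",
  representation(chiGrid = "numeric", intensity = "numeric", sigma = "numeric",
                 branch = "character", scaleFactor = "numeric",
                 qBand = "numeric", meta = "list"),
  validity = function(object) {
    msg <- character()
    n <- length(object@chiGrid)
    if (length(object@intensity) != n || length(object@branch) != n ||
        length(object@sigma) != n)
      msg <- c(msg, "chiGrid, intensity, sigma, branch must have equal length")
    if (n > 1 && any(diff(object@chiGrid) <= 0))
      msg <- c(msg, "chiGrid must be strictly increasing")
    if (any(!is.finite(object@intensity)))
      msg <- c(msg, "intensity must be finite everywhere on the grid")
    if (any(!object@branch %in% c("giwaxs", "rocking", "overlap")))
      msg <- c(msg, "branch labels must be 'giwaxs', 'rocking' or 'overlap'")
    if (length(object@scaleFactor) != 1L || object@scaleFactor <= 0)
      msg <- c(msg, "scaleFactor must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' UnitCell: triclinic lattice constants
#'
#' @slot a,b,c numeric, axis lengths in Angstrom.
#' @slot alpha,beta,gamma numeric, inter-axial angles in degrees.
#' @exportClass UnitCell
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric"),
  validity = function(object) {
    msg <- character()
    len <- c(object@a, object@b, object@c)
    ang <- c(object@alpha, object@beta, object@gamma)
    if (any(len <= 0)) msg <- c(msg, "axis lengths must be positive")
    if (any(ang <= 0 | ang >= 180))
      msg <- c(msg, "angles must lie in (0, 180) degrees")
    if (!length(msg)) {
      G <- .metricTensor(object)
      if (any(eigen(G, symmetric = TRUE, only.values = TRUE)$values <= 0))
        msg <- c(msg, "metric tensor must be positive-definite")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a UnitCell
#'
#' @param a,b,c axis lengths in Angstrom.
#' @param alpha,beta,gamma inter-axial angles in degrees.
#' @return A [UnitCell-class] object.
#' @examples
#' unitCell(7.784, 8.201, 10.38, gamma = 96.5)   # cellulose I-beta
#' @export
unitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90)
  new("UnitCell", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma))

#' PhasePeakSet: a crystalline phase as a reflection list
#'
#' @slot name character.
#' @slot reflections data.frame with columns `h, k, l, d_A, q_invA,
#'   family_label, weight`.
#' @slot crystalSize numeric, coherent crystal size in Angstrom (drives
#'   Scherrer broadening).
#' @slot relativeWeight numeric, overall phase weight.
#' @exportClass PhasePeakSet
setClass("PhasePeakSet",
  representation(name = "character", reflections = "data.frame",
                 crystalSize = "numeric", relativeWeight = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("h", "k", "l", "d_A", "q_invA", "family_label", "weight")
    if (!all(need %in% names(object@reflections)))
      msg <- c(msg, paste("reflections must have columns",
                          paste(need, collapse = ", ")))
    else {
      r <- object@reflections
      if (any(r$q_invA <= 0)) msg <- c(msg, "q must be positive")
      if (any(abs(r$q_invA * r$d_A - 2 * pi) > 1e-9))
        msg <- c(msg, "q * d must equal 2*pi (1e-9)")
    }
    if (object@crystalSize <= 0) msg <- c(msg, "crystalSize must be positive")
    if (object@relativeWeight < 0) msg <- c(msg, "weight must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a PhasePeakSet
#'
#' @param name phase name.
#' @param reflections data.frame as produced by [peakList()], or with at
#'   least a `q_invA` column (then `d_A` is filled as `2*pi/q` and `h,k,l`
#'   as NA).
#' @param crystalSize coherent size in Angstrom.
#' @param relativeWeight overall phase weight (default 1).
#' @return A [PhasePeakSet-class] object.
#' @export
phasePeakSet <- function(name, reflections, crystalSize,
                         relativeWeight = 1) {
  r <- as.data.frame(reflections)
  if (!"q_invA" %in% names(r))
    stop("'reflections' must contain a q_invA column")
  if (!"d_A" %in% names(r)) r$d_A <- 2 * pi / r$q_invA
  for (col in c("h", "k", "l")) if (!col %in% names(r)) r[[col]] <- NA_integer_
  if (!"family_label" %in% names(r)) r$family_label <- ""
  if (!"weight" %in% names(r)) r$weight <- 1
  new("PhasePeakSet", name = name,
      reflections = r[, c("h", "k", "l", "d_A", "q_invA",
                          "family_label", "weight")],
      crystalSize = as.numeric(crystalSize),
      relativeWeight = as.numeric(relativeWeight))
}

#' TextureModel: orientation distribution of a phase
#'
#' The orientation density g(chi) of plane normals over the hemisphere,
#' normalized so that `integral_0^90 g(chi) sin(chi) dchi = 1` (chi in
#' radians internally). Kinds: `"isotropic"` (g constant = 1),
#' `"gaussian_out_of_plane"` (Gaussian about `centerChi`, width `sigmaChi`),
#' and `"delta_in_plane"` (narrow 4-degree Gaussian at chi = 90, the
#' renderable stand-in for a true in-plane delta, e.g. lamellar wax).
#'
#' @slot kind character.
#' @slot sigmaChi numeric, degrees (Gaussian width).
#' @slot centerChi numeric, degrees.
#' @exportClass TextureModel
setClass("TextureModel",
  representation(kind = "character", sigmaChi = "numeric",
                 centerChi = "numeric"),
  validity = function(object) {
    msg <- character()
    kinds <- c("isotropic", "gaussian_out_of_plane", "delta_in_plane")
    if (!object@kind %in% kinds)
      msg <- c(msg, paste("kind must be one of:", paste(kinds, collapse = ", ")))
    if (object@kind != "isotropic" &&
        (!is.finite(object@sigmaChi) || object@sigmaChi <= 0))
      msg <- c(msg, "sigmaChi must be positive for non-isotropic textures")
    if (length(msg)) msg else TRUE
  })

#' Construct a TextureModel
#'
#' @param kind `"isotropic"`, `"gaussian_out_of_plane"` or `"delta_in_plane"`.
#' @param sigmaChi Gaussian width in degrees (ignored for isotropic;
#'   defaults to 4 for `"delta_in_plane"`).
#' @param centerChi center of the distribution in degrees (0 = substrate
#'   normal; 90 for in-plane).
#' @return A [TextureModel-class] object.
#' @export
textureModel <- function(kind = c("isotropic", "gaussian_out_of_plane",
                                  "delta_in_plane"),
                         sigmaChi = NA_real_, centerChi = NA_real_) {
  kind <- match.arg(kind)
  if (kind == "delta_in_plane") {
    if (is.na(sigmaChi)) sigmaChi <- 4
    if (is.na(centerChi)) centerChi <- 90
  }
  if (kind == "gaussian_out_of_plane" && is.na(centerChi)) centerChi <- 0
  if (kind == "isotropic") { sigmaChi <- 1; centerChi <- 0 }
  new("TextureModel", kind = kind, sigmaChi = as.numeric(sigmaChi),
      centerChi = as.numeric(centerChi))
}

#' Scene: generative description of a synthetic sample
#'
#' @slot phases list of `list(phase = PhasePeakSet, texture = TextureModel,
#'   scale = numeric)`.
#' @slot amorphousHalo numeric length-3: center q (A^-1), FWHM (A^-1),
#'   peak amplitude.
#' @slot flatBackground numeric, counts per unit solid-angle weight.
#' @slot exposure numeric, overall scale.
#' @exportClass Scene
setClass("Scene",
  representation(phases = "list", amorphousHalo = "numeric",
                 flatBackground = "numeric", exposure = "numeric"),
  validity = function(object) {
    msg <- character()
    ok <- vapply(object@phases, function(p)
      is.list(p) && is(p$phase, "PhasePeakSet") &&
        is(p$texture, "TextureModel") && is.numeric(p$scale) && p$scale >= 0,
      logical(1))
    if (length(object@phases) && !all(ok))
      msg <- c(msg, "each phase entry needs $phase, $texture, $scale >= 0")
    if (length(object@amorphousHalo) != 3L || any(object@amorphousHalo < 0))
      msg <- c(msg, "amorphousHalo must be (center, fwhm, amplitude), >= 0")
    if (object@flatBackground < 0 || object@exposure < 0)
      msg <- c(msg, "flatBackground and exposure must be >= 0")
    if (!length(object@phases) && all(object@amorphousHalo[3] == 0) &&
        object@flatBackground == 0)
      msg <- c(msg, "scene must contain at least one component")
    if (length(msg)) msg else TRUE
  })

#' Construct a Scene
#'
#' @param phases list of phase entries, each
#'   `list(phase = <PhasePeakSet>, texture = <TextureModel>, scale = <num>)`.
#' @param amorphousHalo numeric (center q, FWHM, amplitude); default
#'   `c(1.4, 0.7, 0)` (halo off unless amplitude set).
#' @param flatBackground flat counts per unit solid-angle weight.
#' @param exposure overall multiplicative exposure scale.
#' @return A [Scene-class] object.
#' @export
scene <- function(phases = list(), amorphousHalo = c(1.4, 0.7, 0),
                  flatBackground = 0, exposure = 1)
  new("Scene", phases = phases, amorphousHalo = as.numeric(amorphousHalo),
      flatBackground = as.numeric(flatBackground),
      exposure = as.numeric(exposure))

#' RockingSeries: frames from a specular rocking scan
#'
#' @slot sampleAngles numeric, strictly increasing sample angles theta_s
#'   (degrees).
#' @slot frames list of count matrices, one per angle.
#' @slot qBand numeric length-2, the reflection band targeted (A^-1).
#' @slot geometry the [DetectorGeometry-class] used.
#' @slot beam the [BeamSpec-class] used (energy; incidence varies per frame).
#' @exportClass RockingSeries
setClass("RockingSeries",
  representation(sampleAngles = "numeric", frames = "list",
                 qBand = "numeric", geometry = "DetectorGeometry",
                 beam = "BeamSpec"),
  validity = function(object) {
    msg <- character()
    if (length(object@frames) != length(object@sampleAngles))
      msg <- c(msg, "one frame per sample angle required")
    if (length(object@sampleAngles) > 1 && any(diff(object@sampleAngles) <= 0))
      msg <- c(msg, "sample angles must be strictly increasing")
    if (length(object@qBand) != 2L || object@qBand[1] >= object@qBand[2])
      msg <- c(msg, "qBand must be (q_lo, q_hi) with q_lo < q_hi")
    if (length(msg)) msg else TRUE
  })
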