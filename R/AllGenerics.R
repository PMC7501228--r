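# Accessor generics and show/plot methods. Slots are never reached into
# directly by user code; these accessors are the supported surface.

#' @rdname accessors
#' @param object an object from this package.
#' @export
setGeneric("energy", function(object) standardGeneric("energy"))
#' @rdname accessors
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))
#' @rdname accessors
#' @export
setGeneric("incidenceAngle", function(object) standardGeneric("incidenceAngle"))
#' @rdname accessors
#' @export
setGeneric("massDensity", function(object) standardGeneric("massDensity"))
#' @rdname accessors
#' @export
setGeneric("massFractions", function(object) standardGeneric("massFractions"))
#' @rdname accessors
#' @export
setGeneric("qValues", function(object) standardGeneric("qValues"))
#' @rdname accessors
#' @export
setGeneric("chiValues", function(object) standardGeneric("chiValues"))
#' @rdname accessors
#' @export
setGeneric("solidAngleWeight",
           function(object) standardGeneric("solidAngleWeight"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("profileGrid", function(object) standardGeneric("profileGrid"))
#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("uncertainty", function(object) standardGeneric("uncertainty"))
#' @rdname accessors
#' @export
setGeneric("nPixels", function(object) standardGeneric("nPixels"))
#' @rdname accessors
#' @export
setGeneric("profileMeta", function(object) standardGeneric("profileMeta"))
#' @rdname accessors
#' @export
setGeneric("branchLabels", function(object) standardGeneric("branchLabels"))
#' @rdname accessors
#' @export
setGeneric("scaleFactor", function(object) standardGeneric("scaleFactor"))
#' @rdname accessors
#' @export
setGeneric("qBand", function(object) standardGeneric("qBand"))
#' @rdname accessors
#' @export
setGeneric("sampleAngles", function(object) standardGeneric("sampleAngles"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("reflections", function(object) standardGeneric("reflections"))
#' @rdname accessors
#' @export
setGeneric("crystalSize", function(object) standardGeneric("crystalSize"))

#' Accessors for gixtex classes
#'
#' Small read-only accessors for the S4 data classes: beam parameters,
#' per-pixel maps, profile vectors, pole-figure components, rocking-series
#' contents.
#'
#' @name accessors
#' @return The corresponding slot value.
NULL

#' @rdname accessors
setMethod("energy", "BeamSpec", function(object) object@energy)
#' @rdname accessors
setMethod("wavelength", "BeamSpec", function(object) object@wavelength)
#' @rdname accessors
setMethod("incidenceAngle", "BeamSpec", function(object) object@incidence)
#' @rdname accessors
setMethod("massDensity", "Material", function(object) object@density)
#' @rdname accessors
setMethod("massFractions", "Material", function(object) object@massFractions)
#' @rdname accessors
setMethod("qValues", "QChiMap", function(object) object@q)
#' @rdname accessors
setMethod("chiValues", "QChiMap", function(object) object@chi)
#' @rdname accessors
setMethod("solidAngleWeight", "QChiMap", function(object) object@weight)
#' @rdname accessors
setMethod("validMask", "QChiMap", function(object) object@mask)
#' @rdname accessors
setMethod("profileGrid", "Profile1D", function(object) object@grid)
#' @rdname accessors
setMethod("intensity", "Profile1D", function(object) object@intensity)
#' @rdname accessors
setMethod("uncertainty", "Profile1D", function(object) object@sigma)
#' @rdname accessors
setMethod("nPixels", "Profile1D", function(object) object@nPixels)
#' @rdname accessors
setMethod("profileMeta", "Profile1D", function(object) object@meta)
#' @rdname accessors
setMethod("profileGrid", "PoleFigure", function(object) object@chiGrid)
#' @rdname accessors
setMethod("intensity", "PoleFigure", function(object) object@intensity)
#' @rdname accessors
setMethod("uncertainty", "PoleFigure", function(object) object@sigma)
#' @rdname accessors
setMethod("branchLabels", "PoleFigure", function(object) object@branch)
#' @rdname accessors
setMethod("scaleFactor", "PoleFigure", function(object) object@scaleFactor)
#' @rdname accessors
setMethod("qBand", "PoleFigure", function(object) object@qBand)
#' @rdname accessors
setMethod("profileMeta", "PoleFigure", function(object) object@meta)
#' @rdname accessors
setMethod("sampleAngles", "RockingSeries", function(object) object@sampleAngles)
#' @rdname accessors
setMethod("frames", "RockingSeries", function(object) object@frames)
#' @rdname accessors
setMethod("qBand", "RockingSeries", function(object) object@qBand)
#' @rdname accessors
setMethod("reflections", "PhasePeakSet", function(object) object@reflections)
#' @rdname accessors
setMethod("crystalSize", "PhasePeakSet", function(object) object@crystalSize)

setMethod("show", "BeamSpec", function(object) {
  cat(sprintf("BeamSpec: %.4g keV (lambda = %.5g A), alpha_i = %.3g deg\n",
              object@energy, object@wavelength, object@incidence))
})

setMethod("show", "Material", function(object) {
  w <- object@massFractions
  cat(sprintf("Material: %.3g g/cm^3; mass fractions %s\n", object@density,
              paste(sprintf("%s=%.3f", names(w), w), collapse = " ")))
})

setMethod("show", "DetectorGeometry", function(object) {
  cat(sprintf(
    "DetectorGeometry: %d x %d px of %.3g mm at %.4g mm; beam center (%.1f, %.1f); %s\n",
    object@shape[1], object@shape[2], object@pixelSize, object@distance,
    object@beamCenter[1], object@beamCenter[2], object@orientation))
})

setMethod("show", "QChiMap", function(object) {
  qr <- range(object@q[object@mask])
  cat(sprintf(
    "QChiMap (%s): %d x %d px; q in [%.3g, %.3g] A^-1; %d valid px (%.1f%%)\n",
    object@mode, nrow(object@q), ncol(object@q), qr[1], qr[2],
    sum(object@mask), 100 * mean(object@mask)))
})

setMethod("show", "Profile1D", function(object) {
  unit <- if (object@axis == "q") "A^-1" else "deg"
  ok <- object@nPixels > 0L
  cat(sprintf(
    "Profile1D over %s: %d bins in [%.3g, %.3g] %s (%d populated)\n",
    object@axis, length(object@grid), min(object@grid), max(object@grid),
    unit, sum(ok)))
})

setMethod("show", "PoleFigure", function(object) {
  cat(sprintf(
    "PoleFigure: chi in [%.1f, %.1f] deg (%d bins), q band [%.3g, %.3g] A^-1\n",
    min(object@chiGrid), max(object@chiGrid), length(object@chiGrid),
    object@qBand[1], object@qBand[2]))
  cat(sprintf("  branches: %s; GIWAXS scale factor %.4g\n",
              paste(sprintf("%s=%d", names(table(object@branch)),
                            as.integer(table(object@branch))), collapse = " "),
              object@scaleFactor))
})

setMethod("show", "UnitCell", function(object) {
  cat(sprintf(
    "UnitCell: a=%.4g b=%.4g c=%.4g A; alpha=%.4g beta=%.4g gamma=%.4g deg\n",
    object@a, object@b, object@c, object@alpha, object@beta, object@gamma))
})

setMethod("show", "PhasePeakSet", function(object) {
  cat(sprintf("PhasePeakSet '%s': %d reflections, L = %.3g A, weight %.3g\n",
              object@name, nrow(object@reflections), object@crystalSize,
              object@relativeWeight))
})

setMethod("show", "TextureModel", function(object) {
  cat(sprintf("TextureModel: %s (center %.3g deg, sigma %.3g deg)\n",
              object@kind, object@centerChi, object@sigmaChi))
})

setMethod("show", "Scene", function(object) {
  cat(sprintf(
    "Scene: %d phase(s); halo (center %.3g, fwhm %.3g, amp %.3g); bg %.3g; exposure %.3g\n",
    length(object@phases), object@amorphousHalo[1], object@amorphousHalo[2],
    object@amorphousHalo[3], object@flatBackground, object@exposure))
  for (p in object@phases)
    cat(sprintf("  - %s x %.3g [%s]\n", p$phase@name, p$scale,
                p$texture@kind))
})

setMethod("show", "RockingSeries", function(object) {
  cat(sprintf(
    "RockingSeries: %d frames, theta_s in [%.3g, %.3g] deg, q band [%.3g, %.3g] A^-1\n",
    length(object@frames), min(object@sampleAngles), max(object@sampleAngles),
    object@qBand[1], object@qBand[2]))
})

#' Plot a reduced profile or pole figure
#'
#' Base-graphics line plot with +/- 1 sigma error band where uncertainties
#' are available.
#'
#' @param x a [Profile1D-class] or [PoleFigure-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
setMethod("plot", signature(x = "Profile1D", y = "missing"),
  function(x, y, ...) {
    ok <- x@nPixels > 0L
    xl <- if (x@axis == "q") expression(q ~ (ring(A)^-1)) else
      expression(chi ~ (degree))
    plot(x@grid[ok], x@intensity[ok], type = "l", xlab = xl,
         ylab = "intensity (counts / solid angle)", ...)
    lines(x@grid[ok], x@intensity[ok] + x@sigma[ok], lty = 3, col = gray(0.5))
    lines(x@grid[ok], x@intensity[ok] - x@sigma[ok], lty = 3, col = gray(0.5))
    invisible(x)
  })

#' @rdname plot-Profile1D-missing-method
#' @export
setMethod("plot", signature(x = "PoleFigure", y = "missing"),
  function(x, y, ...) {
    plot(x@chiGrid, x@intensity, type = "n",
         xlab = expression(chi ~ (degree)), ylab = "pole-figure intensity",
         ...)
    for (b in unique(x@branch)) {
      sel <- x@branch == b
      lines(x@chiGrid[sel], x@intensity[sel],
            col = if (b == "rocking") "red" else "black")
    }
    abline(v = c(-1, 1) * x@meta$matchChi %||% 7.5, lty = 3, col = gray(0.6))
    invisible(x)
  })

`%||%` <- function(a, b) if (is.null(a)) b else a
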