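# X-ray optics: wavelength, electron density, critical angle, penetration
# depth, and the grazing-incidence detector -> reciprocal-space mapping.

# atomic numbers and standard atomic weights for the elements a dried
# carbohydrate sample can contain (plus common hetero-elements)
.element_Z <- c(H = 1, C = 6, N = 7, O = 8, Na = 11, Mg = 12, P = 15,
                S = 16, Cl = 17, K = 19, Ca = 20, Si = 14)
.element_A <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, Na = 22.990,
                Mg = 24.305, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
                Ca = 40.078, Si = 28.085)

# Mass attenuation coefficients mu/rho in cm^2/g (total, with coherent
# scattering) at 8, 10, 15, 20 keV; NIST-style anchors, log-log
# interpolated in between. Only H, C, N, O are needed for cell-wall work.
.mu_rho_energies <- c(8, 10, 15, 20)
.mu_rho_table <- rbind(
  H = c(0.3914, 0.3854, 0.3764, 0.3695),
  C = c(4.576,  2.373,  0.8063, 0.4420),
  N = c(7.562,  3.879,  1.236,  0.6178),
  O = c(11.63,  5.952,  1.976,  0.8651))

#' Photon energy to wavelength
#'
#' `lambda = hc/E` with `hc = 12.3984 keV*Angstrom`.
#'
#' @param energy photon energy in keV (positive).
#' @return Wavelength in Angstrom.
#' @examples
#' energyToWavelength(10)       # 1.23984
#' energyToWavelength(12.3984)  # 1
#' @export
energyToWavelength <- function(energy) {
  if (!is.numeric(energy) || any(!is.finite(energy)) || any(energy <= 0))
    stop("'energy' must be positive (keV)")
  .hc_keV_A / energy
}

#' Scattering angle to momentum transfer and back
#'
#' `q = 4*pi*sin(theta/2)/lambda`, with `theta` the full scattering angle
#' between the incident and scattered wavevectors.
#'
#' @param theta full scattering angle in degrees, in `[0, 180)`.
#' @param wavelength X-ray wavelength in Angstrom.
#' @return `qFromScatteringAngle`: q in inverse Angstrom.
#'   `scatteringAngleFromQ`: theta in degrees.
#' @examples
#' qFromScatteringAngle(17.59, 1.23984)   # ~1.55
#' scatteringAngleFromQ(1.55, 1.23984)
#' @export
qFromScatteringAngle <- function(theta, wavelength) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta >= 180))
    stop("'theta' must lie in [0, 180) degrees")
  if (any(wavelength <= 0)) stop("'wavelength' must be positive (A)")
  4 * pi * sin(.deg2rad(theta) / 2) / wavelength
}

#' @rdname qFromScatteringAngle
#' @param q momentum transfer in inverse Angstrom; must satisfy
#'   `q < 4*pi/lambda`.
#' @export
scatteringAngleFromQ <- function(q, wavelength) {
  if (any(q < 0)) stop("'q' must be >= 0")
  s <- q * wavelength / (4 * pi)
  if (any(s >= 1)) stop("'q' exceeds the 4*pi/lambda backscattering limit")
  .rad2deg(2 * asin(s))
}

#' Lattice spacing from momentum transfer (and back)
#'
#' `d = 2*pi/q`; the map is its own inverse, so the same function converts a
#' d-spacing to q.
#'
#' @param q momentum transfer in inverse Angstrom (positive); or, read as
#'   a d-spacing in Angstrom, the return value is the corresponding q.
#' @return `2*pi/q` in Angstrom (or inverse Angstrom).
#' @examples
#' dFromQ(1.52)  # 4.13 A, epicuticular wax
#' dFromQ(1.70)  # 3.70 A
#' @export
dFromQ <- function(q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0))
    stop("'q' must be positive")
  2 * pi / q
}

#' @rdname dFromQ
#' @param d lattice spacing in Angstrom.
#' @export
qFromD <- function(d) dFromQ(d)

#' Electron density of a material
#'
#' `rho_e = rho * N_A * sum_i(w_i * Z_i / A_i)`, converted to electrons per
#' cubic Angstrom.
#'
#' @param material a [Material-class].
#' @return Electron density in e/A^3.
#' @examples
#' electronDensity(cellWallMaterial())   # ~0.479 e/A^3
#' @export
electronDensity <- function(material) {
  stopifnot(is(material, "Material"))
  w <- massFractions(material)
  el <- names(w)
  unknown <- setdiff(el, names(.element_Z))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  perGram <- sum(w * .element_Z[el] / .element_A[el]) * .N_A  # e per gram
  massDensity(material) * perGram * 1e-24                    # e per A^3
}

#' Critical angle for total external reflection
#'
#' `delta = r_e * lambda^2 * rho_e / (2*pi)` and `theta_c = sqrt(2*delta)`,
#' with `r_e = 2.8179403e-5 A`. For the model cell wall (C6H10O5 at
#' 1.5 g/cm^3) this gives 0.147 deg at 10 keV and 0.116 deg at 12.7 keV.
#' `theta_c * E` is constant for a fixed material (theta_c proportional to
#' lambda).
#'
#' @param material a [Material-class].
#' @param energy photon energy in keV.
#' @return Critical angle in degrees.
#' @examples
#' criticalAngle(cellWallMaterial(), 10)
#' criticalAngle(cellWallMaterial(), 12.7)
#' @export
criticalAngle <- function(material, energy) {
  lambda <- energyToWavelength(energy)
  delta <- .r_e_A * lambda^2 * electronDensity(material) / (2 * pi)
  .rad2deg(sqrt(2 * delta))
}

#' Mass attenuation coefficient of a material
#'
#' Mixture rule `(mu/rho) = sum_i w_i (mu/rho)_i` using the embedded H/C/N/O
#' anchors at 8, 10, 15 and 20 keV with log-log interpolation; valid for
#' 8-20 keV.
#'
#' @param material a [Material-class].
#' @param energy photon energy in keV (8-20).
#' @return `list(mu_rho = cm^2/g, mu = linear attenuation in 1/cm)`.
#' @export
massAttenuation <- function(material, energy) {
  stopifnot(is(material, "Material"))
  if (energy < min(.mu_rho_energies) || energy > max(.mu_rho_energies))
    stop("attenuation table covers 8-20 keV only")
  w <- massFractions(material)
  missing <- setdiff(names(w), rownames(.mu_rho_table))
  if (length(missing))
    stop("no attenuation data for element(s): ",
         paste(missing, collapse = ", "))
  perEl <- vapply(names(w), function(el) {
    exp(approx(log(.mu_rho_energies), log(.mu_rho_table[el, ]),
               xout = log(energy))$y)
  }, numeric(1))
  mu_rho <- sum(w * perEl)
  list(mu_rho = mu_rho, mu = mu_rho * massDensity(material))
}

#' 1/e penetration depth in grazing incidence
#'
#' Depth at which the transmitted wave falls to 1/e, from the complex
#' refraction argument: `Lambda = lambda / (c * Im[sqrt(alpha_i^2 -
#' theta_c^2 + 2i*beta)])` with `beta = mu*lambda/(4*pi)` and `c = 4*pi`
#' for the intensity-1/e convention (default) or `2*pi` for the
#' amplitude-1/e convention (twice as deep). Angles in radians inside the
#' formula. Limits: well above the critical angle the depth approaches
#' `sin(alpha_i)/mu` (intensity convention); below it with absorption off it
#' approaches the evanescent form `lambda/(4*pi*sqrt(theta_c^2 -
#' alpha_i^2))`.
#'
#' Published grazing-incidence depths rarely state which convention (or
#' which attenuation data) they use; the two conventions differ by exactly a
#' factor of 2, so treat literature values as order-of-magnitude anchors.
#'
#' @param material a [Material-class].
#' @param energy photon energy in keV.
#' @param alphaI incidence angle in degrees (positive).
#' @param convention `"intensity"` (default) or `"amplitude"`.
#' @param muOverride optional linear attenuation coefficient in 1/cm to use
#'   instead of the embedded table (set 0 for the absorption-free limit).
#' @return Penetration depth in micrometers.
#' @examples
#' penetrationDepth(cellWallMaterial(), 10, 0.15)
#' penetrationDepth(cellWallMaterial(), 12.7, 0.12)
#' @export
penetrationDepth <- function(material, energy, alphaI,
                             convention = c("intensity", "amplitude"),
                             muOverride = NULL) {
  convention <- match.arg(convention)
  if (!is.numeric(alphaI) || alphaI <= 0)
    stop("'alphaI' must be positive (degrees)")
  lambda <- energyToWavelength(energy)
  thetaC <- .deg2rad(criticalAngle(material, energy))
  mu_cm <- if (is.null(muOverride)) massAttenuation(material, energy)$mu
           else muOverride
  mu_A <- mu_cm * 1e-8                      # 1/cm -> 1/A
  beta <- mu_A * lambda / (4 * pi)
  a <- .deg2rad(alphaI)
  imag <- Im(sqrt(complex(real = a^2 - thetaC^2, imaginary = 2 * beta)))
  if (imag <= 0) return(Inf)
  denom <- if (convention == "intensity") 4 * pi else 2 * pi
  depth_A <- lambda / (denom * imag)
  depth_A * 1e-4                            # A -> um
}

#' Smallest accessible |chi| at a given q (missing wedge half-angle)
#'
#' A flat detector in grazing incidence cannot reach the polar region
#' around the substrate normal: the smallest attainable |chi| at momentum
#' transfer q is `chi_min = asin(q/(2k)) - alpha_i` (floored at 0), with
#' `k = 2*pi/lambda`. This is exact on the detector meridian: there
#' `chi = (alpha_f - alpha_i)/2` while `asin(q/2k) = (alpha_f + alpha_i)/2`.
#'
#' @param q momentum transfer in inverse Angstrom, `0 < q < 2k`.
#' @param beam a [BeamSpec-class] (its energy and incidence angle are used).
#' @return Half-angle of the missing wedge in degrees.
#' @examples
#' missingWedgeHalfangle(1.15, beamSpec(10, 0.15))   # ~6.4 deg
#' @export
missingWedgeHalfangle <- function(q, beam) {
  stopifnot(is(beam, "BeamSpec"))
  k <- 2 * pi / wavelength(beam)
  if (any(q <= 0) || any(q >= 2 * k))
    stop("'q' must satisfy 0 < q < 2k = ", format(2 * k))
  pmax(.rad2deg(asin(q / (2 * k))) - incidenceAngle(beam), 0)
}

# per-pixel "up" (v) and "right" (h) displacements in mm, row-major matrices
.pixelOffsets <- function(geometry) {
  rows <- geometry@shape[1]; cols <- geometry@shape[2]
  px <- geometry@pixelSize
  rowIdx <- matrix(seq_len(rows), rows, cols)
  colIdx <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  v <- if (geometry@orientation == "up_is_low_row")
    (geometry@beamCenter[1] - rowIdx) * px
  else (rowIdx - geometry@beamCenter[1]) * px
  h <- (colIdx - geometry@beamCenter[2]) * px
  list(v = v, h = h)
}

#' Map every detector pixel to (q, chi) with Ewald-curvature correction
#'
#' In grazing mode the laboratory frame is rotated by the incidence angle
#' alpha_i (exact trigonometry, no small-angle approximation): the incident
#' wavevector is `k(cos a, 0, -sin a)` and the pixel direction is obtained
#' by rotating the detector-frame direction `(D, h, v)/L` by `-alpha_i`
#' about the horizontal axis. The scattered wavevector sits on the Ewald
#' sphere, `q = k_f - k_i`, `q = |q|`, and
#' `chi = sign(h) * atan2(|q_xy|, q_z)` in degrees (0 = substrate normal).
#' The mask is FALSE at the direct beam, for exit directions below the
#' sample horizon, and inside the missing wedge
#' (`|chi| < asin(q/2k) - alpha_i`).
#'
#' In transmission mode the beam is normal to the sample: q depends only on
#' the in-detector radius, chi is the apparent azimuth from the "up" axis
#' folded to `[-90, 90]` (Friedel equivalence), and there is no wedge.
#'
#' The solid-angle weight is the relative subtended solid angle
#' `(D/L)^3`, normalized to 1 at the beam center.
#'
#' @param geometry a [DetectorGeometry-class].
#' @param beam a [BeamSpec-class].
#' @param mode `"grazing"` (default) or `"transmission"`.
#' @return A [QChiMap-class].
#' @examples
#' m <- buildQChiMap(defaultGeometry(rebin = 8L), beamSpec(10, 0.15))
#' range(qValues(m)[validMask(m)])
#' @export
buildQChiMap <- function(geometry, beam,
                         mode = c("grazing", "transmission")) {
  stopifnot(is(geometry, "DetectorGeometry"), is(beam, "BeamSpec"))
  mode <- match.arg(mode)
  if (geometry@distance <= 0) stop("degenerate geometry: distance must be > 0")
  D <- geometry@distance
  off <- .pixelOffsets(geometry)
  v <- off$v; h <- off$h
  L <- sqrt(D^2 + h^2 + v^2)
  k <- 2 * pi / wavelength(beam)
  weight <- (D / L)^3

  if (mode == "transmission") {
    theta <- atan2(sqrt(h^2 + v^2), D)              # full scattering angle
    q <- 2 * k * sin(theta / 2)
    chi <- .rad2deg(atan2(h, v))                    # apparent azimuth
    flip <- abs(chi) > 90
    chi[flip] <- -sign(chi[flip]) * (180 - abs(chi[flip]))
    mask <- q > 0
  } else {
    a <- .deg2rad(incidenceAngle(beam))
    # pixel direction in the lab frame (rotation by -a about the y axis)
    ux <- (D * cos(a) + v * sin(a)) / L
    uy <- h / L
    uz <- (v * cos(a) - D * sin(a)) / L
    qx <- k * (ux - cos(a))
    qy <- k * uy
    qz <- k * (uz + sin(a))
    q <- sqrt(qx^2 + qy^2 + qz^2)
    qxy <- sqrt(qx^2 + qy^2)
    chi <- .rad2deg(atan2(qxy, qz))
    sgn <- ifelse(h < 0, -1, 1)
    chi <- sgn * pmin(chi, 90)                      # qz < 0 is masked below
    aboveHorizon <- uz >= 0
    chiMin <- pmax(.rad2deg(asin(pmin(q / (2 * k), 1))) -
                     incidenceAngle(beam), 0)
    inWedge <- abs(chi) < chiMin - 1e-9
    mask <- aboveHorizon & q > 0 & !inWedge
  }
  chi[q == 0] <- 0
  new("QChiMap", q = q, chi = chi, weight = weight, mask = mask,
      geometry = geometry, beam = beam, mode = mode)
}
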