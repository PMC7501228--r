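# Unit-cell crystallography for cellulose I-beta and the lamellar wax
# phase: d-spacings via the reciprocal metric tensor, symmetry-reduced peak
# lists, Scherrer size broadening, and simulated 1D powder patterns.

# direct-space metric tensor (A^2)
.metricTensor <- function(cell) {
  ca <- cos(.deg2rad(cell@alpha)); cb <- cos(.deg2rad(cell@beta))
  cg <- cos(.deg2rad(cell@gamma))
  a <- cell@a; b <- cell@b; cc <- cell@c
  matrix(c(a * a,      a * b * cg, a * cc * cb,
           a * b * cg, b * b,      b * cc * ca,
           a * cc * cb, b * cc * ca, cc * cc), 3, 3)
}

#' The cellulose I-beta unit cell
#'
#' Monoclinic cell of the I-beta allomorph (the dominant form in higher
#' plants), from the synchrotron/neutron fiber-diffraction structure of
#' tunicate cellulose: a = 7.784, b = 8.201, c = 10.38 Angstrom,
#' gamma = 96.5 degrees (c is the chain axis).
#'
#' @return A [UnitCell-class].
#' @export
celluloseIbeta <- function()
  unitCell(7.784, 8.201, 10.38, gamma = 96.5)

#' d-spacing of a lattice plane (general triclinic)
#'
#' `1/d^2 = h' G* h` with `G*` the reciprocal metric tensor (inverse of the
#' direct metric tensor); works for any crystal system. For the cellulose
#' I-beta cell the principal equatorial pair comes out at
#' q = 2*pi/d of 1.055 and 1.182 A^-1 (the (110)/(1-10) pair; which label
#' attaches to which member depends on the sign convention adopted for the
#' monoclinic angle, so this package reports the pair) and 1.625 A^-1 for
#' (200).
#'
#' @param cell a [UnitCell-class].
#' @param h,k,l Miller indices, not all zero.
#' @return `list(d = Angstrom, q = 2*pi/d in A^-1)`.
#' @examples
#' dHkl(celluloseIbeta(), 2, 0, 0)
#' @export
dHkl <- function(cell, h, k, l) {
  stopifnot(is(cell, "UnitCell"))
  if (length(h) != 1L || length(k) != 1L || length(l) != 1L)
    stop("one (h, k, l) triple at a time")
  if (h == 0 && k == 0 && l == 0)
    stop("(0, 0, 0) is not a reflection")
  Gstar <- solve(.metricTensor(cell))
  v <- c(h, k, l)
  d <- 1 / sqrt(drop(t(v) %*% Gstar %*% v))
  list(d = d, q = 2 * pi / d)
}

#' Enumerate reflections up to a q limit
#'
#' Enumerates (h, k, l) with `|h|,|k|,|l| <= hklRange`, keeps one member of
#' each Friedel pair (d(hkl) = d(-h-k-l) exactly), deduplicates reflections
#' whose d agree within 1e-6 Angstrom into one row (family label lists the
#' members), and sorts ascending in q.
#'
#' @param cell a [UnitCell-class].
#' @param qMax upper q limit in A^-1 (positive).
#' @param hklRange maximum |index| searched (default 2; raise for dense
#'   cells or large qMax).
#' @return data.frame with columns `h, k, l, d_A, q_invA, family_label,
#'   weight` (weight = multiplicity of the merged family).
#' @examples
#' peakList(celluloseIbeta(), qMax = 1.7)
#' @export
peakList <- function(cell, qMax, hklRange = 2L) {
  stopifnot(is(cell, "UnitCell"))
  if (!is.numeric(qMax) || qMax <= 0) stop("'qMax' must be positive")
  rng <- seq.int(-hklRange, hklRange)
  hkl <- expand.grid(h = rng, k = rng, l = rng)
  hkl <- hkl[!(hkl$h == 0 & hkl$k == 0 & hkl$l == 0), ]
  # one member per Friedel pair: first nonzero index positive
  keep <- with(hkl, h > 0 | (h == 0 & k > 0) | (h == 0 & k == 0 & l > 0))
  hkl <- hkl[keep, ]
  Gstar <- solve(.metricTensor(cell))
  M <- as.matrix(hkl)
  d <- 1 / sqrt(rowSums((M %*% Gstar) * M))
  q <- 2 * pi / d
  sel <- q <= qMax
  hkl <- hkl[sel, , drop = FALSE]; d <- d[sel]; q <- q[sel]
  if (!nrow(hkl))
    return(data.frame(h = integer(), k = integer(), l = integer(),
                      d_A = numeric(), q_invA = numeric(),
                      family_label = character(), weight = numeric()))
  ord <- order(q)
  hkl <- hkl[ord, ]; d <- d[ord]; q <- q[ord]
  # merge rows whose d agree within 1e-6 A
  group <- cumsum(c(TRUE, diff(d) < -1e-6 | diff(d) > 1e-6))
  out <- do.call(rbind, lapply(split(seq_along(group), group), function(i) {
    lab <- paste(sprintf("(%d%d%d)", hkl$h[i], hkl$k[i], hkl$l[i]),
                 collapse = "/")
    data.frame(h = hkl$h[i[1]], k = hkl$k[i[1]], l = hkl$l[i[1]],
               d_A = d[i[1]], q_invA = 2 * pi / d[i[1]],
               family_label = lab, weight = length(i))
  }))
  rownames(out) <- NULL
  out
}

#' Scherrer peak width in q-space
#'
#' `Delta_q(FWHM) = 2*pi*K/L` for coherent crystal size L and shape factor
#' K. The 3-nm microfibril crystals of primary cell walls give
#' Delta_q ~ 0.19 A^-1, wide enough to merge the 1.055/1.182 A^-1 pair into
#' the single broad feature observed near 1.15 A^-1.
#'
#' @param crystalSize coherent size L in Angstrom (positive).
#' @param shapeFactor Scherrer constant K, in `[0.5, 1.5]` (default 0.9).
#' @return FWHM in inverse Angstrom.
#' @examples
#' scherrerFwhm(30)    # 0.188 A^-1
#' scherrerFwhm(300)
#' @export
scherrerFwhm <- function(crystalSize, shapeFactor = 0.9) {
  if (any(crystalSize <= 0)) stop("'crystalSize' must be positive (A)")
  if (any(shapeFactor < 0.5) || any(shapeFactor > 1.5))
    stop("'shapeFactor' must lie in [0.5, 1.5]")
  2 * pi * shapeFactor / crystalSize
}

# area-normalized line profiles on a q grid
.gaussProfile <- function(q, q0, fwhm)
  dnorm(q, mean = q0, sd = fwhm / (2 * sqrt(2 * log(2))))
.lorentzProfile <- function(q, q0, fwhm) {
  hw <- fwhm / 2
  (hw / pi) / ((q - q0)^2 + hw^2)
}
.peakProfile <- function(q, q0, fwhm, eta = 0) {
  if (eta <= 0) .gaussProfile(q, q0, fwhm)
  else eta * .lorentzProfile(q, q0, fwhm) +
    (1 - eta) * .gaussProfile(q, q0, fwhm)
}

# radial intensity of one phase on a q vector (sum of area-normalized
# peaks times reflection weights, times the phase weight)
.phaseRadial <- function(phase, q, shapeFactor = 0.9, eta = 0) {
  fwhm <- scherrerFwhm(phase@crystalSize, shapeFactor)
  r <- phase@reflections
  out <- 0
  for (i in seq_len(nrow(r)))
    out <- out + r$weight[i] * .peakProfile(q, r$q_invA[i], fwhm, eta)
  phase@relativeWeight * out
}

.haloIntensity <- function(halo, q) {
  if (halo[3] <= 0) return(rep(0, length(q)))
  sd <- halo[2] / (2 * sqrt(2 * log(2)))
  halo[3] * exp(-(q - halo[1])^2 / (2 * sd^2))
}

#' Simulated 1D powder pattern
#'
#' Sum of Scherrer-broadened, area-normalized peaks (Gaussian by default,
#' pseudo-Voigt via `eta`) for each phase, plus an optional broad amorphous
#' Gaussian halo. The integrated area equals the sum of the component areas
#' (each reflection contributes `phase weight x reflection weight`).
#'
#' @param phases list of [PhasePeakSet-class] objects (or a single one).
#' @param qGrid strictly increasing q grid in A^-1.
#' @param amorphousHalo numeric (center, FWHM, amplitude); amplitude is the
#'   halo peak height (0 disables it).
#' @param shapeFactor Scherrer constant K (default 0.9).
#' @param eta pseudo-Voigt Lorentzian fraction in `[0, 1]` (0 = Gaussian).
#' @return A [Profile1D-class] over q (sigma 0: noiseless model).
#' @examples
#' cel <- celluloseIbetaPhase(crystalSize = 30)
#' p <- powderPattern(cel, qGrid = seq(0.2, 2.2, by = 0.002))
#' @export
powderPattern <- function(phases, qGrid, amorphousHalo = c(1.4, 0.7, 0),
                          shapeFactor = 0.9, eta = 0) {
  if (is(phases, "PhasePeakSet")) phases <- list(phases)
  if (any(diff(qGrid) <= 0)) stop("'qGrid' must be strictly increasing")
  y <- rep(0, length(qGrid))
  for (ph in phases) y <- y + .phaseRadial(ph, qGrid, shapeFactor, eta)
  y <- y + .haloIntensity(amorphousHalo, qGrid)
  .profile1D("q", qGrid, y, sigma = rep(0, length(qGrid)),
             nPixels = rep(1L, length(qGrid)),
             meta = list(kind = "powder_pattern", shapeFactor = shapeFactor,
                         eta = eta, halo = amorphousHalo))
}

#' Cellulose I-beta phase preset
#'
#' Reflections of the I-beta cell up to `qMax`, by default the three
#' principal equatorial reflections (the 1.055/1.182 A^-1 pair and (200) at
#' 1.625 A^-1) with equal weights, at the ~3 nm coherent size typical of
#' primary-cell-wall microfibrils.
#'
#' @param crystalSize coherent size in Angstrom (default 30).
#' @param qMax reflection list limit (default 1.7 A^-1).
#' @param relativeWeight phase weight (default 1).
#' @return A [PhasePeakSet-class].
#' @export
celluloseIbetaPhase <- function(crystalSize = 30, qMax = 1.7,
                                relativeWeight = 1) {
  pl <- peakList(celluloseIbeta(), qMax = qMax)
  # principal equatorial reflections: the (110)/(1-10) pair and (200)
  pl <- pl[pl$l == 0 &
             ((pl$h == 1 & abs(pl$k) == 1) | (pl$h == 2 & pl$k == 0)), ]
  pl$weight <- 1
  phasePeakSet("cellulose_Ibeta", pl, crystalSize = crystalSize,
               relativeWeight = relativeWeight)
}

#' Epicuticular wax phase
#'
#' Two-reflection lamellar phase with d = 4.13 and 3.73 Angstrom
#' (q = 1.521 and 1.684 A^-1), the spacings reported for plant epicuticular
#' wax platelets. Default crystal size 300 Angstrom: wax peaks are much
#' sharper than the 3-nm cellulose reflections.
#'
#' @param crystalSize coherent size in Angstrom (default 300).
#' @param relativeWeight phase weight (default 1).
#' @return A [PhasePeakSet-class].
#' @examples
#' reflections(waxPhase())
#' @export
waxPhase <- function(crystalSize = 300, relativeWeight = 1) {
  d <- c(4.13, 3.73)
  refl <- data.frame(h = c(1L, 2L), k = 0L, l = 0L,
                     d_A = d, q_invA = 2 * pi / d,
                     family_label = c("wax_001", "wax_002"),
                     weight = c(1, 1))
  phasePeakSet("epicuticular_wax", refl, crystalSize = crystalSize,
               relativeWeight = relativeWeight)
}

#' Export a reflection list as CSV
#'
#' Columns `h, k, l, d_A, q_invA, family_label` (plus `weight`).
#'
#' @param reflections data.frame from [peakList()] or
#'   [reflections()][accessors].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writePeakListCsv <- function(reflections, path) {
  write.csv(reflections, path, row.names = FALSE)
  invisible(path)
}
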