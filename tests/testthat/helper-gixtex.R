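# Shared fixtures: small detector geometries, cached (q, chi) maps, and a
# peak-detection oracle. Everything is generated in code; no binary data.

# desk-scale geometries: same physical aperture as the default detector,
# coarsened for speed
geomG64 <- defaultGeometry("giwaxs", rebin = 8L)     # 64 x 64
geomG128 <- defaultGeometry("giwaxs", rebin = 4L)    # 128 x 128
geomG256 <- defaultGeometry("giwaxs", rebin = 2L)    # 256 x 256
geomT256 <- defaultGeometry("transmission", rebin = 2L)

beam10 <- beamSpec(10, 0.15)     # ALS-style setting
beam127 <- beamSpec(12.7, 0.12)  # SSRL-style setting (rocking scans)

mapG64 <- buildQChiMap(geomG64, beam10)
mapG128 <- buildQChiMap(geomG128, beam127)
mapG256 <- buildQChiMap(geomG256, beam127)
mapT256 <- buildQChiMap(geomT256, beamSpec(10, 0), mode = "transmission")

qGridStd <- seq(0.25, 2.3, by = 0.01)
chiGridStd <- seq(-35, 35) * 2.5          # centers include 0 and +/-7.5

# a halo-free Gaussian-textured cellulose scene: isolates the texture
# estimator from the amorphous-background pedestal
gaussScene <- function(sigmaChi, exposure = 15, flat = 0.05,
                       crystalSize = 30) {
  scene(phases = list(list(
    phase = celluloseIbetaPhase(crystalSize = crystalSize),
    texture = textureModel("gaussian_out_of_plane", sigmaChi = sigmaChi),
    scale = 1)),
    amorphousHalo = c(1.4, 0.7, 0), flatBackground = flat,
    exposure = exposure)
}

# local maxima of a profile (interior sign changes of the first difference)
localMaxima <- function(profile, window = NULL) {
  g <- profileGrid(profile)
  i <- intensity(profile)
  ok <- !is.na(i)
  g <- g[ok]; i <- i[ok]
  j <- which(diff(sign(diff(i))) == -2) + 1L
  res <- data.frame(q = g[j], intensity = i[j])
  if (!is.null(window))
    res <- res[res$q >= window[1] & res$q <= window[2], ]
  res[order(-res$intensity), ]
}

# z-score of a band excess over the linear interpolation of two flanking
# bands; a peak oracle robust to smooth backgrounds
peakZ <- function(profile, window, flankLo, flankHi) {
  g <- profileGrid(profile); i <- intensity(profile)
  s <- uncertainty(profile)
  pick <- function(w) {
    sel <- !is.na(i) & g >= w[1] & g <= w[2]
    c(mean(g[sel]), mean(i[sel]), sqrt(sum(s[sel]^2)) / sum(sel))
  }
  w <- pick(window); lo <- pick(flankLo); hi <- pick(flankHi)
  slope <- (hi[2] - lo[2]) / (hi[1] - lo[1])
  base <- lo[2] + slope * (w[1] - lo[1])
  (w[2] - base) / sqrt(w[3]^2 + lo[3]^2 + hi[3]^2)
}

# internal 1D-profile constructor, used to build synthetic traces for
# stitching unit tests
mkProfile <- function(axis, grid, intensity, sigma = rep(0, length(grid)),
                      n = rep(1L, length(grid)), meta = list())
  gixtex:::.profile1D(axis, grid, intensity, sigma, n, meta = meta)

mkPoleFigure <- function(chiGrid, intensity,
                         sigma = rep(0, length(chiGrid)),
                         branch = rep("giwaxs", length(chiGrid)),
                         scale = 1, qBand = c(0.99, 1.31), meta = list())
  methods::new("PoleFigure", chiGrid = chiGrid, intensity = intensity,
               sigma = sigma, branch = branch, scaleFactor = scale,
               qBand = qBand, meta = meta)
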