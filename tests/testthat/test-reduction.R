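# Frame reduction: sector/azimuthal/cake integration, line cuts and local
# background subtraction.

test_that("a flat unit frame reduces to a constant profile of 1", {
  fr <- matrix(1, 64, 64)
  p <- sectorProfile(fr, mapG64, c(-90, 90), seq(0.2, 3.2, by = 0.05),
                     applySolidAngle = FALSE)
  i <- intensity(p)[nPixels(p) > 0L]
  expect_equal(i, rep(1, length(i)), tolerance = 1e-12)
})

test_that("cake integration conserves masked counts", {
  scn <- scenePreset("unextracted", exposure = 20)
  fr <- renderGiwaxs(scn, geomG128, beam127, seed = 31, map = mapG128)
  cake <- cakeIntegrate(fr, mapG128, qGrid = seq(0.025, 4.175, by = 0.05),
                        chiGrid = seq(-89, 89, by = 2),
                        applySolidAngle = FALSE)
  binned <- sum(cake$intensity * cake$nPixels, na.rm = TRUE)
  total <- sum(fr[validMask(mapG128)])
  expect_equal(binned, total, tolerance = 1e-6)
  expect_equal(cake$totalBinnedCounts, total, tolerance = 1e-6)
  expect_equal(sum(cake$nPixels), sum(validMask(mapG128)))
})

test_that("sector profiles locate the cellulose and wax reflections", {
  scn <- scenePreset("unextracted", exposure = 40)
  fr <- renderGiwaxs(scn, geomG256, beam127, noiseless = TRUE,
                     map = mapG256)
  op <- sectorProfile(fr, mapG256, c(-17, 17), qGridStd)
  mxO <- localMaxima(op, window = c(1.00, 1.30))
  expect_gte(nrow(mxO), 1L)     # merged 110-family feature
  expect_gte(mxO$q[1], 1.08); expect_lte(mxO$q[1], 1.20)
  mx200 <- localMaxima(op, window = c(1.45, 1.70))
  expect_gte(nrow(mx200), 1L)   # (200)-region feature
  ip <- sectorProfile(fr, mapG256, c(78, 88), qGridStd, bothLobes = TRUE)
  mxI <- localMaxima(ip, window = c(1.40, 1.80))
  expect_gte(nrow(mxI), 2L)
  expect_equal(sort(mxI$q[1:2]), c(1.52, 1.68), tolerance = 0.02)
  # no exit direction reaches chi = 90 exactly in grazing incidence
  expect_error(sectorProfile(fr, mapG256, c(89.9, 90), qGridStd),
               "empty sector")
})

test_that("azimuthal profiles recover an injected gaussian texture width", {
  fr <- renderGiwaxs(gaussScene(20), geomG256, beam127, seed = 6,
                     map = mapG256)
  az <- azimuthalProfile(fr, mapG256, chiGrid = seq(-60, 60, by = 2.5))
  ok <- !is.na(intensity(az)) & intensity(az) > 0 &
    abs(profileGrid(az)) <= 45
  fit <- lm(log(intensity(az)[ok]) ~ I(profileGrid(az)[ok]^2))
  expect_equal(sqrt(-1 / (2 * coef(fit)[[2]])), 20, tolerance = 0.10)
})

test_that("wedge bins are flagged for grazing maps, populated in transmission", {
  frG <- matrix(1, 128, 128)
  azG <- azimuthalProfile(frG, mapG128, qBand = c(0.99, 1.31),
                          chiGrid = chiGridStd, applySolidAngle = FALSE)
  # the wedge half-angle over this band is ~4-6 deg: the chi = 0 bin
  # (spanning +/-1.25 deg) is unreachable in grazing incidence
  expect_identical(nPixels(azG)[chiGridStd == 0], 0L)
  expect_true(is.na(intensity(azG)[chiGridStd == 0]))
  frT <- matrix(1, 256, 256)
  azT <- azimuthalProfile(frT, mapT256, qBand = c(0.99, 1.31),
                          chiGrid = chiGridStd, applySolidAngle = FALSE)
  expect_gt(nPixels(azT)[chiGridStd == 0], 0L)
  expect_error(azimuthalProfile(frG, mapG128, qBand = c(5, 6),
                                chiGrid = chiGridStd), "outside")
})

test_that("profiles are invariant under vertical flip with the matching flag", {
  scn <- scenePreset("unextracted", exposure = 20)
  fr <- renderGiwaxs(scn, geomG64, beam10, seed = 33, map = mapG64)
  flipped <- fr[64:1, ]
  gFlip <- detectorGeometry(geomG64@distance, geomG64@pixelSize,
                            c(64 + 1 - geomG64@beamCenter[1],
                              geomG64@beamCenter[2]),
                            c(64L, 64L), orientation = "up_is_high_row")
  mFlip <- buildQChiMap(gFlip, beam10)
  qG <- seq(0.3, 2.2, by = 0.02)
  p1 <- sectorProfile(fr, mapG64, c(-17, 17), qG)
  p2 <- sectorProfile(flipped, mFlip, c(-17, 17), qG)
  expect_equal(intensity(p1), intensity(p2), tolerance = 1e-12)
  expect_identical(nPixels(p1), nPixels(p2))
})

test_that("GISAXS line cuts use the quoted defaults and find a 6-nm feature", {
  gsax <- detectorGeometry(2000, 0.688, c(126, 64.5), c(128, 128))
  bsax <- beamSpec(10, 0.15)
  msax <- buildQChiMap(gsax, bsax)
  bundles <- scene(phases = list(list(
    phase = phasePeakSet("bundles", data.frame(q_invA = 0.1),
                         crystalSize = 300),
    texture = textureModel("gaussian_out_of_plane", sigmaChi = 8),
    scale = 1)),
    amorphousHalo = c(0, 0.12, 3), flatBackground = 0.01, exposure = 200)
  fr <- renderGiwaxs(bundles, gsax, bsax, noiseless = TRUE, map = msax)
  vc <- gisaxsLineCut(fr, msax, "vertical")
  expect_equal(profileMeta(vc)$center, 0.012)
  expect_equal(profileMeta(vc)$width, 0.005)
  gv <- profileGrid(vc); iv <- intensity(vc)
  sel <- gv > 0.03 & !is.na(iv)
  qPeak <- gv[sel][which.max(iv[sel])]
  expect_equal(qPeak, 0.10, tolerance = 0.012)     # ~6.3 nm spacing
  expect_equal(2 * pi / qPeak / 10, 6.3, tolerance = 0.1)  # nm
  hc <- gisaxsLineCut(fr, msax, "horizontal")
  expect_equal(profileMeta(hc)$center, 0.03)
  # featureless scene: the cut decays monotonically
  fog <- scene(phases = list(), amorphousHalo = c(0, 0.12, 3),
               flatBackground = 0.01, exposure = 200)
  frF <- renderGiwaxs(fog, gsax, bsax, noiseless = TRUE, map = msax)
  vcF <- gisaxsLineCut(frF, msax, "vertical")
  iF <- intensity(vcF); gF <- profileGrid(vcF)
  keep <- !is.na(iF) & gF > 0.02 & gF < 0.25
  expect_true(all(diff(iF[keep]) < 0))
})

test_that("local background subtraction is exact and flags negatives", {
  g <- seq(-30, 30, by = 5)
  a <- mkProfile("chi", g, intensity = 5 + g^2 / 100,
                 sigma = rep(0.2, length(g)))
  zero <- localBackgroundSubtract(a, a)
  expect_equal(intensity(zero), rep(0, length(g)))
  expect_equal(uncertainty(zero), rep(0.2 * sqrt(2), length(g)))
  b <- mkProfile("chi", g, intensity = rep(6, length(g)),
                 sigma = rep(0, length(g)))
  expect_message(d <- localBackgroundSubtract(b, a), "negative")
  expect_gt(profileMeta(d)$nNegative, 0)
  expect_true(any(intensity(d) < 0))        # negatives retained, not clipped
  other <- mkProfile("chi", g + 1, intensity = rep(1, length(g)))
  expect_error(localBackgroundSubtract(a, other), "grids differ")
})

test_that("background subtraction recovers the texture atop a halo", {
  haloOnly <- scene(phases = list(), amorphousHalo = c(1.4, 0.7, 20),
                    flatBackground = 0.02, exposure = 40)
  textured <- scenePreset("chloroform", exposure = 40)   # cellulose + halo
  frS <- renderGiwaxs(textured, geomG256, beam127, seed = 41,
                      map = mapG256)
  frB <- renderGiwaxs(haloOnly, geomG256, beam127, seed = 42,
                      map = mapG256)
  chiG <- chiGridStd
  sig <- azimuthalProfile(frS, mapG256, qBand = c(0.99, 1.31),
                          chiGrid = chiG)
  bg <- azimuthalProfile(frB, mapG256, qBand = c(0.99, 1.31),
                         chiGrid = chiG)
  rec <- localBackgroundSubtract(sig, bg)
  # pure textured reference (no halo), noiseless
  ref <- renderGiwaxs(gaussScene(35, exposure = 40, flat = 0), geomG256,
                      beam127, noiseless = TRUE, map = mapG256)
  refAz <- azimuthalProfile(ref, mapG256, qBand = c(0.99, 1.31),
                            chiGrid = chiG)
  ok <- !is.na(intensity(rec)) & !is.na(intensity(refAz))
  z <- (intensity(rec) - intensity(refAz))[ok] / uncertainty(rec)[ok]
  expect_lt(mean(abs(z)), 1.5)
  expect_lt(max(abs(z)), 4.5)
})

test_that("the background-band registry holds the per-specimen defaults", {
  expect_equal(backgroundBand("onion", "giwaxs"), c(0.5, 0.6))
  expect_equal(backgroundBand("arabidopsis", "giwaxs"), c(0.6, 0.7))
  expect_equal(backgroundBand("onion", "rocking"), c(2.0, 2.2))
  expect_equal(backgroundBand("arabidopsis", "rocking"), c(1.8, 1.9))
  expect_equal(backgroundBand("moss", "rocking"), c(0.7, 0.8))
})

test_that("peak positions are stable when the bin width is halved", {
  scn <- scenePreset("unextracted", exposure = 40)
  fr <- renderGiwaxs(scn, geomG256, beam127, noiseless = TRUE,
                     map = mapG256)
  loc <- vapply(c(0.02, 0.01), function(h) {
    p <- sectorProfile(fr, mapG256, c(-17, 17), seq(0.3, 2.2, by = h))
    localMaxima(p, window = c(1.0, 1.3))$q[1]
  }, numeric(1))
  expect_lte(abs(diff(loc)), 0.02)
})
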