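# Forward renderer: expected-count frames, Poisson statistics,
# determinism, transmission geometry and scene presets.

test_that("orientation densities integrate to 1 over the hemisphere", {
  for (tex in list(textureModel("isotropic"),
                   textureModel("gaussian_out_of_plane", sigmaChi = 20),
                   textureModel("delta_in_plane"))) {
    tot <- integrate(function(x)
      orientationDensity(tex, x * 180 / pi) * sin(x), 0, pi / 2,
      rel.tol = 1e-9)$value
    expect_equal(tot, 1, tolerance = 1e-6)
  }
})

test_that("a scene with all amplitudes zero renders an all-zero frame", {
  nul <- scene(phases = list(list(phase = waxPhase(),
                                  texture = textureModel("isotropic"),
                                  scale = 0)),
               amorphousHalo = c(1.4, 0.7, 0), flatBackground = 0)
  fr <- renderGiwaxs(nul, geomG64, beam10, seed = 1)
  expect_true(all(fr == 0))
})

test_that("radially flat isotropic scenes give chi-flat azimuthal profiles", {
  flatScene <- scene(phases = list(), amorphousHalo = c(1.4, 0.7, 0),
                     flatBackground = 3)
  fr <- renderGiwaxs(flatScene, geomG128, beam127, noiseless = TRUE,
                     map = mapG128)
  az <- azimuthalProfile(fr, mapG128, qBand = c(0.99, 1.31),
                         chiGrid = chiGridStd)
  i <- intensity(az)[nPixels(az) > 0L]
  expect_lt(max(abs(i - 3)) / 3, 1e-9)
})

test_that("expected counts are linear in exposure", {
  s1 <- scenePreset("unextracted", exposure = 1)
  s2 <- scenePreset("unextracted", exposure = 3.5)
  f1 <- renderGiwaxs(s1, geomG64, beam10, noiseless = TRUE, map = mapG64)
  f2 <- renderGiwaxs(s2, geomG64, beam10, noiseless = TRUE, map = mapG64)
  expect_equal(f2, 3.5 * f1, tolerance = 1e-12)
})

test_that("same seed gives bit-identical frames; different seeds differ", {
  scn <- scenePreset("unextracted", exposure = 10)
  a <- renderGiwaxs(scn, geomG64, beam10, seed = 5, map = mapG64)
  b <- renderGiwaxs(scn, geomG64, beam10, seed = 5, map = mapG64)
  d <- renderGiwaxs(scn, geomG64, beam10, seed = 6, map = mapG64)
  expect_identical(a, b)
  expect_gt(sum(a != d), 0)
  expect_error(renderGiwaxs(scn, geomG64, beam10, seed = "x"), "integer")
  ser1 <- renderRockingSeries(scn, geomG64, beam10, c(5.6, 7.4), 3L,
                              seed = 9)
  ser2 <- renderRockingSeries(scn, geomG64, beam10, c(5.6, 7.4), 3L,
                              seed = 9)
  expect_identical(frames(ser1), frames(ser2))
})

test_that("the mean of many Poisson frames converges to the noiseless frame", {
  scn <- scenePreset("unextracted", exposure = 10)
  mN <- renderGiwaxs(scn, geomG64, beam10, noiseless = TRUE, map = mapG64)
  tot <- matrix(0, 64, 64)
  for (i in 1:200)
    tot <- tot + renderGiwaxs(scn, geomG64, beam10, seed = 1000 + i,
                              map = mapG64)
  sel <- validMask(mapG64)
  qb <- cut(qValues(mapG64)[sel], breaks = seq(0, 3.4, by = 0.2))
  z <- tapply(seq_along(qb), qb, function(ii) {
    mu <- 200 * sum(mN[sel][ii])
    if (mu == 0) return(0)
    (sum(tot[sel][ii]) - mu) / sqrt(mu)
  })
  expect_lt(max(abs(z), na.rm = TRUE), 3.5)
})

test_that("transmission frames show wax rings that vanish without wax", {
  scn <- scenePreset("unextracted", exposure = 40)
  fr <- renderTransmission(scn, geomT256, beamSpec(10, 0),
                           noiseless = TRUE, map = mapT256)
  prof <- sectorProfile(fr, mapT256, c(-90, 90), qGridStd)
  mx <- localMaxima(prof, window = c(1.45, 1.75))
  expect_gte(nrow(mx), 2L)
  expect_equal(sort(mx$q[1:2]), c(1.52, 1.68), tolerance = 0.015)
  noWax <- scenePreset("chloroform", exposure = 40)
  frW <- renderTransmission(noWax, geomT256, beamSpec(10, 0),
                            noiseless = TRUE, map = mapT256)
  profW <- sectorProfile(frW, mapT256, c(-90, 90), qGridStd)
  # sharp-ring oracle: local maxima confined to tight windows around the
  # lamellar positions; the broad cellulose/halo features that remain
  # after wax removal have no turning point there
  expect_equal(nrow(localMaxima(prof, window = c(1.49, 1.55))), 1L)
  expect_equal(nrow(localMaxima(prof, window = c(1.65, 1.71))), 1L)
  expect_equal(nrow(localMaxima(profW, window = c(1.49, 1.55))), 0L)
  expect_equal(nrow(localMaxima(profW, window = c(1.65, 1.71))), 0L)
})

test_that("transmission rings are azimuthally uniform", {
  scn <- scenePreset("unextracted", exposure = 100)
  fr <- renderTransmission(scn, geomT256, beamSpec(10, 0), seed = 4,
                           map = mapT256)
  band <- qValues(mapT256) >= 1.45 & qValues(mapT256) <= 1.60
  expect_gt(sum(fr[band]), 1e6)
  az <- azimuthalProfile(fr, mapT256, qBand = c(1.45, 1.60),
                         chiGrid = seq(-87.5, 87.5, by = 5))
  cv <- sd(intensity(az)) / mean(intensity(az))
  expect_lt(cv, 0.02)
  # out-of-plane texture is invisible in this projection: the textured and
  # isotropic versions of the same phases render identical expected frames
  iso <- scenePreset("ground", exposure = 100)
  chl <- scenePreset("chloroform", exposure = 100)
  expect_equal(
    renderTransmission(chl, geomT256, beamSpec(10, 0), noiseless = TRUE,
                       map = mapT256),
    renderTransmission(iso, geomT256, beamSpec(10, 0), noiseless = TRUE,
                       map = mapT256), tolerance = 1e-12)
})

test_that("rocking series geometry behaves as specified", {
  scn <- gaussScene(20, exposure = 15)
  expect_error(renderRockingSeries(scn, geomG64, beam127, c(4.4, 5.9), 1L,
                                   seed = 1), "nFrames")
  expect_error(renderRockingSeries(scn, geomG64, beam127, c(25, 30), 2L,
                                   seed = 1), "0, 20")
  expect_warning(renderRockingSeries(scn, geomG64, beam127, c(1.0, 1.5),
                                     4L, seed = 1), "misses the Bragg")
  ser <- renderRockingSeries(scn, geomG64, beam127, c(4.4, 5.9), 6L,
                             seed = 2)
  expect_length(frames(ser), 6L)
  expect_equal(range(sampleAngles(ser)), c(4.4, 5.9))
})

test_that("rocking branch recovers delta, flat and gaussian textures", {
  chiG <- seq(-35, 35) * 2.5
  # near-delta at chi = 0 concentrates within the grid resolution
  delta <- scene(phases = list(list(
    phase = celluloseIbetaPhase(30),
    texture = textureModel("gaussian_out_of_plane", sigmaChi = 0.5),
    scale = 1)), flatBackground = 0, exposure = 15)
  serD <- renderRockingSeries(delta, geomG256, beam127, c(4.4, 5.9), 8L,
                              noiseless = TRUE)
  rbD <- rockingBranch(serD, chiGrid = chiG)
  iD <- intensity(rbD); gD <- profileGrid(rbD)
  expect_lt(abs(gD[which.max(iD)]), 2.5)
  ok <- !is.na(iD)
  expect_gt(max(iD[ok]), 20 * stats::median(iD[ok & abs(gD) > 10]))
  # isotropic: flat within Poisson scatter
  iso <- scene(phases = list(list(phase = celluloseIbetaPhase(30),
                                  texture = textureModel("isotropic"),
                                  scale = 1)),
               flatBackground = 0, exposure = 15)
  serI <- renderRockingSeries(iso, geomG256, beam127, c(4.4, 5.9), 8L,
                              seed = 21)
  rbI <- rockingBranch(serI, chiGrid = chiG)
  iI <- intensity(rbI); okI <- !is.na(iI)
  expect_lt(sd(iI[okI]) / mean(iI[okI]), 0.05)
  # gaussian sigma = 20: log-quadratic fit recovers sigma within 10%
  g20 <- gaussScene(20, exposure = 15, flat = 0)
  serG <- renderRockingSeries(g20, geomG256, beam127, c(4.4, 5.9), 8L,
                              seed = 22)
  expect_gt(sum(frames(serG)[[4]]), 1e5)
  rbG <- rockingBranch(serG, chiGrid = chiG)
  okG <- !is.na(intensity(rbG)) & intensity(rbG) > 0 &
    abs(profileGrid(rbG)) <= 28
  fit <- lm(log(intensity(rbG)[okG]) ~ I(profileGrid(rbG)[okG]^2))
  sigmaHat <- sqrt(-1 / (2 * coef(fit)[[2]]))
  expect_equal(sigmaHat, 20, tolerance = 0.10)
})

test_that("scene presets mirror the specimen treatments", {
  dri <- scenePreset("driselase")
  expect_false(any(vapply(dri@phases, function(p)
    p$phase@name == "cellulose_Ibeta", logical(1))))
  expect_true(any(vapply(dri@phases, function(p)
    p$phase@name == "epicuticular_wax", logical(1))))
  grd <- scenePreset("ground")
  expect_equal(grd@phases[[1]]$texture@kind, "isotropic")
  expect_error(scenePreset("nosuch"), "unextracted")
  # unextracted reduces to chloroform as the wax scale goes to zero
  a <- renderGiwaxs(scenePreset("unextracted", waxScale = 0), geomG64,
                    beam10, noiseless = TRUE, map = mapG64)
  b <- renderGiwaxs(scenePreset("chloroform"), geomG64, beam10,
                    noiseless = TRUE, map = mapG64)
  expect_equal(a, b, tolerance = 1e-12)
})
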