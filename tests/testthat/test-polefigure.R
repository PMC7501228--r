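# Pole-figure assembly and texture/crystallinity metrics.

test_that("giwaxs branch drops the wedge region and records its band", {
  fr <- renderGiwaxs(gaussScene(20, exposure = 15), geomG128, beam127,
                     seed = 51, map = mapG128)
  gb <- giwaxsBranch(fr, mapG128, chiGrid = chiGridStd)
  inWedge <- abs(chiGridStd) < 7.5
  expect_true(all(is.na(intensity(gb)[inWedge])))
  expect_identical(nPixels(gb)[inWedge], rep(0L, sum(inWedge)))
  expect_true(any(!is.na(intensity(gb)[!inWedge])))
  expect_equal(profileMeta(gb)$qBand, c(0.99, 1.31))  # 1.15 +/- 0.16
})

test_that("rocking branch keeps |chi| < 30 and peaks where injected", {
  delta <- scene(phases = list(list(
    phase = celluloseIbetaPhase(30),
    texture = textureModel("gaussian_out_of_plane", sigmaChi = 0.5),
    scale = 1)), flatBackground = 0, exposure = 15)
  ser <- renderRockingSeries(delta, geomG128, beam127, c(4.4, 5.9), 8L,
                             noiseless = TRUE)
  rb <- rockingBranch(ser, chiGrid = chiGridStd)
  outside <- abs(chiGridStd) >= 30
  expect_true(all(is.na(intensity(rb)[outside])))
  g <- profileGrid(rb); i <- intensity(rb)
  expect_lt(abs(g[which.max(i)]), 2.5)
  empty <- methods::new("RockingSeries", sampleAngles = numeric(),
                        frames = list(), qBand = c(0.99, 1.31),
                        geometry = geomG128, beam = beam127)
  expect_error(rockingBranch(empty, chiGrid = chiGridStd), "empty")
})

test_that("stitching scales, matches and stays continuous at +/-7.5 deg", {
  g <- chiGridStd
  shape <- exp(-g^2 / (2 * 25^2))
  gi <- ifelse(abs(g) >= 7.5, shape, NA_real_)
  ro <- ifelse(abs(g) < 30, 4 * shape, NA_real_)
  giP <- mkProfile("chi", g, gi, sigma = rep(0.01, length(g)),
                   n = ifelse(is.na(gi), 0L, 25L),
                   meta = list(qBand = c(0.99, 1.31)))
  roP <- mkProfile("chi", g, ro, sigma = rep(0.01, length(g)),
                   n = ifelse(is.na(ro), 0L, 25L))
  pf <- stitchPoleFigure(giP, roP)
  expect_equal(scaleFactor(pf), 4)
  # continuity: the composite equals 4*shape everywhere it is defined
  expect_equal(intensity(pf), 4 * shape[chiGridStd %in% profileGrid(pf)],
               tolerance = 1e-9)
  expect_setequal(unique(branchLabels(pf)), c("giwaxs", "rocking"))
  expect_true(all(branchLabels(pf)[abs(profileGrid(pf)) < 7.5] ==
                    "rocking"))
  expect_true(all(branchLabels(pf)[abs(profileGrid(pf)) >= 7.5] ==
                    "giwaxs"))
  # idempotence: branches already on a common scale stitch with s = 1
  giS <- mkProfile("chi", g, 4 * gi, sigma = rep(0.01, length(g)),
                   n = ifelse(is.na(gi), 0L, 25L))
  expect_equal(scaleFactor(stitchPoleFigure(giS, roP)), 1)
  # zero intensity at the match angle cannot be scaled
  bad <- mkProfile("chi", g, ifelse(abs(g) >= 7.5, 0, NA_real_),
                   n = ifelse(abs(g) >= 7.5, 25L, 0L))
  expect_error(stitchPoleFigure(bad, roP), "cannot scale")
})

test_that("stitched pole figure reproduces an injected gaussian texture", {
  scn <- gaussScene(20, exposure = 15)
  fr <- renderGiwaxs(scn, geomG256, beam127, seed = 52, map = mapG256)
  ser <- renderRockingSeries(scn, geomG256, beam127, c(4.4, 5.9), 8L,
                             seed = 53)
  pf <- stitchPoleFigure(giwaxsBranch(fr, mapG256, chiGrid = chiGridStd),
                         rockingBranch(ser, chiGrid = chiGridStd))
  tex <- textureModel("gaussian_out_of_plane", sigmaChi = 20)
  gdens <- orientationDensity(tex, profileGrid(pf))
  scale <- sum(intensity(pf) * gdens) / sum(gdens^2)
  z <- (intensity(pf) - scale * gdens) / pmax(uncertainty(pf), 1e-9)
  expect_lt(mean(abs(z)), 1.5)
  expect_lt(unname(quantile(abs(z), 0.95)), 3.5)
  expect_lt(max(abs(z)), 6)
})

test_that("oriented fraction reproduces closed forms for a uniform figure", {
  g <- seq(0, 90, by = 1)
  pf <- mkPoleFigure(g, rep(2.7, length(g)))
  expect_equal(as.numeric(orientedFraction(pf, 34)),
               1 - cos(34 * pi / 180), tolerance = 1e-6)
  expect_equal(as.numeric(orientedFraction(pf, 34, weighting = "flat")),
               34 / 90, tolerance = 1e-6)
  expect_equal(as.numeric(orientedFraction(pf, 90)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(orientedFraction(pf, 90, weighting = "flat")),
               1, tolerance = 1e-12)
  expect_error(orientedFraction(pf, 0), "chi0")
  expect_error(orientedFraction(pf, 120), "chi0")
  # no coverage below chi0
  pfHigh <- mkPoleFigure(seq(40, 90, by = 1), rep(1, 51))
  expect_error(orientedFraction(pfHigh, 34), "below chi0")
})

test_that("oriented fraction warns on badly asymmetric lobes", {
  g <- seq(-80, 80, by = 2)
  asym <- ifelse(g < 0, 1, 3)
  pf <- mkPoleFigure(g, asym)
  expect_warning(orientedFraction(pf, 34), "asymmetry")
})

test_that("end-to-end oriented-fraction recovery within Monte-Carlo error", {
  # five independent replicates per texture width; every replicate must
  # land within 3 Monte-Carlo standard errors of the injected fraction,
  # with the MC error taken from the replicate spread (floored by the
  # propagated counting error, in case the spread estimate comes out low)
  for (sig in c(10, 20, 35)) {
    tex <- textureModel("gaussian_out_of_plane", sigmaChi = sig)
    scn <- gaussScene(sig, exposure = 20)
    reps <- lapply(1:5, function(r) {
      fr <- renderGiwaxs(scn, geomG256, beam127, seed = 100 * sig + r,
                         map = mapG256)
      expect_gt(sum(fr), 1e6)
      ser <- renderRockingSeries(scn, geomG256, beam127, c(4.4, 5.9), 8L,
                                 seed = 200 * sig + r)
      stitchPoleFigure(giwaxsBranch(fr, mapG256, chiGrid = chiGridStd),
                       rockingBranch(ser, chiGrid = chiGridStd))
    })
    for (wt in c("sin_chi", "flat")) {
      truth <- textureFractionWithin(tex, 34, weighting = wt)
      est <- lapply(reps, orientedFraction, chi0 = 34, weighting = wt)
      err <- vapply(est, function(e) as.numeric(e) - truth, numeric(1))
      seMC <- max(sd(err),
                  stats::median(vapply(est, attr, numeric(1), "se")))
      expect_lt(max(abs(err)), 3 * seMC)
      expect_lt(abs(mean(err)), 3 * seMC / sqrt(5))
    }
  }
})

test_that("texture width tracks the injected distribution", {
  widths <- vapply(c(10, 20, 35), function(sig) {
    scn <- gaussScene(sig, exposure = 15)
    fr <- renderGiwaxs(scn, geomG256, beam127, noiseless = TRUE,
                       map = mapG256)
    ser <- renderRockingSeries(scn, geomG256, beam127, c(4.4, 5.9), 8L,
                               noiseless = TRUE)
    pf <- stitchPoleFigure(
      giwaxsBranch(fr, mapG256, chiGrid = chiGridStd),
      rockingBranch(ser, chiGrid = chiGridStd))
    as.numeric(textureWidth(pf))
  }, numeric(1))
  expect_equal(widths[2], 2.3548 * 20, tolerance = 0.10)
  expect_true(all(diff(widths) > 0))      # narrower texture, smaller FWHM
  flat <- mkPoleFigure(seq(0, 90, by = 2), rep(1, 46))
  w <- textureWidth(flat)
  expect_true(is.na(w))
  expect_false(is.na(attr(w, "flag")))
})

test_that("Segal CI vanishes for a decaying amorphous profile", {
  # gently decaying background: both Segal windows share the boundary
  # value, so the height-based index sits at zero up to binning effects
  amorph <- scene(phases = list(), amorphousHalo = c(0.8, 2.0, 10),
                  flatBackground = 0.02, exposure = 40)
  fr <- renderGiwaxs(amorph, geomG128, beam127, noiseless = TRUE,
                     map = mapG128)
  prof <- sectorProfile(fr, mapG128, c(-17, 17), qGridStd)
  expect_lt(abs(segalCI(prof)), 3)
  short <- mkProfile("q", seq(1.45, 1.7, by = 0.01), rep(1, 26))
  expect_error(segalCI(short), "Segal windows")
})

test_that("Segal CI increases strictly with the crystalline fraction", {
  # crystalline peaks atop a fixed decaying amorphous background
  ci <- vapply(c(0.25, 0.5, 1, 2, 4), function(s) {
    scn <- scene(phases = list(list(
      phase = celluloseIbetaPhase(30),
      texture = textureModel("gaussian_out_of_plane", sigmaChi = 35),
      scale = s)),
      amorphousHalo = c(0.8, 2.0, 10), flatBackground = 0.02,
      exposure = 40)
    fr <- renderGiwaxs(scn, geomG128, beam127, noiseless = TRUE,
                       map = mapG128)
    segalCI(sectorProfile(fr, mapG128, c(-17, 17), qGridStd))
  }, numeric(1))
  expect_true(all(diff(ci) > 0))
})

test_that("pole figures separate textured from ground specimens", {
  mkpf <- function(preset, seed) {
    scn <- scenePreset(preset, exposure = 40)
    fr <- renderGiwaxs(scn, geomG256, beam127, seed = seed, map = mapG256)
    ser <- renderRockingSeries(scn, geomG256, beam127, c(4.4, 5.9), 8L,
                               seed = seed + 1)
    stitchPoleFigure(giwaxsBranch(fr, mapG256, chiGrid = chiGridStd),
                     rockingBranch(ser, chiGrid = chiGridStd))
  }
  ratio <- function(pf) max(intensity(pf)) / min(intensity(pf))
  expect_gt(ratio(mkpf("unextracted", 71)), 2)
  expect_lt(ratio(mkpf("ground", 73)), 1.2)
})

test_that("pole-figure CSV round-trips the stitched trace", {
  g <- chiGridStd
  pf <- mkPoleFigure(g, exp(-g^2 / 800) + 0.1,
                     sigma = rep(0.01, length(g)),
                     meta = list(matchChi = 7.5))
  path <- withr::local_tempfile(fileext = ".csv")
  writePoleFigureCsv(pf, path)
  lines <- readLines(path)
  expect_true(any(grepl("scale_factor", lines)))
  back <- read.csv(path, comment.char = "#")
  expect_equal(back$intensity, intensity(pf), tolerance = 1e-9)
  expect_equal(back$chi_deg, profileGrid(pf))
})
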