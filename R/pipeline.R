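# Orchestration: validated run configuration, the end-to-end pipeline
# (simulate -> map -> reduce -> pole figure -> metrics), deterministic
# fixtures, run records and logging.

.configSchema <- list(
  seed = NULL, output_dir = NULL,
  beam = list(energy_keV = NULL, incidence_deg = NULL),
  geometry = list(distance_mm = NULL, pixel_mm = NULL, center_row = NULL,
                  center_col = NULL, rows = NULL, cols = NULL,
                  orientation = NULL),
  scene = list(preset = NULL, sigma_chi = NULL, exposure = NULL,
               wax_scale = NULL, cellulose_scale = NULL, noiseless = NULL),
  rocking = list(theta_min_deg = NULL, theta_max_deg = NULL,
                 n_frames = NULL),
  reduction = list(q_min = NULL, q_max = NULL, q_step = NULL,
                   out_of_plane_chi = NULL, in_plane_chi = NULL,
                   specimen = NULL),
  polefigure = list(q_band = NULL, match_chi = NULL, weighting = NULL,
                    chi_step = NULL, chi0_deg = NULL))

.checkKeys <- function(cfg, schema, path = "") {
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  for (k in names(cfg))
    if (is.list(schema[[k]]) && !is.null(cfg[[k]]))
      .checkKeys(cfg[[k]], schema[[k]], paste0(path, k, "."))
  invisible(TRUE)
}

#' Read and validate a pipeline run configuration
#'
#' YAML configuration with sections `beam` (energy_keV, incidence_deg),
#' `geometry` (distance_mm, pixel_mm, center_row, center_col, rows, cols,
#' orientation), `scene` (preset, sigma_chi, exposure, ...), `rocking`
#' (theta_min_deg, theta_max_deg, n_frames), `reduction` and `polefigure`,
#' plus top-level `seed` and `output_dir`. Unknown keys are rejected by
#' name before any computation.
#'
#' @param path path to a YAML file, or a list already in memory.
#' @return The validated configuration list (with defaults filled).
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  .checkKeys(cfg, .configSchema)
  # defaults: the beamline settings used for rocking-scan pole figures
  cfg$seed <- cfg$seed %||% 1L
  cfg$beam <- utils::modifyList(list(energy_keV = 12.7,
                                     incidence_deg = 0.12),
                                cfg$beam %||% list())
  g <- utils::modifyList(list(distance_mm = 125, pixel_mm = 0.688,
                              rows = 128L, cols = 128L,
                              orientation = "up_is_low_row"),
                         cfg$geometry %||% list())
  g$center_row <- g$center_row %||% (g$rows - 2.5)
  g$center_col <- g$center_col %||% ((g$cols + 1) / 2)
  cfg$geometry <- g
  cfg$scene <- utils::modifyList(
    list(preset = "unextracted", sigma_chi = 35, exposure = 40,
         wax_scale = 0.6, cellulose_scale = 1, noiseless = FALSE),
    cfg$scene %||% list())
  cfg$rocking <- utils::modifyList(list(n_frames = 8L),
                                   cfg$rocking %||% list())
  cfg$reduction <- utils::modifyList(
    list(q_min = 0.25, q_max = 2.3, q_step = 0.01,
         out_of_plane_chi = c(-17, 17), in_plane_chi = c(78, 88),
         specimen = "onion"),
    cfg$reduction %||% list())
  cfg$polefigure <- utils::modifyList(
    list(q_band = c(0.99, 1.31), match_chi = 7.5, weighting = "sin_chi",
         chi_step = 2.5, chi0_deg = 34),
    cfg$polefigure %||% list())
  cfg
}

.beamFromConfig <- function(cfg)
  beamSpec(cfg$beam$energy_keV, cfg$beam$incidence_deg)

.geometryFromConfig <- function(cfg) {
  g <- cfg$geometry
  detectorGeometry(g$distance_mm, g$pixel_mm,
                   c(g$center_row, g$center_col), c(g$rows, g$cols),
                   orientation = g$orientation)
}

.sceneFromConfig <- function(cfg) {
  s <- cfg$scene
  scenePreset(s$preset, sigmaChi = s$sigma_chi, exposure = s$exposure,
              waxScale = s$wax_scale, celluloseScale = s$cellulose_scale)
}

#' Run the full analysis pipeline
#'
#' Simulates a GIWAXS frame and a rocking series for the configured scene,
#' maps the detector to (q, chi), reduces out-of-plane and in-plane sector
#' profiles, assembles the stitched chi-pole figure, and computes the
#' texture and crystallinity metrics. All artifacts (TIFF frames, profile
#' and pole-figure CSVs, a YAML run record referencing the config hash and
#' per-file checksums, and a plain-text log) are written under `outdir`.
#' Fully deterministic given (config, seed).
#'
#' @param config a config list or YAML path (see [readRunConfig()]).
#' @param outdir output directory (default: `output_dir` from the config,
#'   or a temporary directory).
#' @param seed optional integer overriding the config seed.
#' @return Invisibly, the run record list (class `gixRunRecord`).
#' @export
runPipeline <- function(config, outdir = NULL, seed = NULL) {
  cfg <- readRunConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  outdir <- outdir %||% cfg$output_dir %||%
    file.path(tempdir(), paste0("gixtex_run_", cfg$seed))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outdir, "run.log")
  logLines <- character()
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    logLines <<- c(logLines, line)
    message(line)
  }
  stage <- "setup"
  record <- tryCatch({
    cfgHash <- .contentHash(cfg)
    logmsg("config hash %s, seed %d", cfgHash, cfg$seed)
    beam <- .beamFromConfig(cfg)
    geom <- .geometryFromConfig(cfg)
    scn <- .sceneFromConfig(cfg)

    stage <- "simulate"
    set.seed(cfg$seed)
    seeds <- sample.int(2^30, 2)
    logmsg("rendering GIWAXS frame (seed %d) and rocking series (seed %d)",
           seeds[1], seeds[2])
    map <- buildQChiMap(geom, beam, mode = "grazing")
    frame <- renderGiwaxs(scn, geom, beam, seed = seeds[1],
                          noiseless = isTRUE(cfg$scene$noiseless),
                          map = map)
    k <- 2 * pi / wavelength(beam)
    band <- cfg$polefigure$q_band
    thetaB <- .rad2deg(asin(band / (2 * k)))
    thetaMin <- cfg$rocking$theta_min_deg %||% thetaB[1]
    thetaMax <- cfg$rocking$theta_max_deg %||% thetaB[2]
    series <- renderRockingSeries(scn, geom, beam,
                                  thetaRange = c(thetaMin, thetaMax),
                                  nFrames = cfg$rocking$n_frames,
                                  seed = seeds[2],
                                  noiseless = isTRUE(cfg$scene$noiseless),
                                  qBandTarget = band)
    writeFrameTiff(frame, file.path(outdir, "giwaxs_frame.tif"))
    manifest <- data.frame(frame = sprintf("rocking_%02d.tif",
                                           seq_along(frames(series))),
                           theta_deg = sampleAngles(series))
    for (i in seq_along(frames(series)))
      writeFrameTiff(frames(series)[[i]],
                     file.path(outdir, manifest$frame[i]))
    write.csv(manifest, file.path(outdir, "rocking_manifest.csv"),
              row.names = FALSE)

    stage <- "reduce"
    red <- cfg$reduction
    qGrid <- seq(red$q_min, red$q_max, by = red$q_step)
    outPlane <- sectorProfile(frame, map, chiRange = red$out_of_plane_chi,
                              qGrid = qGrid)
    inPlane <- sectorProfile(frame, map, chiRange = red$in_plane_chi,
                             qGrid = qGrid, bothLobes = TRUE)
    for (nm in c("outPlane", "inPlane")) {
      p <- get(nm)
      p@meta$config_hash <- cfgHash
      writeProfileCsv(p, file.path(outdir, paste0(
        if (nm == "outPlane") "profile_out_of_plane" else
          "profile_in_plane", ".csv")))
    }

    stage <- "polefigure"
    # bin centers at multiples of the step so that 0 and +/-match_chi are
    # centers (the stitch matches at those bins)
    nb <- floor((90 - cfg$polefigure$chi_step / 2) /
                  cfg$polefigure$chi_step)
    chiGrid <- seq(-nb, nb) * cfg$polefigure$chi_step
    gb <- giwaxsBranch(frame, map, qBand = band, chiGrid = chiGrid,
                       bgBand = backgroundBand(red$specimen, "giwaxs"),
                       matchChi = cfg$polefigure$match_chi)
    rb <- rockingBranch(series, chiGrid = chiGrid, qBand = band,
                        bgBand = backgroundBand(red$specimen, "rocking"))
    pf <- stitchPoleFigure(gb, rb, matchChi = cfg$polefigure$match_chi)
    pf@meta$config_hash <- cfgHash
    writePoleFigureCsv(pf, file.path(outdir, "pole_figure.csv"))
    logmsg("stitch scale factor %.4g", scaleFactor(pf))

    stage <- "metrics"
    chi0 <- cfg$polefigure$chi0_deg
    fracSin <- orientedFraction(pf, chi0, weighting = "sin_chi")
    fracFlat <- orientedFraction(pf, chi0, weighting = "flat")
    width <- textureWidth(pf)
    ci <- segalCI(outPlane)
    metrics <- list(
      oriented_fraction_sin = as.numeric(fracSin),
      oriented_fraction_sin_se = attr(fracSin, "se"),
      oriented_fraction_flat = as.numeric(fracFlat),
      chi0_deg = chi0,
      texture_fwhm_deg = as.numeric(width),
      segal_ci_percent = ci,
      stitch_scale_factor = scaleFactor(pf))
    logmsg("oriented fraction (|chi|<=%g, sin): %.3f; FWHM %.1f deg; Segal CI %.1f%%",
           chi0, metrics$oriented_fraction_sin, metrics$texture_fwhm_deg,
           metrics$segal_ci_percent)

    stage <- "record"
    files <- list.files(outdir, pattern = "\\.(tif|csv)$")
    checksums <- vapply(files, function(f)
      .contentHash(readBin(file.path(outdir, f), "raw",
                           file.size(file.path(outdir, f)))),
      character(1))
    rec <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                package_version = as.character(packageVersion("gixtex")),
                config_hash = cfgHash, seed = cfg$seed,
                stage_seeds = as.list(setNames(seeds,
                                               c("giwaxs", "rocking"))),
                scale_factor = scaleFactor(pf), metrics = metrics,
                files = as.list(checksums))
    tmp <- file.path(outdir, ".run_record.yaml.tmp")
    yaml::write_yaml(rec, tmp)
    file.rename(tmp, file.path(outdir, "run_record.yaml"))
    writeLines(logLines, logPath)
    class(rec) <- "gixRunRecord"
    rec
  }, error = function(e) {
    writeLines(c(logLines, sprintf("FAILED at stage '%s': %s", stage,
                                   conditionMessage(e))), logPath)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(record)
}

#' @export
print.gixRunRecord <- function(x, ...) {
  cat("gixtex run record", x$timestamp, "\n")
  cat("  config hash:", x$config_hash, " seed:", x$seed, "\n")
  cat(sprintf("  oriented fraction (sin): %.3f; FWHM %.1f deg; Segal CI %.1f%%\n",
              x$metrics$oriented_fraction_sin,
              x$metrics$texture_fwhm_deg, x$metrics$segal_ci_percent))
  invisible(x)
}

#' Write the deterministic synthetic fixture set
#'
#' Renders each scene preset as a small GIWAXS frame plus one rocking
#' series, writing 32-bit TIFFs, a CSV manifest and a checksum listing.
#' Deterministic given the seed; used by the test suite.
#'
#' @param dir output directory.
#' @param seed integer master seed.
#' @param rebin detector coarsening factor (default 8: 64 x 64 frames).
#' @return Invisibly, a data.frame of files and checksums.
#' @export
makeFixtures <- function(dir, seed = 1L, rebin = 8L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geom <- defaultGeometry("giwaxs", rebin = rebin)
  beam <- beamSpec(12.7, 0.12)
  map <- buildQChiMap(geom, beam)
  presets <- c("unextracted", "driselase", "chloroform", "ground",
               "stem_segment")
  set.seed(as.integer(seed))
  seeds <- sample.int(2^30, length(presets) + 1L)
  paths <- character()
  for (i in seq_along(presets)) {
    fr <- renderGiwaxs(scenePreset(presets[i], exposure = 40), geom, beam,
                       seed = seeds[i], map = map)
    p <- file.path(dir, paste0(presets[i], ".tif"))
    writeFrameTiff(fr, p)
    paths <- c(paths, p)
  }
  series <- renderRockingSeries(scenePreset("unextracted", exposure = 40),
                                geom, beam, thetaRange = c(4.4, 5.9),
                                nFrames = 4L,
                                seed = seeds[length(seeds)])
  manifest <- data.frame(frame = sprintf("rocking_%02d.tif",
                                         seq_along(frames(series))),
                         theta_deg = sampleAngles(series))
  for (i in seq_along(frames(series))) {
    p <- file.path(dir, manifest$frame[i])
    writeFrameTiff(frames(series)[[i]], p)
    paths <- c(paths, p)
  }
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  paths <- c(paths, mpath)
  out <- data.frame(
    file = basename(paths),
    checksum = vapply(paths, function(f)
      .contentHash(readBin(f, "raw", file.size(f))), character(1)))
  write.csv(out, file.path(dir, "checksums.csv"), row.names = FALSE)
  invisible(out)
}
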