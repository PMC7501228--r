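# File I/O: TIFF frames (32-bit integer counts), float map export, CSV
# profiles with '#' header comments, and a small content checksum.

# position-weighted polynomial checksum over a serialized object (hex
# string); dependency-free provenance fingerprint for run records. All
# intermediate sums stay below 2^53, so the arithmetic is exact.
.contentHash <- function(object) {
  b <- as.integer(serialize(object, NULL, version = 2))
  i <- seq_along(b)
  h1 <- (sum(b) + length(b)) %% 2^31
  h2 <- sum((i %% 8191 + 1) * b) %% 2^31
  h3 <- sum(((i * 31) %% 9973 + 1) * b) %% 2^31
  sprintf("%08x%08x", bitwXor(as.integer(h1), as.integer(h3)),
          as.integer(h2))
}

#' Write / read a detector frame as 32-bit integer TIFF
#'
#' Counts are rounded to integers and stored losslessly as 32-bit samples.
#'
#' @param frame counts matrix.
#' @param path file path.
#' @return `writeFrameTiff`: invisibly, the path. `readFrameTiff`: the
#'   counts matrix.
#' @export
writeFrameTiff <- function(frame, path) {
  m <- round(frame)
  if (any(m < 0)) stop("negative counts cannot be stored")
  tiff::writeTIFF(m / (2^32 - 1), path, bits.per.sample = 32L,
                  compression = "none")
  invisible(path)
}

#' @rdname writeFrameTiff
#' @export
readFrameTiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "double"
  m
}

#' Export a QChiMap as TIFF for inspection
#'
#' Writes `<stem>_q.tif`, `<stem>_chi.tif` (both affinely scaled to `[0, 1]`
#' 32-bit floats; the scaling is recorded in `<stem>_scaling.txt`) and
#' `<stem>_mask.tif` (0/1).
#'
#' @param map a [QChiMap-class].
#' @param stem output path stem.
#' @return Invisibly, the paths written.
#' @export
writeQChiMapTiff <- function(map, stem) {
  stopifnot(is(map, "QChiMap"))
  paths <- paste0(stem, c("_q.tif", "_chi.tif", "_mask.tif",
                          "_scaling.txt"))
  qm <- qValues(map); qmax <- max(qm)
  tiff::writeTIFF(qm / qmax, paths[1], bits.per.sample = 32L)
  tiff::writeTIFF((chiValues(map) + 90) / 180, paths[2],
                  bits.per.sample = 32L)
  tiff::writeTIFF(validMask(map) * 1, paths[3], bits.per.sample = 8L)
  writeLines(c(sprintf("q_tif_scale: value = pixel * %.10g", qmax),
               "chi_tif_scale: value = pixel * 180 - 90",
               "mask_tif: 1 = valid"), paths[4])
  invisible(paths)
}

#' Write / read a 1D profile as CSV
#'
#' Columns `axis_value, intensity, sigma, n_pixels`; '#'-prefixed header
#' comments record the axis and the reduction parameters in
#' `profileMeta()`.
#'
#' @param profile a [Profile1D-class].
#' @param path file path.
#' @return `writeProfileCsv`: invisibly, the path. `readProfileCsv`: a
#'   [Profile1D-class] (header comments are not parsed back beyond the
#'   axis).
#' @export
writeProfileCsv <- function(profile, path) {
  stopifnot(is(profile, "Profile1D"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- profileMeta(profile)
  flat <- vapply(meta, function(x)
    paste(format(unlist(x)), collapse = " "), character(1))
  writeLines(c(sprintf("# axis: %s", profile@axis),
               sprintf("# %s: %s", names(flat), flat)), con)
  write.csv(data.frame(axis_value = profileGrid(profile),
                       intensity = intensity(profile),
                       sigma = uncertainty(profile),
                       n_pixels = nPixels(profile)),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfileCsv
#' @export
readProfileCsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  axis <- sub("^# axis: ", "", grep("^# axis:", hdr, value = TRUE)[1])
  df <- read.csv(text = lines[!grepl("^#", lines)])
  .profile1D(axis, df$axis_value, df$intensity, df$sigma, df$n_pixels,
             meta = list(header = hdr))
}
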