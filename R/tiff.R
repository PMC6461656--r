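## Minimal baseline TIFF codec: little-endian, grayscale, 16-bit,
## uncompressed, one strip per page.  Written by hand because the
## installed R stack has no TIFF package; only the subset needed for
## lossless round-trips of rendered series is implemented.  Values are
## clamped to 0..32767 (writeBin cannot emit unsigned 16-bit above the
## signed range).

writeTiff <- function(pages, path) {
  stopifnot(is.list(pages), length(pages) >= 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  w2(42L)
  ## layout: header(8) then per page [pixel data][IFD]
  nTags <- 9L
  ifdSize <- 2 + nTags * 12 + 4
  offset <- 8L
  offsets <- list()
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    nb <- 2L * length(p)
    offsets[[i]] <- c(data = offset, ifd = offset + nb)
    offset <- offset + nb + ifdSize
  }
  w4(offsets[[1]]["ifd"])
  tag <- function(id, type, count, value) {
    w2(id); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    stopifnot(is.matrix(p))
    v <- matrix(as.integer(round(pmin(pmax(p, 0), 32767))), nrow(p))
    ## TIFF scanline order is row-major; R matrices are column-major
    writeBin(as.vector(t(v)), con, size = 2, endian = "little")
    h <- nrow(p); wd <- ncol(p)
    w2(nTags)
    tag(256L, 3L, 1L, wd)                    # ImageWidth
    tag(257L, 3L, 1L, h)                     # ImageLength
    tag(258L, 3L, 1L, 16L)                   # BitsPerSample
    tag(259L, 3L, 1L, 1L)                    # Compression: none
    tag(262L, 3L, 1L, 1L)                    # Photometric: BlackIsZero
    tag(273L, 4L, 1L, offsets[[i]]["data"])  # StripOffsets
    tag(277L, 3L, 1L, 1L)                    # SamplesPerPixel
    tag(278L, 3L, 1L, h)                     # RowsPerStrip
    tag(279L, 4L, 1L, 2L * h * wd)           # StripByteCounts
    w4(if (i < length(pages)) offsets[[i + 1]]["ifd"] else 0L)
  }
  invisible(path)
}

readTiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  r2 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  r4 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "II" || r2(2) != 42L)
    stop("corrupt TIFF: bad header in ", path)
  ifd <- r4(4)
  pages <- list()
  while (ifd != 0) {
    n <- r2(ifd)
    tags <- list()
    for (k in seq_len(n)) {
      off <- ifd + 2 + (k - 1) * 12
      id <- r2(off); type <- r2(off + 2)
      val <- if (type == 3L) r2(off + 8) else r4(off + 8)
      tags[[as.character(id)]] <- val
    }
    if ((tags[["259"]] %||% 1L) != 1L) stop("unsupported TIFF compression")
    if ((tags[["258"]] %||% 16L) != 16L) stop("only 16-bit TIFF supported")
    wd <- tags[["256"]]; h <- tags[["257"]]
    dataOff <- tags[["273"]]
    v <- readBin(raw[(dataOff + 1):(dataOff + 2 * h * wd)], "integer",
                 n = h * wd, size = 2, signed = FALSE, endian = "little")
    pages[[length(pages) + 1L]] <- matrix(v, nrow = h, byrow = TRUE)
    ifd <- r4(ifd + 2 + n * 12)
  }
  pages
}

#' Write an image series as multi-page TIFF plus sidecar JSON
#'
#' Pages are ordered t-major, then z, then channel (green before red);
#' the ordering and acquisition metadata are recorded in `<path>.json`.
#' Round-tripping integer-valued data through [readSeries()] is lossless.
#'
#' @param series an [ImageSeries-class].
#' @param path output TIFF path (`.json` sidecar is written next to it).
#' @return `path`, invisibly.
#' @export
writeSeries <- function(series, path) {
  chans <- Filter(function(ch) length(slot(series, ch)) > 0, c("green", "red"))
  stopIfNot(length(chans) > 0, "series has no channels")
  d <- dim(slot(series, chans[[1]]))
  pages <- list()
  for (ti in seq_len(d[1])) for (zi in seq_len(d[2])) for (ch in chans)
    pages[[length(pages) + 1L]] <- slot(series, ch)[ti, zi, , ]
  writeTiff(pages, path)
  meta <- list(frame_period_s = series@framePeriodS,
               pixel_size_um = series@pixelSizeUm,
               z_step_um = series@zStepUm,
               n_baseline_frames = series@nBaselineFrames,
               mode = series@mode,
               channel_order = chans,
               page_order = "t,z,channel",
               n_t = d[1], n_z = d[2], n_y = d[3], n_x = d[4],
               pixel_convention = "0-based (row, col), origin top-left, pixel-center inclusion")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image series written by [writeSeries()]
#'
#' @param path TIFF path; `<path>.json` must exist.
#' @return an [ImageSeries-class].
#' @export
readSeries <- function(path) {
  metaPath <- paste0(path, ".json")
  if (!file.exists(metaPath)) stop("missing sidecar metadata: ", metaPath)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  required <- c("frame_period_s", "pixel_size_um", "z_step_um",
                "n_baseline_frames", "channel_order", "n_t", "n_z", "n_y", "n_x")
  absent <- setdiff(required, names(meta))
  if (length(absent))
    stop("metadata missing required keys: ", paste(absent, collapse = ", "))
  pages <- readTiff(path)
  chans <- meta$channel_order
  expected <- meta$n_t * meta$n_z * length(chans)
  if (length(pages) != expected)
    stop("metadata promises ", expected, " pages but TIFF holds ", length(pages))
  arrs <- lapply(chans, function(ch)
    array(0, dim = c(meta$n_t, meta$n_z, meta$n_y, meta$n_x)))
  names(arrs) <- chans
  i <- 1L
  for (ti in seq_len(meta$n_t)) for (zi in seq_len(meta$n_z)) for (ch in chans) {
    arrs[[ch]][ti, zi, , ] <- pages[[i]]
    i <- i + 1L
  }
  empty <- array(0, dim = c(0, 0, 0, 0))
  new("ImageSeries",
      green = arrs[["green"]] %||% empty,
      red = arrs[["red"]] %||% empty,
      framePeriodS = meta$frame_period_s,
      pixelSizeUm = meta$pixel_size_um,
      zStepUm = meta$z_step_um,
      nBaselineFrames = as.integer(meta$n_baseline_frames),
      mode = meta$mode %||% "anatomy")
}
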