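## Pixel convention used throughout: 0-based (row, col), origin top-left,
## row = y / pixel size, col = x / pixel size; the centre of pixel (i, j)
## sits at (i + 0.5, j + 0.5); a pixel belongs to a polygon when its centre
## is inside (even-odd rule).

#' Rasterise a polygon to a logical pixel mask
#'
#' @param poly matrix of polygon vertices `[[row, col], ...]` (0-based
#'   pixel coordinates).
#' @param dim image dimensions (rows, cols).
#' @return logical matrix; `TRUE` where the pixel centre is inside.
#' @export
polygonMask <- function(poly, dim) {
  stopifnot(is.matrix(poly), ncol(poly) == 2L)
  rows <- matrix(rep(seq_len(dim[1]) - 0.5, dim[2]), dim[1])
  cols <- matrix(rep(seq_len(dim[2]) - 0.5, each = dim[1]), dim[1])
  inside <- matrix(FALSE, dim[1], dim[2])
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    cross <- ((yi > rows) != (yj > rows)) &
      (cols < (xj - xi) * (rows - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

squareRoi <- function(centerRowCol, halfPx) {
  r <- centerRowCol[1]; c <- centerRowCol[2]
  rbind(c(r - halfPx, c - halfPx), c(r - halfPx, c + halfPx),
        c(r + halfPx, c + halfPx), c(r + halfPx, c - halfPx))
}

## Walk a polyline backwards from its last vertex by `arc` and return the
## point, or NULL if the polyline is shorter than `arc`.
pointAtArcFromEnd <- function(path, arc) {
  rev <- path[rev(seq_len(nrow(path))), , drop = FALSE]
  seg <- sqrt(rowSums(diff(rev)^2))
  cum <- c(0, cumsum(seg))
  if (arc > cum[length(cum)]) return(NULL)
  k <- findInterval(arc, cum, rightmost.closed = TRUE)
  k <- min(k, length(seg))
  frac <- (arc - cum[k]) / seg[k]
  rev[k, ] + frac * (rev[k + 1, ] - rev[k, ])
}

trunkPath <- function(stump) stump$path  # trunk only; the arm is separate

#' Place the four perfusion ROIs and the region masks
#'
#' ROIs A and B sit inside the lumen of the first proximal stump at
#' geodesic offsets of 250 and 50 µm from the proximal wound edge; C and D
#' mirror them distally (50 and 250 µm from the distal edge), so the
#' ordering A, B, C, D runs proximal to distal.  Region masks split the
#' frame into proximal, wound and distal bands.
#'
#' @param scene a [VascularScene-class].
#' @param res image resolution (pixels per side), 128 or 256.
#' @param offsetsUm geodesic offsets (far, near) from the wound edge (µm).
#' @param roiHalfUm half-side of the square ROI (µm).
#' @return a [RoiSet-class].
#' @examples
#' placeRois(makeScene(1), res = 128)
#' @export
placeRois <- function(scene, res = 128, offsetsUm = c(250, 50), roiHalfUm = 12) {
  if (!res %in% c(128, 256))
    stop("configuration error: resolution must be 128 or 256")
  stopIfNot(length(stumps(scene, "proximal")) >= 1 &&
              length(stumps(scene, "distal")) >= 1,
            "scene needs at least one proximal and one distal stump")
  ps <- scene@fovUm[1] / res
  prox <- trunkPath(stumps(scene, "proximal")[[1]])
  dist <- trunkPath(stumps(scene, "distal")[[1]])
  anchor <- function(path, arc, label) {
    p <- pointAtArcFromEnd(path, arc)
    if (is.null(p))
      stop("placement error: stump too short for ROI ", label,
           " at offset ", arc, " um (stump length ",
           round(sum(sqrt(rowSums(diff(path)^2)))), " um)")
    c(p[2], p[1]) / ps                       # (row, col) = (y, x) / pixel
  }
  centers <- list(A = anchor(prox, offsetsUm[1], "A"),
                  B = anchor(prox, offsetsUm[2], "B"),
                  C = anchor(dist, offsetsUm[2], "C"),
                  D = anchor(dist, offsetsUm[1], "D"))
  half <- max(1, roiHalfUm / ps)
  polys <- lapply(centers, squareRoi, halfPx = half)
  band <- scene@woundBand / ps
  rows <- matrix(rep(seq_len(res) - 0.5, res), res)
  regions <- list(proximal = rows < band[1],
                  wound = rows >= band[1] & rows <= band[2],
                  distal = rows > band[2])
  new("RoiSet", rois = polys, regions = regions, pixelSizeUm = ps,
      dim = as.integer(c(res, res)))
}

#' Maximum-intensity z-projection
#'
#' @param series an [ImageSeries-class].
#' @param channel `"red"` or `"green"`.
#' @return numeric array `[t, y, x]`.
#' @export
maxProject <- function(series, channel = "red") {
  a <- frames(series, channel)
  stopIfNot(length(a) > 0, paste("series has no", channel, "channel"))
  d <- dim(a)
  out <- array(0, d[c(1, 3, 4)])
  for (ti in seq_len(d[1])) out[ti, , ] <-
    apply(a[ti, , , , drop = FALSE], c(3, 4), max)
  out
}

#' Extract a mean-intensity trace over an ROI polygon
#'
#' Frames are maximum-projected over z, then averaged over the pixels whose
#' centres fall inside the polygon; the time axis is
#' `(frame index - 1) * framePeriodS`.
#'
#' @param series an [ImageSeries-class].
#' @param roi polygon matrix `[[row, col], ...]` in pixel coordinates.
#' @param channel `"red"` or `"green"`.
#' @return data.frame with `time_s` and `intensity`.
#' @export
extractTrace <- function(series, roi, channel = "red") {
  proj <- maxProject(series, channel)
  d <- dim(proj)
  mask <- polygonMask(roi, d[2:3])
  if (!any(mask)) stop("empty ROI: no pixel centres fall inside the polygon")
  idx <- which(mask)
  vals <- vapply(seq_len(d[1]), function(ti) mean(proj[ti, , ][idx]), 0)
  data.frame(time_s = (seq_len(d[1]) - 1) * series@framePeriodS,
             intensity = vals)
}
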