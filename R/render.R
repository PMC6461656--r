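## Rasterisation of vessel geometry: vessels are Gaussian-profile tubes on
## the pixel grid.  All rendering works in µm and converts to the 0-based
## (row, col) pixel convention at the end.

pixelCentersUm <- function(res, fovUm) {
  ps <- fovUm[1] / res
  list(x = matrix(rep((seq_len(res) - 0.5) * ps, each = res), res),   # col -> x
       y = matrix(rep((seq_len(res) - 0.5) * ps, res), res),          # row -> y
       ps = ps)
}

## Distance from every pixel centre to a polyline, plus the arclength of the
## projection point (for arrival-time interpolation along a vessel).
distanceToPolyline <- function(grid, path) {
  d2 <- matrix(Inf, nrow(grid$x), ncol(grid$x))
  arc <- matrix(0, nrow(grid$x), ncol(grid$x))
  cum <- 0
  for (k in seq_len(nrow(path) - 1L)) {
    p1 <- path[k, ]; p2 <- path[k + 1L, ]
    v <- p2 - p1
    len2 <- sum(v^2)
    if (len2 == 0) next
    tproj <- ((grid$x - p1[1]) * v[1] + (grid$y - p1[2]) * v[2]) / len2
    tproj <- pmin(pmax(tproj, 0), 1)
    dx <- grid$x - (p1[1] + tproj * v[1])
    dy <- grid$y - (p1[2] + tproj * v[2])
    dd <- dx * dx + dy * dy
    better <- dd < d2
    d2[better] <- dd[better]
    arc[better] <- cum + tproj[better] * sqrt(len2)
    cum <- cum + sqrt(len2)
  }
  list(d = sqrt(d2), arc = arc, totalArc = cum)
}

tubeProfile <- function(dist, radiusUm, ps) {
  ## Gaussian cross-section with half-maximum near the lumen radius,
  ## convolved with a pixel-scale PSF (mass-preserving), so sub-pixel
  ## vessels dim rather than vanish and off-axis halos stay compact
  sigma <- radiusUm / 2
  eff <- sqrt(sigma^2 + (0.5 * ps)^2)
  (sigma / eff) * exp(-dist^2 / (2 * eff^2))
}

applyNoise <- function(img, readSd) {
  n <- length(img)
  noisy <- rpois(n, pmax(img, 0)) + rnorm(n, 0, readSd)
  matrix(pmax(noisy, 0), nrow(img))
}

zProfile <- function(nz, zIdx, sigmaSlices = 1.2) {
  if (nz == 1L) return(1)
  exp(-(zIdx - (nz + 1) / 2)^2 / (2 * sigmaSlices^2))
}

#' Render a two-channel image series from ground truth
#'
#' Vessels are drawn as Gaussian-profile tubes.  The green channel carries
#' the intrinsic GCaMP baseline of arteries (stumps and sprouts; veins are
#' GCaMP-negative) plus, in calcium mode, transient fluorescence with
#' exponential decay in the event region.  The red channel carries the
#' intravascular tracer: in perfusion mode every vascular segment fills
#' from its ground-truth arrival time with a sigmoidal front (arrival
#' varying linearly along the stump between its two ROI anchor times);
#' censored compartments never fill.  Poisson shot noise and Gaussian read
#' noise are added.
#'
#' @param scene a [VascularScene-class].
#' @param truth mode-dependent: a one-row data.frame from
#'   [simulatePerfusionTruth()] (perfusion), a `CalciumEventTrain`
#'   (calcium), or `NULL` (anatomy).
#' @param mode `"anatomy"`, `"calcium"` or `"perfusion"`.
#' @param res resolution per side, 128 or 256.
#' @param sprouts optional sprouts data.frame rendered into both channels
#'   (red only where perfused).
#' @param dpt observation day used to truncate sprout paths.
#' @param nz number of z slices (anatomy/perfusion stacks).
#' @param nFrames number of time frames (defaults per mode).
#' @param amplitude vessel peak intensity.
#' @param baselineLevel background intensity.
#' @param readSd Gaussian read-noise SD.
#' @param gcampFrac green arterial baseline as a fraction of `amplitude`
#'   ("intrinsic weak GCaMP activity").
#' @param seed RNG seed for the noise.
#' @return an [ImageSeries-class].
#' @export
renderSeries <- function(scene, truth = NULL,
                         mode = c("anatomy", "calcium", "perfusion"),
                         res = 128, sprouts = NULL, dpt = NULL, nz = 1L,
                         nFrames = NULL, amplitude = 3000, baselineLevel = 50,
                         readSd = 10, gcampFrac = 0.4, seed = 1) {
  mode <- match.arg(mode)
  if (!res %in% c(128, 256))
    stop("configuration error: resolution must be 128 or 256")
  grid <- pixelCentersUm(res, scene@fovUm)
  ps <- grid$ps

  arteries <- c(stumps(scene, "proximal"), stumps(scene, "distal"))
  arteryFields <- lapply(arteries, function(s) distanceToPolyline(grid, s$path))
  armFields <- lapply(arteries, function(s) distanceToPolyline(grid, s$arm))
  arteryTube <- Reduce(pmax, c(
    Map(function(f, s) tubeProfile(f$d, s$radiusUm, ps), arteryFields, arteries),
    Map(function(f, s) tubeProfile(f$d, s$armRadiusUm, ps), armFields, arteries)))
  veinTube <- if (length(veins(scene)))
    Reduce(pmax, lapply(veins(scene), function(s)
      tubeProfile(distanceToPolyline(grid, s$path)$d, s$radiusUm, ps)))
  else 0

  sproutTube <- 0
  sproutPerfTube <- 0
  if (!is.null(sprouts) && nrow(sprouts)) {
    stopIfNot(!is.null(dpt), "rendering sprouts requires dpt")
    paths <- renderableSproutPaths(scene, sprouts, dpt)
    keep <- !vapply(paths, is.null, TRUE)
    if (any(keep)) {
      tubes <- lapply(paths[keep], function(p)
        tubeProfile(distanceToPolyline(grid, p)$d, 4, ps))
      sproutTube <- Reduce(pmax, tubes)
      perf <- sprouts$perfused[keep] %in% TRUE
      if (any(perf)) sproutPerfTube <- Reduce(pmax, tubes[perf])
    }
  }

  greenStatic <- gcampFrac * amplitude * pmax(arteryTube, sproutTube)

  if (mode == "anatomy") {
    nFrames <- nFrames %||% 1L
    fp <- 2 / 3
    mkFrame <- function(ti, zi) baselineLevel +
      greenStatic * zProfile(nz, zi)
    series <- buildSeries(mkFrame, NULL, nFrames, nz, res, readSd, seed)
    red <- array(0, c(0, 0, 0, 0))
    return(new("ImageSeries", green = series$green %||% array(0, c(0, 0, 0, 0)),
               red = red, framePeriodS = fp,
               pixelSizeUm = ps, zStepUm = 2, nBaselineFrames = 0L,
               mode = "anatomy"))
  }

  if (mode == "calcium") {
    stopIfNot(inherits(truth, "CalciumEventTrain"),
              "calcium mode needs a CalciumEventTrain")
    fp <- 2 / 3
    nFrames <- nFrames %||% as.integer(truth$session_s / fp)
    band <- scene@woundBand
    regionMaskUm <- if (truth$region == "distal") grid$y > band[2] else grid$y < band[1]
    tt <- (seq_len(nFrames) - 1) * fp
    dff <- vapply(tt, function(t0)
      sum(truth$amplitude_dff * exp(-(t0 - truth$event_times_s[truth$event_times_s <= t0]) /
                                      truth$decay_tau_s)), 0)
    mkGreen <- function(ti, zi) baselineLevel +
      greenStatic * (1 + dff[ti] * regionMaskUm) * zProfile(nz, zi)
    series <- buildSeries(mkGreen, NULL, nFrames, nz, res, readSd, seed)
    return(new("ImageSeries", green = series$green, red = array(0, c(0, 0, 0, 0)),
               framePeriodS = fp, pixelSizeUm = ps, zStepUm = 2,
               nBaselineFrames = 0L, mode = "calcium"))
  }

  ## perfusion: per-pixel arrival-time map
  stopIfNot(is.data.frame(truth) && nrow(truth) == 1L,
            "perfusion mode needs a one-row ground-truth data.frame")
  fp <- 2 / 3
  nFrames <- nFrames %||% truth$n_frames
  arrMap <- arrivalMapUm(scene, truth, grid, arteryFields, armFields, arteries)
  sproutArr <- if (!identical(sproutTube, 0) && !is.na(truth$t_C))
    truth$t_C else NA_real_
  veinArr <- if (is.na(truth$t_A)) NA_real_ else truth$t_A - 1

  tt <- (seq_len(nFrames) - 1) * fp
  rise <- 0.5
  sigmoid <- function(t0, arr)                 # linear bolus front from arrival
    ifelse(is.na(arr), 0, pmin(pmax((t0 - arr) / rise, 0), 1))
  mkRed <- function(ti, zi) {
    t0 <- tt[ti]
    fillA <- arteryTube * sigmoid(t0, arrMap)
    fillV <- veinTube * sigmoid(t0, veinArr)
    fillS <- if (identical(sproutPerfTube, 0)) 0 else
      sproutPerfTube * sigmoid(t0, sproutArr)
    baselineLevel + amplitude * pmax(fillA, fillV, fillS) * zProfile(nz, zi)
  }
  mkGreen <- function(ti, zi) baselineLevel + greenStatic * zProfile(nz, zi)
  series <- buildSeries(mkGreen, mkRed, nFrames, nz, res, readSd, seed)
  new("ImageSeries", green = series$green, red = series$red,
      framePeriodS = fp, pixelSizeUm = ps, zStepUm = 2,
      nBaselineFrames = 30L, mode = "perfusion")
}

## Arrival-time map over artery pixels: linear in arclength between the two
## ROI anchors of each stump, constant beyond; NA (never fills) past the
## last uncensored anchor.  The cut-wall arm fills with the near-edge
## anchor's arrival.
arrivalMapUm <- function(scene, truth, grid, arteryFields, armFields, arteries) {
  map <- matrix(NA_real_, nrow(grid$x), ncol(grid$x))
  prox <- stumps(scene, "proximal")
  nProx <- length(prox)
  for (i in seq_along(arteries)) {
    s <- arteries[[i]]
    f <- arteryFields[[i]]
    isProx <- i <= nProx
    trunk <- trunkPath(s)
    total <- sum(sqrt(rowSums(diff(trunk)^2)))
    ## anchors at geodesic offsets 250 (far) and 50 (near) from the edge
    if (isProx) {
      tFar <- truth$t_A; tNear <- truth$t_B
    } else {
      tFar <- truth$t_D; tNear <- truth$t_C
    }
    arcFar <- total - 250
    arcNear <- total - 50
    owner <- tubeProfile(f$d, s$radiusUm, grid$ps) > 0.05
    if (is.na(tFar) && is.na(tNear)) next
    arc <- f$arc
    if (is.na(tNear)) {
      val <- ifelse(arc <= arcFar + 25, tFar, NA_real_)
    } else if (is.na(tFar)) {
      val <- ifelse(arc >= arcNear - 25, tNear, NA_real_)
    } else {
      fr <- pmin(pmax((arc - arcFar) / (arcNear - arcFar), 0), 1)
      val <- tFar + fr * (tNear - tFar)
    }
    sel <- owner & !is.na(val)
    upd <- sel & (is.na(map) | val < map)
    map[upd] <- val[upd]
    if (!is.na(tNear)) {
      armOwner <- tubeProfile(armFields[[i]]$d, s$armRadiusUm, grid$ps) > 0.05
      updA <- armOwner & (is.na(map) | tNear < map)
      map[updA] <- tNear
    }
  }
  map
}

buildSeries <- function(mkGreen, mkRed, nFrames, nz, res, readSd, seed) {
  withSeed(seed, {
    green <- if (!is.null(mkGreen)) array(0, c(nFrames, nz, res, res)) else NULL
    red <- if (!is.null(mkRed)) array(0, c(nFrames, nz, res, res)) else NULL
    for (ti in seq_len(nFrames)) for (zi in seq_len(nz)) {
      if (!is.null(mkGreen)) green[ti, zi, , ] <- applyNoise(mkGreen(ti, zi), readSd)
      if (!is.null(mkRed)) red[ti, zi, , ] <- applyNoise(mkRed(ti, zi), readSd)
    }
    list(green = green, red = red)
  })
}

#' Render a post-fill red-channel projection
#'
#' The steady state after complete tracer filling: arteries, veins and
#' *perfused* sprouts carry tracer; non-perfused sprouts stay dark.  Used
#' for perfused-sprout colocalization counting on compressed stacks.
#'
#' @inheritParams renderSeries
#' @param sprouts sprouts data.frame with perfusion flags.
#' @return numeric matrix (rows x cols).
#' @export
renderRedProjection <- function(scene, sprouts, dpt, res = 256,
                                amplitude = 3000, baselineLevel = 50,
                                readSd = 10, seed = 1) {
  grid <- pixelCentersUm(res, scene@fovUm)
  ps <- grid$ps
  arteries <- c(stumps(scene, "proximal"), stumps(scene, "distal"))
  tube <- Reduce(pmax, c(
    lapply(c(arteries, veins(scene)), function(s)
      tubeProfile(distanceToPolyline(grid, s$path)$d, s$radiusUm, ps)),
    lapply(arteries, function(s)
      tubeProfile(distanceToPolyline(grid, s$arm)$d, s$armRadiusUm, ps))))
  if (!is.null(sprouts) && nrow(sprouts)) {
    paths <- renderableSproutPaths(scene, sprouts, dpt)
    for (i in seq_along(paths)) {
      if (is.null(paths[[i]]) || !isTRUE(sprouts$perfused[i])) next
      tube <- pmax(tube, tubeProfile(distanceToPolyline(grid, paths[[i]])$d, 4, ps))
    }
  }
  withSeed(seed, applyNoise(baselineLevel + amplitude * tube, readSd))
}
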