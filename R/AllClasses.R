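#' @import methods
NULL

#' Geometric model of a transsected-artery wound scene
#'
#' A calibrated (micrometre) description of the field of view used by the
#' synthetic generator: the wound band crossing the FOV, the proximal and
#' distal arterial stumps terminating on its edges, and adjacent veins
#' (GCaMP-negative, visible only in the tracer channel).  Candidate
#' artery-to-vein anastomosis sites are stored per stump.
#'
#' @slot sceneId character scene identifier.
#' @slot fovUm numeric length-2, field of view in µm (default 1000 x 1000).
#' @slot woundBand numeric length-2, the y-range (µm) of the wound band;
#'   the band spans the full x-range of the FOV.
#' @slot woundGapUm numeric, the functional bridging distance (µm) a sprout
#'   must cover before a perfused connection across the wound can form.
#' @slot proximalStumps,distalStumps,veins lists of vessel segments; each is
#'   a list with elements `id`, `path` (n x 2 matrix of (x, y) vertices in
#'   µm) and `radiusUm`.
#' @slot anastomosisSites data.frame with columns `stump_id`, `vein_id`,
#'   `x_um`, `y_um`.
#' @slot rngSeed integer seed the scene was built from.
#' @export
setClass("VascularScene", representation(
  sceneId = "character",
  fovUm = "numeric",
  woundBand = "numeric",
  woundGapUm = "numeric",
  proximalStumps = "list",
  distalStumps = "list",
  veins = "list",
  anastomosisSites = "data.frame",
  rngSeed = "integer"
))

setValidity("VascularScene", function(object) {
  msg <- character()
  fov <- object@fovUm
  wb <- object@woundBand
  if (length(fov) != 2L || any(fov <= 0)) msg <- c(msg, "fovUm must be two positive lengths")
  if (length(wb) != 2L || wb[1] >= wb[2]) msg <- c(msg, "woundBand must be an increasing y-range")
  if (length(wb) == 2L && (wb[1] < 0 || wb[2] > fov[2]))
    msg <- c(msg, "wound band must lie inside the FOV")
  inFov <- function(p) all(p[, 1] >= 0 & p[, 1] <= fov[1] & p[, 2] >= 0 & p[, 2] <= fov[2])
  term <- function(s) s$terminalUm %||% s$path[nrow(s$path), ]
  for (s in object@proximalStumps) {
    if (s$radiusUm <= 0) msg <- c(msg, "vessel radii must be positive")
    if (!inFov(s$path)) msg <- c(msg, "proximal stump leaves the FOV")
    if (abs(term(s)[2] - wb[1]) > 1e-6) msg <- c(msg, "proximal terminal not on proximal wound edge")
  }
  for (s in object@distalStumps) {
    if (s$radiusUm <= 0) msg <- c(msg, "vessel radii must be positive")
    if (!inFov(s$path)) msg <- c(msg, "distal stump leaves the FOV")
    if (abs(term(s)[2] - wb[2]) > 1e-6) msg <- c(msg, "distal terminal not on distal wound edge")
  }
  arteries <- c(vapply(object@proximalStumps, `[[`, "", "id"),
                vapply(object@distalStumps, `[[`, "", "id"))
  veins <- vapply(object@veins, `[[`, "", "id")
  if (length(intersect(arteries, veins))) msg <- c(msg, "artery and vein ids must be disjoint")
  if (anyDuplicated(c(arteries, veins))) msg <- c(msg, "duplicate vessel ids")
  if (length(msg)) msg else TRUE
})

#' Two-channel time-lapse image series
#'
#' Frames are stored per channel as 4-D arrays indexed `[t, z, y, x]`.  A
#' channel that was not acquired is a zero-extent array.  Acquisition
#' metadata mirror the sidecar JSON written by [writeSeries()].
#'
#' @slot green,red numeric 4-D arrays `[t, z, y, x]`.
#' @slot framePeriodS seconds per frame (default 2/3 s).
#' @slot pixelSizeUm µm per pixel.
#' @slot zStepUm µm between z-slices.
#' @slot nBaselineFrames frames recorded before tracer injection.
#' @slot mode character, one of `"anatomy"`, `"calcium"`, `"perfusion"`.
#' @export
setClass("ImageSeries", representation(
  green = "array",
  red = "array",
  framePeriodS = "numeric",
  pixelSizeUm = "numeric",
  zStepUm = "numeric",
  nBaselineFrames = "integer",
  mode = "character"
))

setValidity("ImageSeries", function(object) {
  msg <- character()
  for (ch in c("green", "red")) {
    a <- slot(object, ch)
    if (length(a) && length(dim(a)) != 4L)
      msg <- c(msg, sprintf("%s channel must be a [t, z, y, x] array", ch))
    if (length(a) && any(a < 0)) msg <- c(msg, sprintf("%s intensities must be >= 0", ch))
  }
  if (object@framePeriodS <= 0) msg <- c(msg, "framePeriodS must be positive")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be positive")
  if (identical(object@mode, "perfusion")) {
    nt <- if (length(object@red)) dim(object@red)[1] else 0L
    if (nt < object@nBaselineFrames)
      msg <- c(msg, "perfusion series shorter than its baseline")
  }
  if (length(msg)) msg else TRUE
})

#' Labelled ROI polygons and region masks
#'
#' Pixel coordinates are 0-based `(row, col)` with origin top-left; a pixel
#' belongs to a polygon when its centre falls inside (half-open rule).
#'
#' @slot rois named list (`A`, `B`, `C`, `D`) of polygon matrices
#'   `[[row, col], ...]`.
#' @slot regions named list of logical matrices (`proximal`, `distal`,
#'   `wound`) over the image grid.
#' @slot pixelSizeUm µm per pixel of the grid the coordinates refer to.
#' @slot dim integer length-2 image dimensions (rows, cols).
#' @export
setClass("RoiSet", representation(
  rois = "list",
  regions = "list",
  pixelSizeUm = "numeric",
  dim = "integer"
))

setValidity("RoiSet", function(object) {
  msg <- character()
  for (nm in names(object@rois)) {
    p <- object@rois[[nm]]
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
      msg <- c(msg, sprintf("ROI %s polygon is degenerate", nm))
  }
  if (!all(c("proximal", "distal", "wound") %in% names(object@regions)))
    msg <- c(msg, "regions must include proximal, distal and wound masks")
  if (length(msg)) msg else TRUE
})

#' Tracer arrival times and derived perfusion metrics for one session
#'
#' Arrival times are seconds from recording start; a censored compartment
#' (tracer never crossed the detection threshold within the window) is
#' `NA` with its censoring flag set.  Delta-t pairs follow
#' `dt[j - i] = t(j) - t(i)` for (i, j) = (A, B), (B, C), (C, D); a pair is
#' missing iff either endpoint is censored, and the integral flow measure
#' `|dtBA| + |dtCB| + |dtDC|` is present iff all three pairs are.
#'
#' @slot t named numeric (A, B, C, D) arrival times in s, `NA` = censored.
#' @slot censored named logical (A, B, C, D).
#' @slot dtBA,dtCB,dtDC numeric seconds or `NA`.
#' @slot integralDt numeric seconds or `NA`.
#' @slot perfused named logical (proximal, wound, distal): the 66.66 s rule.
#' @slot anastomosis named logical (proximal, distal): the 1.3 s rule.
#' @slot recordingWindowS recording length in seconds.
#' @export
setClass("ArrivalResult", representation(
  t = "numeric",
  censored = "logical",
  dtBA = "numeric",
  dtCB = "numeric",
  dtDC = "numeric",
  integralDt = "numeric",
  perfused = "logical",
  anastomosis = "logical",
  recordingWindowS = "numeric"
))

setValidity("ArrivalResult", function(object) {
  msg <- character()
  if (!identical(names(object@t), c("A", "B", "C", "D")))
    msg <- c(msg, "arrival times must be named A, B, C, D")
  if (!identical(names(object@censored), c("A", "B", "C", "D")))
    msg <- c(msg, "censoring flags must be named A, B, C, D")
  if (any(is.na(object@t) != object@censored))
    msg <- c(msg, "t must be NA exactly for censored compartments")
  pair <- function(dt, i, j) is.na(dt) == (object@censored[i] || object@censored[j])
  if (!pair(object@dtBA, "A", "B") || !pair(object@dtCB, "B", "C") ||
      !pair(object@dtDC, "C", "D"))
    msg <- c(msg, "dt fields must be missing iff an endpoint is censored")
  if (is.na(object@integralDt) !=
      (is.na(object@dtBA) || is.na(object@dtCB) || is.na(object@dtDC)))
    msg <- c(msg, "integralDt present iff all three dt present")
  if (length(msg)) msg else TRUE
})

#' Fitted longitudinal model summary
#'
#' Uniform container for the cohort-level fits: Poisson GLMM sprout-count
#' slope, LMM length slope, treatment-by-time interaction models, and the
#' through-origin perfused-fraction regression.
#'
#' @slot modelKind one of `"poisson_glmm"`, `"lmm"`, `"mlmr_interaction"`,
#'   `"through_origin_mixed"`.
#' @slot formulaText character model formula.
#' @slot coefficients data.frame with columns `term`, `estimate`, `se`, `p`.
#' @slot omnibus named numeric `F`, `df1`, `df2`, `p` (empty if not applicable).
#' @slot posthoc data.frame of pairwise contrasts with raw and Holm-adjusted p.
#' @slot fit the underlying lme4 fit (or NULL).
#' @export
setClass("ModelFit", representation(
  modelKind = "character",
  formulaText = "character",
  coefficients = "data.frame",
  omnibus = "numeric",
  posthoc = "data.frame",
  fit = "ANY"
))

setValidity("ModelFit", function(object) {
  msg <- character()
  cf <- object@coefficients
  if (!all(c("term", "estimate", "se") %in% names(cf)))
    msg <- c(msg, "coefficients need term/estimate/se columns")
  if (nrow(cf) && any(cf$se <= 0, na.rm = TRUE)) msg <- c(msg, "slope SEs must be > 0")
  ph <- object@posthoc
  if (nrow(ph) && all(c("p", "p_holm") %in% names(ph))) {
    if (any(ph$p_holm < ph$p - 1e-12)) msg <- c(msg, "Holm-adjusted p must be >= raw p")
    if (any(ph$p_holm > 1 + 1e-12)) msg <- c(msg, "adjusted p must be <= 1")
  }
  if (length(msg)) msg else TRUE
})
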