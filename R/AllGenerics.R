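#' Accessors for the core classes
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @param channel `"green"` or `"red"`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sceneId", function(x) standardGeneric("sceneId"))
#' @rdname accessors
#' @export
setMethod("sceneId", "VascularScene", function(x) x@sceneId)

#' @rdname accessors
#' @export
setGeneric("woundBand", function(x) standardGeneric("woundBand"))
#' @rdname accessors
#' @export
setMethod("woundBand", "VascularScene", function(x) x@woundBand)

#' @rdname accessors
#' @export
setGeneric("stumps", function(x, ...) standardGeneric("stumps"))
#' @rdname accessors
#' @param side `"proximal"` or `"distal"`.
#' @param ... passed on to methods.
#' @export
setMethod("stumps", "VascularScene", function(x, side = c("proximal", "distal")) {
  side <- match.arg(side)
  if (side == "proximal") x@proximalStumps else x@distalStumps
})

#' @rdname accessors
#' @export
setGeneric("veins", function(x) standardGeneric("veins"))
#' @rdname accessors
#' @export
setMethod("veins", "VascularScene", function(x) x@veins)

#' @rdname accessors
#' @export
setGeneric("frames", function(x, channel = "red") standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "ImageSeries", function(x, channel = "red") {
  slot(x, match.arg(channel, c("red", "green")))
})

#' @rdname accessors
#' @export
setGeneric("framePeriod", function(x) standardGeneric("framePeriod"))
#' @rdname accessors
#' @export
setMethod("framePeriod", "ImageSeries", function(x) x@framePeriodS)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "ImageSeries", function(x) x@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("pixelSize", "RoiSet", function(x) x@pixelSizeUm)

#' @rdname accessors
#' @export
setGeneric("rois", function(x) standardGeneric("rois"))
#' @rdname accessors
#' @export
setMethod("rois", "RoiSet", function(x) x@rois)

#' @rdname accessors
#' @export
setGeneric("regionMasks", function(x) standardGeneric("regionMasks"))
#' @rdname accessors
#' @export
setMethod("regionMasks", "RoiSet", function(x) x@regions)

#' @rdname accessors
#' @export
setGeneric("arrivalTimes", function(x) standardGeneric("arrivalTimes"))
#' @rdname accessors
#' @export
setMethod("arrivalTimes", "ArrivalResult", function(x) x@t)

#' @rdname accessors
#' @export
setGeneric("deltaT", function(x) standardGeneric("deltaT"))
#' @rdname accessors
#' @export
setMethod("deltaT", "ArrivalResult", function(x)
  c(dtBA = x@dtBA, dtCB = x@dtCB, dtDC = x@dtDC, integral = x@integralDt))

#' @rdname accessors
#' @export
setGeneric("perfusedFlags", function(x) standardGeneric("perfusedFlags"))
#' @rdname accessors
#' @export
setMethod("perfusedFlags", "ArrivalResult", function(x) x@perfused)

#' @rdname accessors
#' @export
setGeneric("anastomosisFlags", function(x) standardGeneric("anastomosisFlags"))
#' @rdname accessors
#' @export
setMethod("anastomosisFlags", "ArrivalResult", function(x) x@anastomosis)

#' @rdname accessors
#' @export
setGeneric("modelCoef", function(x) standardGeneric("modelCoef"))
#' @rdname accessors
#' @export
setMethod("modelCoef", "ModelFit", function(x) x@coefficients)

#' Extract a named slope estimate with its standard error
#'
#' @param x a [ModelFit-class] object.
#' @param term coefficient name.
#' @return named numeric `estimate`, `se`, `p`.
#' @export
setGeneric("slopeOf", function(x, term) standardGeneric("slopeOf"))
#' @rdname slopeOf
#' @export
setMethod("slopeOf", "ModelFit", function(x, term) {
  cf <- x@coefficients
  i <- match(term, cf$term)
  if (is.na(i)) stop("no coefficient named '", term, "'")
  c(estimate = cf$estimate[i], se = cf$se[i], p = cf$p[i])
})

setMethod("show", "VascularScene", function(object) {
  cat("VascularScene '", object@sceneId, "'\n", sep = "")
  cat(sprintf("  FOV %g x %g um, wound band y = [%g, %g] um (gap %g um)\n",
              object@fovUm[1], object@fovUm[2], object@woundBand[1],
              object@woundBand[2], object@woundGapUm))
  cat(sprintf("  %d proximal + %d distal stumps, %d veins, %d anastomosis sites\n",
              length(object@proximalStumps), length(object@distalStumps),
              length(object@veins), nrow(object@anastomosisSites)))
})

setMethod("show", "ImageSeries", function(object) {
  dimStr <- function(a) if (length(a)) paste(dim(a), collapse = " x ") else "absent"
  cat("ImageSeries (", object@mode, ")\n", sep = "")
  cat("  green [t,z,y,x]:", dimStr(object@green), "\n")
  cat("  red   [t,z,y,x]:", dimStr(object@red), "\n")
  cat(sprintf("  %.4g s/frame, %.4g um/px, z-step %g um, %d baseline frames\n",
              object@framePeriodS, object@pixelSizeUm, object@zStepUm,
              object@nBaselineFrames))
})

setMethod("show", "RoiSet", function(object) {
  cat("RoiSet:", paste(names(object@rois), collapse = ", "),
      "| regions:", paste(names(object@regions), collapse = ", "), "\n")
})

setMethod("show", "ArrivalResult", function(object) {
  fmt <- function(v) ifelse(is.na(v), "censored", sprintf("%.2f s", v))
  cat("ArrivalResult\n  t:", paste(names(object@t), fmt(object@t), collapse = "  "), "\n")
  cat(sprintf("  dtBA=%s dtCB=%s dtDC=%s integral=%s\n", fmt(object@dtBA),
              fmt(object@dtCB), fmt(object@dtDC), fmt(object@integralDt)))
  cat("  perfused:", paste(names(object@perfused), object@perfused, collapse = " "), "\n")
  cat("  anastomosis:", paste(names(object@anastomosis), object@anastomosis, collapse = " "), "\n")
})

setMethod("show", "ModelFit", function(object) {
  cat("ModelFit <", object@modelKind, "> ", object@formulaText, "\n", sep = "")
  print(object@coefficients, row.names = FALSE)
  if (length(object@omnibus))
    cat(sprintf("  omnibus F(%g, %g) = %.3f, p = %.4g\n", object@omnibus["df1"],
                object@omnibus["df2"], object@omnibus["F"], object@omnibus["p"]))
  if (nrow(object@posthoc)) {
    cat("  post-hoc (Holm-adjusted):\n")
    print(head(object@posthoc, 10), row.names = FALSE)
  }
})
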