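#' Detect tracer arrival in an ROI intensity trace
#'
#' Arrival is a sustained threshold crossing: baseline mean `m` and SD `s`
#' are taken over the first `nBaseline` frames; the arrival frame is the
#' first post-baseline frame at which the trace stays at or above
#' `m + kSd * s` for `minConsecutive` consecutive frames.  The reported
#' time is refined to sub-frame precision by linear interpolation of the
#' threshold crossing between the previous frame and the arrival frame.
#' Returns `NA` (censored) when no such frame exists within the recording.
#'
#' @param trace numeric intensity vector, or a data.frame with an
#'   `intensity` column as returned by the trace renderers/extractors.
#' @param framePeriodS seconds per frame (default 2/3).
#' @param nBaseline baseline frames (default 30).
#' @param kSd threshold multiplier (default 3).
#' @param minConsecutive persistence requirement in frames (default 2).
#' @param sdFloor absolute SD floor used when the baseline is flat.
#' @return arrival time in seconds from recording start, or `NA`.
#' @examples
#' tr <- c(rep(100, 39), rep(200, 21))
#' detectArrival(tr, nBaseline = 30)
#' @export
detectArrival <- function(trace, framePeriodS = 2 / 3, nBaseline = 30,
                          kSd = 3, minConsecutive = 2, sdFloor = 1e-6) {
  if (is.data.frame(trace)) trace <- trace$intensity
  n <- length(trace)
  if (n <= nBaseline) stop("trace shorter than its baseline")
  m <- mean(trace[seq_len(nBaseline)])
  s <- max(sd(trace[seq_len(nBaseline)]), sdFloor)
  thr <- m + kSd * s
  above <- trace >= thr
  ## frames starting a run of >= minConsecutive above-threshold frames
  ok <- above
  if (minConsecutive > 1)
    for (k in seq_len(minConsecutive - 1L))
      ok <- ok & c(above[-seq_len(k)], rep(FALSE, k))
  cand <- which(ok)
  cand <- cand[cand > nBaseline]
  if (!length(cand)) return(NA_real_)
  f <- cand[1]
  ## interpolate the crossing between f-1 and f
  lo <- trace[f - 1]; hi <- trace[f]
  frac <- if (hi > lo) min(max((thr - lo) / (hi - lo), 0), 1) else 0
  (f - 2 + frac) * framePeriodS
}

#' Assemble arrival metrics for one session
#'
#' Computes the delta-t pairs `dtBA`, `dtCB`, `dtDC` (sign preserved:
#' negative `dtDC` indicates retrograde distal flow), the integral flow
#' measure `|dtBA| + |dtCB| + |dtDC|`, the per-compartment perfusion
#' booleans (delta-t defined and below the 66.66 s window) and the
#' anastomosis booleans (`|dt| < 1.3` s, strict).
#'
#' @param arrivals named numeric (A, B, C, D); `NA` = censored.
#' @param recordingWindowS recording length (s).
#' @param perfusionWindowS perfusion classification window (s); fixed at
#'   66.66 s (the 100-frame minimum recording) regardless of the actual
#'   recording length, for comparability.
#' @param anastomosisThresholdS the 1.3 s rule.
#' @return an [ArrivalResult-class].
#' @examples
#' computeMetrics(c(A = 10, B = 10.5, C = 12, D = 11))
#' @export
computeMetrics <- function(arrivals, recordingWindowS = 200,
                           perfusionWindowS = 66.66,
                           anastomosisThresholdS = 1.3) {
  stopIfNot(all(c("A", "B", "C", "D") %in% names(arrivals)),
            "arrivals must be named A, B, C, D")
  t <- as.numeric(arrivals[c("A", "B", "C", "D")])
  names(t) <- c("A", "B", "C", "D")
  cens <- is.na(t)
  names(cens) <- names(t)
  dtBA <- t["B"] - t["A"]
  dtCB <- t["C"] - t["B"]
  dtDC <- t["D"] - t["C"]
  integral <- abs(dtBA) + abs(dtCB) + abs(dtDC)
  perf <- c(proximal = isTRUE(unname(dtBA) < perfusionWindowS),
            wound = isTRUE(unname(dtCB) < perfusionWindowS),
            distal = isTRUE(unname(dtDC) < perfusionWindowS))
  ana <- c(proximal = isTRUE(abs(unname(dtBA)) < anastomosisThresholdS),
           distal = isTRUE(abs(unname(dtDC)) < anastomosisThresholdS))
  new("ArrivalResult", t = t, censored = cens,
      dtBA = unname(dtBA), dtCB = unname(dtCB), dtDC = unname(dtDC),
      integralDt = unname(integral), perfused = perf, anastomosis = ana,
      recordingWindowS = recordingWindowS)
}

#' Classify artery-vein anastomoses from arrival metrics
#'
#' A side is classified as anastomosed when its intra-stump delta-t is
#' defined and strictly below the threshold in absolute value
#' (`|dtBA|` proximal, `|dtDC|` distal); the absolute value admits
#' retrograde (negative) distal delays.
#'
#' @param result an [ArrivalResult-class] or a named numeric with `dtBA`
#'   and `dtDC`.
#' @param thresholdS threshold in seconds (default 1.3, about two frame
#'   periods).
#' @return named logical (proximal, distal).
#' @export
classifyAnastomosis <- function(result, thresholdS = 1.3) {
  dt <- if (is(result, "ArrivalResult"))
    c(dtBA = result@dtBA, dtDC = result@dtDC)
  else c(dtBA = unname(result["dtBA"]), dtDC = unname(result["dtDC"]))
  c(proximal = isTRUE(abs(dt["dtBA"]) < thresholdS),
    distal = isTRUE(abs(dt["dtDC"]) < thresholdS))
}

#' Count perfused sprouts by red-channel colocalization
#'
#' A sprout counts as perfused when at least `coverageFraction` of its
#' skeleton pixels exceed the red baseline mean plus `snrThreshold` SDs in
#' the compressed (z-projected) red image.  Baseline statistics are taken
#' robustly over the whole projection (median and MAD), which the
#' tracer-free background dominates.
#'
#' @param sproutPaths list of skeleton pixel paths ((row, col) matrices,
#'   0-based), one per sprout.
#' @param redProjection 2-D numeric matrix (post-injection red channel,
#'   z-compressed).
#' @param snrThreshold SD multiplier (default 3).
#' @param coverageFraction fraction of skeleton pixels required (default
#'   0.5; the boundary is closed, >= counts).
#' @return named integer vector `c(n_perfused, n_total)`.
#' @export
countPerfusedSprouts <- function(sproutPaths, redProjection, snrThreshold = 3,
                                 coverageFraction = 0.5) {
  nTotal <- length(sproutPaths)
  if (nTotal == 0L) return(c(n_perfused = 0L, n_total = 0L))
  base <- median(redProjection)
  spread <- max(mad(redProjection), 1e-9)
  thr <- base + snrThreshold * spread
  nr <- nrow(redProjection)
  perf <- vapply(sproutPaths, function(p) {
    r <- pmin(pmax(round(p[, 1]), 0), nr - 1L)
    c0 <- pmin(pmax(round(p[, 2]), 0), ncol(redProjection) - 1L)
    mean(redProjection[cbind(r + 1L, c0 + 1L)] > thr) >= coverageFraction
  }, TRUE)
  c(n_perfused = sum(perf), n_total = nTotal)
}
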