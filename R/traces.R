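#' Render tracer intensity traces for the four perfusion ROIs
#'
#' Produces the red-channel mean-intensity time series that arrival
#' detection consumes, directly from one row of perfusion ground truth
#' (the image-free route; [renderSeries()] plus [extractTrace()] is the
#' image route).  Each ROI trace is a flat baseline plus a linear fill
#' front of duration `riseS` starting at the true arrival time: the
#' arrival is the moment intensity change begins, and the compact front
#' keeps any threshold crossing within `riseS` of it.  A censored
#' compartment stays at baseline.
#'
#' @param truth one-row data.frame from [simulatePerfusionTruth()].
#' @param baseline baseline intensity.
#' @param amplitude fill amplitude above baseline.
#' @param riseS duration of the linear fill front (s).
#' @param snr amplitude / noise-SD ratio at the filled plateau.  Noise is
#'   shot-noise-like: Gaussian per frame with SD scaling as the square
#'   root of the local intensity, so the pre-arrival baseline is quieter
#'   than the plateau, as in photon-limited recordings.
#' @param framePeriodS seconds per frame.
#' @param seed RNG seed.
#' @return data.frame with columns `time_s`, `roi_A`..`roi_D`.
#' @examples
#' sc <- makeScene(1)
#' tr <- simulatePerfusionTruth(sc, dpt = 8, n = 1, seed = 2)
#' head(renderRoiTraces(tr, seed = 2))
#' @export
renderRoiTraces <- function(truth, baseline = 100, amplitude = 400,
                            riseS = 0.5, snr = 20, framePeriodS = 2 / 3,
                            seed = 1) {
  stopIfNot(nrow(truth) == 1L, "renderRoiTraces takes a single session row")
  tt <- seq(0, by = framePeriodS, length.out = truth$n_frames)
  sdN <- amplitude / snr
  arr <- c(A = truth$t_A, B = truth$t_B, C = truth$t_C, D = truth$t_D)
  withSeed(seed, {
    cols <- lapply(arr, function(ta) {
      fill <- if (is.na(ta)) 0 else
        amplitude * pmin(pmax((tt - ta) / riseS, 0), 1)
      level <- baseline + fill
      sdLocal <- sdN * sqrt(level / (baseline + amplitude))
      pmax(0, level + rnorm(length(tt), 0, sdLocal))
    })
    names(cols) <- paste0("roi_", names(arr))
    cbind(data.frame(time_s = tt), as.data.frame(cols))
  })
}
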