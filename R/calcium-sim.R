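#' Calcium transient generator parameters
#'
#' Endothelial Ca2+ transient incidence follows a triangular time profile:
#' zero at 3.0 dpt, peaking at 5.0 dpt with a mean of 5 events per 22-min
#' session on the distal stump/sprouts, and declining back to zero by
#' 8.0 dpt.  Proximal activity is a fixed fraction of distal
#' (`asymmetry`, default 0.1), reflecting the strong distal dominance of
#' angiogenic signalling.  Events have a fixed fluorescence amplitude
#' (dF/F) with single-exponential decay.
#'
#' @param peakRate mean events per session at the profile peak.
#' @param peakDpt day of peak activity.
#' @param riseFromDpt,fallToDpt zeros of the triangular profile.
#' @param asymmetry proximal/distal rate ratio.
#' @param sessionS session length in seconds (22 min).
#' @param amplitudeDff event amplitude as dF/F.
#' @param decayTauS exponential decay constant (s).
#' @param framePeriodS acquisition period for rendered traces (s).
#' @param noiseSdDff Gaussian noise SD of rendered dF/F traces.
#' @return named list of parameters.
#' @export
calciumParams <- function(peakRate = 5, peakDpt = 5.0, riseFromDpt = 3.0,
                          fallToDpt = 8.0, asymmetry = 0.1, sessionS = 1320,
                          amplitudeDff = 0.5, decayTauS = 5,
                          framePeriodS = 2 / 3, noiseSdDff = 0.05) {
  as.list(environment())
}

#' Expected transient count for a session
#'
#' Evaluates the triangular activity profile.
#'
#' @param dpt days post-transection (vectorised).
#' @param region `"proximal"` or `"distal"`.
#' @param params see [calciumParams()].
#' @return expected events per session.
#' @export
calciumRate <- function(dpt, region = c("distal", "proximal"),
                        params = calciumParams()) {
  region <- match.arg(region)
  up <- (dpt - params$riseFromDpt) / (params$peakDpt - params$riseFromDpt)
  down <- (params$fallToDpt - dpt) / (params$fallToDpt - params$peakDpt)
  rate <- params$peakRate * pmax(0, pmin(up, down, 1))
  if (region == "proximal") rate <- rate * params$asymmetry
  rate
}

#' Simulate a Ca2+ event train for one session
#'
#' Event times are a homogeneous Poisson process within the session at the
#' session-mean rate given by the triangular profile, sorted ascending.
#'
#' @inheritParams calciumRate
#' @param seed integer RNG seed.
#' @return a list of class `CalciumEventTrain` with `event_times_s`,
#'   `amplitude_dff`, `decay_tau_s`, `region`, `dpt`, `session_s`.
#' @examples
#' tr <- simulateCalciumEvents(5, "distal", seed = 1)
#' length(tr$event_times_s)
#' @export
simulateCalciumEvents <- function(dpt, region = c("distal", "proximal"),
                                  params = calciumParams(), seed = 1) {
  region <- match.arg(region)
  rate <- calciumRate(dpt, region, params)
  ev <- withSeed(seed, sort(runif(rpois(1, rate), 0, params$sessionS)))
  structure(list(event_times_s = ev, amplitude_dff = params$amplitudeDff,
                 decay_tau_s = params$decayTauS, region = region, dpt = dpt,
                 session_s = params$sessionS),
            class = "CalciumEventTrain")
}

#' Render the GCaMP region trace for an event train
#'
#' The noise-free trace is a constant baseline scaled by
#' `1 + sum_k A * exp(-(t - t_k)/tau)` over past events (instantaneous
#' rise, exponential decay); multiplicative Gaussian noise of SD
#' `noiseSdDff * F0` is added.
#'
#' @param events a `CalciumEventTrain` from [simulateCalciumEvents()].
#' @param params see [calciumParams()].
#' @param f0 baseline fluorescence (arbitrary units).
#' @param seed RNG seed for the noise.
#' @return data.frame with `time_s` and `intensity`.
#' @export
renderCalciumTrace <- function(events, params = calciumParams(), f0 = 100,
                               seed = 1) {
  tt <- seq(0, events$session_s - params$framePeriodS, by = params$framePeriodS)
  dff <- rep(0, length(tt))
  for (te in events$event_times_s) {
    on <- tt >= te
    dff[on] <- dff[on] + events$amplitude_dff * exp(-(tt[on] - te) / events$decay_tau_s)
  }
  noise <- withSeed(seed, rnorm(length(tt), 0, params$noiseSdDff * f0))
  data.frame(time_s = tt, intensity = pmax(0, f0 * (1 + dff) + noise))
}
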