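#' Perfusion ground-truth parameters
#'
#' The stated world of the tracer-arrival generator, per perfusion session
#' day (4, 6, 8 dpt), control condition:
#'
#' * `pAnaProx`, `pAnaDist`: probabilities that the proximal / distal stump
#'   is connected to an adjacent vein (0.9 / 0.8 at 4 dpt, 1.0 later).
#' * `dtBAFast`: the proximal intra-stump delay when an anastomosis exists;
#'   kept strictly inside the 1.3 s anastomosis criterion and declining
#'   with healing (0.7, 0.5, 0.3 s).
#' * `dtBASlow`: the slow capillary-backfill arrival of a non-anastomosed
#'   proximal stump — measurable within the extended 300-frame recording
#'   but beyond the 66.66 s perfusion window (mean 70 s).
#' * `dtDAVein`: delay of the distal-stump vein feed relative to ROI A; at
#'   4 dpt Gamma with mean 4.74 s and SD 6.62 s so that the wound-crossing
#'   delta-t among connected sessions reproduces the observed
#'   4.74 +- 6.62 s.
#' * `dtDCRetro`: magnitude of the retrograde delay C after D.
#' * `dtWound`: anterograde wound-crossing delay t(C) - t(B) once sprouts
#'   bridge the wound (mean 2 s at 6 dpt, 0 +- 0.05 s at 8 dpt).
#' * `dtCDAnte`: anterograde D after C delay once the wound path dominates.
#' * `bolus*`: lognormal circulation delay of the bolus to ROI A after the
#'   30-frame baseline.
#'
#' @return a named list of generator parameters.
#' @export
perfusionParams <- function() {
  list(
    pAnaProx = c(`4` = 0.9, `6` = 1.0, `8` = 1.0),
    pAnaDist = c(`4` = 0.8, `6` = 1.0, `8` = 1.0),
    dtBAFast = list(mean = c(`4` = 0.7, `6` = 0.5, `8` = 0.3),
                    sd = 0.15, range = c(0.05, 1.0)),
    dtBASlow = list(mean = 69, sd = 3, range = c(67, 120)),
    dtDAVein = list(mean = c(`4` = 4.74, `6` = 1.5, `8` = 0.8),
                    sd = c(`4` = 6.62, `6` = 1.5, `8` = 0.3)),
    dtDCRetro = list(mean = c(`4` = 0.7, `6` = 0.5, `8` = 0.3),
                     sd = 0.15, range = c(0.05, 1.0)),
    dtWound = list(mean = c(`4` = 4.74, `6` = 2.0, `8` = 0.0),
                   sd = c(`4` = 6.62, `6` = 2.0, `8` = 0.05)),
    dtCDAnte = list(mean = 0.3, sd = 0.1, range = c(0.05, 1.0)),
    bolusMeanlog = log(10), bolusSdlog = 0.3,
    framePeriodS = 2 / 3, nBaselineFrames = 30L,
    nFramesStd = 100L, nFramesExt = 300L,
    perfusionWindowS = 66.66
  )
}

rGammaMoments <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, scale = sd^2 / mean)
}

## Per-session wound-bridging indicator, consistent with the sprouting
## model: births Poisson, uniform birth times, lognormal tip speeds, and a
## sprout bridges once perfused and longer than the scene's wound gap.
simulateWoundConnection <- function(n, dpt, gapUm, birthRate = 1.5,
                                    elongation = 10.4, cv = 0.3,
                                    pPerfused = 2 / 3, onsetDpt = 3.5,
                                    treatment = treatmentSpec("control")) {
  rate <- birthRate * treatment$birthRateFactor
  tipSpeed <- tipSpeedFactor * elongation * treatment$elongationFactor
  k <- rpois(n, rate * max(0, dpt - onsetDpt))
  total <- sum(k)
  if (total == 0 || tipSpeed == 0) return(rep(FALSE, n))
  birth <- runif(total, onsetDpt, dpt)
  sdlog <- sqrt(log(1 + cv^2))
  speed <- rlnorm(total, log(tipSpeed) - sdlog^2 / 2, sdlog)
  spans <- speed * (dpt - birth) >= gapUm & rbinom(total, 1, pPerfused) == 1
  as.logical(tapply(spans, rep.int(seq_len(n), k), any)[as.character(seq_len(n))]) %in% TRUE
}

#' Simulate tracer-arrival ground truth for perfusion sessions
#'
#' Constructs per-session anastomosis states, wound connectivity and the
#' four ROI arrival times additively along the feeding paths.  ROI A is
#' reached by the bolus after the baseline; B follows A through the
#' proximal stump (fast if vein-anastomosed, slow backfill otherwise); the
#' distal stump is fed retrogradely through its own vein anastomosis
#' (D before C) and/or anterogradely across the wound through bridging
#' perfused sprouts (B before C before D); each compartment takes the
#' earliest feed.  Arrivals beyond the recording window are censored.
#'
#' @param scene a [VascularScene-class] (supplies the wound gap).
#' @param sprouts optional sprouts data.frame with perfusion assigned; if
#'   given, wound connectivity is derived from it, otherwise it is
#'   simulated per session from the sprouting model.
#' @param dpt perfusion session day; must be 4, 6 or 8.
#' @param n number of independent sessions to draw.
#' @param params generator parameters, see [perfusionParams()].
#' @param treatment a [treatmentSpec()].
#' @param pPerfused sprout perfusion probability (wound-bridging model).
#' @param seed integer RNG seed.
#' @return data.frame with one row per session: anastomosis and
#'   connectivity booleans, arrival times `t_A`..`t_D` (s, `NA` =
#'   censored), `flow_direction_distal`, `n_frames` and `window_s`.
#' @examples
#' sc <- makeScene(1)
#' simulatePerfusionTruth(sc, dpt = 8, n = 3, seed = 7)
#' @export
simulatePerfusionTruth <- function(scene, sprouts = NULL, dpt, n = 1,
                                   params = perfusionParams(),
                                   treatment = treatmentSpec("control"),
                                   pPerfused = 2 / 3, seed = 1) {
  if (!dpt %in% c(4, 6, 8))
    stop("domain error: perfusion sessions exist only at 4, 6 or 8 dpt")
  key <- as.character(dpt)
  anaFac <- treatment$anastomosisFactor(dpt)
  withSeed(seed, {
    anaProx <- rbinom(n, 1, min(1, params$pAnaProx[key] * anaFac)) == 1
    anaDist <- rbinom(n, 1, min(1, params$pAnaDist[key] * anaFac)) == 1
    wound <- if (!is.null(sprouts)) {
      rep(any(sprouts$perfused %in% TRUE &
                lengthAt(sprouts, dpt) >= scene@woundGapUm), n)
    } else {
      simulateWoundConnection(n, dpt, scene@woundGapUm,
                              pPerfused = pPerfused, treatment = treatment)
    }

    baselineS <- params$nBaselineFrames * params$framePeriodS
    tA <- baselineS + rlnorm(n, params$bolusMeanlog, params$bolusSdlog)

    fast <- params$dtBAFast
    slow <- params$dtBASlow
    dtBA <- ifelse(anaProx,
                   rtruncnorm(n, fast$mean[key], fast$sd, fast$range[1], fast$range[2]),
                   rtruncnorm(n, slow$mean, slow$sd, slow$range[1], slow$range[2]))
    tB <- tA + dtBA

    vein <- params$dtDAVein
    tDvein <- ifelse(anaDist,
                     tA + rGammaMoments(n, vein$mean[key], vein$sd[key]),
                     Inf)
    retro <- params$dtDCRetro
    tCretro <- tDvein + rtruncnorm(n, retro$mean[key], retro$sd,
                                   retro$range[1], retro$range[2])
    wnd <- params$dtWound
    tCwound <- ifelse(wound, tB + rnorm(n, wnd$mean[key], wnd$sd[key]), Inf)
    tC <- pmin(tCretro, tCwound)
    ante <- params$dtCDAnte
    tD <- pmin(tDvein, tC + rtruncnorm(n, ante$mean, ante$sd,
                                       ante$range[1], ante$range[2]))

    ## recording extends to 300 frames when the standard 100 do not capture
    ## all reachable compartments, as in the emulated protocol
    stdS <- params$nFramesStd * params$framePeriodS
    extS <- params$nFramesExt * params$framePeriodS
    reach <- cbind(tA, tB, tC, tD)
    needExt <- apply(reach, 1, function(r) any(is.finite(r) & r > stdS))
    nFrames <- ifelse(needExt, params$nFramesExt, params$nFramesStd)
    windowS <- ifelse(needExt, extS, stdS)
    censor <- function(t) ifelse(is.finite(t) & t <= windowS, t, NA_real_)

    data.frame(
      dpt = dpt,
      anastomosis_proximal = anaProx,
      anastomosis_distal = anaDist,
      wound_connected = wound,
      t_A = censor(tA), t_B = censor(tB), t_C = censor(tC), t_D = censor(tD),
      flow_direction_distal = ifelse(!is.finite(tC) & !is.finite(tD), NA_character_,
                                     ifelse(tD < tC, "retrograde", "anterograde")),
      n_frames = as.integer(nFrames),
      window_s = windowS,
      stringsAsFactors = FALSE)
  })
}
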