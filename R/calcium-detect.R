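#' Compute a dF/F series from a raw fluorescence trace
#'
#' The baseline F0 is a running percentile (default 20th) over a sliding
#' window (default 60 s), which tracks slow drift while ignoring sparse
#' transients; F0 is floored at `eps` to keep the ratio stable.
#'
#' @param trace numeric fluorescence vector, or data.frame with an
#'   `intensity` column.
#' @param framePeriodS seconds per frame.
#' @param baselinePercentile percentile (0-100) defining F0.
#' @param windowS sliding window length (s).
#' @param eps floor for F0.
#' @return numeric dF/F series of the same length.
#' @export
computeDff <- function(trace, framePeriodS = 2 / 3, baselinePercentile = 20,
                       windowS = 60, eps = 1e-6) {
  if (is.data.frame(trace)) trace <- trace$intensity
  n <- length(trace)
  stopIfNot(n >= 100, "trace must have at least 100 frames")
  if (all(trace == 0)) stop("all-zero trace: no fluorescence to normalise")
  half <- max(1L, round(windowS / framePeriodS / 2))
  q <- baselinePercentile / 100
  ## running percentile over a centred window; quantile type 7
  f0 <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    quantile(trace[lo:hi], q, names = FALSE)
  }, 0)
  f0 <- pmax(f0, eps)
  (trace - f0) / f0
}

#' Detect Ca2+ transients in a dF/F series
#'
#' Events are maximal runs of dF/F at or above `kSd` robust SDs (median
#' absolute deviation of the series) lasting at least `minDurationS`;
#' runs separated by gaps shorter than `mergeGapS` are merged first.
#'
#' @param dff numeric dF/F series.
#' @param framePeriodS seconds per frame.
#' @param kSd threshold in robust SDs (default 3).
#' @param minDurationS minimum event duration (s, default 2).
#' @param mergeGapS sub-threshold gap below which runs merge (s, default 1).
#' @return data.frame of events: `onset_s`, `peak_s`, `peak_dff`,
#'   `duration_s`.
#' @export
detectTransients <- function(dff, framePeriodS = 2 / 3, kSd = 3,
                             minDurationS = 2, mergeGapS = 1) {
  sdRob <- max(mad(dff, center = median(dff)), 1e-9)
  thr <- median(dff) + kSd * sdRob
  above <- dff >= thr
  if (!any(above)) return(emptyTransients())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ## merge runs separated by short gaps
  gapFrames <- mergeGapS / framePeriodS
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - merged$end[nrow(merged)] - 1L < gapFrames)
      merged$end[nrow(merged)] <- runs$end[i]
    else merged <- rbind(merged, runs[i, ])
  }
  dur <- (merged$end - merged$start + 1L) * framePeriodS
  keep <- dur >= minDurationS
  if (!any(keep)) return(emptyTransients())
  merged <- merged[keep, , drop = FALSE]
  peakIdx <- mapply(function(s, e) s + which.max(dff[s:e]) - 1L,
                    merged$start, merged$end)
  data.frame(onset_s = (merged$start - 1) * framePeriodS,
             peak_s = (peakIdx - 1) * framePeriodS,
             peak_dff = dff[peakIdx],
             duration_s = dur[keep])
}

emptyTransients <- function() {
  data.frame(onset_s = numeric(), peak_s = numeric(), peak_dff = numeric(),
             duration_s = numeric())
}

#' Tally transient counts per animal, session and side
#'
#' @param events data.frame with columns `animal_id`, `dpt`, `region` and
#'   one row per detected event (zero-event sessions are supplied through
#'   `sessions`).
#' @param sessions data.frame of all (animal_id, dpt) sessions recorded,
#'   so that event-free sessions appear with count 0.
#' @return data.frame (`animal_id`, `dpt`, `region`, `n_transients`).
#' @export
countBySide <- function(events, sessions) {
  grid <- merge(sessions, data.frame(region = c("proximal", "distal")))
  if (nrow(events)) {
    agg <- aggregate(list(n_transients = events$region),
                     by = events[c("animal_id", "dpt", "region")], FUN = length)
  } else {
    agg <- data.frame(animal_id = character(), dpt = numeric(),
                      region = character(), n_transients = integer())
  }
  out <- merge(grid, agg, by = c("animal_id", "dpt", "region"), all.x = TRUE)
  out$n_transients[is.na(out$n_transients)] <- 0L
  out[order(out$animal_id, out$dpt, out$region), , drop = FALSE]
}
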