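fp <- 2 / 3

test_that("dF/F normalisation handles constants, plateaus and drift", {
  expect_true(all(computeDff(rep(80, 300), fp) == 0))
  ## short plateau at 1.5 x baseline reads as dF/F = 0.5
  tr <- rep(100, 400); tr[200:229] <- 150
  dff <- computeDff(tr, fp)
  expect_lt(max(abs(dff[210:220] - 0.5)), 1e-6)
  ## slow linear drift stays below the detection threshold
  drift <- 100 + seq(0, 10, length.out = 1980) + rnorm(1980, 0, 0.5)
  set.seed(8)
  expect_equal(nrow(detectTransients(computeDff(drift, fp), fp)), 0)
  expect_error(computeDff(rep(0, 300), fp), "all-zero")
  expect_error(computeDff(rep(1, 50), fp), "100 frames")
})

test_that("transients are recovered with correct onsets on clean traces", {
  ev <- structure(list(event_times_s = c(100, 400, 700, 1000, 1200),
                       amplitude_dff = 0.5, decay_tau_s = 5, region = "distal",
                       dpt = 5, session_s = 1320), class = "CalciumEventTrain")
  tr <- renderCalciumTrace(ev, calciumParams(noiseSdDff = 1e-4), seed = 1)
  det <- detectTransients(computeDff(tr$intensity, fp), fp)
  expect_equal(nrow(det), 5)
  expect_true(all(abs(det$onset_s - ev$event_times_s) <= 1))
})

test_that("short events are rejected and detection is monotone in thresholds", {
  ev <- structure(list(event_times_s = c(300, 800), amplitude_dff = 0.5,
                       decay_tau_s = 5, region = "distal", dpt = 5,
                       session_s = 1320), class = "CalciumEventTrain")
  tr <- renderCalciumTrace(ev, seed = 3)
  dff <- computeDff(tr$intensity, fp)
  n3 <- nrow(detectTransients(dff, fp, kSd = 3))
  ## a 1 s suprathreshold blip is rejected by the 2 s duration filter
  blip <- dff; blip[900] <- 1.0
  expect_equal(nrow(detectTransients(blip, fp, kSd = 3, minDurationS = 2)), n3)
  for (ks in c(4, 6, 10))
    expect_lte(nrow(detectTransients(dff, fp, kSd = ks)), n3)
  for (md in c(4, 8, 20))
    expect_lte(nrow(detectTransients(dff, fp, minDurationS = md)), n3)
})

test_that("recall and false-positive rates meet the stated targets", {
  ## amplitude 0.5 at noise SD 0.05 (10 x): recall >= 0.95 over 100 sessions
  nTrue <- 0; nDet <- 0
  for (k in 1:100) {
    ev <- simulateCalciumEvents(5.0, "distal", seed = 100 + k)
    tr <- renderCalciumTrace(ev, seed = 4000 + k)
    det <- detectTransients(computeDff(tr$intensity, fp), fp)
    nTrue <- nTrue + length(ev$event_times_s)
    nDet <- nDet + min(nrow(det), length(ev$event_times_s))
  }
  expect_gte(nDet / nTrue, 0.95)
  ## false positives on event-free traces: <= 0.05 events per session
  fps <- vapply(1:100, function(k) {
    ev <- structure(list(event_times_s = numeric(), amplitude_dff = 0.5,
                         decay_tau_s = 5, region = "proximal", dpt = 5,
                         session_s = 1320), class = "CalciumEventTrain")
    tr <- renderCalciumTrace(ev, seed = 6000 + k)
    nrow(detectTransients(computeDff(tr$intensity, fp), fp))
  }, 0L)
  expect_lte(mean(fps), 0.05)
})

test_that("side tallies cover every session and peak near 5 dpt", {
  sessions <- expand.grid(animal_id = c("a1", "a2"), dpt = seq(3.5, 6.5, 0.5),
                          stringsAsFactors = FALSE)
  ev <- data.frame(animal_id = "a1", dpt = 5.0, region = "distal")
  tab <- countBySide(ev[rep(1, 4), ], sessions)
  expect_equal(nrow(tab), nrow(sessions) * 2)
  expect_equal(tab$n_transients[tab$animal_id == "a1" & tab$dpt == 5 &
                                  tab$region == "distal"], 4)
  expect_true(all(tab$n_transients[tab$animal_id == "a2"] == 0))
  ## generator counts through the tally peak at the profile maximum
  coh <- simulateCohort(groups = c(control = 8), seed = 5,
                        perfusionSessions = numeric(0))
  ca <- cohortMetric(coh$table, "ca_transients", side = "distal")
  m <- tapply(ca$value, ca$dpt, mean)
  expect_equal(as.numeric(names(which.max(m))), 5.0, tolerance = 0.51)
})
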