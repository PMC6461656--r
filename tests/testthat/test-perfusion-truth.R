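sc <- fixtureScene(1)

test_that("perfusion sessions exist only at 4, 6 and 8 dpt", {
  expect_error(simulatePerfusionTruth(sc, dpt = 5, seed = 1), "domain error")
})

test_that("anastomosis prevalence matches the stated probabilities", {
  ## brute-force Bernoulli means at 4 dpt: 0.90 proximal, 0.80 distal
  tr <- simulatePerfusionTruth(sc, dpt = 4, n = 10000, seed = 17)
  expect_lt(abs(mean(tr$anastomosis_proximal) - 0.90), 0.01)
  expect_lt(abs(mean(tr$anastomosis_distal) - 0.80), 0.015)
})

test_that("censoring is structurally consistent with connectivity", {
  tr <- simulatePerfusionTruth(sc, dpt = 4, n = 3000, seed = 5)
  ## A is always reached by the bolus
  expect_true(all(!is.na(tr$t_A)))
  ## unreachable distal compartment: no distal anastomosis and no wound path
  dead <- !tr$anastomosis_distal & !tr$wound_connected
  expect_true(all(is.na(tr$t_C[dead])))
  expect_true(all(is.na(tr$t_D[dead])))
  ## reachable distal compartment carries numeric times
  live <- tr$anastomosis_distal
  expect_true(all(!is.na(tr$t_C[live]) | tr$t_C[live] > tr$window_s[live],
                  na.rm = TRUE))
  ## retrograde feed means D fills before C
  retro <- which(tr$flow_direction_distal == "retrograde")
  expect_true(all(tr$t_D[retro] < tr$t_C[retro], na.rm = TRUE))
})

test_that("wound transit times reproduce the stated healing trajectory", {
  tr4 <- simulatePerfusionTruth(sc, dpt = 4, n = 4000, seed = 7)
  perf <- !is.na(tr4$t_B) & !is.na(tr4$t_C) &
    (tr4$t_B - tr4$t_A) < 66.66 & (tr4$t_C - tr4$t_B) < 66.66
  dtcb <- (tr4$t_C - tr4$t_B)[perf]
  expect_lt(abs(mean(dtcb) - 4.74), 2 * sd(dtcb) / sqrt(length(dtcb)) + 0.1)
  expect_lt(abs(sd(dtcb) - 6.62), 1.0)
  ## no wound crossing at 4 dpt: sprouts are far too short
  expect_lt(mean(tr4$wound_connected), 0.01)
  tr8 <- simulatePerfusionTruth(sc, dpt = 8, n = 4000, seed = 8)
  expect_gt(mean(tr8$wound_connected), 0.85)
  expect_lt(abs(mean(tr8$t_C - tr8$t_B, na.rm = TRUE)), 0.15)
})

test_that("removing a feed path never makes a downstream arrival earlier", {
  ## path consistency: compartments take the earliest feed, so forcing the
  ## distal anastomosis away (treatment factor 0) can only delay or censor
  ## C and D relative to the wound-fed construction
  noAna <- treatmentSpec("combo", anastomosisFactor = function(dpt) 0 * dpt)
  tr <- simulatePerfusionTruth(sc, dpt = 4, n = 500, seed = 9,
                               treatment = noAna)
  expect_true(all(!tr$anastomosis_proximal & !tr$anastomosis_distal))
  expect_true(all(is.na(tr$t_C) & is.na(tr$t_D)))   # nothing feeds distal at 4 dpt
  expect_true(all(!is.na(tr$t_B)))                  # slow backfill, uncensored
  expect_true(all(tr$t_B - tr$t_A > 66.66))
})

test_that("sprout-derived wound connectivity uses perfused spanning sprouts", {
  sp <- manualSprouts(sc, lengthsUm = 50, dpt = 8, perfused = TRUE)
  tr <- simulatePerfusionTruth(sc, sprouts = sp, dpt = 8, n = 50, seed = 2)
  expect_true(all(tr$wound_connected))
  spShort <- manualSprouts(sc, lengthsUm = 10, dpt = 8, perfused = TRUE)
  tr2 <- simulatePerfusionTruth(sc, sprouts = spShort, dpt = 8, n = 50, seed = 2)
  expect_true(!any(tr2$wound_connected))
  spUnperf <- manualSprouts(sc, lengthsUm = 50, dpt = 8, perfused = FALSE)
  tr3 <- simulatePerfusionTruth(sc, sprouts = spUnperf, dpt = 8, n = 50, seed = 2)
  expect_true(!any(tr3$wound_connected))
})
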