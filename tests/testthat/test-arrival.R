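fp <- 2 / 3

test_that("arrival is the interpolated sustained threshold crossing", {
  ## oracle: closed-form crossing of a step trace under the stated rule
  base <- rep(c(99, 101), 15)                # mean 100, sd ~1.02
  trace <- c(base, rep(100, 9), rep(200, 21))
  m <- mean(trace[1:30]); s <- sd(trace[1:30])
  thr <- m + 3 * s
  f <- 40                                     # first frame at 200 (1-based)
  expected <- (f - 2 + (thr - trace[f - 1]) / (trace[f] - trace[f - 1])) * fp
  expect_equal(detectArrival(trace, framePeriodS = fp), expected)
})

test_that("flat traces censor and single-frame spikes are ignored", {
  expect_true(is.na(detectArrival(rep(100, 120), framePeriodS = fp)))
  spike <- rep(100, 120); spike[50] <- 500
  expect_true(is.na(detectArrival(spike, framePeriodS = fp)))
  ## flat baseline with zero SD falls back to the absolute floor
  stepped <- c(rep(100, 40), rep(200, 20))
  expect_false(is.na(detectArrival(stepped, framePeriodS = fp)))
  expect_error(detectArrival(rep(1, 10), nBaseline = 30), "shorter")
})

test_that("raising the detection threshold never advances the arrival", {
  set.seed(21)
  for (k in 1:15) {
    tr <- 100 + rnorm(150, 0, 5) + 300 / (1 + exp(-((1:150) - 70) / 2))
    det <- vapply(c(2, 3, 4, 6), function(ks)
      detectArrival(tr, framePeriodS = fp, kSd = ks), 0)
    det <- det[!is.na(det)]
    expect_true(all(diff(det) >= 0))
  }
})

test_that("delta-t metrics, censor propagation and the 66.66 s rule", {
  m <- computeMetrics(c(A = 10.0, B = 10.5, C = 12.0, D = 11.0))
  expect_equal(deltaT(m), c(dtBA = 0.5, dtCB = 1.5, dtDC = -1.0, integral = 3.0))
  expect_true(all(perfusedFlags(m)))
  expect_true(anastomosisFlags(m)["proximal"])
  expect_true(anastomosisFlags(m)["distal"])   # retrograde but fast
  mc <- computeMetrics(c(A = 10, B = 10.5, C = NA, D = NA))
  expect_true(is.na(mc@dtCB) && is.na(mc@dtDC) && is.na(mc@integralDt))
  expect_false(perfusedFlags(mc)["wound"])
  expect_false(perfusedFlags(mc)["distal"])
  expect_true(perfusedFlags(mc)["proximal"])
  ## slow arrival: uncensored but beyond the perfusion window
  ms <- computeMetrics(c(A = 10, B = 80, C = NA, D = NA))
  expect_false(perfusedFlags(ms)["proximal"])
  expect_false(anastomosisFlags(ms)["proximal"])
})

test_that("anastomosis classification uses a strict absolute threshold", {
  expect_true(classifyAnastomosis(c(dtBA = 0.5, dtDC = NA))["proximal"])
  expect_true(classifyAnastomosis(c(dtBA = NA, dtDC = -1.0))["distal"])
  expect_false(classifyAnastomosis(c(dtBA = 1.3, dtDC = NA))["proximal"])
  expect_false(classifyAnastomosis(c(dtBA = -1.3, dtDC = 1.31))["distal"])
  expect_false(classifyAnastomosis(c(dtBA = NA, dtDC = NA))["proximal"])
})

test_that("the integral flow measure is invariant to a global time shift", {
  for (shift in c(-5, 0, 12.3)) {
    m0 <- computeMetrics(c(A = 20, B = 20.7, C = 26, D = 25.4))
    ms <- computeMetrics(c(A = 20, B = 20.7, C = 26, D = 25.4) + shift)
    expect_equal(ms@integralDt, m0@integralDt)
  }
})

test_that("arrival recovery stays within one frame across SNR levels", {
  sc <- fixtureScene(1)
  tr <- simulatePerfusionTruth(sc, dpt = 6, n = 40, seed = 13)
  errs <- unlist(lapply(c(5, 10, 20), function(snr)
    lapply(seq_len(nrow(tr)), function(k) {
      row <- tr[k, , drop = FALSE]
      tt <- renderRoiTraces(row, snr = snr, seed = 7000 + k)
      det <- vapply(c("A", "B", "C", "D"), function(r)
        detectArrival(tt[[paste0("roi_", r)]], framePeriodS = fp), 0)
      (det - c(row$t_A, row$t_B, row$t_C, row$t_D))
    })))
  errs <- errs[!is.na(errs)]
  expect_gte(mean(abs(errs) <= fp), 0.98)
  expect_lt(abs(mean(errs)), fp)
})

test_that("perfused-sprout counting applies the closed coverage boundary", {
  red <- matrix(100, 60, 60)
  paths <- list(cbind(10, 10:19), cbind(30, 10:19))
  expect_equal(unname(countPerfusedSprouts(paths, red)), c(0L, 2L))
  expect_equal(unname(countPerfusedSprouts(list(), red)), c(0L, 0L))
  ## half-filled sprout exactly at the 0.5 boundary counts as perfused
  set.seed(2)
  noisy <- matrix(rnorm(3600, 100, 2), 60, 60)
  noisy[31, 11:15] <- 1000                   # 5 of 10 path pixels bright
  cnt <- countPerfusedSprouts(list(cbind(30, 10:19)), noisy,
                              snrThreshold = 3, coverageFraction = 0.5)
  expect_equal(unname(cnt["n_perfused"]), 1L)
})

test_that("end-to-end anastomosis classification matches ground truth", {
  sc <- fixtureScene(1)
  coh <- list(perfusion = simulatePerfusionTruth(sc, dpt = 4, n = 250, seed = 19))
  coh$perfusion$animal_id <- sprintf("a%03d", seq_len(250))
  coh$perfusion$group <- "control"
  class(coh) <- "SyntheticCohort"
  q <- quantifyPerfusion(coh, seed = 5)
  expect_gte(mean(q$ana_prox == q$true_ana_prox), 0.95)
  expect_gte(mean(q$ana_dist == q$true_ana_dist), 0.95)
})
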