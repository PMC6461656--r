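test_that("Holm step-down matches the hand oracle and stats::p.adjust", {
  expect_equal(holmAdjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  ## brute-force oracle: direct definition, independent of the implementation
  holmOracle <- function(p) {
    m <- length(p); o <- order(p); out <- numeric(m); run <- 0
    for (i in seq_len(m)) {
      run <- max(run, min(1, (m - i + 1) * p[o[i]]))
      out[o[i]] <- run
    }
    out
  }
  set.seed(11)
  for (k in 1:25) {
    p <- runif(sample(1:8, 1))
    expect_equal(holmAdjust(p), holmOracle(p))
    expect_equal(holmAdjust(p), p.adjust(p, "holm"))
    expect_true(all(holmAdjust(p) >= p))
  }
  expect_error(holmAdjust(c(0.5, 1.2)), "p-values")
})

test_that("Fisher's exact test agrees with hypergeometric enumeration", {
  tab <- matrix(c(9, 2, 1, 5), 2)             # [[9,1],[2,5]]
  res <- fisherPerfusionTest(tab)
  ## oracle: two-sided p by enumerating all tables with the same margins
  m <- 11; n <- 6; k <- 10
  probs <- dhyper(0:min(m, k), m, n, k)
  pObs <- dhyper(9, m, n, k)
  pEnum <- sum(probs[probs <= pObs + 1e-12])
  expect_equal(res$p_value, pEnum, tolerance = 1e-10)
  expect_equal(res$p_value, 0.0345, tolerance = 1e-3)
  empty <- matrix(c(0, 0, 3, 4), 2)
  resE <- fisherPerfusionTest(empty)
  expect_equal(resE$p_value, 1)
  expect_false(is.na(resE$flag))
})

test_that("rank tests reproduce exact small-sample results", {
  mw <- mannWhitneyTest(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(mw$U), 0)
  expect_equal(mw$p_value, 0.1)               # 2 / C(6,3)
  eq <- wilcoxonSideTest(c(2, 2, 2), c(2, 2, 2))
  expect_true(is.na(eq$p_value))
  expect_false(is.na(eq$flag))
  ws <- wilcoxonSideTest(c(0, 1, 0, 2, 1, 0), c(5, 6, 4, 7, 6, 5))
  expect_lt(ws$p_value, 0.05)
})

test_that("Poisson GLMM degenerates and scales as the count law demands", {
  d0 <- data.frame(animal_id = rep(letters[1:5], each = 4),
                   dpt = rep(4:7, 5), count = 0L)
  expect_error(fitPoissonGlmm(d0), "degenerate")
  dc <- d0; dc$count <- 3L
  f <- fitPoissonGlmm(dc)
  expect_lt(abs(slopeOf(f, "count_slope")["estimate"]), 0.05)
  expect_gt(slopeOf(f, "log_dpt")["p"], 0.5)
  ## doubling the birth rate doubles the recovered count slope
  mk <- function(rate, seed) {
    coh <- simulateCohort(groups = c(control = 10), seed = seed,
                          perfusionSessions = numeric(0),
                          params = list(birthRate = rate))
    x <- cohortMetric(coh$table, "sprout_count", side = "distal")
    names(x)[names(x) == "value"] <- "count"
    slopeOf(fitPoissonGlmm(x), "count_slope")
  }
  s1 <- mk(1.5, 101); s2 <- mk(3.0, 102)
  expect_lt(abs(s2["estimate"] / s1["estimate"] - 2),
            2 * (s2["se"] / s1["estimate"] +
                   s2["estimate"] * s1["se"] / s1["estimate"]^2))
})

test_that("the length LMM is exact on noise-free data and guards small n", {
  d <- expand.grid(animal_id = letters[1:6], dpt = seq(4, 6.5, 0.5))
  d$mean_length <- 5 * d$dpt
  f <- fitLmm(d)
  expect_equal(unname(slopeOf(f, "dpt")["estimate"]), 5, tolerance = 1e-6)
  expect_lt(slopeOf(f, "dpt")["se"], 1e-3)
  expect_error(fitLmm(d[d$animal_id %in% c("a", "b"), ]), "3 animals")
  ## permuting session labels destroys the slope
  coh <- simulateCohort(groups = c(control = 6), seed = 55,
                        perfusionSessions = numeric(0))
  lens <- cohortMetric(coh$table, "mean_length_um", side = "distal")
  names(lens)[names(lens) == "value"] <- "mean_length"
  set.seed(9)
  ps <- vapply(1:12, function(k) {
    perm <- lens
    perm$dpt <- ave(perm$dpt, perm$animal_id, FUN = sample)
    slopeOf(fitLmm(perm), "dpt")["p"]
  }, 0)
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("interaction model recovers slopes, omnibus and Holm post-hocs", {
  sc <- fixtureScene(1)
  rows <- do.call(rbind, lapply(c(4, 6, 8), function(d)
    simulatePerfusionTruth(sc, dpt = d, n = 12, seed = 70 + d)))
  rows$animal_id <- rep(sprintf("m%02d", 1:12), 3)
  rows$integral <- abs(rows$t_B - rows$t_A) + abs(rows$t_C - rows$t_B) +
    abs(rows$t_D - rows$t_C)
  d1 <- data.frame(animal_id = rows$animal_id, group = "control",
                   dpt = rows$dpt, value = rows$integral)
  f1 <- fitMlmrInteraction(d1)
  s <- slopeOf(f1, "slope_control")
  expect_lt(s["estimate"], 0)                # perfusion improves with healing
  expect_lt(s["p"], 0.05)
  ## null calibration: identical generating process in every group, the
  ## interaction omnibus rejects at about the nominal rate over replicates
  set.seed(31)
  rej <- vapply(1:20, function(r) {
    dn <- expand.grid(animal_id = sprintf("n%02d", 1:18), dpt = c(4, 6, 8),
                      stringsAsFactors = FALSE)
    dn$group <- setNames(rep(c("control", "shamA", "shamB"), each = 6),
                         sprintf("n%02d", 1:18))[dn$animal_id]
    dn$value <- 5 - 0.5 * dn$dpt + rnorm(nrow(dn)) +
      rep(rnorm(18, 0, 0.5), 3)[match(dn$animal_id, sprintf("n%02d", 1:18))]
    fitMlmrInteraction(dn)@omnibus["p"] < 0.05
  }, TRUE)
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 20))
  f2 <- fitMlmrInteraction(d1[sample(nrow(d1)), ])
  expect_true(all(f2@posthoc$p_holm >= f2@posthoc$p | is.na(f2@posthoc$p)))
  ## groups with < 2 animals are dropped with a warning
  d3 <- rbind(d1, data.frame(animal_id = "solo", group = "tiny",
                             dpt = c(4, 6, 8), value = c(1, 1, 1)))
  expect_warning(fitMlmrInteraction(d3), "dropping group")
})

test_that("through-origin regression reads off the perfused fraction", {
  d <- data.frame(animal_id = letters[1:8], perfused = c(3, 5, 2, 7, 4, 6, 1, 8),
                  total = c(3, 5, 2, 7, 4, 6, 1, 8))
  f <- fitPerfusedRatio(d)
  expect_equal(unname(slopeOf(f, "total")["estimate"]), 1, tolerance = 1e-8)
  ## invariant to animal relabeling
  d2 <- d; d2$animal_id <- rev(d2$animal_id)
  expect_equal(modelCoef(fitPerfusedRatio(d2))$estimate,
               modelCoef(f)$estimate, tolerance = 1e-8)
  expect_error(fitPerfusedRatio(data.frame(animal_id = "a", perfused = 0,
                                           total = 0)), "degenerate")
  expect_error(fitPerfusedRatio(data.frame(animal_id = "a", perfused = 2,
                                           total = 1)), "exceed")
})

test_that("recovered perfused fraction is unbiased across cohorts", {
  ## estimator check at ground-truth level over pooled cohorts
  est <- vapply(1:12, function(ms) {
    coh <- simulateCohort(groups = c(control = 6), seed = 400 + ms,
                          structuralSessions = c(4), perfusionSessions = c(8))
    tp <- cohortMetric(coh$table, "n_perfused_true")
    tt <- cohortMetric(coh$table, "n_sprouts_true")
    d <- data.frame(animal_id = tp$animal_id, perfused = tp$value,
                    total = tt$value)
    modelCoef(fitPerfusedRatio(d))$estimate
  }, 0)
  expect_lt(abs(mean(est) - 2 / 3), 3 * sd(est) / sqrt(length(est)))
})

test_that("Poisson-GLMM interval coverage is close to nominal", {
  ## 90% intervals on the count-scale slope across simulated cohorts
  hits <- vapply(1:100, function(ms) {
    coh <- simulateCohort(groups = c(control = 10), seed = 1200 + ms,
                          perfusionSessions = numeric(0))
    x <- cohortMetric(coh$table, "sprout_count", side = "distal")
    names(x)[names(x) == "value"] <- "count"
    s <- slopeOf(fitPoissonGlmm(x), "count_slope")
    z <- qnorm(0.95)
    s["estimate"] - z * s["se"] <= 1.5 && 1.5 <= s["estimate"] + z * s["se"]
  }, TRUE)
  expect_gte(mean(hits), 0.84)
  expect_lte(mean(hits), 0.96)
})
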