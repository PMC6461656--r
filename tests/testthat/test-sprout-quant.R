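test_that("Otsu segmentation is scale invariant and safe on blank input", {
  sc <- fixtureScene(3)
  ser <- renderFixture(sc, manualSprouts(sc, c(40, 60)), seed = 2)
  img <- apply(maxProject(ser, "green"), c(2, 3), max)
  m1 <- segmentVessels(img)
  m2 <- segmentVessels(2 * img)
  expect_identical(m1, m2)
  set.seed(4)
  noise <- matrix(abs(rnorm(128^2, 50, 5)), 128)
  expect_warning(mnoise <- segmentVessels(noise), "empty mask")
  expect_true(!any(mnoise))
})

test_that("segmentation covers the artery centerlines", {
  sc <- fixtureScene(3)
  ser <- renderFixture(sc, manualSprouts(sc, c(40, 60)), seed = 2)
  mask <- segmentVessels(ser)
  ps <- pixelSize(ser)
  cover <- unlist(lapply(c(stumps(sc, "proximal"), stumps(sc, "distal")),
                         function(s) {
    px <- angioQuant:::densifyPolyline(s$path, ps)
    idx <- cbind(pmin(pmax(round(px[, 2] / ps + 0.5), 1), nrow(mask)),
                 pmin(pmax(round(px[, 1] / ps + 0.5), 1), ncol(mask)))
    mask[idx]
  }))
  expect_gte(mean(cover), 0.95)
})

test_that("well-separated sprouts are each detected with the right side", {
  sc <- fixtureScene(3)
  lens <- c(25, 40, 55, 80)
  sp <- manualSprouts(sc, lens)
  ser <- renderFixture(sc, sp, seed = 2)
  det <- detectSprouts(segmentVessels(ser), placeRois(sc, res = 256),
                       minLengthUm = 10)
  expect_equal(nrow(det), length(lens))
  expect_true(all(det$side == "distal"))
  ## measured length within ~2 pixels' worth of the truth
  ps <- pixelSize(ser)
  expect_setequalish(det$length_um, lens, tol = 2 * ps)
})

test_that("skeleton paths start at the wall and end at the tip", {
  sc <- fixtureScene(3)
  sp <- manualSprouts(sc, c(50))
  ser <- renderFixture(sc, sp, seed = 2)
  rs <- placeRois(sc, res = 256)
  det <- detectSprouts(segmentVessels(ser), rs, minLengthUm = 10)
  path <- det$skeleton_path[[1]]
  band <- which(rowSums(regionMasks(rs)$wound) > 0)
  ## entry near the distal wound edge, tip deeper inside the band
  expect_lt(abs(path[1, "row"] - (max(band) - 1)), 4)
  expect_lt(path[nrow(path), "row"], path[1, "row"])
  expect_equal(unname(path[nrow(path), ]), c(det$tip_row[1], det$tip_col[1]))
})

test_that("the minimum-length filter is monotone and excludes short branches", {
  sc <- fixtureScene(3)
  sp <- manualSprouts(sc, c(8, 25, 40))     # 8 um is below the default floor
  ser <- renderFixture(sc, sp, seed = 2)
  mask <- segmentVessels(ser)
  rs <- placeRois(sc, res = 256)
  det10 <- detectSprouts(mask, rs, minLengthUm = 10)
  expect_equal(nrow(det10), 2)
  counts <- vapply(c(5, 10, 30, 50, 90), function(ml)
    nrow(detectSprouts(mask, rs, minLengthUm = ml)), 0L)
  expect_true(all(diff(counts) <= 0))
  ## a mask without wound-band branches yields zero sprouts
  bare <- segmentVessels(renderFixture(sc, manualSprouts(sc, numeric(0)),
                                       seed = 2))
  expect_equal(nrow(detectSprouts(bare, rs)), 0)
})

test_that("length measurement follows the Euclidean pixel metric", {
  horiz <- cbind(rep(5, 10), 0:9)
  expect_equal(measureLength(horiz, 3.90625), 9 * 3.90625)
  diag2 <- rbind(c(0, 0), c(1, 1))
  expect_equal(measureLength(diag2, 1), sqrt(2))
  expect_warning(l0 <- measureLength(matrix(c(3, 3), 1), 2), "zero length")
  expect_equal(l0, 0)
})

test_that("sprout summaries keep zero-count sessions distinct from zero length", {
  m <- data.frame(side = c("distal", "distal", "distal"),
                  length_um = c(10, 20, 30))
  s <- summarizeSprouts(m, "a1", 5.0)
  expect_equal(s$value[s$metric == "sprout_count" & s$side == "distal"], 3)
  expect_equal(s$value[s$metric == "mean_length_um" & s$side == "distal"], 20)
  s0 <- summarizeSprouts(m[0, ], "a1", 3.5)
  expect_equal(s0$value[s0$metric == "sprout_count" & s0$side == "distal"], 0)
  expect_true(is.na(s0$value[s0$metric == "mean_length_um" & s0$side == "distal"]))
})

test_that("no proximal sprouts are ever measured on default cohorts", {
  coh <- simulateCohort(groups = c(control = 4), seed = 31,
                        perfusionSessions = numeric(0))
  prox <- cohortMetric(coh$table, "sprout_count", side = "proximal")
  expect_true(all(prox$value == 0))
})
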