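test_that("TIFF series round-trips losslessly with its metadata", {
  sc <- fixtureScene(1)
  tr <- simulatePerfusionTruth(sc, dpt = 8, n = 1, seed = 3)
  ser <- renderSeries(sc, truth = tr, mode = "perfusion", res = 128,
                      nFrames = 35, seed = 4)
  ## integer-valued copy for the lossless guarantee
  ser@green <- round(ser@green); ser@red <- round(ser@red)
  path <- file.path(tempdir(), "series.tif")
  writeSeries(ser, path)
  back <- readSeries(path)
  expect_equal(back@green, ser@green)
  expect_equal(back@red, ser@red)
  expect_equal(framePeriod(back), framePeriod(ser))
  expect_equal(pixelSize(back), pixelSize(ser))
  expect_equal(back@nBaselineFrames, ser@nBaselineFrames)
  unlink(c(path, paste0(path, ".json")))
})

test_that("metadata inconsistencies are reported by name", {
  sc <- fixtureScene(1)
  ser <- renderSeries(sc, mode = "anatomy", res = 128, seed = 1)
  path <- file.path(tempdir(), "meta.tif")
  writeSeries(ser, path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ## promise more pages than the TIFF holds
  bad <- meta; bad$n_t <- 10
  jsonlite::write_json(bad, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(readSeries(path), "promises")
  ## drop a required key
  bad2 <- meta[setdiff(names(meta), "frame_period_s")]
  jsonlite::write_json(bad2, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(readSeries(path), "frame_period_s")
  expect_error(readSeries(file.path(tempdir(), "absent.tif")), "metadata")
  unlink(c(path, paste0(path, ".json")))
})

test_that("trace extraction averages exactly the pixels inside the polygon", {
  arr <- array(7, c(3, 1, 20, 20))
  ser <- new("ImageSeries", green = array(0, c(0, 0, 0, 0)), red = arr,
             framePeriodS = 2 / 3, pixelSizeUm = 7.8125, zStepUm = 2,
             nBaselineFrames = 0L, mode = "perfusion")
  roi <- rbind(c(5, 5), c(5, 10), c(10, 10), c(10, 5))
  tr <- extractTrace(ser, roi, "red")
  expect_equal(tr$intensity, rep(7, 3))
  expect_equal(tr$time_s, (0:2) * 2 / 3)
  ## single-pixel ROI equals that pixel's values
  arr2 <- arr; arr2[, , 8, 9] <- c(1, 2, 3)
  ser@red <- arr2
  one <- rbind(c(7, 8), c(7, 9), c(8, 9), c(8, 8))   # encloses centre (7.5, 8.5)
  tr1 <- extractTrace(ser, one, "red")
  expect_equal(tr1$intensity, c(1, 2, 3))
  ## empty ROI errors
  tiny <- rbind(c(5, 5), c(5, 5.1), c(5.1, 5.1))
  expect_error(extractTrace(ser, tiny, "red"), "empty ROI")
})

test_that("ROI placement is ordered proximal to distal on the centerline", {
  sc <- fixtureScene(1)
  rs <- placeRois(sc, res = 128)
  cent <- t(vapply(rois(rs), function(p) colMeans(p), numeric(2)))
  ## proximal wound edge is at smaller y (row): A above B above C above D
  expect_true(cent["A", 1] < cent["B", 1])
  expect_true(cent["B", 1] < cent["C", 1])
  expect_true(cent["C", 1] < cent["D", 1])
  ## ROI centroids fall on the stump centerline within one pixel
  ps <- pixelSize(rs)
  proxX <- stumps(sc, "proximal")[[1]]$terminalUm[1] / ps
  expect_lt(abs(cent["B", 2] - proxX), 1.5)
  expect_error(placeRois(sc, res = 128, offsetsUm = c(2000, 50)),
               "placement error")
  expect_error(placeRois(sc, res = 64), "configuration error")
})

test_that("rendered perfusion traces cross threshold at the true arrival", {
  sc <- fixtureScene(1)
  tr <- simulatePerfusionTruth(sc, dpt = 6, n = 1, seed = 11)
  ser <- renderSeries(sc, truth = tr, mode = "perfusion", res = 256, seed = 2)
  rs <- placeRois(sc, res = 256)
  for (roi in c("A", "B")) {
    trace <- extractTrace(ser, rois(rs)[[roi]], "red")
    det <- detectArrival(trace$intensity, framePeriodS = 2 / 3)
    expect_lt(abs(det - tr[[paste0("t_", roi)]]), 2 / 3)
  }
})

test_that("green fluorescence outside arteries is at the noise floor", {
  sc <- fixtureScene(1)
  ser <- renderSeries(sc, mode = "anatomy", res = 128, baselineLevel = 50,
                      seed = 3)
  img <- ser@green[1, 1, , ]
  grid <- angioQuant:::pixelCentersUm(128, sc@fovUm)
  d <- Reduce(pmin, lapply(c(stumps(sc, "proximal"), stumps(sc, "distal")),
                           function(s)
                             angioQuant:::distanceToPolyline(grid, s$path)$d))
  far <- d > 60
  expect_lt(abs(mean(img[far]) - 50), 2)
})
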