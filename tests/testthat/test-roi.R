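test_that("ROI standardization follows the resize-then-pad contract", {
  img <- matrix(runif(1000 * 1000, 0, 255), 1000, 1000)

  ## oversized crop is rescaled by target/max-side, ratio preserved
  r1 <- standardizeROI(img, boundingBox(0, 0, 900, 600), target = 450)
  expect_equal(unname(r1@contentSize), c(450, 300))
  expect_equal(r1@scaleFactor, 0.5)
  expect_equal(dim(roiPixels(r1)), c(450, 450))

  ## small crops are never upscaled
  r2 <- standardizeROI(img, boundingBox(0, 0, 200, 100), target = 450)
  expect_equal(unname(r2@contentSize), c(200, 100))
  expect_equal(r2@scaleFactor, 1)
  expect_true(all(roiPixels(r2)[101:450, ] == 0))
  expect_true(all(roiPixels(r2)[, 201:450] == 0))

  ## exact-size crop passes through unchanged
  r3 <- standardizeROI(img, boundingBox(0, 0, 450, 450), target = 450)
  expect_identical(roiPixels(r3), img[1:450, 1:450])

  expect_error(standardizeROI(img, boundingBox(10, 10, 11, 30)), "degenerate")
})

test_that("standardization preserves aspect ratio and inverts within a pixel", {
  set.seed(11)
  img <- matrix(runif(600 * 800, 0, 255), 600, 800)
  for (i in 1:50) {
    box <- randomBoxIn(800, 600, minSide = 12)
    roi <- standardizeROI(img, box, target = 96)
    px <- roiPixels(roi)
    expect_equal(dim(px), c(96, 96))
    cw <- roi@contentSize[1]; ch <- roi@contentSize[2]
    ## padding exactly zero
    if (ch < 96) expect_true(all(px[(ch + 1):96, ] == 0))
    if (cw < 96) expect_true(all(px[, (cw + 1):96] == 0))
    ## aspect ratio preserved within 1 px of rounding
    w <- roi@sourceBox@x1 - roi@sourceBox@x0
    h <- roi@sourceBox@y1 - roi@sourceBox@y0
    expect_lt(abs(cw - w * roi@scaleFactor), 1)
    expect_lt(abs(ch - h * roi@scaleFactor), 1)
    ## inverse mapping recovers the source box corners
    corners <- roiToImage(roi, rbind(c(0, 0), c(cw, ch)))
    expect_lt(max(abs(corners[1, ] - c(roi@sourceBox@x0, roi@sourceBox@y0))), 1)
    expect_lt(max(abs(corners[2, ] - c(roi@sourceBox@x1, roi@sourceBox@y1))), 1)
  }
})

test_that("detection front ends honor the oracle, thresholds and monotonicity", {
  m <- fixtureDataset()
  dir <- attr(m, "dir")
  img <- readGrayPNG(file.path(dir, m$file[1]))
  truth <- list(boundingBox(m$x0[1], m$y0[1], m$x1[1], m$y1[1]))

  or <- detectNodules(img, method = "oracle", truth = truth)
  expect_equal(length(or), 1)
  expect_equal(boxCoords(or[[1]]), boxCoords(truth[[1]]))

  expect_error(detectNodules(img, confThreshold = 1.2), "confThreshold")
  expect_error(detectNodules(matrix(numeric(0), 0, 0)), "empty")

  ## lowering the threshold never removes a previously returned box
  ids <- function(boxes) vapply(boxes, function(b)
    paste(boxCoords(b), collapse = ","), character(1))
  for (i in 1:4) {
    hi <- detectNodules(readGrayPNG(file.path(dir, m$file[i])),
                        confThreshold = 0.6)
    lo <- detectNodules(readGrayPNG(file.path(dir, m$file[i])),
                        confThreshold = 0.1)
    expect_true(all(ids(hi) %in% ids(lo)))
  }
})

test_that("the fallback detector localizes a clean hypoechoic phantom", {
  found <- NULL
  for (s in seq(1500, 1800)) {
    cand <- samplePhantomSpec(s)
    if (cand@echogenicity == "hypoechoic" && cand@margin == "circumscribed" &&
        cand@halo == "absent") { found <- cand; break }
  }
  r <- renderPhantom(found)
  det <- detectNodules(r$image, confThreshold = 0.1, method = "fallback")
  expect_gte(length(det), 1)
  iou <- sonodescribe:::.iou(det[[1]], r$box)
  expect_gte(iou, 0.5)
})

test_that("detection metrics match hand counts and the brute-force matcher", {
  t1 <- list(a = list(boundingBox(0, 0, 10, 10), boundingBox(20, 20, 30, 30)))
  ## perfect predictions
  ev <- evaluateDetection(t1, t1)
  expect_equal(ev$precision, 1); expect_equal(ev$recall, 1)
  expect_equal(ev$ap, 1)
  ## no predictions: precision reported 0 by convention
  ev0 <- evaluateDetection(list(), t1)
  expect_equal(ev0$precision, 0); expect_equal(ev0$recall, 0)
  ## one prediction matching 1 of 2 truths
  ev1 <- evaluateDetection(list(a = list(boundingBox(0, 0, 10, 10, 0.9))), t1)
  expect_equal(ev1$precision, 1); expect_equal(ev1$recall, 0.5)
  expect_error(evaluateDetection(t1, t1, iouThreshold = 0), "iouThreshold")

  ## equivalence with the independent matcher on random small instances
  set.seed(21)
  for (rep in 1:20) {
    truth <- list(); pred <- list()
    for (id in c("i1", "i2")) {
      truth[[id]] <- lapply(seq_len(sample(0:4, 1)), function(k)
        randomBoxIn(200, 200))
      pred[[id]] <- lapply(seq_len(sample(0:5, 1)), function(k)
        randomBoxIn(200, 200))
      ## seed some true positives by jittering truth boxes
      for (tb in truth[[id]]) if (runif(1) < 0.6) {
        j <- runif(4, -2, 2)
        pred[[id]] <- c(pred[[id]], list(boundingBox(
          max(0, tb@x0 + j[1]), max(0, tb@y0 + j[2]),
          tb@x1 + abs(j[3]), tb@y1 + abs(j[4]),
          confidence = runif(1))))
      }
    }
    ev <- evaluateDetection(pred, truth)
    br <- bruteDetectionPR(pred, truth)
    expect_equal(ev$precision, unname(br["precision"]), tolerance = 1e-12)
    expect_equal(ev$recall, unname(br["recall"]), tolerance = 1e-12)
  }
})
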