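test_that("encoder geometry matches the configured feature-space contract", {
  ## tiny: 96x96 input, downsample 16, 64 channels -> 36 x 64
  netT <- biradsNet("tiny", seed = 1)
  FT <- encodeROI(matrix(runif(96 * 96, 0, 255), 96, 96), netT)
  expect_equal(dim(FT), c(36, 64))
  expect_true(all(is.finite(FT)))

  ## constant-zero input stays finite (normalization epsilon guard)
  F0 <- encodeROI(matrix(0, 96, 96), netT)
  expect_true(all(is.finite(F0)))

  expect_error(encodeROI(matrix(0, 80, 80), netT), "96")

  ## full-size configuration: 450x450 input -> 196 x 512 feature space
  netD <- biradsNet("default", seed = 1)
  FD <- encodeROI(matrix(runif(450 * 450, 0, 255), 450, 450), netD)
  expect_equal(dim(FD), c(196, 512))
})

test_that("attention computes a softmax-weighted context", {
  set.seed(51)
  ## zero scoring vector: uniform weights, context = column means
  F <- matrix(rnorm(36 * 8), 36, 8)
  at <- attend(F, rep(0, 8))
  expect_equal(at$a, rep(1 / 36, 36))
  expect_equal(at$c, colMeans(F), tolerance = 1e-12)

  ## toy case against a direct softmax of the tanh scores
  F4 <- diag(4) * 10
  v <- c(10, -10, -10, -10) / 10
  at4 <- attend(F4, v)
  sc <- tanh(F4 %*% v)
  expect_equal(at4$a, as.numeric(exp(sc) / sum(exp(sc))), tolerance = 1e-12)

  ## softmax properties on random inputs
  for (i in 1:20) {
    F <- matrix(rnorm(9 * 5), 9, 5)
    v <- rnorm(5)
    at <- attend(F, v)
    expect_true(all(at$a >= 0))
    expect_lt(abs(sum(at$a) - 1), 1e-6)
    expect_equal(at$c, as.numeric(crossprod(F, at$a)), tolerance = 1e-12)
  }
  expect_error(attend(matrix(0, 4, 3), rep(0, 5)), "dimension")
})

test_that("head wiring feeds descriptors and context into the dependent heads", {
  net <- biradsNet("tiny", seed = 2)
  d <- net@config$encoder$d
  uLen <- net@config$u_len
  expect_equal(uLen, 3 + 4 + 2 + 5 + 3 + 2)
  ## suggestivity input = six descriptor outputs + context
  expect_equal(ncol(net@params$sugg$W), uLen + d)
  ## malignancy input = descriptors + suggestivity + context
  expect_equal(ncol(net@params$malig$W),
               uLen + length(net@config$vocab$suggestivity) + d)

  ctx <- rnorm(d)
  ho <- headsForward(net, ctx)
  for (nm in c("shape", "margin", "echogenicity", "posterior", "halo"))
    expect_lt(abs(sum(ho$heads[[nm]]) - 1), 1e-6)
  expect_true(all(ho$heads$orientation >= 0 & ho$heads$orientation <= 1))
  expect_lt(abs(sum(ho$suggestivity) - 1), 1e-6)
  expect_lt(abs(sum(ho$malignancy) - 1), 1e-6)

  ## zeroing the descriptor outputs changes the suggestivity logits;
  ## zeroing the context alone changes them too
  hoZeroU <- headsForward(net, ctx, descriptorOverride = rep(0, uLen))
  expect_gt(max(abs(hoZeroU$sugg_logits - ho$sugg_logits)), 1e-6)
  hoZeroC <- headsForward(net, ctx, contextOverride = rep(0, d))
  expect_gt(max(abs(hoZeroC$sugg_logits - ho$sugg_logits)), 1e-6)
})

test_that("orientation decisions threshold the sigmoid pair", {
  expect_identical(decideOrientation(c(0.2, 0.25)), "none")
  expect_identical(decideOrientation(c(0.9, 0.1)), "parallel")
  expect_identical(decideOrientation(c(0.1, 0.8)), "anti_parallel")
  expect_identical(decideOrientation(c(0.6, 0.5)), "parallel")   # argmax
  expect_identical(decideOrientation(c(0.5, 0.5)), "parallel")   # tie rule
  expect_identical(decideOrientation(c(0.29, 0.29)), "none")
  expect_identical(decideOrientation(c(0.29, 0.31)), "anti_parallel")
  expect_identical(decideOrientation(c(0.2, 0.25), tau = 0.1), "anti_parallel")
})

test_that("augmentation samples the documented intervals and collapses to identity", {
  m <- fixtureDataset()
  img <- readGrayPNG(file.path(attr(m, "dir"), m$file[2]))
  box <- boundingBox(m$x0[2], m$y0[2], m$x1[2], m$y1[2])

  ## all ranges collapsed to zero reproduces plain standardization
  cfg0 <- pipelineConfig(augment = list(
    enlarge_vertical = c(0, 0), enlarge_horizontal = c(0, 0),
    zoom = c(0, 0), contrast = c(1, 1), brightness = c(0, 0),
    flip_prob = 0, rotation_max = 0))
  set.seed(61)
  a0 <- augmentROI(img, box, target = 96, config = cfg0)
  expect_identical(roiPixels(a0$roi),
                   roiPixels(standardizeROI(img, box, target = 96)))

  ## sampled parameters honor the published intervals
  cfg <- pipelineConfig()
  set.seed(62)
  small <- matrix(runif(40 * 40, 0, 255), 40, 40)
  sbox <- boundingBox(10, 10, 30, 30)
  for (i in 1:1000) {
    p <- suppressWarnings(augmentROI(small, sbox, target = 96,
                                     config = cfg))$params
    expect_true(p$enlargeV >= -0.1 && p$enlargeV <= 0.25)
    expect_true(p$enlargeH >= -0.1 && p$enlargeH <= 0.15)
    expect_true(p$zoom >= -0.3 && p$zoom <= 0.3)
    expect_true(p$contrast >= 0.8 && p$contrast <= 1.2)
    expect_true(p$brightness >= -25 && p$brightness <= 25)
    expect_true(abs(p$rotation) <= 0.05 * 2 * pi)
  }

  ## fixed seed reproduces the augmented pixels exactly
  set.seed(63); a1 <- augmentROI(img, box, target = 96)
  set.seed(63); a2 <- augmentROI(img, box, target = 96)
  expect_identical(roiPixels(a1$roi), roiPixels(a2$roi))
})

test_that("training overfits a small batch and is seed-deterministic", {
  m <- fixtureDataset()[1:8, ]
  attr(m, "dir") <- attr(fixtureDataset(), "dir")
  net <- trainBiradsNet(m, encoder = "tiny", epochs = 50, batchSize = 8,
                        seed = 5, lrDropEpoch = 51)
  h <- net@history
  expect_lt(h$loss[50], 0.2 * h$loss[1])

  netA <- trainBiradsNet(m, encoder = "tiny", epochs = 3, batchSize = 8,
                         seed = 9)
  netB <- trainBiradsNet(m, encoder = "tiny", epochs = 3, batchSize = 8,
                         seed = 9)
  expect_identical(netA@history$loss, netB@history$loss)
  expect_identical(netA@params$v, netB@params$v)

  bad <- m; bad$margin[1] <- "smooth"
  expect_error(trainBiradsNet(bad), "vocabulary")
  expect_error(trainBiradsNet(m[0, ]), "empty")
})

test_that("prediction outputs valid descriptors and a faithful attention map", {
  net <- biradsNet("tiny", seed = 8)
  net@trained <- TRUE    # plumbing test with random weights
  roi <- matrix(runif(96 * 96, 0, 255), 96, 96)
  pr <- predictROI(net, roi)
  voc <- descriptorVocabularies()
  vals <- descriptorValues(pr$descriptors)
  for (dsc in names(vals)) expect_true(vals[[dsc]] %in% voc[[dsc]])
  expect_true(pr$malignancyProb >= 0 && pr$malignancyProb <= 1)
  expect_equal(dim(pr$attentionGrid), c(6, 6))
  expect_equal(dim(pr$attention), c(96, 96))

  ## uniform attention weights give a constant upsampled map
  netU <- net
  netU@params$v <- rep(0, 64)
  prU <- predictROI(netU, roi)
  expect_lt(diff(range(prU$attention)), 1e-9)

  netUntrained <- biradsNet("tiny", seed = 8)
  expect_error(predictROI(netUntrained, roi), "untrained")
})

test_that("checkpoints round-trip through a single file", {
  net <- biradsNet("tiny", seed = 13)
  net@trained <- TRUE
  f <- tempfile(fileext = ".ckpt")
  saveBiradsNet(net, f)
  back <- loadBiradsNet(f)
  expect_identical(back@params$v, net@params$v)
  expect_identical(back@config$encoder$name, "tiny")
  roi <- matrix(runif(96 * 96, 0, 255), 96, 96)
  expect_identical(predictROI(back, roi)$descriptors@values,
                   predictROI(net, roi)$descriptors@values)
  unlink(f)
})
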