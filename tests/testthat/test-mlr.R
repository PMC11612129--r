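test_that("one-hot encoding lays out the descriptor blocks", {
  voc <- descriptorVocabularies()
  d <- descriptorValues(samplePhantomSpec(3))
  x <- encodeFeatures(d)
  expect_equal(ncol(x), sum(lengths(voc[c("shape", "margin", "orientation",
    "echogenicity", "posterior", "halo", "suggestivity")])))
  expect_equal(sum(x), 7)                      # exactly one value per block
  expect_true(all(x %in% c(0, 1)))
  expect_equal(unname(x[1, paste0("shape=", d[["shape"]])]), 1)

  ## flipping one descriptor changes exactly two positions
  d2 <- d
  d2[["halo"]] <- setdiff(voc$halo, d[["halo"]])
  expect_equal(sum(encodeFeatures(d) != encodeFeatures(d2)), 2)

  d3 <- d; d3[["margin"]] <- "smooth"
  expect_error(encodeFeatures(d3), "out-of-vocabulary")
})

test_that("the category model fits separable descriptor tables", {
  specs <- fixtureSpecs(300)
  df <- specFrame(specs)
  cats <- vapply(specs, deriveBirads, character(1))
  mlr <- fitBiradsMLR(df, cats)
  expect_true(mlr@converged)
  acc <- mean(predictBirads(df, mlr) == cats)
  expect_gte(acc, 0.95)

  ## duplicating every row leaves the fit unchanged
  X <- encodeFeatures(df)
  m1 <- fitBiradsMLR(X, cats)
  m2 <- fitBiradsMLR(rbind(X, X), c(cats, cats))
  expect_lt(max(abs(m1@weights - m2@weights)), 1e-6)
  expect_lt(max(abs(m1@intercepts - m2@intercepts)), 1e-6)

  ## heavy shrinkage drives weights to zero, probabilities to frequencies
  mInf <- fitBiradsMLR(X, cats, l2 = 1e5)
  expect_lt(max(abs(mInf@weights)), 1e-3)
  p <- predictExplain(descriptorValues(specs[[1]]), mInf)@probabilities
  freq <- table(factor(cats, descriptorVocabularies()$birads)) / length(cats)
  expect_lt(max(abs(p - as.numeric(freq))), 0.01)

  expect_error(fitBiradsMLR(X, rep("3", nrow(X))), "degenerate")
})

test_that("probabilities agree with an independent multinomial fit", {
  ## noisy (non-separable) simulated labels keep the unpenalized optimum
  ## interior, so both fitters converge to the same probabilities
  voc <- descriptorVocabularies()
  set.seed(42)
  X <- encodeFeatures(specFrame(fixtureSpecs(300)))
  W0 <- matrix(rnorm(ncol(X) * 6, sd = 0.6), ncol(X), 6)
  P0 <- exp(X %*% W0); P0 <- P0 / rowSums(P0)
  y <- apply(P0, 1, function(p) sample(voc$birads, 1, prob = p))
  mine <- fitBiradsMLR(X, y, l2 = 1e-6)
  Z <- sweep(X %*% mine@weights, 2, mine@intercepts, "+")
  pm <- exp(Z - apply(Z, 1, max)); pm <- pm / rowSums(pm)
  nn <- nnet::multinom(factor(y, levels = mine@categories) ~ X,
                       trace = FALSE, maxit = 800, reltol = 1e-13,
                       MaxNWts = 10000)
  pn <- predict(nn, type = "probs")
  expect_lt(max(abs(pm - pn[, colnames(pm)])), 0.02)
})

test_that("explanations decompose the logits exactly", {
  specs <- fixtureSpecs(300)
  mlr <- fitBiradsMLR(specFrame(specs),
                      vapply(specs, deriveBirads, character(1)))
  set.seed(41)
  for (i in sample(300, 50)) {
    res <- predictExplain(descriptorValues(specs[[i]]), mlr)
    expect_lt(abs(sum(res@probabilities) - 1), 1e-6)
    for (cat in unique(res@explanation$category)) {
      s <- sum(res@explanation$weight[res@explanation$category == cat])
      expect_lt(abs(s - res@logits[[cat]]), 1e-9)
    }
    ## explanation covers the 7 active features + intercept for 2 categories
    expect_equal(nrow(res@explanation), 2 * 8)
  }

  ## probabilities invariant to a constant shift of all logits
  res <- predictExplain(descriptorValues(specs[[1]]), mlr)
  shifted <- mlr
  shifted@intercepts <- mlr@intercepts + 5
  res2 <- predictExplain(descriptorValues(specs[[1]]), shifted)
  expect_lt(max(abs(res@probabilities - res2@probabilities)), 1e-9)

  ## a simple-cyst pattern lands on category 2 with high confidence
  sc <- which(vapply(specs, function(s) s@suggestivity, character(1)) ==
              "simple_cyst")[1]
  rc <- predictExplain(descriptorValues(specs[[sc]]), mlr)
  expect_identical(rc@category, "2")
  expect_gt(rc@probabilities[["2"]], 0.5)

  expect_error(predictExplain(descriptorValues(specs[[1]]), "not a model"))
})

test_that("known multinomial-logit weights are recovered from simulated data", {
  voc <- descriptorVocabularies()
  blocks <- rep(1:7, lengths(voc[1:7]))
  set.seed(9)
  Wtrue <- matrix(rnorm(24 * 6, sd = 1.2), 24, 6)
  ## identifiable representative: centered within blocks and across categories
  for (b in unique(blocks))
    Wtrue[blocks == b, ] <- sweep(Wtrue[blocks == b, , drop = FALSE], 2,
                                  colMeans(Wtrue[blocks == b, , drop = FALSE]))
  Wtrue <- Wtrue - rowMeans(Wtrue)
  df <- specFrame(lapply(5001:8000, samplePhantomSpec))
  X <- encodeFeatures(df)
  P <- exp(X %*% Wtrue); P <- P / rowSums(P)
  y <- apply(P, 1, function(p) sample(voc$birads, 1, prob = p))
  fit <- fitBiradsMLR(X, y)
  big <- abs(Wtrue) >= 1
  expect_gt(sum(big), 20)
  ## smoke-scale check (n = 3,000); the full n = 5,000 recovery contract
  ## (every |w| >= 1 sign correct) runs in the acceptance suite
  expect_gte(mean(sign(fit@weights[big]) == sign(Wtrue[big])), 0.95)
  expect_gt(cor(as.numeric(fit@weights), as.numeric(Wtrue)), 0.9)
})

test_that("models round-trip through JSON", {
  specs <- fixtureSpecs(100)
  mlr <- fitBiradsMLR(specFrame(specs),
                      vapply(specs, deriveBirads, character(1)))
  f <- tempfile(fileext = ".json")
  writeBiradsMLR(mlr, f)
  back <- readBiradsMLR(f)
  expect_equal(back@weights, mlr@weights, tolerance = 1e-12)
  expect_equal(back@intercepts, mlr@intercepts, tolerance = 1e-12)
  d <- descriptorValues(specs[[5]])
  expect_equal(predictExplain(d, back)@probabilities,
               predictExplain(d, mlr)@probabilities, tolerance = 1e-12)
  unlink(f)
})
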