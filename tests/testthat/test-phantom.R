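test_that("spec sampling is deterministic and honors forced invariants", {
  expect_identical(samplePhantomSpec(7), samplePhantomSpec(7))

  ## forcing round shapes forces the no-orientation invariant
  w <- list(shape = c(oval = 0, round = 1, irregular = 0),
            suggestivity = c(simple_cyst = 0, complex_cyst = 0,
                             fibroadenoma = 0, no_clear_suggestivity = 1))
  for (s in 1:25) {
    sp <- samplePhantomSpec(s, weights = w)
    expect_identical(sp@shape, "round")
    expect_identical(sp@orientation, "none")
    ratio <- sp@semiAxes[1] / sp@semiAxes[2]
    expect_true(ratio >= 0.9 && ratio <= 1.1)
  }

  expect_error(samplePhantomSpec(1, weights = list(shape = c(-1, 1, 1))),
               "weights")
})

test_that("sampled shape frequencies follow the class weights", {
  ## margin excludes spiculated (which is coupled to irregular shape) and
  ## suggestivity is free-form, so the shape marginal is exactly the weights
  w <- list(shape = c(oval = 0.5, round = 0.25, irregular = 0.25),
            margin = c(circumscribed = 1/3, indistinct = 1/3,
                       microlobulated = 1/3, spiculated = 0),
            suggestivity = c(simple_cyst = 0, complex_cyst = 0,
                             fibroadenoma = 0, no_clear_suggestivity = 1))
  shapes <- vapply(seq_len(2000), function(s)
    samplePhantomSpec(s, weights = w)@shape, character(1))
  freq <- table(factor(shapes, c("oval", "round", "irregular"))) / 2000
  expect_lt(abs(freq[["oval"]] - 0.5), 0.05)
  expect_lt(abs(freq[["round"]] - 0.25), 0.05)
  expect_lt(abs(freq[["irregular"]] - 0.25), 0.05)
})

test_that("structural invariants hold across many sampled specs", {
  for (sp in fixtureSpecs(200)) {
    expect_true(validObject(sp))
    if (sp@shape == "round") expect_identical(sp@orientation, "none")
    if (sp@suggestivity == "simple_cyst") {
      expect_identical(sp@echogenicity, "anechoic")
      expect_identical(sp@margin, "circumscribed")
      expect_identical(sp@posterior, "enhancement")
    }
    if (sp@margin == "spiculated") expect_true(sp@malignant)
  }
})

test_that("the generative category table is total, deterministic and monotone", {
  voc <- descriptorVocabularies()
  base <- c(shape = "oval", margin = "circumscribed",
            orientation = "parallel", echogenicity = "hypoechoic",
            posterior = "none", halo = "absent",
            suggestivity = "no_clear_suggestivity")

  ## hard rules
  sc <- base
  sc[c("echogenicity", "posterior", "suggestivity")] <-
    c("anechoic", "enhancement", "simple_cyst")
  expect_identical(deriveBirads(sc), "2")
  spic <- base; spic["margin"] <- "spiculated"
  expect_identical(deriveBirads(spic), "5")
  cc <- base
  cc[c("echogenicity", "suggestivity")] <- c("heterogeneous", "complex_cyst")
  expect_identical(deriveBirads(cc), "4A")

  ## benign combination sits at 3; a fibroadenoma at 2
  expect_identical(deriveBirads(base), "3")
  fib <- base; fib["suggestivity"] <- "fibroadenoma"
  expect_identical(deriveBirads(fib), "2")

  ## monotone in the count of suspicious features
  lvl <- function(cat) match(cat, voc$birads)
  s1 <- base; s1["halo"] <- "present"
  s2 <- s1; s2["posterior"] <- "shadowing"
  s3 <- s2; s3["orientation"] <- "anti_parallel"
  s4 <- s3; s4["shape"] <- "irregular"
  cats <- vapply(list(base, s1, s2, s3, s4), deriveBirads, character(1))
  expect_identical(cats, c("3", "4A", "4B", "4C", "5"))
  expect_true(all(diff(vapply(cats, lvl, numeric(1))) > 0))

  ## total on every sampled spec
  for (sp in fixtureSpecs(100))
    expect_true(deriveBirads(sp) %in% voc$birads)
})

test_that("rendering is deterministic with ordered echogenicity contrasts", {
  sp <- samplePhantomSpec(31)
  r1 <- renderPhantom(sp); r2 <- renderPhantom(sp)
  expect_identical(r1$image, r2$image)

  insideMask <- function(sp, img, shrink = 0.7) {
    H <- nrow(img); W <- ncol(img)
    xs <- matrix(rep(seq_len(W) - 0.5, each = H), H)
    ys <- matrix(rep(seq_len(H) - 0.5, W), H)
    dx <- xs - sp@center[1]; dy <- ys - sp@center[2]
    u <- dx * cos(sp@rotation) + dy * sin(sp@rotation)
    v <- -dx * sin(sp@rotation) + dy * cos(sp@rotation)
    sqrt((u / sp@semiAxes[1])^2 + (v / sp@semiAxes[2])^2) < shrink
  }

  ## interior intensity ordering over echogenicity classes
  means <- vapply(c("anechoic", "hypoechoic", "isoechoic", "hyperechoic"),
    function(ec) {
      found <- NULL
      for (s in seq(500, 800)) {
        cand <- samplePhantomSpec(s)
        if (cand@echogenicity == ec && cand@margin != "spiculated") {
          found <- cand; break
        }
      }
      img <- renderPhantom(found)$image
      mean(img[insideMask(found, img)]) / found@backgroundMean
    }, numeric(1))
  expect_lt(means[["anechoic"]], 0.5)       # anechoic well below background
  expect_true(means[["anechoic"]] < means[["hypoechoic"]])
  expect_true(means[["hypoechoic"]] < means[["isoechoic"]])
  expect_lt(abs(means[["isoechoic"]] - 1), 0.25)
  expect_true(means[["isoechoic"]] < means[["hyperechoic"]])
})

test_that("posterior enhancement brightens the column below the nodule", {
  found <- NULL
  for (s in seq(900, 1200)) {
    cand <- samplePhantomSpec(s)
    if (cand@posterior == "enhancement" && cand@halo == "absent") {
      found <- cand; break
    }
  }
  r <- renderPhantom(found)
  img <- r$image
  ## the posterior column ends at the bottom of the ground-truth box; read
  ## a band just above it, inside the nodule's x-extent, vs flanking strips
  cx <- found@center[1]; hw <- 0.5 * found@semiAxes[1]
  yBot <- round(r$box@y1); yTop <- max(1, yBot - 10)
  colBand <- img[yTop:yBot, round(cx - hw):round(cx + hw)]
  fx1 <- max(1, round(r$box@x0 - 18)):max(2, round(r$box@x0 - 4))
  flankL <- img[yTop:yBot, fx1]
  expect_gt(mean(colBand), mean(flankL) * 1.15)
})

test_that("rendering rejects nodules that do not fit the canvas", {
  sp <- samplePhantomSpec(5)
  sp@center <- c(2, 2)
  expect_error(renderPhantom(sp), "canvas")
})

test_that("datasets are written completely and reproducibly", {
  m <- fixtureDataset()
  dir <- attr(m, "dir")
  expect_equal(nrow(m), 12)
  expect_true(all(file.exists(file.path(dir, m$file))))
  expect_true(all(file.exists(file.path(dir, m$box_file))))
  labels <- read.csv(file.path(dir, "labels.csv"))
  expect_equal(nrow(labels), 12)

  ## same (n, seed) gives a byte-identical manifest
  dir2 <- file.path(tempdir(), "sono_repro")
  unlink(dir2, recursive = TRUE)
  makeDataset(12, seed = 401, outDir = dir2)
  expect_identical(unname(tools::md5sum(file.path(dir, "manifest.json"))),
                   unname(tools::md5sum(file.path(dir2, "manifest.json"))))
  unlink(dir2, recursive = TRUE)

  ## box files round-trip through the normalized format within a pixel
  b <- readBoxFile(file.path(dir, m$box_file[1]), c(160, 160))[[1]]
  expect_lt(abs(b@x0 - m$x0[1]), 1e-3)
  expect_lt(abs(b@y1 - m$y1[1]), 1e-3)
})

test_that("extra-information images never enter validation folds or test splits", {
  m <- fixtureDataset()
  m$extra_info[1:3] <- TRUE     # ensure flagged rows exist
  fold <- makeFolds(m, k = 5, seed = 3)
  expect_true(all(fold[m$extra_info] == 0))
  expect_true(all(fold[!m$extra_info] > 0))
  sp <- splitManifest(m, nTest = 4, seed = 3)
  expect_false(any(sp$test$extra_info))
})

test_that("planted duplicates carry provenance, bounded transforms and label conflicts", {
  m2 <- fixtureDupDataset()
  dups <- m2[!is.na(m2$duplicate_of), ]
  expect_equal(nrow(dups), 5)
  expect_true(all(abs(dups$dup_rotation) <= 15))
  expect_true(all(dups$dup_zoom >= 0.8 & dups$dup_zoom <= 1.2))
  ## conflict fraction 0.4 of 5 pairs, rounded half up -> 2 flipped labels
  lab <- setNames(m2$malignant, m2$image_id)
  flipped <- sum(vapply(seq_len(nrow(dups)), function(i)
    dups$malignant[i] != lab[[dups$duplicate_of[i]]], logical(1)))
  expect_equal(flipped, 2)
  expect_error(makeDuplicates(m2[0, ], 1), "empty")
})
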