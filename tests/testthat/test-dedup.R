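test_that("an image matches itself and featureless images are handled", {
  m <- fixtureDupDataset()
  img <- readGrayPNG(file.path(attr(m, "dir"), m$file[1]))
  mm <- matchPair(img, img)
  expect_true(mm$is_duplicate)
  expect_gte(mm$inliers, 25)

  flat <- matrix(128, 120, 120)
  expect_warning(mf <- matchPair(flat, img), "featureless")
  expect_false(mf$is_duplicate)
})

test_that("matching is symmetric and transforms are recovered", {
  m <- fixtureDupDataset()
  dir <- attr(m, "dir")
  dups <- m[!is.na(m$duplicate_of), ]
  a <- readGrayPNG(file.path(dir, paste0(dups$duplicate_of[1], ".png")))
  b <- readGrayPNG(file.path(dir, dups$file[1]))
  ab <- matchPair(a, b); ba <- matchPair(b, a)
  expect_true(ab$is_duplicate)
  expect_identical(ab$is_duplicate, ba$is_duplicate)
  expect_identical(ab$inliers, ba$inliers)
  ## recovered similarity scale close to the planted zoom (either direction)
  sc <- Mod(ab$transform$a)
  expect_lt(min(abs(sc - dups$dup_zoom[1]), abs(1 / sc - dups$dup_zoom[1])),
            0.1)
})

test_that("planted duplicates cluster perfectly with no false positives", {
  m <- fixtureDupDataset()        # 10 originals + 5 planted copies
  clusters <- findDuplicates(m)
  expect_equal(length(clusters), 5)
  expect_true(all(vapply(clusters, function(cl)
    length(cl@members), integer(1)) == 2))
  ## each cluster is exactly {original, its copy}
  dups <- m[!is.na(m$duplicate_of), ]
  for (cl in clusters) {
    d <- intersect(cl@members, dups$image_id)
    expect_equal(length(d), 1)
    expect_setequal(cl@members,
                    c(d, dups$duplicate_of[dups$image_id == d]))
  }
})

test_that("chained duplicates collapse into one cluster", {
  m <- fixtureDupDataset()
  dir0 <- attr(m, "dir")
  dir <- file.path(tempdir(), "sono_chain")
  unlink(dir, recursive = TRUE); dir.create(dir)
  img <- readGrayPNG(file.path(dir0, m$file[3]))
  writeGrayPNG(img, file.path(dir, "a.png"))
  writeGrayPNG(sonodescribe:::.transformDuplicate(img, 5, 1.0)$image,
               file.path(dir, "b.png"))
  writeGrayPNG(sonodescribe:::.transformDuplicate(img, 10, 1.05)$image,
               file.path(dir, "c.png"))
  mani <- data.frame(image_id = c("a", "b", "c"),
                     file = c("a.png", "b.png", "c.png"),
                     malignant = c(FALSE, FALSE, TRUE),
                     duplicate_of = c(NA, "a", "a"))
  attr(mani, "dir") <- dir
  cl <- findDuplicates(mani)
  expect_equal(length(cl), 1)
  expect_setequal(cl[[1]]@members, c("a", "b", "c"))
  expect_true(cl[[1]]@conflict)            # mixed malignancy labels
  unlink(dir, recursive = TRUE)
})

test_that("conflict reports apply the discard policy arithmetic", {
  m <- fixtureDupDataset()        # 5 pairs, 2 with flipped labels
  clusters <- findDuplicates(m)
  rep <- conflictReport(clusters, m)
  expect_equal(rep$n_conflicted, 2)
  ## drop both images of each conflicted pair, keep one of each clean pair
  expect_equal(rep$n_discard, 2 * 2 + 3 * 1)
  expect_true(all(rep$table$conflict == grepl("drop", rep$table$action)))

  repKeep <- conflictReport(clusters, m, dropConflicted = FALSE)
  expect_equal(repKeep$n_discard, 5)

  mBad <- m[m$image_id != clusters[[1]]@members[1], ]
  expect_error(conflictReport(clusters, mBad), "missing label")

  f <- tempfile(fileext = ".csv")
  writeDedupReport(rep, f)
  expect_equal(nrow(read.csv(f)), 5)
  unlink(f)
})

test_that("re-acquisitions of the same nodule are not flagged (documented limit)", {
  ## same underlying nodule, new speckle realization and probe shift: the
  ## keypoint texture is new, so geometric matching finds no consensus
  sp <- samplePhantomSpec(7001)
  r1 <- renderPhantom(sp)
  sp2 <- sp
  sp2@seed <- 7002L
  sp2@center <- sp@center + c(5, -4)
  r2 <- renderPhantom(sp2)
  mm <- matchPair(r1$image, r2$image)
  expect_false(mm$is_duplicate)
})
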