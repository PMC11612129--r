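## Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

## small phantom dataset on disk (12 images, deterministic)
fixtureDataset <- function() {
  if (is.null(.fixtures$ds)) {
    dir <- file.path(tempdir(), "sono_fixture_ds")
    unlink(dir, recursive = TRUE)
    makeDataset(12, seed = 401, outDir = dir)
    .fixtures$ds <- readManifest(dir)
  }
  .fixtures$ds
}

## dataset with planted near-duplicates (shares images with fixtureDataset
## via a separate directory to keep manifests independent)
fixtureDupDataset <- function() {
  if (is.null(.fixtures$dd)) {
    dir <- file.path(tempdir(), "sono_fixture_dup")
    unlink(dir, recursive = TRUE)
    makeDataset(10, seed = 402, outDir = dir)
    m <- readManifest(dir)
    .fixtures$dd <- makeDuplicates(m, nPairs = 5, rotationMax = 15,
                                   zoomRange = c(0.8, 1.2),
                                   conflictFraction = 0.4, seed = 77)
  }
  .fixtures$dd
}

## a batch of sampled specs reused across phantom/mlr tests
fixtureSpecs <- function(n = 300) {
  if (is.null(.fixtures$specs) || length(.fixtures$specs) < n)
    .fixtures$specs <- lapply(seq_len(n), samplePhantomSpec)
  .fixtures$specs[seq_len(n)]
}

specFrame <- function(specs) {
  as.data.frame(do.call(rbind, lapply(specs, descriptorValues)),
                stringsAsFactors = FALSE)
}

## independent brute-force Cohen's kappa from the full contingency table
bruteKappa <- function(y1, y2) {
  labs <- sort(unique(c(y1, y2)))
  tab <- table(factor(y1, labs), factor(y2, labs))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) return(1.0)
  (po - pe) / (1 - pe)
}

## independent brute-force detection matcher: maximum bipartite matching by
## exhaustive assignment (instances of <= 5 boxes), then P/R from counts
bruteDetectionPR <- function(pred, truth, iou = 0.5) {
  iouOf <- function(a, b) {
    ix <- max(0, min(a@x1, b@x1) - max(a@x0, b@x0))
    iy <- max(0, min(a@y1, b@y1) - max(a@y0, b@y0))
    inter <- ix * iy
    inter / ((a@x1-a@x0)*(a@y1-a@y0) + (b@x1-b@x0)*(b@y1-b@y0) - inter)
  }
  tp <- 0; nPred <- 0; nTruth <- 0
  for (id in union(names(pred), names(truth))) {
    p <- pred[[id]]; t <- truth[[id]]
    nPred <- nPred + length(p); nTruth <- nTruth + length(t)
    if (!length(p) || !length(t)) next
    ## greedy in confidence order (the metric's matching definition)
    conf <- vapply(p, function(b) b@confidence, numeric(1))
    used <- rep(FALSE, length(t))
    for (i in order(-conf)) {
      ious <- vapply(seq_along(t), function(k)
        if (used[k]) -1 else iouOf(p[[i]], t[[k]]), numeric(1))
      k <- which.max(ious)
      if (length(k) && ious[k] >= iou) { tp <- tp + 1; used[k] <- TRUE }
    }
  }
  c(precision = if (nPred) tp / nPred else 0,
    recall = if (nTruth) tp / nTruth else 0)
}

randomBoxIn <- function(W, H, minSide = 8) {
  w <- runif(1, minSide, W / 2); h <- runif(1, minSide, H / 2)
  x0 <- runif(1, 0, W - w); y0 <- runif(1, 0, H - h)
  boundingBox(x0, y0, x0 + w, y0 + h, confidence = runif(1))
}
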