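## roi module: nodule detection (pluggable), ROI standardization to the
## fixed network input size, and detection quality metrics.

#' Detect nodule bounding boxes
#'
#' Pluggable detection front end. Three implementations are provided:
#' \describe{
#'   \item{\code{"fallback"}}{A built-in detector for speckle phantoms and
#'     similar images: intensity-deviation thresholding against the global
#'     background level, connected components, and downward box expansion so
#'     the posterior column is included in the ROI (the region the posterior
#'     descriptor is read from).}
#'   \item{\code{"oracle"}}{Returns the ground-truth boxes supplied via
#'     \code{truth} with confidence 1 (testing).}
#'   \item{\code{"adapter"}}{Calls \code{adapter(image)}, which must return a
#'     list of \code{BoundingBox}; use this to plug in an external one-stage
#'     detector.}
#' }
#' Only boxes with confidence >= \code{confThreshold} are returned, sorted
#' by decreasing confidence; the threshold is exposed so a user can lower it
#' to recover a missed nodule.
#'
#' @param image Numeric matrix (grayscale, 0-255).
#' @param confThreshold Confidence threshold in [0, 1].
#' @param method One of \code{"fallback"}, \code{"oracle"}, \code{"adapter"}.
#' @param truth List of \code{BoundingBox} (oracle method).
#' @param adapter Function image -> list of \code{BoundingBox}.
#' @return List of \code{BoundingBox}, confidence-descending.
#' @export
detectNodules <- function(image, confThreshold = 0.25,
                          method = c("fallback", "oracle", "adapter"),
                          truth = NULL, adapter = NULL) {
  method <- match.arg(method)
  if (!is.matrix(image) || length(image) == 0) stop("empty or invalid image")
  if (confThreshold < 0 || confThreshold > 1)
    stop("confThreshold must be in [0, 1]")
  boxes <- switch(method,
    oracle = {
      if (is.null(truth)) stop("oracle detection needs ground-truth boxes")
      lapply(truth, function(b) { b@confidence <- 1; b })
    },
    adapter = {
      if (!is.function(adapter)) stop("adapter must be a function")
      adapter(image)
    },
    fallback = .fallbackDetect(image)
  )
  boxes <- Filter(function(b) b@confidence >= confThreshold, boxes)
  ord <- order(vapply(boxes, function(b) b@confidence, numeric(1)),
               decreasing = TRUE)
  boxes[ord]
}

## deviation-from-background detector. A nodule's dark interior, bright
## halo and posterior column segment into adjacent components, so nearby
## components are merged before boxing; confidence = saturating contrast.
.fallbackDetect <- function(image) {
  H <- nrow(image); W <- ncol(image)
  sm <- .gblur(image, 3)
  bg <- stats::median(sm)
  dev <- abs(sm - bg)
  mask <- dev > 0.28 * bg
  mask <- .gblur(mask * 1, 2) > 0.35         # close small gaps
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0) return(list())
  comps <- list()
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < 80) next                  # speckle flecks
    comps[[length(comps) + 1]] <- list(
      x0 = min(idx[, 2]) - 1, y0 = min(idx[, 1]) - 1,
      x1 = max(idx[, 2]), y1 = max(idx[, 1]),
      strength = sum(dev[idx]), peak = mean(dev[idx]))
  }
  if (!length(comps)) return(list())
  ## merge components whose boxes (padded by 8 px) touch
  touches <- function(a, b, pad = 8)
    a$x0 - pad < b$x1 & b$x0 - pad < a$x1 &
    a$y0 - pad < b$y1 & b$y0 - pad < a$y1
  repeat {
    merged <- FALSE
    for (i in seq_along(comps)) {
      for (j in seq_along(comps)) {
        if (j <= i) next
        if (touches(comps[[i]], comps[[j]])) {
          a <- comps[[i]]; b <- comps[[j]]
          comps[[i]] <- list(x0 = min(a$x0, b$x0), y0 = min(a$y0, b$y0),
                             x1 = max(a$x1, b$x1), y1 = max(a$y1, b$y1),
                             strength = a$strength + b$strength,
                             peak = max(a$peak, b$peak))
          comps[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  boxes <- list()
  for (cp in comps) {
    w <- cp$x1 - cp$x0; h <- cp$y1 - cp$y0
    if (w < 10 || h < 10) next
    ## dilate laterally (threshold erodes weak boundaries) and grow
    ## downward so the (possibly echo-neutral) posterior column is kept
    x0 <- cp$x0 - 4; x1 <- cp$x1 + 4; y0 <- cp$y0 - 4
    y1 <- min(H, cp$y1 + 4 + round(0.3 * h))
    conf <- min(1, cp$peak / (0.5 * bg))
    boxes[[length(boxes) + 1]] <-
      boundingBox(max(0, x0), max(0, y0), min(W, x1), y1, conf)
  }
  boxes
}

#' Standardize an ROI for the descriptor network
#'
#' Crops the box from the image; if the crop's width or height exceeds
#' \code{target}, rescales it by \code{target / max(width, height)},
#' preserving the width-height ratio (which carries the orientation
#' descriptor); smaller crops are never upscaled. The content is then
#' zero-padded to \code{target x target} with the content at the top-left
#' corner. \code{scaleFactor} and \code{padOffsets} are recorded so ROI
#' coordinates (e.g. attention maps) can be mapped back exactly.
#'
#' @param image Numeric matrix (grayscale, 0-255).
#' @param box A \code{BoundingBox} within the image.
#' @param target Standardized side length in pixels (default 450).
#' @return A \code{StandardROI}.
#' @examples
#' img <- matrix(runif(200 * 300, 0, 255), 200, 300)
#' roi <- standardizeROI(img, boundingBox(10, 20, 110, 70), target = 96)
#' dim(roiPixels(roi))
#' @export
standardizeROI <- function(image, box, target = 450L) {
  H <- nrow(image); W <- ncol(image)
  x0 <- max(0, floor(box@x0)); y0 <- max(0, floor(box@y0))
  x1 <- min(W, ceiling(box@x1)); y1 <- min(H, ceiling(box@y1))
  if (x1 - x0 < 2 || y1 - y0 < 2) stop("degenerate box")
  crop <- image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  w <- ncol(crop); h <- nrow(crop)
  if (max(w, h) > target) {
    s <- target / max(w, h)
    newW <- max(1L, round(w * s)); newH <- max(1L, round(h * s))
    crop <- .resizeImage(crop, newW, newH)
  } else s <- 1
  cw <- ncol(crop); ch <- nrow(crop)
  out <- matrix(0, target, target)
  out[seq_len(ch), seq_len(cw)] <- crop
  new("StandardROI", pixels = out, scaleFactor = s,
      padOffsets = c(0, 0), contentSize = c(cw, ch),
      sourceBox = boundingBox(x0, y0, x1, y1, box@confidence))
}

#' Map ROI coordinates back to the source image
#'
#' Inverse of the standardization transform: ROI pixel coordinates (0-based,
#' within the content area) are mapped to source-image coordinates. The
#' realized per-axis scales (content size over source box size) are used,
#' so the rounding of the content area to whole pixels does not leak into
#' the recovered coordinates: the content corners map back exactly onto
#' the source box corners.
#'
#' @param roi A \code{StandardROI}.
#' @param xy Numeric matrix or length-2 vector of (x, y) ROI coordinates.
#' @return Matrix of source-image (x, y) coordinates.
#' @export
roiToImage <- function(roi, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  b <- roi@sourceBox
  sx <- roi@contentSize[1] / (b@x1 - b@x0)
  sy <- roi@contentSize[2] / (b@y1 - b@y0)
  rel <- sweep(xy, 2, roi@padOffsets)
  cbind(rel[, 1] / sx + b@x0, rel[, 2] / sy + b@y0)
}

.iou <- function(a, b) {
  ix <- max(0, min(a@x1, b@x1) - max(a@x0, b@x0))
  iy <- max(0, min(a@y1, b@y1) - max(a@y0, b@y0))
  inter <- ix * iy
  areaA <- (a@x1 - a@x0) * (a@y1 - a@y0)
  areaB <- (b@x1 - b@x0) * (b@y1 - b@y0)
  inter / (areaA + areaB - inter)
}

#' Score detections against ground truth
#'
#' Greedy confidence-ordered matching: predictions are visited in order of
#' decreasing confidence (across all images) and matched to the unmatched
#' ground-truth box of the same image with highest IoU >= the threshold.
#' Precision and recall are computed over all predictions; AP is the area
#' under the interpolated precision-recall curve (precision at each recall
#' level taken as the maximum precision at any higher recall).
#'
#' @param pred Named list (by image id) of lists of predicted
#'   \code{BoundingBox}.
#' @param truth Named list (by image id) of lists of ground-truth boxes.
#' @param iouThreshold IoU required for a match, in (0, 1].
#' @return List with \code{precision}, \code{recall}, \code{ap} (and the
#'   per-prediction match table as \code{matches}). With no predictions,
#'   precision and AP are reported as 0 by convention.
#' @export
evaluateDetection <- function(pred, truth, iouThreshold = 0.5) {
  if (iouThreshold <= 0 || iouThreshold > 1)
    stop("iouThreshold must be in (0, 1]")
  ids <- names(truth)
  if (is.null(ids) || (length(pred) && is.null(names(pred))))
    stop("pred and truth must be named by image id")
  nTruth <- sum(vapply(truth, length, integer(1)))
  flat <- do.call(rbind, lapply(names(pred), function(id) {
    bs <- pred[[id]]
    if (!length(bs)) return(NULL)
    data.frame(id = id, j = seq_along(bs),
               conf = vapply(bs, function(b) b@confidence, numeric(1)))
  }))
  if (is.null(flat) || nrow(flat) == 0)
    return(list(precision = 0, recall = 0, ap = 0,
                matches = data.frame()))
  flat <- flat[order(-flat$conf), , drop = FALSE]
  used <- lapply(truth, function(t) rep(FALSE, length(t)))
  tp <- logical(nrow(flat))
  for (i in seq_len(nrow(flat))) {
    id <- flat$id[i]
    tb <- truth[[id]]
    if (is.null(tb) || !length(tb)) next
    ious <- vapply(seq_along(tb), function(k)
      if (used[[id]][k]) -1 else .iou(pred[[id]][[flat$j[i]]], tb[[k]]),
      numeric(1))
    best <- which.max(ious)
    if (length(best) && ious[best] >= iouThreshold) {
      tp[i] <- TRUE
      used[[id]][best] <- TRUE
    }
  }
  cumTP <- cumsum(tp); cumFP <- cumsum(!tp)
  prec <- cumTP / (cumTP + cumFP)
  rec <- if (nTruth > 0) cumTP / nTruth else rep(0, length(cumTP))
  ## interpolated AP over all points
  ap <- 0
  if (nTruth > 0) {
    mrec <- c(0, rec, rec[length(rec)])
    mpre <- c(0, prec, 0)
    for (i in rev(seq_len(length(mpre) - 1)))
      mpre[i] <- max(mpre[i], mpre[i + 1])
    drops <- which(diff(mrec) > 0)
    ap <- sum((mrec[drops + 1] - mrec[drops]) * mpre[drops + 1])
  }
  list(precision = prec[length(prec)],
       recall = rec[length(rec)],
       ap = ap,
       matches = cbind(flat, tp = tp))
}
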