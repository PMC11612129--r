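## dedup module: scale-invariant near-duplicate detection. A compact SIFT-
## style pipeline: difference-of-Gaussian keypoints over an octave pyramid,
## orientation-normalized gradient-histogram descriptors, nearest-neighbor
## matching with Lowe's ratio test, and similarity-transform RANSAC
## verification. Zoomed/rotated copies of the same acquisition match with
## many geometric inliers; different acquisitions of the same nodule (new
## speckle realization) do not — by design, matching the behavior of SIFT
## dataset cleaning.

## shift a matrix by (dy, dx), zero fill
.shift2 <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(-Inf, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

## local 3x3 neighborhood max/min (excluding center)
.neigh8 <- function(m, op) {
  acc <- NULL
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    s <- .shift2(m, dy, dx)
    acc <- if (is.null(acc)) s else op(acc, s)
  }
  acc
}

#' Detect scale-invariant keypoints and descriptors
#'
#' Difference-of-Gaussian extrema over an octave pyramid with contrast and
#' edge-response filtering, dominant gradient orientation per keypoint, and
#' a 4x4x8 orientation-normalized gradient-histogram descriptor (L2
#' normalized, clipped at 0.2, renormalized). Deterministic.
#'
#' @param image Grayscale matrix (0-255).
#' @param nOctaves Pyramid octaves (image halved per octave).
#' @param scales Scales per octave.
#' @param sigma0 Base smoothing scale in pixels.
#' @param contrast Minimum |DoG| response (on a 0-1 intensity scale).
#' @param maxKeypoints Keep at most this many strongest keypoints.
#' @return List with \code{xy} (n x 2 keypoint coordinates, original image
#'   pixels), \code{scale}, \code{angle}, and \code{desc} (n x 128 matrix).
#' @export
siftFeatures <- function(image, nOctaves = 4, scales = 3, sigma0 = 1.6,
                         contrast = 0.003, maxKeypoints = 300) {
  img <- image / 255
  kps <- list()
  base <- .gblur(img, 0.8)
  for (oct in seq_len(nOctaves) - 1L) {
    H <- nrow(base); W <- ncol(base)
    if (min(H, W) < 24) break
    k <- 2^(1 / scales)
    nLev <- scales + 3
    gs <- vector("list", nLev)
    gs[[1]] <- .gblur(base, sigma0)
    for (s in 2:nLev) {
      sigPrev <- sigma0 * k^(s - 2); sigCur <- sigma0 * k^(s - 1)
      gs[[s]] <- .gblur(gs[[s - 1]], sqrt(sigCur^2 - sigPrev^2))
    }
    dog <- lapply(seq_len(nLev - 1), function(s) gs[[s + 1]] - gs[[s]])
    for (s in 2:(nLev - 2)) {
      d <- dog[[s]]
      up <- dog[[s + 1]]; dn <- dog[[s - 1]]
      ## extremum among the 8 spatial neighbors and the same pixel of the
      ## adjacent DoG levels (center-only in scale: speckle-scale levels
      ## are strongly correlated, the full 26-neighbor test starves the
      ## detector on fine texture)
      isMax <- d > .neigh8(d, pmax) & d > up & d > dn & d > contrast
      nmin <- function(m) { x <- .neigh8(-m, pmax); -x }
      isMin <- d < nmin(d) & d < up & d < dn & d < -contrast
      cand <- which((isMax | isMin), arr.ind = TRUE)
      if (!nrow(cand)) next
      keep <- cand[, 1] > 8 & cand[, 1] < H - 8 & cand[, 2] > 8 &
              cand[, 2] < W - 8
      cand <- cand[keep, , drop = FALSE]
      if (!nrow(cand)) next
      ## edge response: Hessian trace^2 / det threshold (r = 10)
      dxx <- .shift2(d, 0, -1) + .shift2(d, 0, 1) - 2 * d
      dyy <- .shift2(d, -1, 0) + .shift2(d, 1, 0) - 2 * d
      dxy <- (.shift2(d, -1, -1) + .shift2(d, 1, 1) -
              .shift2(d, -1, 1) - .shift2(d, 1, -1)) / 4
      tr <- dxx[cand] + dyy[cand]
      det <- dxx[cand] * dyy[cand] - dxy[cand]^2
      edgeOK <- det > 0 & tr^2 / det < (11^2) / 10
      cand <- cand[edgeOK, , drop = FALSE]
      if (!nrow(cand)) next
      sig <- sigma0 * k^(s - 1)
      gimg <- gs[[s]]
      kps[[length(kps) + 1]] <- data.frame(
        y = (cand[, 1] - 0.5) * 2^oct, x = (cand[, 2] - 0.5) * 2^oct,
        octave = oct, level = s, scale = sig * 2^oct,
        response = abs(d[cand]))
    }
    base <- base[seq(1, H, by = 2), seq(1, W, by = 2)]
  }
  if (!length(kps))
    return(list(xy = matrix(0, 0, 2), scale = numeric(), angle = numeric(),
                desc = matrix(0, 0, 128)))
  kp <- do.call(rbind, kps)
  kp <- kp[order(-kp$response), , drop = FALSE]
  if (nrow(kp) > maxKeypoints) kp <- kp[seq_len(maxKeypoints), ]

  ## gradients of the smoothed image at original resolution
  sm <- .gblur(img, sigma0)
  H <- nrow(sm); W <- ncol(sm)
  gx <- (cbind(sm[, -1], sm[, W]) - cbind(sm[, 1], sm[, -W])) / 2
  gy <- (rbind(sm[-1, ], sm[H, ]) - rbind(sm[1, ], sm[-H, ])) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)

  out <- lapply(seq_len(nrow(kp)), function(i)
    .describeKeypoint(kp[i, ], mag, ang))
  rep_i <- rep(seq_len(nrow(kp)), vapply(out, length, integer(1)))
  out <- do.call(c, out)
  kp <- kp[rep_i, , drop = FALSE]
  if (!length(out))
    return(list(xy = matrix(0, 0, 2), scale = numeric(), angle = numeric(),
                desc = matrix(0, 0, 128)))
  list(xy = cbind(kp$x, kp$y), scale = kp$scale,
       angle = vapply(out, `[[`, numeric(1), "angle"),
       desc = do.call(rbind, lapply(out, `[[`, "desc")))
}

## orientation assignment + 4x4x8 descriptors for one keypoint; returns a
## list with one element per dominant orientation (up to 2 peaks >= 0.8 of
## the histogram maximum), possibly empty
.describeKeypoint <- function(kp, mag, ang) {
  H <- nrow(mag); W <- ncol(mag)
  r <- min(24, max(4, round(4 * kp$scale)))
  y0 <- round(kp$y + 0.5); x0 <- round(kp$x + 0.5)
  ys <- max(1, y0 - r):min(H, y0 + r)
  xs <- max(1, x0 - r):min(W, x0 + r)
  m <- mag[ys, xs]; a <- ang[ys, xs]
  dy <- outer(ys - kp$y, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - kp$x)
  wgt <- exp(-(dx^2 + dy^2) / (2 * (1.5 * kp$scale * 2)^2))
  bins <- floor(((a + pi) / (2 * pi)) * 36) %% 36
  hist <- vapply(0:35, function(b) sum(m[bins == b] * wgt[bins == b]),
                 numeric(1))
  hist <- (hist + c(hist[-1], hist[1]) + c(hist[36], hist[-36])) / 3
  peaks <- which(hist >= 0.8 * max(hist) &
                 hist >= c(hist[36], hist[-36]) &
                 hist > c(hist[-1], hist[1]))
  if (!length(peaks)) peaks <- which.max(hist)
  peaks <- peaks[order(-hist[peaks])][seq_len(min(2, length(peaks)))]

  grid <- as.matrix(expand.grid(gy = seq(-7.5, 7.5), gx = seq(-7.5, 7.5)))
  sp <- kp$scale
  out <- lapply(peaks, function(pk) {
    theta <- (pk - 0.5) / 36 * 2 * pi - pi
    rx <- (grid[, "gx"] * cos(theta) - grid[, "gy"] * sin(theta)) * sp
    ry <- (grid[, "gx"] * sin(theta) + grid[, "gy"] * cos(theta)) * sp
    xi <- round(kp$x + rx + 0.5); yi <- round(kp$y + ry + 0.5)
    ok <- xi >= 1 & xi <= W & yi >= 1 & yi <= H
    if (mean(ok) < 0.8) return(NULL)
    sm <- cbind(yi[ok], xi[ok])
    mV <- mag[sm]; aV <- (ang[sm] - theta + 2 * pi) %% (2 * pi)
    wV <- exp(-(grid[ok, "gx"]^2 + grid[ok, "gy"]^2) / (2 * 6^2))
    cellX <- pmin(3, pmax(0, floor((grid[ok, "gx"] + 8) / 4)))
    cellY <- pmin(3, pmax(0, floor((grid[ok, "gy"] + 8) / 4)))
    ob <- floor(aV / (2 * pi) * 8) %% 8
    idx <- cellY * 32 + cellX * 8 + ob + 1
    desc <- numeric(128)
    acc <- tapply(mV * wV, idx, sum)
    desc[as.integer(names(acc))] <- acc
    nrm <- sqrt(sum(desc^2))
    if (nrm < 1e-9) return(NULL)
    desc <- pmin(desc / nrm, 0.2)
    list(angle = theta, desc = desc / sqrt(sum(desc^2)))
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Match two images for near-duplication
#'
#' Extracts scale-invariant features from both images, finds
#' nearest-neighbor descriptor matches filtered by the ratio test, and
#' verifies them with a RANSAC similarity transform
#' (rotation + scale + translation, the transform class of zoomed/rotated
#' copies). The pair is a duplicate iff the best transform explains at
#' least \code{minInliers} matches. Symmetric in its arguments.
#'
#' @param imgA,imgB Grayscale matrices (0-255), or precomputed feature
#'   lists from \code{\link{siftFeatures}}.
#' @param ratio Lowe ratio-test threshold (default 0.75).
#' @param minInliers Geometric inlier count required (default 25).
#' @return List: \code{is_duplicate}, \code{matches} (ratio-test matches),
#'   \code{inliers}, \code{transform} (a, b complex similarity parameters
#'   or NULL).
#' @export
matchPair <- function(imgA, imgB, ratio = 0.75, minInliers = 25) {
  fA <- if (is.matrix(imgA)) siftFeatures(imgA) else imgA
  fB <- if (is.matrix(imgB)) siftFeatures(imgB) else imgB
  ## canonical orientation (fewer keypoints queried against more) makes the
  ## result exactly symmetric in (a, b)
  if (nrow(fA$desc) > nrow(fB$desc) ||
      (nrow(fA$desc) == nrow(fB$desc) && sum(fA$desc) > sum(fB$desc))) {
    tmp <- fA; fA <- fB; fB <- tmp
  }
  if (nrow(fA$desc) == 0 || nrow(fB$desc) == 0) {
    warning("featureless image; reported as not duplicate")
    return(list(is_duplicate = FALSE, matches = 0L, inliers = 0L,
                transform = NULL))
  }
  ## squared descriptor distances
  d2 <- outer(rowSums(fA$desc^2), rowSums(fB$desc^2), "+") -
        2 * tcrossprod(fA$desc, fB$desc)
  d2 <- pmax(d2, 0)
  ## nearest neighbor + ratio test; the second-best distance is taken from
  ## a keypoint at a different location (dual-orientation descriptors of
  ## the same point must not defeat the ratio test)
  nn <- t(apply(d2, 1, function(r) {
    o <- order(r)
    bestXY <- fB$xy[o[1], ]
    second <- o[which(abs(fB$xy[o, 1] - bestXY[1]) +
                      abs(fB$xy[o, 2] - bestXY[2]) > 2)[1]]
    c(o[1], r[o[1]], if (is.na(second)) Inf else r[second])
  }))
  pass <- nn[, 2] < ratio^2 * nn[, 3]
  mi <- which(pass)
  if (length(mi) >= 2) {
    ## collapse duplicate correspondences (same point pair under two
    ## orientation hypotheses)
    key <- paste(round(fA$xy[mi, 1]), round(fA$xy[mi, 2]),
                 round(fB$xy[nn[mi, 1], 1]), round(fB$xy[nn[mi, 1], 2]))
    mi <- mi[!duplicated(key)]
  }
  if (length(mi) < 3)
    return(list(is_duplicate = FALSE, matches = length(mi), inliers = 0L,
                transform = NULL))
  pa <- complex(real = fA$xy[mi, 1], imaginary = fA$xy[mi, 2])
  pb <- complex(real = fB$xy[nn[mi, 1], 1], imaginary = fB$xy[nn[mi, 1], 2])

  ## RANSAC: similarity z -> a z + b from 2 point pairs
  best <- list(count = 0L, inl = integer(), a = NULL, b = NULL)
  nM <- length(pa)
  tol <- 3
  .withSeed(20011017L, {
    for (it in seq_len(600)) {
      pick <- sample.int(nM, 2)
      dz <- pa[pick[2]] - pa[pick[1]]
      if (Mod(dz) < 1e-9) next
      a <- (pb[pick[2]] - pb[pick[1]]) / dz
      if (Mod(a) < 0.5 || Mod(a) > 2) next   # plausible zoom range
      b <- pb[pick[1]] - a * pa[pick[1]]
      err <- Mod(a * pa + b - pb)
      inl <- which(err < tol)
      if (length(inl) > best$count)
        best <- list(count = length(inl), inl = inl, a = a, b = b)
    }
  })
  if (best$count >= 3) {   # least-squares refit on the consensus set
    A <- cbind(pa[best$inl], 1)
    sol <- qr.solve(A, pb[best$inl])
    err <- Mod(sol[1] * pa + sol[2] - pb)
    best$inl <- which(err < tol)
    best$count <- length(best$inl)
    best$a <- sol[1]; best$b <- sol[2]
  }
  list(is_duplicate = best$count >= minInliers,
       matches = nM, inliers = best$count,
       transform = if (best$count >= minInliers)
         list(a = best$a, b = best$b) else NULL)
}

#' Find duplicate clusters in a dataset
#'
#' Runs pairwise near-duplicate matching over all images of a manifest and
#' returns the connected components of the duplicate graph as
#' \code{DuplicateCluster} objects; images in no cluster are unique.
#'
#' @param manifest Manifest data.frame (attribute \code{"dir"} locating the
#'   PNGs).
#' @param ratio,minInliers Matching thresholds, see \code{\link{matchPair}}.
#' @param dir Image directory.
#' @return List of \code{DuplicateCluster}.
#' @export
findDuplicates <- function(manifest, ratio = 0.75, minInliers = 25,
                           dir = attr(manifest, "dir")) {
  n <- nrow(manifest)
  if (n < 2) stop("need at least 2 images")
  feats <- lapply(seq_len(n), function(i)
    siftFeatures(readGrayPNG(file.path(dir, manifest$file[i]))))
  ids <- manifest$image_id
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mm <- matchPair(feats[[i]], feats[[j]], ratio = ratio,
                      minInliers = minInliers)
      if (mm$is_duplicate)
        edges[[length(edges) + 1]] <-
          data.frame(id_a = ids[i], id_b = ids[j],
                     matches = mm$matches, inliers = mm$inliers)
    }
  }
  if (!length(edges)) return(list())
  ev <- do.call(rbind, edges)
  ## connected components by label propagation
  comp <- setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(ev))) {
      a <- ev$id_a[r]; b <- ev$id_b[r]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  inCluster <- names(comp)[comp %in% comp[c(ev$id_a, ev$id_b)]]
  lab <- ifelse(manifest$malignant, "malignant", "benign")
  names(lab) <- ids
  lapply(unique(comp[inCluster]), function(cid) {
    members <- sort(names(comp)[comp == cid])
    labs <- sort(unique(lab[members]))
    new("DuplicateCluster", members = members,
        evidence = ev[ev$id_a %in% members | ev$id_b %in% members, ],
        labels = unname(labs), conflict = length(labs) > 1,
        representative = members[1])
  })
}

#' Duplicate conflict report and discard policy
#'
#' Flags clusters whose members carry more than one malignancy label, and
#' counts the images to discard: for clean clusters one representative is
#' kept and the rest dropped; conflicted clusters are dropped entirely
#' (their label cannot be trusted) unless \code{dropConflicted = FALSE},
#' in which case they too keep one representative.
#'
#' @param clusters List of \code{DuplicateCluster} from
#'   \code{\link{findDuplicates}}.
#' @param manifest Manifest with the malignancy labels.
#' @param dropConflicted Drop conflicted clusters entirely (default TRUE).
#' @return List with \code{table} (data.frame: cluster, members, labels,
#'   conflict, action), \code{n_conflicted}, \code{discard} (image ids to
#'   drop), \code{n_discard}.
#' @export
conflictReport <- function(clusters, manifest, dropConflicted = TRUE) {
  lab <- setNames(ifelse(manifest$malignant, "malignant", "benign"),
                  manifest$image_id)
  rows <- list(); discard <- character()
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    if (any(!cl@members %in% names(lab)))
      stop("missing label for cluster member(s): ",
           paste(setdiff(cl@members, names(lab)), collapse = ", "))
    if (cl@conflict && dropConflicted) {
      action <- "drop all"
      discard <- c(discard, cl@members)
    } else {
      action <- paste("keep", cl@representative)
      discard <- c(discard, setdiff(cl@members, cl@representative))
    }
    rows[[i]] <- data.frame(
      cluster = i, members = paste(cl@members, collapse = ";"),
      labels = paste(cl@labels, collapse = ";"),
      conflict = cl@conflict, action = action)
  }
  list(table = if (length(rows)) do.call(rbind, rows) else data.frame(),
       n_conflicted = sum(vapply(clusters, function(c) c@conflict,
                                 logical(1))),
       discard = discard, n_discard = length(discard))
}

#' Write a duplicate report CSV
#'
#' @param report Output of \code{\link{conflictReport}}.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
writeDedupReport <- function(report, path) {
  write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
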