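## phantom module: synthetic speckle-textured ultrasound-like images with
## nodules of known BI-RADS descriptors, ground-truth boxes, and optional
## planted near-duplicates.

#' Deterministic suggestivity pattern
#'
#' Maps the other six descriptors to the tumor-type suggestivity used by the
#' phantom generator. The mapping is deterministic so the synthetic
#' description task is fully separable: a nodule's suggestivity can always
#' be inferred from its rendered appearance.
#'
#' @param values Named character vector with shape, margin, orientation,
#'   echogenicity, posterior, halo.
#' @return One of \code{simple_cyst}, \code{complex_cyst},
#'   \code{fibroadenoma}, \code{no_clear_suggestivity}.
#' @keywords internal
.suggestivityPattern <- function(values) {
  v <- as.list(values)
  roundish <- v$shape %in% c("oval", "round")
  if (v$echogenicity == "anechoic" && v$margin == "circumscribed" &&
      v$posterior == "enhancement" && v$halo == "absent" && roundish)
    return("simple_cyst")
  if (v$echogenicity == "heterogeneous" && v$margin == "circumscribed" &&
      v$posterior != "shadowing" && v$halo == "absent" && roundish)
    return("complex_cyst")
  if (v$echogenicity == "hypoechoic" && v$shape == "oval" &&
      v$margin == "circumscribed" && v$orientation == "parallel" &&
      v$posterior == "none" && v$halo == "absent")
    return("fibroadenoma")
  "no_clear_suggestivity"
}

#' Derive the BI-RADS category from descriptor values
#'
#' Deterministic generative labeling table of the phantom module. Hard
#' rules first: a simple cyst is category 2, a complex cyst 4A, and a
#' spiculated margin 5 (spiculated wins on conflict). Otherwise the
#' category grows monotonically with the number of suspicious features
#' among \{irregular shape, microlobulated margin, anti-parallel
#' orientation, posterior shadowing, halo present\}:
#'
#' \tabular{ll}{
#'   suspicious count 0 \tab 3 (2 for a fibroadenoma) \cr
#'   1 \tab 4A \cr
#'   2 \tab 4B \cr
#'   3 \tab 4C \cr
#'   4 or more \tab 5
#' }
#'
#' @param x A \code{PhantomSpec}, a \code{DescriptorSet}, or a named
#'   character vector of descriptor values.
#' @return Character scalar in \code{2,3,4A,4B,4C,5}.
#' @examples
#' deriveBirads(c(shape = "oval", margin = "circumscribed",
#'   orientation = "parallel", echogenicity = "hypoechoic",
#'   posterior = "none", halo = "absent", suggestivity = "fibroadenoma"))
#' @export
deriveBirads <- function(x) {
  if (is(x, "PhantomSpec") || is(x, "DescriptorSet")) x <- descriptorValues(x)
  v <- as.list(x)
  if (v$margin == "spiculated") return("5")
  if (v$suggestivity == "simple_cyst") return("2")
  if (v$suggestivity == "complex_cyst") return("4A")
  k <- sum(v$shape == "irregular", v$margin == "microlobulated",
           v$orientation == "anti_parallel", v$posterior == "shadowing",
           v$halo == "present")
  if (k == 0) return(if (v$suggestivity == "fibroadenoma") "2" else "3")
  if (k >= 4) "5" else c("4A", "4B", "4C")[k]
}

## extent of the rendered nodule beyond the nominal ellipse, as a fraction
## of the semi-axes (boundary perturbation + spikes + halo + margin blur)
.extentFraction <- function(spec, ph) {
  frac <- 1
  if (spec@shape == "irregular") frac <- frac + ph$irregular_amp[2]
  if (spec@margin == "microlobulated") frac <- frac + ph$lobe_amp
  if (spec@margin == "spiculated") frac <- frac + ph$spike_len[2]
  if (spec@halo == "present")
    frac <- frac + ph$halo_width / min(spec@semiAxes)
  if (spec@margin == "indistinct")
    frac <- frac + 2 * ph$indistinct_sigma / min(spec@semiAxes)
  frac + 2 / min(spec@semiAxes)   # 2 px guard band
}

## half-extent (hw, hh) in pixels of the rotated, perturbed nodule
.nodExtent <- function(spec, ph) {
  f <- .extentFraction(spec, ph)
  A <- spec@semiAxes[1] * f; B <- spec@semiAxes[2] * f
  phi <- spec@rotation
  c(hw = sqrt((A * cos(phi))^2 + (B * sin(phi))^2),
    hh = sqrt((A * sin(phi))^2 + (B * cos(phi))^2))
}

#' Sample a phantom specification
#'
#' Draws one synthetic nodule specification from the configured descriptor
#' priors. Sampling is seed-deterministic and enforces the structural
#' invariants: suggestivity is drawn first and, when it names a special-case
#' tumor type, the remaining descriptors are constrained to its pattern
#' (see \code{\link{.suggestivityPattern}}); a round shape forces
#' orientation \code{"none"} and a near-unit axis ratio; the BI-RADS
#' category and malignancy flag follow \code{\link{deriveBirads}}
#' (malignant iff 4B or higher).
#'
#' @param seed Integer RNG seed; identical seeds give identical specs.
#' @param weights Named list of per-descriptor probability tables (each
#'   non-negative, summing to 1); defaults from
#'   \code{pipelineConfig()$phantom$weights}.
#' @param config A \code{\link{pipelineConfig}}.
#' @return A \code{PhantomSpec}.
#' @examples
#' samplePhantomSpec(7)
#' @export
samplePhantomSpec <- function(seed, weights = NULL,
                              config = pipelineConfig()) {
  ph <- config$phantom
  if (!is.null(weights)) ph$weights[names(weights)] <- weights
  w <- ph$weights
  voc <- config$vocab
  .withSeed(seed, {
    sugg <- .sampleCat(voc$suggestivity, w$suggestivity)
    vals <- NULL
    for (try in 1:50) {
      cand <- list(
        shape = .sampleCat(voc$shape, w$shape),
        margin = .sampleCat(voc$margin, w$margin),
        echogenicity = .sampleCat(voc$echogenicity, w$echogenicity),
        posterior = .sampleCat(voc$posterior, w$posterior),
        halo = .sampleCat(voc$halo, w$halo)
      )
      if (sugg == "simple_cyst") {
        cand$shape <- .sampleCat(c("oval", "round"),
                                 .renorm(w$shape[c("oval", "round")]))
        cand$margin <- "circumscribed"; cand$echogenicity <- "anechoic"
        cand$posterior <- "enhancement"; cand$halo <- "absent"
      } else if (sugg == "complex_cyst") {
        cand$shape <- .sampleCat(c("oval", "round"),
                                 .renorm(w$shape[c("oval", "round")]))
        cand$margin <- "circumscribed"; cand$echogenicity <- "heterogeneous"
        cand$posterior <- .sampleCat(c("none", "enhancement"),
                                     .renorm(w$posterior[c("none", "enhancement")]))
        cand$halo <- "absent"
      } else if (sugg == "fibroadenoma") {
        cand$shape <- "oval"; cand$margin <- "circumscribed"
        cand$echogenicity <- "hypoechoic"; cand$posterior <- "none"
        cand$halo <- "absent"
      }
      ## a spiculated mass is, by lexicon convention, irregular in shape:
      ## spikes make the silhouette non-oval, and readers describe such
      ## masses as irregular. Enforced by rejection over the joint draw so
      ## user-forced shape weights keep their meaning.
      if (cand$margin == "spiculated" && cand$shape != "irregular") next
      cand$orientation <- if (cand$shape == "round") "none"
        else if (sugg == "fibroadenoma") "parallel"
        else .sampleCat(c("parallel", "anti_parallel"), w$orientation)
      if (.suggestivityPattern(unlist(cand)) == sugg) { vals <- cand; break }
      ## free draw collided with a special-case pattern: redraw
    }
    if (is.null(vals))
      stop("could not draw a coherent descriptor combination (suggestivity '",
           sugg, "') under the given weights")

    ratio <- if (vals$shape == "round") runif(1, ph$aspect_round[1], ph$aspect_round[2])
             else runif(1, ph$aspect_elongated[1], ph$aspect_elongated[2])
    major <- runif(1, ph$semi_axis_range[1], ph$semi_axis_range[2])
    semi <- switch(vals$orientation,
      parallel = c(major, major / ratio),
      anti_parallel = c(major / ratio, major),
      none = c(major, major / ratio))      # round: ratio ~ 1
    rot <- runif(1, -0.08, 0.08)
    bg <- runif(1, ph$background_range[1], ph$background_range[2])

    vals$suggestivity <- sugg
    birads <- deriveBirads(unlist(vals))
    spec <- new("PhantomSpec",
      shape = vals$shape, margin = vals$margin,
      orientation = vals$orientation, echogenicity = vals$echogenicity,
      posterior = vals$posterior, halo = vals$halo,
      suggestivity = sugg, malignant = birads %in% c("4B", "4C", "5"),
      center = c(0, 0), semiAxes = semi, rotation = rot,
      backgroundMean = bg, seed = as.integer(seed))

    ## place the nodule so that body + posterior column fit the canvas
    W <- ph$canvas[1]; H <- ph$canvas[2]
    for (i in 1:8) {
      ext <- .nodExtent(spec, ph)
      depth <- ph$posterior_depth * ext["hh"]
      if (2 * ext["hw"] + 5 <= W && ext["hh"] + depth + 5 <= H - ext["hh"])
        break
      spec@semiAxes <- spec@semiAxes * 0.85
    }
    ext <- .nodExtent(spec, ph)
    depth <- ph$posterior_depth * ext["hh"]
    cx <- runif(1, ext["hw"] + 2, W - ext["hw"] - 2)
    cy <- runif(1, ext["hh"] + 2, H - ext["hh"] - depth - 2)
    spec@center <- c(cx, cy)
    validObject(spec)
    spec
  })
}

.renorm <- function(w) w / sum(w)

#' Render a phantom image
#'
#' Renders the nodule described by a \code{PhantomSpec} on a multiplicative
#' Rayleigh-speckle background and returns the image together with the tight
#' ground-truth box. Rendering semantics: interior intensity is ordered
#' anechoic < hypoechoic < isoechoic (= background) < hyperechoic, with
#' heterogeneous a coarse two-level patchwork; a circumscribed margin shows
#' a sharp edge with a thin dark capsule rim, indistinct a Gaussian-blurred
#' edge, microlobulated a lobed boundary, spiculated radial spikes; the
#' column below the nodule is brightened (posterior enhancement) or darkened
#' (shadowing); an echogenic halo is a bright ring around the boundary. The
#' box encloses the nodule, its spikes and halo, and the posterior column,
#' so that posterior features survive ROI cropping.
#'
#' @param spec A \code{PhantomSpec}.
#' @param canvas Integer length-2, canvas (width, height); default from
#'   \code{config$phantom$canvas}.
#' @param config A \code{\link{pipelineConfig}}.
#' @param extraInfo If \code{TRUE}, burn a bright marker overlay into the
#'   image (the "extra information" that motivates excluding such images
#'   from validation).
#' @return List with \code{image} (H x W numeric matrix, 0-255) and
#'   \code{box} (a \code{BoundingBox}).
#' @examples
#' p <- renderPhantom(samplePhantomSpec(1))
#' dim(p$image)
#' @export
renderPhantom <- function(spec, canvas = NULL, config = pipelineConfig(),
                          extraInfo = FALSE) {
  ph <- config$phantom
  if (is.null(canvas)) canvas <- ph$canvas
  W <- as.integer(canvas[1]); H <- as.integer(canvas[2])
  ext <- .nodExtent(spec, ph)
  if (spec@center[1] - ext["hw"] < 0 || spec@center[1] + ext["hw"] > W ||
      spec@center[2] - ext["hh"] < 0 || spec@center[2] + ext["hh"] > H)
    stop("nodule (with spikes/halo) exceeds the canvas")

  .withSeed(spec@seed, {
    xs <- matrix(rep(seq_len(W) - 0.5, each = H), nrow = H)  # x coord per px
    ys <- matrix(rep(seq_len(H) - 0.5, times = W), nrow = H) # y coord per px
    dx <- xs - spec@center[1]; dy <- ys - spec@center[2]
    phi <- spec@rotation
    u <- dx * cos(phi) + dy * sin(phi)
    vv <- -dx * sin(phi) + dy * cos(phi)
    a <- spec@semiAxes[1]; b <- spec@semiAxes[2]
    r <- sqrt((u / a)^2 + (vv / b)^2)       # elliptical radius
    theta <- atan2(vv / b, u / a)

    ## boundary radius 1 + g(theta)
    g <- 0
    if (spec@shape == "irregular") {
      k <- sample(seq(ph$irregular_count[1], ph$irregular_count[2]), 1)
      amp <- runif(1, ph$irregular_amp[1], ph$irregular_amp[2])
      ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
      g <- amp * (0.7 * cos(k * theta + ph1) + 0.3 * cos((k + 1) * theta + ph2))
    }
    if (spec@margin == "microlobulated") {
      nl <- sample(seq(ph$lobe_count[1], ph$lobe_count[2]), 1)
      g <- g + ph$lobe_amp * cos(nl * theta + runif(1, 0, 2 * pi))
    }
    bound <- 1 + g
    inside <- r <= bound

    ## interior multiplier
    lev <- ph$echo_levels[[spec@echogenicity]]
    if (spec@echogenicity == "heterogeneous") {
      coarse <- matrix(rnorm(ceiling(H / 8) * ceiling(W / 8)),
                       nrow = ceiling(H / 8))
      field <- .resizeImage(coarse, W, H)
      field <- .gblur(field, 2)
      ## split at the within-nodule median so both patch levels are always
      ## present (otherwise a mostly-dark draw mimics a hypoechoic nodule)
      lev <- ifelse(field > stats::median(field[inside]),
                    ph$hetero_levels[2], ph$hetero_levels[1])
    }
    M <- matrix(1, H, W)
    M[inside] <- if (length(lev) == 1) lev else lev[inside]

    ## capsule rim on circumscribed margins (visible edge even when
    ## isoechoic, as a real capsule is)
    if (spec@margin %in% c("circumscribed")) {
      rim <- r <= bound & r > bound - 2.2 / min(a, b)
      M[rim] <- ph$capsule_gain
    }

    ## indistinct margin: blur the interior/boundary transition before any
    ## halo is drawn, so the ring cue stays crisp when both are present
    if (spec@margin == "indistinct") M <- .gblur(M, ph$indistinct_sigma)

    ## spiculated margin: radial spikes at the interior level
    if (spec@margin == "spiculated") {
      ns <- sample(seq(ph$spike_count[1], ph$spike_count[2]), 1)
      ang <- sort(runif(ns, -pi, pi))
      lens <- runif(ns, ph$spike_len[1], ph$spike_len[2])
      spikeLev <- if (spec@echogenicity == "heterogeneous")
        ph$hetero_levels[1] else min(ph$echo_levels[[spec@echogenicity]], 0.5)
      for (s in seq_len(ns)) {
        dang <- abs(((theta - ang[s] + pi) %% (2 * pi)) - pi)
        ## angular width shrinking with radius: spikes ~4 px wide
        sel <- r > bound & r <= bound + lens[s] & dang < 2.0 / pmax(r * min(a, b), 1)
        M[sel] <- spikeLev
      }
    }

    ## echogenic halo: bright ring just outside the boundary, drawn last so
    ## margin effects (blur, spikes) never erase the ring cue
    if (spec@halo == "present") {
      hw <- ph$halo_width / min(a, b)
      ring <- r > bound & r <= bound + hw
      M[ring] <- ph$halo_gain
    }

    ## posterior column under the nodule
    gain <- ph$posterior_gain[[spec@posterior]]
    extv <- .nodExtent(spec, ph)
    depth <- ph$posterior_depth * extv["hh"]
    yBot <- spec@center[2] + extv["hh"]
    if (gain != 1) {
      halfw <- 0.8 * extv["hw"]
      colSel <- abs(dx) <= halfw & ys > yBot - 2 & ys <= yBot + depth
      taper <- 1 - 0.5 * (abs(dx) / halfw)^4
      Mp <- matrix(1, H, W)
      Mp[colSel] <- 1 + (gain - 1) * taper[colSel]
      Mp <- .gblur(Mp, 1.5)
      M <- M * Mp
    }

    ## multiplicative Rayleigh speckle with unit mean, lightly correlated;
    ## the fluctuation amplitude is scaled so the granular texture reads as
    ## (compounded) envelope speckle without drowning boundary detail
    sigma <- sqrt(2 / pi)
    speckle <- sigma * sqrt(-2 * log(runif(H * W)))
    speckle <- matrix(speckle, H, W)
    speckle <- .gblur(speckle, 0.8)
    speckle <- 1 + ph$speckle_contrast * (speckle / mean(speckle) - 1)

    img <- spec@backgroundMean * M * speckle
    if (extraInfo) img <- .burnMarker(img)
    img <- pmin(pmax(img, 0), 255)

    ## tight ground-truth box: nodule extent plus the posterior column
    x0 <- max(0, floor(spec@center[1] - extv["hw"]))
    x1 <- min(W, ceiling(spec@center[1] + extv["hw"]))
    y0 <- max(0, floor(spec@center[2] - extv["hh"]))
    y1 <- min(H, ceiling(yBot + depth))
    list(image = img, box = boundingBox(x0, y0, x1, y1, 1))
  })
}

## bright caliper-style marker burned into extra-information images
.burnMarker <- function(img) {
  H <- nrow(img); W <- ncol(img)
  img[3:6, 3:18] <- 250
  img[3:18, 3:6] <- 250
  img[seq(5, H - 4, by = 6), W - 4] <- 250
  img
}

#' Write a synthetic phantom dataset to disk
#'
#' Generates \code{n} phantom images with ground truth and writes, under
#' \code{outDir}: one 8-bit grayscale PNG and one normalized box text file
#' per image (lines \code{"0 cx cy w h"} in [0,1], the common one-stage
#' detector dialect), a \code{labels.csv} with one row per image, and a
#' \code{manifest.json} recording per-image seeds, descriptor ground truth,
#' pixel boxes and the \code{extra_info} flag. Images flagged
#' \code{extra_info} carry burned-in markers and are excluded from
#' validation folds by \code{\link{makeFolds}}.
#'
#' @param n Number of images (>= 1).
#' @param seed Master seed; the manifest is a pure function of (n, seed).
#' @param outDir Output directory (created if needed).
#' @param config A \code{\link{pipelineConfig}}.
#' @param weights Optional descriptor prior overrides (see
#'   \code{\link{samplePhantomSpec}}).
#' @return The manifest as a data.frame (invisibly also written to JSON).
#' @export
makeDataset <- function(n, seed, outDir, config = pipelineConfig(),
                        weights = NULL) {
  stopifnot(n >= 1)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outDir)
  ph <- config$phantom
  seeds <- .seedStream(seed, n)
  flags <- .withSeed(seed + 1L, runif(n) < ph$extra_info_frac)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- samplePhantomSpec(seeds[i], weights = weights, config = config)
    rp <- renderPhantom(spec, config = config, extraInfo = flags[i])
    id <- sprintf("phantom_%04d", i)
    writeGrayPNG(rp$image, file.path(outDir, paste0(id, ".png")))
    .writeBoxFile(rp$box, dim(rp$image),
                  file.path(outDir, paste0(id, ".txt")))
    rows[[i]] <- .manifestRow(id, spec, rp$box, seeds[i], flags[i])
  }
  manifest <- do.call(rbind, rows)
  .writeManifestFiles(manifest, outDir)
  invisible(manifest)
}

.manifestRow <- function(id, spec, box, seed, extraInfo,
                         duplicateOf = NA_character_,
                         dupRotation = NA_real_, dupZoom = NA_real_,
                         malignantOverride = NULL) {
  vals <- descriptorValues(spec)
  malignant <- if (is.null(malignantOverride)) spec@malignant else malignantOverride
  data.frame(
    image_id = id, file = paste0(id, ".png"), box_file = paste0(id, ".txt"),
    seed = as.integer(seed), extra_info = extraInfo,
    duplicate_of = duplicateOf, dup_rotation = dupRotation, dup_zoom = dupZoom,
    shape = vals[["shape"]], margin = vals[["margin"]],
    orientation = vals[["orientation"]],
    echogenicity = vals[["echogenicity"]], posterior = vals[["posterior"]],
    halo = vals[["halo"]], suggestivity = vals[["suggestivity"]],
    malignant = malignant, birads = deriveBirads(spec),
    x0 = box@x0, y0 = box@y0, x1 = box@x1, y1 = box@y1,
    stringsAsFactors = FALSE)
}

.writeManifestFiles <- function(manifest, outDir) {
  labelCols <- c("image_id", .DESCRIPTORS, "malignant", "birads")
  write.csv(manifest[, labelCols], file.path(outDir, "labels.csv"),
            row.names = FALSE)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       dataframe = "rows", na = "null", digits = NA,
                       pretty = TRUE)
  invisible(NULL)
}

#' Read a dataset manifest
#'
#' @param path Path to a \code{manifest.json} or its directory.
#' @return The manifest data.frame; the source directory is attached as
#'   attribute \code{"dir"}.
#' @export
readManifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  m <- jsonlite::fromJSON(path)
  for (col in c("duplicate_of")) if (!col %in% names(m)) m[[col]] <- NA
  attr(m, "dir") <- dirname(path)
  m
}

## normalized "0 cx cy w h" box files
.writeBoxFile <- function(box, imgDim, path) {
  H <- imgDim[1]; W <- imgDim[2]
  cx <- (box@x0 + box@x1) / 2 / W
  cy <- (box@y0 + box@y1) / 2 / H
  w <- (box@x1 - box@x0) / W
  h <- (box@y1 - box@y0) / H
  writeLines(sprintf("0 %.6f %.6f %.6f %.6f", cx, cy, w, h), path)
}

#' Read a normalized box file
#'
#' @param path Box text file with lines \code{"class cx cy w h"}, normalized
#'   to [0, 1].
#' @param imgDim Image (height, width) in pixels.
#' @return List of \code{BoundingBox}.
#' @export
readBoxFile <- function(path, imgDim) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    f <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])[-1]
    H <- imgDim[1]; W <- imgDim[2]
    boundingBox((f[1] - f[3] / 2) * W, (f[2] - f[4] / 2) * H,
                (f[1] + f[3] / 2) * W, (f[2] + f[4] / 2) * H)
  })
}

#' Plant near-duplicate copies in a dataset
#'
#' Emits rotated/zoomed copies of randomly chosen manifest images, writing
#' the transformed PNGs next to the originals and appending manifest rows
#' with \code{duplicate_of} provenance and the transform parameters. A
#' configurable fraction of the copies receives a flipped malignancy label,
#' emulating the cross-class duplicates found in public breast ultrasound
#' datasets. The number of conflicted pairs is \code{floor(fraction *
#' nPairs + 0.5)} (round half up).
#'
#' @param manifest A manifest data.frame (attribute \code{"dir"} must point
#'   at the image directory, as returned by \code{\link{makeDataset}} /
#'   \code{\link{readManifest}}).
#' @param nPairs Number of copies to plant (at most the number of original
#'   images).
#' @param rotationMax Maximum |rotation| in degrees (default 15).
#' @param zoomRange Zoom factor interval (default c(0.8, 1.2)).
#' @param conflictFraction Fraction of copies with flipped malignancy.
#' @param seed RNG seed.
#' @param outDir Image directory (defaults to the manifest's).
#' @return The augmented manifest data.frame.
#' @export
makeDuplicates <- function(manifest, nPairs, rotationMax = 15,
                           zoomRange = c(0.8, 1.2), conflictFraction = 0,
                           seed = 1, outDir = attr(manifest, "dir")) {
  if (nrow(manifest) == 0) stop("empty manifest")
  originals <- manifest[is.na(manifest$duplicate_of), ]
  if (nPairs > nrow(originals))
    stop("nPairs exceeds the number of original images")
  nConf <- floor(conflictFraction * nPairs + 0.5)
  newRows <- .withSeed(seed, {
    pick <- sample(seq_len(nrow(originals)), nPairs)
    rots <- runif(nPairs, -rotationMax, rotationMax)
    zooms <- runif(nPairs, zoomRange[1], zoomRange[2])
    lapply(seq_len(nPairs), function(i) {
      src <- originals[pick[i], ]
      img <- readGrayPNG(file.path(outDir, src$file))
      dup <- .transformDuplicate(img, rots[i], zooms[i])
      id <- paste0(src$image_id, "_dup")
      writeGrayPNG(dup$image, file.path(outDir, paste0(id, ".png")))
      box <- .transformBox(boundingBox(src$x0, src$y0, src$x1, src$y1),
                           dim(img), rots[i], zooms[i])
      .writeBoxFile(box, dim(dup$image),
                    file.path(outDir, paste0(id, ".txt")))
      row <- src
      row$image_id <- id; row$file <- paste0(id, ".png")
      row$box_file <- paste0(id, ".txt")
      row$duplicate_of <- src$image_id
      row$dup_rotation <- rots[i]; row$dup_zoom <- zooms[i]
      row[, c("x0", "y0", "x1", "y1")] <-
        c(box@x0, box@y0, box@x1, box@y1)
      if (i <= nConf) row$malignant <- !row$malignant
      row
    })
  })
  out <- rbind(manifest, do.call(rbind, newRows))
  rownames(out) <- NULL
  attr(out, "dir") <- outDir
  .writeManifestFiles(out, outDir)
  out
}

## rotate about the center, then zoom about the center, same canvas
.transformDuplicate <- function(img, degrees, zoom) {
  bg <- stats::median(img)
  out <- .rotateImage(img, degrees, bg = bg / 255)
  H <- nrow(out); W <- ncol(out)
  newH <- round(H * zoom); newW <- round(W * zoom)
  out <- .resizeImage(out, newW, newH)
  canvas <- matrix(bg, H, W)
  if (zoom >= 1) {
    oy <- floor((newH - H) / 2); ox <- floor((newW - W) / 2)
    canvas <- out[oy + seq_len(H), ox + seq_len(W)]
  } else {
    oy <- floor((H - newH) / 2); ox <- floor((W - newW) / 2)
    canvas[oy + seq_len(newH), ox + seq_len(newW)] <- out
  }
  list(image = canvas)
}

## the planted transform maps the source box to an axis-aligned hull
.transformBox <- function(box, imgDim, degrees, zoom) {
  H <- imgDim[1]; W <- imgDim[2]
  cx <- W / 2; cy <- H / 2
  th <- -degrees * pi / 180    # y grows downward
  corners <- rbind(c(box@x0, box@y0), c(box@x1, box@y0),
                   c(box@x0, box@y1), c(box@x1, box@y1))
  rel <- sweep(corners, 2, c(cx, cy))
  rot <- cbind(rel[, 1] * cos(th) - rel[, 2] * sin(th),
               rel[, 1] * sin(th) + rel[, 2] * cos(th)) * zoom
  abs <- sweep(rot, 2, c(cx, cy), "+")
  boundingBox(max(0, min(abs[, 1])), max(0, min(abs[, 2])),
              min(W, max(abs[, 1])), min(H, max(abs[, 2])))
}
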