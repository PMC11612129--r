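#' Descriptor vocabularies
#'
#' The controlled value sets for the six BI-RADS descriptors, the echogenic
#' halo, the tumor-type suggestivity and the BI-RADS malignancy category used
#' throughout the package. They follow the BI-RADS 5th-edition lexicon,
#' restricted to the values a descriptor model can be trained on with a
#' moderate-size dataset: mixed posterior features, complex cystic-and-solid
#' echogenicity and calcifications are omitted, and the angular margin is
#' collapsed into indistinct. Orientation carries an explicit \code{"none"}
#' value for nodules that are neither parallel nor anti-parallel (e.g. round
#' ones). All downstream code is driven by this list, so users working with
#' richer real-data annotations can extend it via the \code{vocab} element of
#' \code{\link{pipelineConfig}}.
#'
#' @return Named list of character vectors, one per descriptor, plus
#'   \code{birads}, the category scale \code{2,3,4A,4B,4C,5}.
#' @examples
#' descriptorVocabularies()$margin
#' @export
descriptorVocabularies <- function() {
  list(
    shape        = c("oval", "round", "irregular"),
    margin       = c("circumscribed", "indistinct", "microlobulated", "spiculated"),
    orientation  = c("parallel", "anti_parallel", "none"),
    echogenicity = c("anechoic", "hypoechoic", "isoechoic", "hyperechoic",
                     "heterogeneous"),
    posterior    = c("none", "enhancement", "shadowing"),
    halo         = c("absent", "present"),
    suggestivity = c("simple_cyst", "complex_cyst", "fibroadenoma",
                     "no_clear_suggestivity"),
    birads       = c("2", "3", "4A", "4B", "4C", "5")
  )
}

## descriptor names in canonical order (the six BI-RADS descriptors, then
## suggestivity); used for head wiring, one-hot layout and reports
.DESCRIPTORS <- c("shape", "margin", "orientation", "echogenicity",
                  "posterior", "halo", "suggestivity")

#' Pipeline configuration
#'
#' Assembles the configuration record consumed by every stage of the
#' pipeline, with validated defaults. Defaults follow the published operating
#' points of the method: ROIs are standardized to 450x450 with zero padding,
#' the orientation sigmoid threshold is 0.3, and the training augmentation
#' intervals are box enlargement [-0.1, 0.25] vertical and [-0.1, 0.15]
#' horizontal, zoom [-0.3, 0.3], contrast [0.8, 1.2], brightness [-25, 25],
#' horizontal flip with probability 0.5, and rotation within 0.05 * 2 * pi
#' radians.
#'
#' @param ... Named overrides of any default; nested lists are replaced
#'   wholesale (e.g. \code{augment = list(...)}).
#' @param file Optional YAML file with overrides, applied before \code{...}.
#' @return A validated named list of class \code{"sonoConfig"}.
#' @examples
#' cfg <- pipelineConfig(encoder = "tiny")
#' cfg$roi_target
#' @export
pipelineConfig <- function(..., file = NULL) {
  cfg <- list(
    vocab = descriptorVocabularies(),
    roi_target = 450L,              # standardized ROI side, pixels
    orientation_tau = 0.3,          # sigmoid threshold for orientation
    encoder = "default",            # "default" (14x14x512) or "tiny"
    detect_conf_threshold = 0.25,
    iou_threshold = 0.5,
    mlr_l2 = 0.001,
    augment = list(
      enlarge_vertical   = c(-0.1, 0.25),
      enlarge_horizontal = c(-0.1, 0.15),
      zoom               = c(-0.3, 0.3),
      contrast           = c(0.8, 1.2),
      brightness         = c(-25, 25),
      flip_prob          = 0.5,
      rotation_max       = 0.05 * 2 * pi   # radians
    ),
    dedup = list(ratio = 0.75, min_inliers = 25L),
    phantom = .phantomDefaults()
  )
  if (!is.null(file)) {
    over <- yaml::read_yaml(file)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("configuration overrides must be named")
    cfg[names(dots)] <- dots
  }
  .validateConfig(cfg)
  class(cfg) <- c("sonoConfig", "list")
  cfg
}

.validateConfig <- function(cfg) {
  stopifnot(is.list(cfg$vocab))
  needed <- c(.DESCRIPTORS, "birads")
  missing <- setdiff(needed, names(cfg$vocab))
  if (length(missing))
    stop("vocabulary missing descriptors: ", paste(missing, collapse = ", "))
  if (!(cfg$roi_target >= 16)) stop("roi_target must be >= 16 pixels")
  if (cfg$orientation_tau < 0 || cfg$orientation_tau > 1)
    stop("orientation_tau must be in [0, 1]")
  if (!cfg$encoder %in% c("default", "tiny"))
    stop("encoder must be 'default' or 'tiny'")
  a <- cfg$augment
  for (nm in c("enlarge_vertical", "enlarge_horizontal", "zoom", "contrast",
               "brightness")) {
    iv <- a[[nm]]
    if (length(iv) != 2 || iv[1] > iv[2])
      stop("augmentation interval '", nm, "' must be c(lo, hi) with lo <= hi")
  }
  if (a$flip_prob < 0 || a$flip_prob > 1) stop("flip_prob must be in [0, 1]")
  if (a$rotation_max < 0) stop("rotation_max must be non-negative")
  if (cfg$mlr_l2 < 0) stop("mlr_l2 must be non-negative")
  if (cfg$dedup$ratio <= 0 || cfg$dedup$ratio >= 1)
    stop("dedup ratio must be in (0, 1)")
  invisible(TRUE)
}

## Sampling priors and rendering constants of the phantom generator. These
## are the study conditions of the synthetic experiments, not tuning dials:
## class weights keep every descriptor value at a workable prevalence, and
## rendering contrasts follow the qualitative ultrasound semantics
## (anechoic ~ black, hyperechoic ~ bright, shadowing ~ dark column, ...).
.phantomDefaults <- function() {
  list(
    canvas = c(160L, 160L),         # width, height in pixels
    background_range = c(90, 140),  # mean speckle intensity, 0-255
    weights = list(
      shape        = c(oval = 0.40, round = 0.30, irregular = 0.30),
      margin       = c(circumscribed = 0.25, indistinct = 0.25,
                       microlobulated = 0.25, spiculated = 0.25),
      orientation  = c(parallel = 0.55, anti_parallel = 0.45), # elongated only
      echogenicity = c(anechoic = 0.18, hypoechoic = 0.22, isoechoic = 0.18,
                       hyperechoic = 0.20, heterogeneous = 0.22),
      posterior    = c(none = 0.40, enhancement = 0.30, shadowing = 0.30),
      halo         = c(absent = 0.65, present = 0.35),
      suggestivity = c(simple_cyst = 0.10, complex_cyst = 0.10,
                       fibroadenoma = 0.12, no_clear_suggestivity = 0.68)
    ),
    # interior intensity as a multiple of the background mean
    echo_levels = c(anechoic = 0.12, hypoechoic = 0.45, isoechoic = 1.0,
                    hyperechoic = 1.70, heterogeneous = NA),
    hetero_levels = c(0.50, 1.40),  # patchy interior mixture
    posterior_gain = c(none = 1.0, enhancement = 1.60, shadowing = 0.45),
    posterior_depth = 0.7,          # column length, multiples of half-height
    halo_gain = 1.70,
    halo_width = 5,                 # pixels
    capsule_gain = 0.72,            # thin dark rim on sharp margins
    semi_axis_range = c(20, 32),    # major semi-axis, pixels
    aspect_elongated = c(1.45, 2.1),# major/minor ratio for oval & irregular
    aspect_round = c(0.95, 1.05),
    indistinct_sigma = 5.5,         # Gaussian blur of the margin, pixels
    ## microlobulated = fine short scallops on an otherwise regular shape;
    ## irregular = global low-order departure from an ellipse (order >= 3,
    ## since an order-2 perturbation only re-elongates the ellipse)
    lobe_count = c(9L, 13L),        # microlobulated boundary
    lobe_amp = 0.14,                # fraction of radius
    irregular_count = c(3L, 5L),    # low-order boundary perturbation
    irregular_amp = c(0.28, 0.40),
    spike_count = c(8L, 12L),
    spike_len = c(0.35, 0.55),      # fraction of radius beyond the boundary
    extra_info_frac = 0.1,          # images with burned-in markers
    speckle_contrast = 0.65         # amplitude of the unit-mean speckle
                                    # fluctuation (1 = raw Rayleigh)
  )
}

## weighted categorical draw used by the sampler; validates the weights
.sampleCat <- function(values, weights) {
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(values)), values)
  w <- weights[values]
  if (any(is.na(w))) w <- weights  # weights given in value order
  w <- as.numeric(w)
  if (length(w) != length(values) || any(w < 0) || abs(sum(w) - 1) > 1e-6)
    stop("class weights must be non-negative and sum to 1 over ",
         paste(values, collapse = "/"))
  values[.sampleIdx(w)]
}

.sampleIdx <- function(w) {
  u <- stats::runif(1)
  cum <- cumsum(w) / sum(w)
  which(u <= cum)[1]
}
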