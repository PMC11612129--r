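#' @import methods
#' @importFrom graphics axis abline points legend
#' @importFrom stats runif rnorm rgamma setNames predict quantile median sd
#' @importFrom utils head write.csv read.csv
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' PhantomSpec: ground truth for one synthetic nodule
#'
#' Records the BI-RADS descriptor values and the geometry/noise parameters
#' used to render one synthetic nodule on a speckle background. All
#' descriptor values are validated against \code{\link{descriptorVocabularies}};
#' structural consistency is enforced: a round nodule has no orientation and
#' near-unit axis ratio, a simple cyst is anechoic, circumscribed and shows
#' posterior enhancement, and a spiculated margin implies malignancy.
#'
#' @slot shape,margin,orientation,echogenicity,posterior,halo,suggestivity
#'   Character scalars from the controlled vocabularies.
#' @slot malignant Logical scalar.
#' @slot center Numeric length-2, nodule center (x, y) in pixels.
#' @slot semiAxes Numeric length-2, semi-axes (a_x, a_y) in pixels before
#'   rotation.
#' @slot rotation Numeric scalar, radians.
#' @slot backgroundMean Numeric scalar, mean speckle intensity in 0-255.
#' @slot seed Integer scalar, the rendering seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    shape = "character", margin = "character", orientation = "character",
    echogenicity = "character", posterior = "character", halo = "character",
    suggestivity = "character", malignant = "logical",
    center = "numeric", semiAxes = "numeric", rotation = "numeric",
    backgroundMean = "numeric", seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  v <- descriptorVocabularies()
  msgs <- character()
  for (d in .DESCRIPTORS) {
    val <- slot(object, if (d == "echogenicity") "echogenicity" else d)
    if (length(val) != 1 || !val %in% v[[d]])
      msgs <- c(msgs, sprintf("%s value '%s' not in vocabulary", d,
                              paste(val, collapse = ",")))
  }
  if (length(object@malignant) != 1 || is.na(object@malignant))
    msgs <- c(msgs, "malignant must be TRUE or FALSE")
  if (length(object@center) != 2 || length(object@semiAxes) != 2)
    msgs <- c(msgs, "center and semiAxes must have length 2")
  if (any(object@semiAxes <= 0)) msgs <- c(msgs, "semiAxes must be positive")
  if (object@backgroundMean < 0 || object@backgroundMean > 255)
    msgs <- c(msgs, "backgroundMean must be in [0, 255]")
  if (identical(object@shape, "round")) {
    ratio <- object@semiAxes[1] / object@semiAxes[2]
    if (object@orientation != "none")
      msgs <- c(msgs, "round nodules have orientation 'none'")
    if (ratio < 0.9 || ratio > 1.1)
      msgs <- c(msgs, "round nodules need a semi-axis ratio in [0.9, 1.1]")
  }
  if (identical(object@suggestivity, "simple_cyst")) {
    if (object@echogenicity != "anechoic" || object@margin != "circumscribed" ||
        object@posterior != "enhancement")
      msgs <- c(msgs,
        "simple cysts are anechoic, circumscribed, with posterior enhancement")
  }
  if (identical(object@margin, "spiculated") && !isTRUE(object@malignant))
    msgs <- c(msgs, "spiculated nodules are malignant")
  if (length(msgs)) msgs else TRUE
})

#' BoundingBox: a pixel-space detection region
#'
#' 0-based, half-open pixel coordinates: the box covers columns
#' \code{[x0, x1)} and rows \code{[y0, y1)}. Used both for ground-truth
#' phantom boxes and detector output.
#'
#' @slot x0,y0,x1,y1 Numeric scalars, 0-based half-open pixel bounds.
#' @slot confidence Numeric scalar in [0, 1].
#' @exportClass BoundingBox
setClass("BoundingBox",
  representation(x0 = "numeric", y0 = "numeric", x1 = "numeric",
                 y1 = "numeric", confidence = "numeric"),
  prototype(confidence = 1)
)

setValidity("BoundingBox", function(object) {
  msgs <- character()
  if (!(object@x0 < object@x1) || !(object@y0 < object@y1))
    msgs <- c(msgs, "box must satisfy x0 < x1 and y0 < y1")
  if (object@x0 < 0 || object@y0 < 0)
    msgs <- c(msgs, "box coordinates must be non-negative")
  if (object@confidence < 0 || object@confidence > 1)
    msgs <- c(msgs, "confidence must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' StandardROI: a standardized region of interest
#'
#' The square, zero-padded crop that is fed to the descriptor network. The
#' crop is rescaled only if one of its sides exceeds the target, preserving
#' the width-height ratio (which carries the orientation descriptor), then
#' zero-padded to target x target with the content at the top-left corner.
#' \code{scaleFactor} and \code{padOffsets} allow exact inverse mapping of
#' ROI coordinates (e.g. attention maps) back to the source image.
#'
#' @slot pixels Numeric matrix (target x target), intensities in 0-255.
#' @slot scaleFactor Numeric scalar, ROI pixels per source pixel (<= 1).
#' @slot padOffsets Numeric length-2, (x, y) offset of the content area.
#' @slot contentSize Numeric length-2, (width, height) of the content area.
#' @slot sourceBox The source \code{BoundingBox}.
#' @exportClass StandardROI
setClass("StandardROI",
  representation(pixels = "matrix", scaleFactor = "numeric",
                 padOffsets = "numeric", contentSize = "numeric",
                 sourceBox = "BoundingBox")
)

setValidity("StandardROI", function(object) {
  msgs <- character()
  if (nrow(object@pixels) != ncol(object@pixels))
    msgs <- c(msgs, "standardized ROI must be square")
  if (object@scaleFactor <= 0 || object@scaleFactor > 1 + 1e-9)
    msgs <- c(msgs, "scaleFactor must be in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' DescriptorSet: one nodule's BI-RADS description
#'
#' The six BI-RADS descriptors plus suggestivity for one nodule, each a
#' single value from the controlled vocabulary (orientation may be
#' \code{"none"}), with optional per-value probability vectors as returned
#' by the descriptor network.
#'
#' @slot values Named character vector over shape, margin, orientation,
#'   echogenicity, posterior, halo, suggestivity.
#' @slot probabilities Named list of per-value probability vectors (may be
#'   empty for e.g. expert annotations).
#' @exportClass DescriptorSet
setClass("DescriptorSet",
  representation(values = "character", probabilities = "list"),
  prototype(probabilities = list())
)

setValidity("DescriptorSet", function(object) {
  v <- descriptorVocabularies()
  msgs <- character()
  if (!identical(sort(names(object@values)), sort(.DESCRIPTORS)))
    msgs <- c(msgs, "values must cover exactly the seven descriptors")
  else
    for (d in .DESCRIPTORS)
      if (!object@values[[d]] %in% v[[d]])
        msgs <- c(msgs, sprintf("%s value '%s' not in vocabulary",
                                d, object@values[[d]]))
  if (length(msgs)) msgs else TRUE
})

#' BiradsResult: category, probabilities and explanation
#'
#' Output of the multinomial logistic regression over descriptor values:
#' the BI-RADS category, the per-category probability vector, and an
#' additive explanation — for each reported category, the weight contributed
#' by every active descriptor value plus the intercept, which sum exactly to
#' the category logit.
#'
#' @slot category Character scalar in \code{2,3,4A,4B,4C,5}.
#' @slot probabilities Named numeric vector over categories, sums to 1.
#' @slot explanation A data.frame with columns \code{category},
#'   \code{feature}, \code{value}, \code{weight} (intercept rows carry
#'   feature \code{"(intercept)"}), for the top-2 categories.
#' @slot logits Named numeric vector of category logits.
#' @exportClass BiradsResult
setClass("BiradsResult",
  representation(category = "character", probabilities = "numeric",
                 explanation = "data.frame", logits = "numeric")
)

setValidity("BiradsResult", function(object) {
  msgs <- character()
  if (!object@category %in% names(object@probabilities))
    msgs <- c(msgs, "category must be one of the probability names")
  if (abs(sum(object@probabilities) - 1) > 1e-6)
    msgs <- c(msgs, "probabilities must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' FinalReport: rule-adjusted output plus narrative
#'
#' The per-nodule result after the rule-based fine-tuning: possibly adjusted
#' descriptors (a round nodule loses its orientation) and category (simple
#' cyst to 2, complex cyst to 4A, spiculated to 5), the malignancy
#' probability, the clinical intervention implied by the category, and a
#' deterministic natural-language narrative with its structured record.
#'
#' @slot descriptors A \code{DescriptorSet} after rules (orientation may be
#'   \code{"none"}, which the narrative omits).
#' @slot category Character scalar.
#' @slot malignancyProb Numeric scalar in [0, 1] (NA when no malignancy
#'   model output is available).
#' @slot intervention Character scalar from the category-intervention table.
#' @slot narrative Character scalar.
#' @slot record Named list, the lossless structured form.
#' @exportClass FinalReport
setClass("FinalReport",
  representation(descriptors = "DescriptorSet", category = "character",
                 malignancyProb = "numeric", intervention = "character",
                 narrative = "character", record = "list")
)

#' DuplicateCluster: a connected component of near-identical images
#'
#' @slot members Character vector of image ids (length >= 2).
#' @slot evidence data.frame of pairwise match evidence (id_a, id_b,
#'   matches, inliers).
#' @slot labels Character vector, the distinct malignancy labels carried by
#'   the members.
#' @slot conflict Logical, TRUE iff the members carry more than one label.
#' @slot representative Character scalar, the member kept under the
#'   keep-one policy.
#' @exportClass DuplicateCluster
setClass("DuplicateCluster",
  representation(members = "character", evidence = "data.frame",
                 labels = "character", conflict = "logical",
                 representative = "character")
)

setValidity("DuplicateCluster", function(object) {
  msgs <- character()
  if (length(object@members) < 2)
    msgs <- c(msgs, "a duplicate cluster has at least 2 members")
  if (!identical(object@conflict, length(object@labels) > 1))
    msgs <- c(msgs, "conflict flag must equal |labels| > 1")
  if (!object@representative %in% object@members)
    msgs <- c(msgs, "representative must be a member")
  if (length(msgs)) msgs else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:",
      sprintf("%s / %s / %s / %s / posterior %s / halo %s / %s%s\n",
              object@shape, object@margin, object@orientation,
              object@echogenicity, object@posterior, object@halo,
              object@suggestivity,
              if (object@malignant) " / malignant" else ""))
  cat(sprintf("  center (%.1f, %.1f), semi-axes (%.1f, %.1f), rot %.2f rad, bg %.0f, seed %d\n",
              object@center[1], object@center[2], object@semiAxes[1],
              object@semiAxes[2], object@rotation, object@backgroundMean,
              object@seed))
})

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox [%g, %g) x [%g, %g), conf %.3f\n",
              object@x0, object@x1, object@y0, object@y1, object@confidence))
})

setMethod("show", "StandardROI", function(object) {
  cat(sprintf("StandardROI %dx%d, content %gx%g, scale %.4f\n",
              nrow(object@pixels), ncol(object@pixels),
              object@contentSize[1], object@contentSize[2],
              object@scaleFactor))
})

setMethod("show", "DescriptorSet", function(object) {
  cat("DescriptorSet:\n")
  for (d in .DESCRIPTORS)
    cat(sprintf("  %-13s %s\n", d, object@values[[d]]))
})

setMethod("show", "BiradsResult", function(object) {
  p <- sort(object@probabilities, decreasing = TRUE)
  cat(sprintf("BiradsResult: category %s (p = %.3f; runner-up %s, p = %.3f)\n",
              object@category, p[1], names(p)[2], p[2]))
})

setMethod("show", "FinalReport", function(object) {
  cat("FinalReport: BI-RADS", object@category, "-", object@intervention, "\n")
  cat(" ", object@narrative, "\n")
})

setMethod("show", "DuplicateCluster", function(object) {
  cat(sprintf("DuplicateCluster of %d images%s: %s (keep %s)\n",
              length(object@members),
              if (object@conflict) " [LABEL CONFLICT]" else "",
              paste(object@members, collapse = ", "),
              object@representative))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for the core classes
#'
#' @param object A package object.
#' @name accessors
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("descriptorValues", function(object) standardGeneric("descriptorValues"))
#' @rdname accessors
#' @export
setMethod("descriptorValues", "DescriptorSet", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("descriptorValues", "PhantomSpec", function(object) {
  vapply(.DESCRIPTORS, function(d) slot(object, d), character(1))
})

#' @rdname accessors
#' @export
setGeneric("biradsCategory", function(object) standardGeneric("biradsCategory"))
#' @rdname accessors
#' @export
setMethod("biradsCategory", "BiradsResult", function(object) object@category)
#' @rdname accessors
#' @export
setMethod("biradsCategory", "FinalReport", function(object) object@category)

#' @rdname accessors
#' @export
setGeneric("roiPixels", function(object) standardGeneric("roiPixels"))
#' @rdname accessors
#' @export
setMethod("roiPixels", "StandardROI", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("boxCoords", function(object) standardGeneric("boxCoords"))
#' @rdname accessors
#' @export
setMethod("boxCoords", "BoundingBox", function(object) {
  c(x0 = object@x0, y0 = object@y0, x1 = object@x1, y1 = object@y1)
})

#' Construct a BoundingBox
#'
#' @param x0,y0,x1,y1 0-based half-open pixel bounds.
#' @param confidence Detection confidence in [0, 1].
#' @return A \code{BoundingBox}.
#' @examples boundingBox(10, 20, 60, 90)
#' @export
boundingBox <- function(x0, y0, x1, y1, confidence = 1) {
  new("BoundingBox", x0 = as.numeric(x0), y0 = as.numeric(y0),
      x1 = as.numeric(x1), y1 = as.numeric(y1),
      confidence = as.numeric(confidence))
}

#' Construct a DescriptorSet
#'
#' @param values Named character vector (or list) covering shape, margin,
#'   orientation, echogenicity, posterior, halo, suggestivity.
#' @param probabilities Optional named list of per-value probability vectors.
#' @return A \code{DescriptorSet}.
#' @examples
#' descriptorSet(c(shape = "oval", margin = "circumscribed",
#'   orientation = "parallel", echogenicity = "hypoechoic",
#'   posterior = "none", halo = "absent",
#'   suggestivity = "fibroadenoma"))
#' @export
descriptorSet <- function(values, probabilities = list()) {
  vals <- unlist(values)
  new("DescriptorSet", values = vals[.DESCRIPTORS],
      probabilities = probabilities)
}
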