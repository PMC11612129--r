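## rules module: BI-RADS rule-based fine-tuning of the model output, the
## category-to-intervention table, and natural-language report rendering.

#' Apply the BI-RADS fine-tuning rules
#'
#' Two rules from the BI-RADS standard adjust the model output:
#' \enumerate{
#'   \item a round nodule has no orientation (neither parallel nor
#'     anti-parallel): the orientation descriptor is set to \code{"none"};
#'   \item the category is overridden for special cases: a simple cyst is
#'     set to 2, a complex cyst to 4A, and a spiculated margin to 5.
#' }
#' When rules conflict (e.g. a spiculated nodule typed as a simple cyst),
#' the malignancy-dominant order wins: spiculated (5) overrides the
#' suggestivity overrides the regression category. The operation is
#' idempotent and leaves all other values untouched.
#'
#' @param d A \code{DescriptorSet} (or named descriptor vector).
#' @param category Character scalar, the regression category.
#' @return List with \code{descriptors} (a \code{DescriptorSet}) and
#'   \code{category}.
#' @examples
#' d <- descriptorSet(c(shape = "round", margin = "circumscribed",
#'   orientation = "parallel", echogenicity = "anechoic",
#'   posterior = "enhancement", halo = "absent",
#'   suggestivity = "simple_cyst"))
#' applyRules(d, "3")
#' @export
applyRules <- function(d, category) {
  if (!is(d, "DescriptorSet")) d <- descriptorSet(d)
  vals <- d@values
  if (vals[["shape"]] == "round") vals[["orientation"]] <- "none"
  category <- as.character(category)
  if (vals[["suggestivity"]] == "simple_cyst") category <- "2"
  if (vals[["suggestivity"]] == "complex_cyst") category <- "4A"
  if (vals[["margin"]] == "spiculated") category <- "5"
  list(descriptors = descriptorSet(vals, d@probabilities),
       category = category)
}

#' Clinical intervention for a BI-RADS category
#'
#' The standard category-to-intervention mapping over the full 0-6 scale
#' (4 split into A/B/C):
#' 0 additional evaluation; 1 and 2 normal procedure; 3 control in 6
#' months; 4A, 4B, 4C and 5 biopsy; 6 treatment.
#'
#' @param category Character scalar in \code{0,1,2,3,4A,4B,4C,5,6}.
#' @return Character scalar, the intervention.
#' @examples
#' intervention("3")
#' @export
intervention <- function(category) {
  map <- c("0" = "Additional evaluation",
           "1" = "Normal procedure",
           "2" = "Normal procedure",
           "3" = "Control in 6 months",
           "4A" = "Biopsy", "4B" = "Biopsy", "4C" = "Biopsy",
           "5" = "Biopsy",
           "6" = "Treatment")
  category <- as.character(category)
  if (length(category) != 1 || !category %in% names(map))
    stop("unknown BI-RADS category '", category, "'")
  unname(map[category])
}

## default English narrative template; named slots in {braces}; the
## {orientation_phrase} slot collapses to nothing when orientation is none
.defaultTemplate <- paste(
  "The nodule is {shape} with {margin} margins{orientation_phrase},",
  "{echogenicity} echogenicity, {posterior_phrase}, and {halo_phrase}.",
  "{suggestivity_phrase}",
  "BI-RADS category {category} ({malignancy_phrase}).",
  "Recommended intervention: {intervention}.")

.slotPhrases <- function(vals, category, malignancyProb) {
  list(
    shape = vals[["shape"]],
    margin = sub("_", " ", vals[["margin"]]),
    orientation_phrase = if (vals[["orientation"]] == "none") "" else
      sprintf(", %s orientation", sub("_", "-", vals[["orientation"]])),
    echogenicity = vals[["echogenicity"]],
    posterior_phrase = switch(vals[["posterior"]],
      none = "no posterior feature",
      enhancement = "posterior enhancement",
      shadowing = "posterior shadowing"),
    halo_phrase = if (vals[["halo"]] == "present") "an echogenic halo"
                  else "no echogenic halo",
    suggestivity_phrase = switch(vals[["suggestivity"]],
      simple_cyst = "The appearance is suggestive of a simple cyst.",
      complex_cyst = "The appearance is suggestive of a complex cyst.",
      fibroadenoma = "The appearance is suggestive of a fibroadenoma.",
      no_clear_suggestivity = "No clear tumor-type suggestivity."),
    category = category,
    malignancy_phrase = if (is.na(malignancyProb)) "malignancy not estimated"
      else sprintf("estimated malignancy probability %.2f", malignancyProb),
    intervention = intervention(category))
}

.fillTemplate <- function(template, slots) {
  out <- template
  for (nm in names(slots))
    out <- gsub(paste0("{", nm, "}"), slots[[nm]], out, fixed = TRUE)
  left <- regmatches(out, regexpr("\\{[a-z_]+\\}", out))
  if (length(left)) stop("template slot not provided: ", left)
  gsub(" +", " ", gsub(" \\.", ".", out))
}

#' Render the final per-nodule report
#'
#' Deterministic template fill producing the natural-language narrative and
#' a lossless structured record. The rules are expected to have been
#' applied already (\code{\link{applyRules}}); when orientation is
#' \code{"none"} the narrative carries no orientation phrase. The
#' structured record serializes to JSON and parses back without loss.
#'
#' @param d A \code{DescriptorSet} after rules.
#' @param category Character scalar, category after rules.
#' @param malignancyProb Malignancy probability in [0, 1], or NA.
#' @param template Template string with \code{\{slot\}} placeholders, or a
#'   path to a template text file; default ships with the package.
#' @return A \code{FinalReport}.
#' @export
renderReport <- function(d, category, malignancyProb = NA_real_,
                         template = NULL) {
  if (!is(d, "DescriptorSet")) d <- descriptorSet(d)
  if (is.null(template)) template <- .defaultTemplate
  else if (length(template) == 1 && file.exists(template))
    template <- paste(readLines(template), collapse = " ")
  vals <- d@values
  slots <- .slotPhrases(vals, category, malignancyProb)
  narrative <- .fillTemplate(template, slots)
  record <- c(as.list(vals),
              list(category = category,
                   malignancy_probability = malignancyProb,
                   intervention = intervention(category),
                   narrative = narrative))
  new("FinalReport", descriptors = d, category = category,
      malignancyProb = as.numeric(malignancyProb),
      intervention = intervention(category),
      narrative = narrative, record = record)
}

#' Serialize / parse a FinalReport record
#'
#' @param report A \code{FinalReport} (or the record list).
#' @param path Optional file; when given, JSON is written there.
#' @return \code{serializeReport}: the JSON string;
#'   \code{parseReport}: the record as a named list.
#' @export
serializeReport <- function(report, path = NULL) {
  rec <- if (is(report, "FinalReport")) report@record else report
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  as.character(js)
}

#' @rdname serializeReport
#' @param json JSON string or file path.
#' @export
parseReport <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- readLines(json)
  jsonlite::fromJSON(paste(json, collapse = "\n"))
}
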