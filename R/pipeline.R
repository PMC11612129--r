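## cli/pipeline module: wiring detect -> standardize -> describe -> classify
## -> rules -> report, with seeds and a structured run log.

#' Describe every nodule in an image
#'
#' Full pipeline on one grayscale image: detect nodule boxes (pluggable
#' detector), standardize each ROI to the network input, predict the
#' BI-RADS descriptors, the suggestivity and the malignancy probability,
#' assign the category with the descriptor-driven multinomial logistic
#' regression, apply the BI-RADS fine-tuning rules, and render one report
#' per nodule. Returns an empty list (not an error) when nothing is
#' detected.
#'
#' @param image Grayscale matrix (0-255) or PNG path.
#' @param net A trained \code{BiradsNet}.
#' @param mlr A fitted \code{BiradsMLR}.
#' @param confThreshold Detection confidence threshold.
#' @param detector Detection method (\code{"fallback"}, \code{"oracle"},
#'   \code{"adapter"}), see \code{\link{detectNodules}}.
#' @param truth,adapter Passed to \code{\link{detectNodules}}.
#' @param template Optional report template (see
#'   \code{\link{renderReport}}).
#' @return List of \code{FinalReport}, one per detected nodule.
#' @export
describeImage <- function(image, net, mlr, confThreshold = 0.25,
                          detector = "fallback", truth = NULL,
                          adapter = NULL, template = NULL) {
  if (is.character(image)) image <- readGrayPNG(image)
  if (confThreshold < 0 || confThreshold > 1)
    stop("confThreshold must be in [0, 1]")
  boxes <- detectNodules(image, confThreshold, method = detector,
                         truth = truth, adapter = adapter)
  lapply(boxes, function(box) {
    roi <- standardizeROI(image, box, target = net@config$encoder$input)
    pr <- predictROI(net, roi)
    cat0 <- predictExplain(pr$descriptors, mlr)
    adj <- applyRules(pr$descriptors, biradsCategory(cat0))
    renderReport(adj$descriptors, adj$category,
                 malignancyProb = pr$malignancyProb, template = template)
  })
}

#' Write a structured run log
#'
#' Records the subcommand, a hash of the configuration, the seed and the
#' artifact paths as one JSON line appended to \code{file}.
#'
#' @param subcommand Character scalar.
#' @param config Configuration list (hashed into the log).
#' @param seed Integer seed.
#' @param artifacts Named character vector of output paths.
#' @param file Log file (default \code{"sonodescribe.log"} in the first
#'   artifact's directory).
#' @return The log line, invisibly.
#' @export
writeRunLog <- function(subcommand, config, seed, artifacts,
                        file = NULL) {
  cfgHash <- paste0(substr(paste(
    tools::md5sum(.tempConfigFile(config))), 1, 12))
  line <- jsonlite::toJSON(list(
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    subcommand = subcommand, config_hash = cfgHash,
    seed = seed, artifacts = as.list(artifacts)), auto_unbox = TRUE)
  if (is.null(file))
    file <- file.path(dirname(artifacts[[1]]), "sonodescribe.log")
  cat(as.character(line), "\n", file = file, append = TRUE)
  invisible(as.character(line))
}

.tempConfigFile <- function(config) {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(.stripFunctions(config), f)
  f
}

.stripFunctions <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x)) return(lapply(x, .stripFunctions))
  x
}
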