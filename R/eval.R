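## eval module: Cohen's kappa per descriptor, mean kappa, accuracy,
## confusion matrices, and the Boolean-malignancy metric suite.

#' Cohen's kappa
#'
#' Unweighted chance-corrected agreement between two label vectors:
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with \eqn{p_o} the observed
#' agreement and \eqn{p_e} the expected agreement from the product of the
#' two raters' marginal distributions. Values above 0.8 are conventionally
#' read as almost perfect agreement, 0.6-0.8 as substantial. If both raters
#' are constant and identical (\eqn{p_e = 1}), kappa is defined as 1 by
#' convention.
#'
#' @param y1,y2 Equal-length label vectors (any atomic type).
#' @return Numeric scalar in [-1, 1].
#' @examples
#' cohensKappa(c("A", "A", "A", "B"), c("A", "A", "B", "B"))  # 0.5
#' @export
cohensKappa <- function(y1, y2) {
  if (length(y1) != length(y2) || length(y1) < 1)
    stop("y1 and y2 must have equal positive length")
  y1 <- as.character(y1); y2 <- as.character(y2)
  labs <- sort(unique(c(y1, y2)))
  n <- length(y1)
  po <- mean(y1 == y2)
  p1 <- table(factor(y1, levels = labs)) / n
  p2 <- table(factor(y2, levels = labs)) / n
  pe <- sum(as.numeric(p1) * as.numeric(p2))
  if (abs(1 - pe) < 1e-12) return(1.0)
  (po - pe) / (1 - pe)
}

#' Boolean malignancy metric suite
#'
#' Accuracy, recall (sensitivity), precision, F1 and specificity from the
#' standard 2x2 contingency definitions, with malignant as the positive
#' class. Undefined ratios (no positives in truth, or no predicted
#' positives) are reported as 0 with a warning.
#'
#' @param pred,truth Equal-length logical vectors (TRUE = malignant).
#' @return Named numeric vector: accuracy, recall, precision, f1,
#'   specificity.
#' @examples
#' malignancyMetrics(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, FALSE))
#' @export
malignancyMetrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  pred <- as.logical(pred); truth <- as.logical(truth)
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  acc <- (tp + tn) / length(pred)
  rec <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no positives in truth; recall reported as 0"); 0 }
  prec <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("no predicted positives; precision reported as 0"); 0 }
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("no negatives in truth; specificity reported as 0"); 0 }
  c(accuracy = acc, recall = rec, precision = prec, f1 = f1,
    specificity = spec)
}

#' Descriptor agreement report
#'
#' Per-descriptor Cohen's kappa, accuracy and confusion matrix between two
#' sources of descriptions (e.g. model vs expert), plus the unweighted mean
#' kappa over the seven descriptor outputs (the six BI-RADS descriptors and
#' suggestivity). The BI-RADS category, when present in both inputs, is
#' scored separately and never enters the mean.
#'
#' @param model,reference Data frames (or lists of \code{DescriptorSet})
#'   with one row/element per nodule, aligned; data frames need the seven
#'   descriptor columns and may carry a \code{birads} column.
#' @return List with \code{table} (data.frame: descriptor, kappa, accuracy),
#'   \code{mean_kappa}, \code{confusion} (named list of matrices),
#'   \code{birads_kappa} (NA unless both sides carry \code{birads}), and
#'   \code{n}.
#' @export
agreementReport <- function(model, reference) {
  model <- .descriptorFrame(model); reference <- .descriptorFrame(reference)
  if (nrow(model) != nrow(reference))
    stop("model and reference must describe the same nodules")
  missing <- setdiff(.DESCRIPTORS, intersect(names(model), names(reference)))
  if (length(missing))
    stop("descriptor(s) missing: ", paste(missing, collapse = ", "))
  tab <- data.frame(descriptor = .DESCRIPTORS, kappa = NA_real_,
                    accuracy = NA_real_)
  confusion <- list()
  for (i in seq_along(.DESCRIPTORS)) {
    d <- .DESCRIPTORS[i]
    m <- as.character(model[[d]]); r <- as.character(reference[[d]])
    if (anyNA(m) || anyNA(r)) stop("descriptor '", d, "' has missing values")
    tab$kappa[i] <- cohensKappa(m, r)
    tab$accuracy[i] <- mean(m == r)
    labs <- sort(unique(c(m, r)))
    confusion[[d]] <- table(model = factor(m, labs),
                            reference = factor(r, labs))
  }
  bk <- NA_real_
  if ("birads" %in% names(model) && "birads" %in% names(reference))
    bk <- cohensKappa(model$birads, reference$birads)
  list(table = tab, mean_kappa = mean(tab$kappa), confusion = confusion,
       birads_kappa = bk, n = nrow(model))
}

.descriptorFrame <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x) && all(vapply(x, is, logical(1), "DescriptorSet"))) {
    return(as.data.frame(do.call(rbind,
      lapply(x, function(d) descriptorValues(d))),
      stringsAsFactors = FALSE))
  }
  stop("expected a data.frame or a list of DescriptorSet")
}

#' Write an agreement report to CSV
#'
#' Writes the per-descriptor kappa/accuracy table, and one confusion-matrix
#' CSV per descriptor under \code{<stem>_confusion_<descriptor>.csv}.
#'
#' @param report Output of \code{\link{agreementReport}}.
#' @param stem Output path stem.
#' @return The main CSV path, invisibly.
#' @export
writeAgreementReport <- function(report, stem) {
  main <- paste0(stem, "_agreement.csv")
  tab <- report$table
  tab <- rbind(tab, data.frame(descriptor = "mean",
                               kappa = report$mean_kappa, accuracy = NA))
  write.csv(tab, main, row.names = FALSE)
  for (d in names(report$confusion))
    write.csv(as.data.frame.matrix(report$confusion[[d]]),
              paste0(stem, "_confusion_", d, ".csv"))
  invisible(main)
}
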