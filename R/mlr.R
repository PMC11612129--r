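## mlr module: multinomial logistic regression from descriptor values to the
## BI-RADS category, with additive per-feature weight explanations.

#' BiradsMLR: explainable multinomial logistic regression
#'
#' L2-penalized multinomial logistic regression over one-hot descriptor
#' indicators, in the symmetric (non-pivot) parameterization: every category
#' carries its own weight vector and intercept, so a weight exists for each
#' (feature value, category) pair and explanations can be read off for any
#' category. The likelihood depends only on between-category differences;
#' the ridge penalty selects the centered representative, making the fit
#' unique and deterministic.
#'
#' @slot weights Numeric matrix, features x categories (dimnames set).
#' @slot intercepts Named numeric vector over categories.
#' @slot categories Character vector of category labels.
#' @slot featureNames Character vector, \code{"descriptor=value"} layout of
#'   the indicator vector.
#' @slot l2 Ridge penalty used in the fit.
#' @slot converged Logical.
#' @exportClass BiradsMLR
setClass("BiradsMLR",
  representation(weights = "matrix", intercepts = "numeric",
                 categories = "character", featureNames = "character",
                 l2 = "numeric", converged = "logical")
)

setValidity("BiradsMLR", function(object) {
  msgs <- character()
  if (ncol(object@weights) != length(object@categories))
    msgs <- c(msgs, "weights must have one column per category")
  if (nrow(object@weights) != length(object@featureNames))
    msgs <- c(msgs, "weights must have one row per feature")
  if (length(object@intercepts) != length(object@categories))
    msgs <- c(msgs, "one intercept per category required")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "BiradsMLR", function(object) {
  cat(sprintf("BiradsMLR: %d features -> %d categories (l2 = %g%s)\n",
              nrow(object@weights), length(object@categories), object@l2,
              if (object@converged) "" else ", NOT converged"))
})

#' One-hot encode a descriptor set
#'
#' Concatenated one-hot blocks, one per descriptor (shape, margin,
#' orientation, echogenicity, posterior, halo, suggestivity), in vocabulary
#' order. Orientation \code{"none"} is encoded as its own indicator, so the
#' absence of orientation is itself a feature the category model can weigh.
#'
#' @param d A \code{DescriptorSet}, named character vector, or data.frame of
#'   descriptor columns (one row per nodule).
#' @param vocab Vocabulary list (default \code{descriptorVocabularies()}).
#' @return Numeric indicator matrix (rows = nodules) with column names
#'   \code{"descriptor=value"}; a single input yields a 1-row matrix.
#' @examples
#' encodeFeatures(descriptorValues(samplePhantomSpec(1)))
#' @export
encodeFeatures <- function(d, vocab = descriptorVocabularies()) {
  if (is(d, "DescriptorSet")) d <- descriptorValues(d)
  if (!is.data.frame(d)) d <- as.data.frame(as.list(d), stringsAsFactors = FALSE)
  featNames <- unlist(lapply(.DESCRIPTORS, function(nm)
    paste0(nm, "=", vocab[[nm]])))
  X <- matrix(0, nrow(d), length(featNames),
              dimnames = list(NULL, featNames))
  for (nm in .DESCRIPTORS) {
    vals <- as.character(d[[nm]])
    bad <- !vals %in% vocab[[nm]]
    if (any(bad))
      stop("out-of-vocabulary ", nm, " value: ",
           paste(unique(vals[bad]), collapse = ", "))
    X[cbind(seq_len(nrow(d)), match(paste0(nm, "=", vals), featNames))] <- 1
  }
  X
}

#' Fit the BI-RADS category model
#'
#' Minimizes the mean multinomial log-loss plus the ridge penalty
#' \eqn{(\lambda/2)\|W\|^2} (weights only, not intercepts) by BFGS with
#' analytic gradients. The mean-loss scaling makes the fit invariant to
#' duplicating observations; the ridge penalty pins the symmetric
#' parameterization (one weight vector per category) to its centered
#' representative, so the fit is unique and deterministic. The default
#' \code{l2 = 0.001} is a light shrinkage chosen so clearly separable
#' descriptor tables are fit essentially to convergence while the weights
#' of rare feature values remain bounded.
#'
#' @param x Indicator matrix from \code{\link{encodeFeatures}}, or a
#'   data.frame of descriptor columns.
#' @param categories Character vector of observed categories (>= 2 distinct).
#' @param l2 Ridge penalty on the mean-loss scale (default 0.001).
#' @param vocab Vocabulary list; \code{vocab$birads} fixes the category
#'   space and ordering.
#' @return A \code{BiradsMLR}.
#' @export
fitBiradsMLR <- function(x, categories, l2 = 0.001,
                         vocab = descriptorVocabularies()) {
  if (is.data.frame(x)) x <- encodeFeatures(x, vocab)
  categories <- as.character(categories)
  if (nrow(x) != length(categories))
    stop("x and categories must have matching length")
  if (length(unique(categories)) < 2)
    stop("degenerate fit: need at least 2 distinct categories")
  cats <- vocab$birads
  if (!all(categories %in% cats))
    stop("categories outside the configured space: ",
         paste(setdiff(categories, cats), collapse = ", "))
  K <- length(cats); P <- ncol(x); n <- nrow(x)
  yIdx <- match(categories, cats)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), yIdx)] <- 1

  unpack <- function(par) list(W = matrix(par[seq_len(P * K)], P, K),
                               b = par[P * K + seq_len(K)])
  objective <- function(par) {
    pp <- unpack(par)
    Z <- sweep(x %*% pp$W, 2, pp$b, "+")
    Z <- Z - apply(Z, 1, max)
    logZ <- log(rowSums(exp(Z)))
    nll <- -mean(Z[cbind(seq_len(n), yIdx)] - logZ)
    nll + l2 / 2 * sum(pp$W^2)
  }
  gradient <- function(par) {
    pp <- unpack(par)
    Z <- sweep(x %*% pp$W, 2, pp$b, "+")
    Z <- Z - apply(Z, 1, max)
    Pm <- exp(Z) / rowSums(exp(Z))
    E <- (Pm - Y) / n
    c(as.vector(crossprod(x, E)) + l2 * as.vector(pp$W), colSums(E))
  }
  fit <- stats::optim(rep(0, P * K + K), objective, gradient,
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  pp <- unpack(fit$par)
  b <- pp$b - mean(pp$b)     # intercept level is unidentified; center it
  dimnames(pp$W) <- list(colnames(x), cats)
  new("BiradsMLR", weights = pp$W, intercepts = setNames(b, cats),
      categories = cats, featureNames = colnames(x), l2 = l2,
      converged = fit$convergence == 0)
}

#' Predict the BI-RADS category with an explanation
#'
#' Computes category logits as intercept plus the sum of the weights of the
#' active (one-hot) descriptor values, probabilities by softmax, and an
#' explanation table listing, for the top-2 categories, each active
#' feature's weight and the intercept. By construction the weights and
#' intercept of each category sum exactly to its logit.
#'
#' @param d A \code{DescriptorSet} or named descriptor vector.
#' @param model A fitted \code{BiradsMLR}.
#' @return A \code{BiradsResult}.
#' @export
predictExplain <- function(d, model) {
  if (!is(model, "BiradsMLR")) stop("model must be a fitted BiradsMLR")
  X <- encodeFeatures(d)
  z <- drop(X %*% model@weights) + model@intercepts
  p <- .softmax(z)
  top2 <- names(sort(p, decreasing = TRUE))[1:2]
  active <- which(X[1, ] == 1)
  expl <- do.call(rbind, lapply(top2, function(cat) {
    rows <- data.frame(
      category = cat,
      feature = sub("=.*", "", names(active)),
      value = sub(".*=", "", names(active)),
      weight = model@weights[active, cat],
      stringsAsFactors = FALSE)
    rbind(rows, data.frame(category = cat, feature = "(intercept)",
                           value = "", weight = model@intercepts[[cat]]))
  }))
  rownames(expl) <- NULL
  new("BiradsResult", category = names(which.max(p)),
      probabilities = p, explanation = expl, logits = z)
}

#' Predict categories for many descriptor rows
#'
#' @param d Data frame of descriptor columns.
#' @param model A fitted \code{BiradsMLR}.
#' @return Character vector of predicted categories.
#' @export
predictBirads <- function(d, model) {
  X <- encodeFeatures(d)
  Z <- sweep(X %*% model@weights, 2, model@intercepts, "+")
  model@categories[max.col(Z, ties.method = "first")]
}

#' Save / load a BiradsMLR as JSON
#'
#' Weights are keyed by feature value and category, so the file is readable
#' as the explanation table itself.
#'
#' @param model A \code{BiradsMLR}.
#' @param path JSON file path.
#' @return \code{writeBiradsMLR}: the path, invisibly; \code{readBiradsMLR}:
#'   the model.
#' @export
writeBiradsMLR <- function(model, path) {
  obj <- list(
    categories = model@categories,
    feature_names = model@featureNames,
    intercepts = as.list(model@intercepts),
    weights = setNames(lapply(model@featureNames, function(f)
      as.list(setNames(model@weights[f, ], model@categories))),
      model@featureNames),
    l2 = model@l2, converged = model@converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeBiradsMLR
#' @export
readBiradsMLR <- function(path) {
  obj <- jsonlite::fromJSON(path)
  W <- do.call(rbind, lapply(obj$feature_names, function(f)
    unlist(obj$weights[[f]])[obj$categories]))
  dimnames(W) <- list(obj$feature_names, obj$categories)
  new("BiradsMLR", weights = W,
      intercepts = setNames(unlist(obj$intercepts)[obj$categories],
                            obj$categories),
      categories = obj$categories, featureNames = obj$feature_names,
      l2 = obj$l2, converged = obj$converged)
}

#' Dot plot of explanation weights
#'
#' Draws the per-descriptor weight contributions for the top-2 categories
#' of a \code{BiradsResult}, one point per active descriptor value.
#'
#' @param result A \code{BiradsResult} from \code{\link{predictExplain}}.
#' @param file Optional PNG path; when given, the plot is written there.
#' @return Invisibly, the explanation data.frame.
#' @export
plotExplanation <- function(result, file = NULL) {
  expl <- result@explanation
  expl <- expl[expl$feature != "(intercept)", ]
  cats <- unique(expl$category)
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 480)
    on.exit(grDevices::dev.off())
  }
  feats <- unique(expl$feature)
  yPos <- seq_along(feats)
  plot(NULL, xlim = range(expl$weight) + c(-0.2, 0.2),
       ylim = c(0.5, length(feats) + 0.5), yaxt = "n",
       xlab = "weight contribution to category logit", ylab = "",
       main = sprintf("BI-RADS %s vs %s", cats[1], cats[2]))
  graphics::axis(2, at = yPos, labels = feats, las = 1)
  graphics::abline(v = 0, lty = 3)
  cols <- c("firebrick", "steelblue")
  for (i in seq_along(cats)) {
    sub <- expl[expl$category == cats[i], ]
    graphics::points(sub$weight, match(sub$feature, feats) +
                       (i - 1.5) * 0.15, pch = 19, col = cols[i])
  }
  graphics::legend("topright", legend = paste("BI-RADS", cats), pch = 19,
                   col = cols, bty = "n")
  invisible(result@explanation)
}
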