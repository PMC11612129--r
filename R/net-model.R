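## net module (model): the attention-based multi-head descriptor network.
## Encoder (conv stack with GELU + max pooling) -> per-image feature-space
## normalization -> soft-attention context -> six descriptor heads ->
## suggestivity head -> Boolean malignancy head.

#' Encoder configurations
#'
#' Two encoder sizes are provided. \code{"default"} is the full-size
#' VGG16-topology stack: 450x450 grayscale input, five pooling stages,
#' channels 64-128-256-512-512, yielding a 14x14x512 output, i.e. a
#' 196x512 feature-space matrix per image. \code{"tiny"} is the same
#' structure with fewer channels and stages (96x96 input, four stages,
#' channels 12-24-48-64, a 6x6x64 output = 36x64 feature space), sized so
#' the network trains in minutes on one CPU; it is the first-class
#' configuration for the synthetic experiments.
#'
#' @param encoder \code{"default"} or \code{"tiny"}.
#' @return List with \code{input} (side), \code{channels},
#'   \code{convs_per_stage}, \code{g} (grid side) and \code{d} (feature
#'   dimension).
#' @export
encoderConfig <- function(encoder = c("tiny", "default")) {
  encoder <- match.arg(encoder)
  if (encoder == "default") {
    list(name = "default", input = 450L, channels = c(64L, 128L, 256L, 512L, 512L),
         convs_per_stage = c(1L, 2L, 2L, 2L, 2L), g = 14L, d = 512L)
  } else {
    list(name = "tiny", input = 96L, channels = c(12L, 24L, 48L, 64L),
         convs_per_stage = c(1L, 1L, 1L, 1L), g = 6L, d = 64L)
  }
}

#' BiradsNet: the attention multi-head descriptor network
#'
#' Holds the encoder/head parameters, the vocabulary-driven head layout,
#' and the training history. Head wiring: the attention context feeds six
#' dense layers (one per BI-RADS descriptor; softmax activations, except
#' orientation which uses two per-neuron sigmoids); the suggestivity head
#' receives the concatenation of the six descriptor head outputs and the
#' context (suggestivity depends on the descriptors); the malignancy head
#' receives the descriptor outputs, the suggestivity output and the
#' context.
#'
#' @slot config List: encoder geometry, vocabularies, orientation
#'   threshold, optimizer defaults.
#' @slot params Named list of weight matrices/vectors.
#' @slot trained Logical.
#' @slot history data.frame of per-epoch losses (empty until trained).
#' @exportClass BiradsNet
setClass("BiradsNet",
  representation(config = "list", params = "list", trained = "logical",
                 history = "data.frame"),
  prototype(trained = FALSE, history = data.frame())
)

setMethod("show", "BiradsNet", function(object) {
  enc <- object@config$encoder
  cat(sprintf("BiradsNet (%s encoder: %dx%d input -> %dx%d feature space)%s\n",
              enc$name, enc$input, enc$input, enc$g^2, enc$d,
              if (object@trained) sprintf(", trained %d epochs",
                                          nrow(object@history)) else
                " [untrained]"))
})

## cardinalities of the head outputs; orientation head has two sigmoid
## neurons (parallel, anti-parallel): "none" is decided by thresholding
.headSizes <- function(vocab) {
  c(shape = length(vocab$shape), margin = length(vocab$margin),
    orientation = 2L, echogenicity = length(vocab$echogenicity),
    posterior = length(vocab$posterior), halo = length(vocab$halo))
}

#' Construct an untrained descriptor network
#'
#' Parameters are He-initialized deterministically from \code{seed}. An
#' optional \code{weightsHook} function receives the parameter list and may
#' return a modified one (e.g. to load pre-trained encoder weights).
#'
#' @param encoder \code{"tiny"} or \code{"default"}.
#' @param vocab Descriptor vocabularies.
#' @param tau Orientation sigmoid threshold (default 0.3).
#' @param seed Initialization seed.
#' @param weightsHook Optional function params -> params.
#' @return A \code{BiradsNet}.
#' @examples
#' net <- biradsNet("tiny", seed = 1)
#' @export
biradsNet <- function(encoder = "tiny", vocab = descriptorVocabularies(),
                      tau = 0.3, seed = 1, weightsHook = NULL) {
  enc <- encoderConfig(encoder)
  hs <- .headSizes(vocab)
  nSugg <- length(vocab$suggestivity)
  uLen <- sum(hs)
  params <- .withSeed(seed, {
    p <- list(conv = list())
    inC <- 1L
    for (s in seq_along(enc$channels)) {
      for (cc in seq_len(enc$convs_per_stage[s])) {
        outC <- enc$channels[s]
        fanIn <- inC * 9
        p$conv[[length(p$conv) + 1]] <- list(
          W = matrix(rnorm(fanIn * outC, sd = sqrt(2 / fanIn)), fanIn, outC),
          b = rep(0, outC), inC = inC)
        inC <- outC
      }
    }
    d <- enc$d
    p$v <- rnorm(d, sd = 1 / sqrt(d))
    p$heads <- lapply(hs, function(k)
      list(W = matrix(rnorm(k * d, sd = sqrt(2 / d)), k, d), b = rep(0, k)))
    p$sugg <- list(W = matrix(rnorm(nSugg * (uLen + d),
                                    sd = sqrt(2 / (uLen + d))),
                              nSugg, uLen + d), b = rep(0, nSugg))
    p$malig <- list(W = matrix(rnorm(2 * (uLen + nSugg + d),
                                     sd = sqrt(2 / (uLen + nSugg + d))),
                               2, uLen + nSugg + d), b = rep(0, 2))
    p
  })
  if (!is.null(weightsHook)) params <- weightsHook(params)
  cfg <- list(encoder = enc, vocab = vocab, tau = tau, seed = seed,
              head_sizes = hs, u_len = uLen,
              lr = if (enc$name == "tiny") 2e-3 else 1e-4)
  new("BiradsNet", config = cfg, params = params)
}

## ---- encoder ------------------------------------------------------------

## forward through the conv stack for a batch of images.
## x: list of input matrices (side x side). Returns list with the cached
## per-layer activations needed for the backward pass and the raw feature
## cube (g, g, N*d).
.encoderForward <- function(net, imgs) {
  enc <- net@config$encoder
  N <- length(imgs)
  side <- enc$input
  x <- array(0, c(side, side, N))
  for (n in seq_len(N)) {
    if (!all(dim(imgs[[n]]) == c(side, side)))
      stop("encoder configured for ", side, "x", side, " input, got ",
           paste(dim(imgs[[n]]), collapse = "x"))
    x[, , n] <- imgs[[n]] / 255   # scale to [0, 1]
  }
  cache <- list()
  layer <- 0L
  for (s in seq_along(enc$channels)) {
    for (cc in seq_len(enc$convs_per_stage[s])) {
      layer <- layer + 1L
      pr <- net@params$conv[[layer]]
      z <- .cpp_conv_forward(x, pr$inC, pr$W, pr$b)
      a <- .cpp_gelu_forward(z)
      cache[[layer]] <- list(x = x, z = z)
      x <- a
    }
    mp <- .cpp_maxpool_forward(x)
    cache[[layer]]$poolIdx <- mp$idx
    cache[[layer]]$prePool <- dim(x)[1:2]
    x <- mp$y
  }
  list(out = x, cache = cache, N = N)
}

.encoderBackward <- function(net, fw, dOut) {
  enc <- net@config$encoder
  grads <- vector("list", length(net@params$conv))
  dy <- dOut
  layer <- length(net@params$conv)
  for (s in rev(seq_along(enc$channels))) {
    pre <- fw$cache[[layer]]$prePool
    dy <- .cpp_maxpool_backward(fw$cache[[layer]]$poolIdx, dy,
                                pre[1], pre[2])
    for (cc in rev(seq_len(enc$convs_per_stage[s]))) {
      cc_cache <- fw$cache[[layer]]
      dz <- .cpp_gelu_backward(cc_cache$z, dy)
      pr <- net@params$conv[[layer]]
      bw <- .cpp_conv_backward(cc_cache$x, pr$inC, pr$W, dz, layer > 1L)
      grads[[layer]] <- list(W = bw$dW, b = as.numeric(bw$db))
      dy <- bw$dx
      layer <- layer - 1L
    }
  }
  grads
}

## slice the encoder output cube into one g^2 x d matrix per image
.featureMatrices <- function(net, cube, N) {
  enc <- net@config$encoder
  d <- enc$d; g <- enc$g
  lapply(seq_len(N), function(n) {
    F <- matrix(0, g * g, d)
    for (k in seq_len(d)) F[, k] <- as.vector(cube[, , (n - 1) * d + k])
    F
  })
}

## per-image feature normalization over the g^2 spatial cells of each
## feature column (epsilon-guarded, so constant inputs stay finite)
.normalizeF <- function(F, eps = 1e-5) {
  mu <- colMeans(F)
  xc <- sweep(F, 2, mu)
  va <- colMeans(xc^2)
  list(Fh = sweep(xc, 2, sqrt(va + eps), "/"), mu = mu, va = va, eps = eps)
}

## backward of the per-column normalization; nf is the cache from
## .normalizeF (nf$Fh is the normalized output)
.normalizeFBackward <- function(nf, dFh) {
  inv <- 1 / sqrt(nf$va + nf$eps)
  mean_d <- colMeans(dFh)
  mean_dx <- colMeans(dFh * nf$Fh)
  sweep(dFh - matrix(mean_d, nrow(dFh), ncol(dFh), byrow = TRUE) -
          sweep(nf$Fh, 2, mean_dx, "*"), 2, inv, "*")
}

#' Encode a standardized ROI into the feature space
#'
#' Runs the convolutional encoder and the per-image feature normalization,
#' returning the g^2 x d feature-space matrix whose rows index the spatial
#' cells of the encoder output grid.
#'
#' @param roi A \code{StandardROI} (or numeric matrix of the configured
#'   input size).
#' @param net A \code{BiradsNet}.
#' @return Numeric matrix, g^2 rows x d columns.
#' @export
encodeROI <- function(roi, net) {
  img <- if (is(roi, "StandardROI")) roiPixels(roi) else roi
  fw <- .encoderForward(net, list(img))
  F <- .featureMatrices(net, fw$out, 1)[[1]]
  .normalizeF(F)$Fh
}

## ---- attention ----------------------------------------------------------

#' Soft-attention context over the feature space
#'
#' Each feature-space row \eqn{f_i} is scored by a one-unit perceptron with
#' tanh activation, \eqn{s_i = \tanh(V \cdot f_i)}; the scores are passed
#' through a softmax so the attention weights are non-negative and sum to
#' one; the context is the attention-weighted average of the rows,
#' \eqn{c = \sum_i a_i f_i}.
#'
#' @param F Numeric matrix (g^2 x d), the (normalized) feature space.
#' @param v Numeric length-d weight vector (the learned scoring perceptron).
#' @return List with \code{a} (attention weights, length g^2, summing to
#'   1), \code{c} (context, length d) and \code{scores} (tanh scores).
#' @examples
#' F <- matrix(rnorm(12), 4, 3)
#' at <- attend(F, rep(0, 3))
#' at$a                     # uniform: zero scores
#' @export
attend <- function(F, v) {
  if (ncol(F) != length(v))
    stop("dimension mismatch: ncol(F) must equal length(v)")
  s <- tanh(as.numeric(F %*% v))
  a <- .softmax(s)
  list(a = a, c = as.numeric(crossprod(F, a)), scores = s)
}

## ---- heads --------------------------------------------------------------

#' Forward pass through the classification heads
#'
#' Computes all head outputs from an attention context: six descriptor
#' heads from the context alone; the suggestivity head from the
#' concatenation of the six descriptor outputs and the context; the
#' malignancy head from the descriptor outputs, the suggestivity output and
#' the context. \code{descriptorOverride} / \code{contextOverride} replace
#' the corresponding inputs of the dependent heads (used to probe the
#' wiring).
#'
#' @param net A \code{BiradsNet}.
#' @param context Numeric length-d context vector.
#' @param descriptorOverride Optional length-19 (sum of head sizes) vector
#'   replacing the descriptor outputs fed to the dependent heads.
#' @param contextOverride Optional vector replacing the context fed to the
#'   dependent heads.
#' @return List: per-descriptor probability vectors (\code{heads}),
#'   \code{suggestivity}, \code{malignancy}, plus the dependent-head input
#'   vector \code{u}.
#' @export
headsForward <- function(net, context, descriptorOverride = NULL,
                         contextOverride = NULL) {
  p <- net@params
  vocab <- net@config$vocab
  hs <- net@config$head_sizes
  heads <- list()
  for (nm in names(hs)) {
    z <- as.numeric(p$heads[[nm]]$W %*% context + p$heads[[nm]]$b)
    heads[[nm]] <- if (nm == "orientation") .sigmoid(z) else .softmax(z)
  }
  u <- unlist(heads, use.names = FALSE)
  if (!is.null(descriptorOverride)) u <- descriptorOverride
  cDep <- if (is.null(contextOverride)) context else contextOverride
  zs <- as.numeric(p$sugg$W %*% c(u, cDep) + p$sugg$b)
  ps <- .softmax(zs)
  zm <- as.numeric(p$malig$W %*% c(u, ps, cDep) + p$malig$b)
  pm <- .softmax(zm)
  names(ps) <- vocab$suggestivity
  names(pm) <- c("benign", "malignant")
  for (nm in names(hs))
    names(heads[[nm]]) <- if (nm == "orientation")
      c("parallel", "anti_parallel") else vocab[[nm]]
  list(heads = heads, suggestivity = ps, malignancy = pm, u = u,
       sugg_logits = zs, malig_logits = zm)
}

#' Decide the orientation label from the sigmoid pair
#'
#' The orientation head emits two independent sigmoid values (parallel,
#' anti-parallel). If both fall below the threshold \code{tau} the nodule
#' is assigned no orientation (\code{"none"}); otherwise the larger value
#' above threshold wins, with ties broken toward parallel.
#'
#' @param values Numeric length-2 in [0, 1]: (parallel, anti_parallel).
#' @param tau Threshold, default 0.3.
#' @return One of \code{"parallel"}, \code{"anti_parallel"}, \code{"none"}.
#' @examples
#' decideOrientation(c(0.2, 0.25))  # "none"
#' decideOrientation(c(0.6, 0.5))   # "parallel"
#' @export
decideOrientation <- function(values, tau = 0.3) {
  stopifnot(length(values) == 2, all(values >= 0), all(values <= 1))
  if (all(values < tau)) return("none")
  ok <- which(values >= tau)
  if (length(ok) == 1) return(c("parallel", "anti_parallel")[ok])
  if (values[1] >= values[2]) "parallel" else "anti_parallel"
}

#' Predict descriptors for a standardized ROI
#'
#' Full forward pass: encoder, attention, heads; per-head argmax gives the
#' descriptor values (orientation via \code{\link{decideOrientation}});
#' the attention weights are reshaped to the g x g grid and bilinearly
#' upsampled to the ROI size.
#'
#' @param net A trained \code{BiradsNet}.
#' @param roi A \code{StandardROI} or input-size matrix.
#' @param flipAverage Average the head probabilities over the ROI and its
#'   horizontal mirror (test-time augmentation; every descriptor,
#'   including orientation, is invariant to a horizontal flip).
#' @return List with \code{descriptors} (a \code{DescriptorSet} with
#'   per-value probabilities), \code{malignancyProb},
#'   \code{attention} (ROI-size matrix) and \code{attentionGrid}
#'   (g x g matrix of weights).
#' @export
predictROI <- function(net, roi, flipAverage = FALSE) {
  if (!net@trained) stop("model is untrained; call trainBiradsNet() first")
  img <- if (is(roi, "StandardROI")) roiPixels(roi) else roi
  fw <- .encoderForward(net, list(img))
  F <- .featureMatrices(net, fw$out, 1)[[1]]
  Fh <- .normalizeF(F)$Fh
  at <- attend(Fh, net@params$v)
  ho <- headsForward(net, at$c)
  if (flipAverage) {
    cw <- if (is(roi, "StandardROI")) roi@contentSize[1] else ncol(img)
    imgF <- img
    imgF[, seq_len(cw)] <- imgF[, rev(seq_len(cw))]
    fwF <- .encoderForward(net, list(imgF))
    FhF <- .normalizeF(.featureMatrices(net, fwF$out, 1)[[1]])$Fh
    hoF <- headsForward(net, attend(FhF, net@params$v)$c)
    avg <- function(a, b) (a + b) / 2
    ho$heads <- Map(avg, ho$heads, hoF$heads)
    ho$suggestivity <- avg(ho$suggestivity, hoF$suggestivity)
    ho$malignancy <- avg(ho$malignancy, hoF$malignancy)
  }
  vocab <- net@config$vocab
  vals <- c(
    shape = vocab$shape[which.max(ho$heads$shape)],
    margin = vocab$margin[which.max(ho$heads$margin)],
    orientation = decideOrientation(as.numeric(ho$heads$orientation),
                                    net@config$tau),
    echogenicity = vocab$echogenicity[which.max(ho$heads$echogenicity)],
    posterior = vocab$posterior[which.max(ho$heads$posterior)],
    halo = vocab$halo[which.max(ho$heads$halo)],
    suggestivity = vocab$suggestivity[which.max(ho$suggestivity)])
  g <- net@config$encoder$g
  grid <- matrix(at$a, g, g)
  side <- nrow(img)
  attn <- .resizeImage(grid, side, side)
  list(descriptors = descriptorSet(vals,
         probabilities = c(ho$heads, list(suggestivity = ho$suggestivity))),
       malignancyProb = unname(ho$malignancy["malignant"]),
       attention = attn, attentionGrid = grid)
}

#' Export an attention overlay image
#'
#' Writes the ROI with the upsampled attention map alpha-blended on top.
#'
#' @param roi A \code{StandardROI} or matrix.
#' @param attention ROI-size attention matrix (from
#'   \code{\link{predictROI}}).
#' @param path Output PNG path.
#' @param alpha Blend weight of the attention map.
#' @return The path, invisibly.
#' @export
writeAttentionOverlay <- function(roi, attention, path, alpha = 0.5) {
  img <- if (is(roi, "StandardROI")) roiPixels(roi) else roi
  att <- attention / max(attention, 1e-12) * 255
  writeGrayPNG((1 - alpha) * img + alpha * att, path)
}
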