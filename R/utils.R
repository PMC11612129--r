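## Internal helpers shared across modules.

## Evaluate expr under a local RNG seed, restoring the caller's RNG state,
## so rendering and sampling are pure functions of (inputs, seed).
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

## Derive a stream of per-item 31-bit seeds from one master seed.
.seedStream <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Read / write 8-bit grayscale PNG images
#'
#' Images are represented in the package as numeric matrices with rows = y
#' (top to bottom) and columns = x, intensities on the 0-255 scale.
#'
#' @param path File path.
#' @param image Numeric matrix, intensities 0-255.
#' @return \code{readGrayPNG} returns the matrix; \code{writeGrayPNG} the
#'   path, invisibly.
#' @export
readGrayPNG <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  px * 255
}

#' @rdname readGrayPNG
#' @export
writeGrayPNG <- function(image, path) {
  img <- pmin(pmax(round(image), 0), 255) / 255
  png::writePNG(img, path)
  invisible(path)
}

## EBImage wrappers. Package images are [row = y, col = x]; EBImage treats
## dim 1 as x, so width/height arguments are swapped rather than transposing.
.gblur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  EBImage::gblur(img, sigma = sigma)
}

.resizeImage <- function(img, newW, newH) {
  EBImage::resize(img, w = newH, h = newW)  # dim1 = our rows
}

.rotateImage <- function(img, degrees, bg = 0) {
  EBImage::rotate(img, angle = degrees, bg.col = bg,
                  output.dim = dim(img))
}

.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))
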