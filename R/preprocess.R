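## Image loading, normalization, inversion and Gaussian smoothing: the
## chain that turns a raster photograph into the marking-intensity field
## the threshold sweep operates on.

#' Load a raster image as a normalized IntensityImage
#'
#' Reads a PNG or TIFF (8- or 16-bit, grayscale or RGB), converts RGB to
#' luminance with the fixed Rec.709 weighting, and min-max normalizes the
#' result to \eqn{[0,1]} within the ROI. A constant image normalizes to
#' all zeros and is flagged \code{degenerate} in the metadata rather than
#' rejected, so batch runs do not abort.
#'
#' @param path path to a PNG/TIFF image.
#' @param roi optional path to a same-size binary mask image (values
#'   above 0.5 are inside the ROI).
#' @return An \linkS4class{IntensityImage}; \code{imgMeta(x)$source}
#'   records \code{path}.
#' @examples
#' f <- tempfile(fileext = ".png")
#' EBImage::writeImage(EBImage::Image(matrix(runif(64), 8, 8)), f)
#' img <- loadImage(f)
#' range(pixels(img))
#' @export
loadImage <- function(path, roi = NULL) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  raw <- EBImage::readImage(path)
  if (EBImage::colorMode(raw) == EBImage::Color)
    raw <- EBImage::channel(raw, "luminance")
  px <- as.matrix(EBImage::imageData(raw))
  if (length(dim(px)) != 2L) px <- px[, , 1]
  px <- t(px)                       # rows = image rows
  mask <- NULL
  if (!is.null(roi)) {
    if (!file.exists(roi)) stop("cannot read ROI mask file: ", roi)
    mraw <- EBImage::readImage(roi)
    if (EBImage::colorMode(mraw) == EBImage::Color)
      mraw <- EBImage::channel(mraw, "luminance")
    mask <- t(as.matrix(EBImage::imageData(mraw))) > 0.5
    if (!identical(dim(mask), dim(px)))
      stop("ROI mask dimensions (", paste(dim(mask), collapse = "x"),
           ") do not match image (", paste(dim(px), collapse = "x"), ")")
  }
  out <- IntensityImage(.minmax(px, mask), mask,
                        meta = list(source = path))
  out@meta$degenerate <- .isConstant(px, mask)
  out
}

## min-max normalization within the ROI; constant fields map to all-zeros
.minmax <- function(px, mask = NULL) {
  vals <- if (is.null(mask)) px else px[mask]
  rng <- range(vals)
  if (diff(rng) < .Machine$double.eps) {
    px[] <- 0
  } else {
    px <- (px - rng[1]) / diff(rng)
    px[px < 0] <- 0; px[px > 1] <- 1   # out-of-ROI values clamped
  }
  px
}

.isConstant <- function(px, mask = NULL) {
  vals <- if (is.null(mask)) px else px[mask]
  diff(range(vals)) < .Machine$double.eps
}

#' Re-normalize an IntensityImage to the unit interval
#'
#' Min-max normalization within the ROI. Idempotent: applying it to an
#' already-normalized image returns the image unchanged.
#'
#' @param img an \linkS4class{IntensityImage}.
#' @return A normalized \linkS4class{IntensityImage}.
#' @export
normalizeIntensity <- function(img) {
  stopifnot(is(img, "IntensityImage"))
  img@pixels <- .minmax(img@pixels, img@mask)
  img@meta$degenerate <- .isConstant(img@pixels, img@mask)
  img
}

#' Convert to the marking-intensity convention
#'
#' All sweep measures assume that high intensity means pattern marking.
#' Photographs of dark markings on a pale egg therefore need their
#' intensity inverted (\eqn{x \to 1 - x}) before measurement. Inversion
#' is an involution: applying it twice restores the original image.
#'
#' @param img an \linkS4class{IntensityImage}.
#' @param invert apply the inversion? Default \code{TRUE} (dark markings
#'   on a light background, the usual egg-photograph polarity).
#' @return An \linkS4class{IntensityImage}; \code{imgMeta(x)$inverted}
#'   tracks the cumulative inversion state.
#' @examples
#' img <- IntensityImage(matrix(c(0.2, 0.8), 4, 4))
#' pixels(toMarkingIntensity(img))[1, 1]   # 0.8
#' @export
toMarkingIntensity <- function(img, invert = TRUE) {
  stopifnot(is(img, "IntensityImage"))
  if (invert) {
    img@pixels <- 1 - img@pixels
    img@meta$inverted <- !isTRUE(img@meta$inverted)
  }
  img
}

## reflect-pad a matrix by r rows/cols on every side (mirror without
## repeating the edge sample; works for any r via modular folding)
.reflectPad <- function(m, r) {
  refl <- function(n) {
    i <- seq.int(1 - r, n + r)
    if (n == 1) return(rep(1L, length(i)))
    p <- 2L * n - 2L
    j <- (i - 1L) %% p
    j <- ifelse(j >= n, p - j, j)
    j + 1L
  }
  m[refl(nrow(m)), refl(ncol(m)), drop = FALSE]
}

#' Gaussian smoothing with reflective boundaries
#'
#' Noise suppression before the threshold sweep. The image is padded by
#' reflection, convolved with a normalized Gaussian kernel
#' (\code{\link[EBImage]{gblur}}), cropped back and re-clipped to
#' \eqn{[0,1]}. Reflection avoids the dark frame that zero-padding would
#' introduce, which the sweep would otherwise register as spurious
#' perimeter. \code{sigma = 0} is the identity.
#'
#' @param img an \linkS4class{IntensityImage}.
#' @param sigma Gaussian standard deviation in pixels (default 2).
#' @return The smoothed \linkS4class{IntensityImage};
#'   \code{imgMeta(x)$sigma} records the scale.
#' @examples
#' img <- IntensityImage(matrix(runif(400), 20, 20))
#' sm <- smoothImage(img, sigma = 2)
#' sd(pixels(sm)) < sd(pixels(img))
#' @export
smoothImage <- function(img, sigma = 2) {
  stopifnot(is(img, "IntensityImage"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) {
    img@meta$sigma <- 0
    return(img)
  }
  r <- 2 * ceiling(3 * sigma) + 1     # >= gblur kernel radius
  pad <- .reflectPad(img@pixels, r)
  sm <- as.matrix(EBImage::imageData(EBImage::gblur(pad, sigma = sigma)))
  core <- sm[(r + 1):(r + nrow(img@pixels)), (r + 1):(r + ncol(img@pixels))]
  core[core < 0] <- 0; core[core > 1] <- 1
  img@pixels <- core
  img@meta$sigma <- sigma
  img@meta$degenerate <- .isConstant(core, img@mask)
  img
}
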