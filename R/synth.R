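## Seeded generators for synthetic egg patterns: long thin smooth strokes
## ("scribbles"), compact elliptical "blotches", an area-matching helper,
## egg-image composition, and the painting manipulation used in the
## rejection experiment. Every generator is a pure function of
## (spec, seed): fixtures for the measurement modules without photographs.

## run expr under a seed, restoring the caller's RNG state afterwards
.withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## precomputed disc offsets for stamping a stroke of the given width
.discOffsets <- function(width) {
  r <- max((width - 1) / 2, 0)
  d <- ceiling(r)
  g <- expand.grid(dy = -d:d, dx = -d:d)
  keep <- g$dy^2 + g$dx^2 <= (width / 2)^2 + 1e-9
  g[keep, , drop = FALSE]
}

## stamp TRUE discs at the given (row, col) path points
.stampPath <- function(canvas, pts, width) {
  off <- .discOffsets(width)
  ii <- outer(pts[, 1], off$dy, `+`)
  jj <- outer(pts[, 2], off$dx, `+`)
  ok <- ii >= 1 & ii <= nrow(canvas) & jj >= 1 & jj <= ncol(canvas)
  canvas[cbind(ii[ok], jj[ok])] <- TRUE
  canvas
}

## one smooth bounded-curvature stroke: unit steps with wrapped-normal
## heading increments, bounced off the canvas margins
.scribblePath <- function(len, H, W, curvatureScale, margin) {
  y <- stats::runif(1, H * 0.25, H * 0.75)
  x <- stats::runif(1, W * 0.25, W * 0.75)
  theta <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(0, nrow = len, ncol = 2)
  for (s in seq_len(len)) {
    theta <- theta + stats::rnorm(1, 0, curvatureScale)
    ny <- y + sin(theta); nx <- x + cos(theta)
    if (ny < margin || ny > H - margin) { theta <- -theta; ny <- y + sin(theta) }
    if (nx < margin || nx > W - margin) { theta <- pi - theta; nx <- x + cos(theta) }
    y <- min(max(ny, 1), H); x <- min(max(nx, 1), W)
    pts[s, ] <- c(y, x)
  }
  round(pts)
}

#' Generate a scribble mask
#'
#' Draws \code{count} long, thin, smoothly curving strokes: each stroke
#' integrates a random heading whose per-step increment is
#' wrapped-normal with sd \code{curvatureScale} (bounded curvature, so
#' strokes wander rather than jitter), then is dilated to
#' \code{strokeWidth} by stamping a disc at every step. Stroke length is
#' chosen so that the expected total painted area is
#' \code{targetTotalArea} (up to self-overlap). Reproducible: the same
#' spec (including its seed) always yields the identical mask.
#'
#' @param spec a \linkS4class{MarkingSpec} with \code{kind = "scribble"}.
#' @param canvas integer c(height, width) of the output mask, pixels.
#' @return A \linkS4class{BinaryImage} containing all strokes.
#' @examples
#' m <- generateScribble(markingSpec("scribble", count = 2,
#'                                   targetTotalArea = 400, seed = 7),
#'                       canvas = c(64, 64))
#' binaryArea(m)
#' @export
generateScribble <- function(spec, canvas = c(160, 120)) {
  stopifnot(is(spec, "MarkingSpec"), spec@kind == "scribble")
  H <- canvas[1]; W <- canvas[2]
  mask <- matrix(FALSE, H, W)
  if (spec@count == 0) return(BinaryImage(mask))
  len <- round(spec@targetTotalArea / (spec@count * spec@strokeWidth))
  if (len < 2) stop("impossible area/width combination: strokes shorter than 2 px")
  if (len > 4 * (H + W)) stop("canvas too small for requested stroke length")
  .withSeed(spec@seed, {
    for (k in seq_len(spec@count)) {
      pts <- .scribblePath(len, H, W, spec@curvatureScale,
                           margin = spec@strokeWidth + 1)
      mask <- .stampPath(mask, pts, spec@strokeWidth)
    }
  })
  BinaryImage(mask)
}

## rasterize one rotated ellipse; a = semi-major, b = semi-minor
.ellipseMask <- function(H, W, cy, cx, a, b, phi) {
  d <- ceiling(a) + 1
  ys <- max(1, floor(cy - d)):min(H, ceiling(cy + d))
  xs <- max(1, floor(cx - d)):min(W, ceiling(cx + d))
  yy <- outer(ys - cy, rep(1, length(xs)))
  xx <- outer(rep(1, length(ys)), xs - cx)
  u <- cos(phi) * xx + sin(phi) * yy
  v <- -sin(phi) * xx + cos(phi) * yy
  inside <- (u / a)^2 + (v / b)^2 <= 1
  list(ys = ys, xs = xs, inside = inside)
}

#' Generate a blotch mask
#'
#' Draws \code{count} compact elliptical discs of bounded eccentricity
#' (axis ratio at least 0.75, random orientation), placed with rejection
#' sampling so that the discs are pairwise disjoint with at least two
#' background pixels between them. Each disc has the area of a circle of
#' the spec radius; if the radius is \code{NA} it is derived from
#' \code{targetTotalArea / count}.
#'
#' @param spec a \linkS4class{MarkingSpec} with \code{kind = "blotch"}.
#' @param canvas integer c(height, width), pixels.
#' @return A \linkS4class{BinaryImage} containing all blotches.
#' @examples
#' m <- generateBlotch(markingSpec("blotch", count = 3, radius = 6,
#'                                 seed = 2), canvas = c(80, 80))
#' eulerCharacteristic(m)   # 3 disjoint discs
#' @export
generateBlotch <- function(spec, canvas = c(160, 120)) {
  stopifnot(is(spec, "MarkingSpec"), spec@kind == "blotch")
  H <- canvas[1]; W <- canvas[2]
  mask <- matrix(FALSE, H, W)
  if (spec@count == 0) return(BinaryImage(mask))
  r <- if (is.na(spec@radius)) sqrt(spec@targetTotalArea / (spec@count * pi))
       else spec@radius
  if (r < 1) stop("impossible area/count combination: radius below 1 px")
  rmax <- r / sqrt(0.75)                  # largest possible semi-axis
  if (2 * (rmax + 3) >= min(H, W))
    stop("cannot place blotches of radius ", round(r, 1),
         " on a ", H, "x", W, " canvas")
  .withSeed(spec@seed, {
    placed <- 0; tries <- 0
    while (placed < spec@count) {
      tries <- tries + 1
      if (tries > 2000 * spec@count)
        stop("cannot place ", spec@count, " disjoint blotches of radius ",
             round(r, 1), " on a ", H, "x", W, " canvas")
      cy <- stats::runif(1, rmax + 3, H - rmax - 2)
      cx <- stats::runif(1, rmax + 3, W - rmax - 2)
      q <- stats::runif(1, 0.75, 1)       # bounded eccentricity
      phi <- stats::runif(1, 0, pi)
      a <- r / sqrt(q); b <- r * sqrt(q)
      # enlarged ellipse guarantees >= 2 background px between blotches
      grown <- .ellipseMask(H, W, cy, cx, a + 2.5, b + 2.5, phi)
      if (any(mask[grown$ys, grown$xs] & grown$inside)) next
      e <- .ellipseMask(H, W, cy, cx, a, b, phi)
      mask[e$ys, e$xs] <- mask[e$ys, e$xs] | e$inside
      placed <- placed + 1
    }
  })
  BinaryImage(mask)
}

#' Match blotch area to a set of scribbles
#'
#' Solves for the blotch radius so that \code{blotchSpec@count} blotches
#' total approximately the same area as the given scribble masks: the
#' closed-form radius \eqn{\sqrt{T/(m\pi)}} followed by a multiplicative
#' digital correction, iterated until the blotch total is within
#' \code{tolerance} of the scribble total.
#'
#' @param scribbles a \linkS4class{BinaryImage}, or a list of them, whose
#'   summed foreground area is the target.
#' @param blotchSpec a \linkS4class{MarkingSpec} with
#'   \code{kind = "blotch"}; its \code{radius} is overridden.
#' @param canvas integer c(height, width), pixels.
#' @param tolerance relative area tolerance (default 0.05).
#' @return A \linkS4class{BinaryImage} of blotches area-matched to the
#'   scribbles; attribute \code{"radius"} records the solved radius.
#' @examples
#' sc <- generateScribble(markingSpec("scribble", count = 2,
#'                                    targetTotalArea = 600, seed = 3),
#'                        canvas = c(96, 96))
#' bl <- matchArea(sc, markingSpec("blotch", count = 4, seed = 3),
#'                 canvas = c(96, 96))
#' abs(binaryArea(bl) - binaryArea(sc)) / binaryArea(sc) < 0.05
#' @export
matchArea <- function(scribbles, blotchSpec, canvas = c(160, 120),
                      tolerance = 0.05) {
  stopifnot(is(blotchSpec, "MarkingSpec"), blotchSpec@kind == "blotch")
  if (is(scribbles, "BinaryImage")) scribbles <- list(scribbles)
  target <- sum(vapply(scribbles, binaryArea, numeric(1)))
  if (target == 0) {
    empty <- blotchSpec; empty@count <- 0
    out <- generateBlotch(empty, canvas)
    attr(out, "radius") <- 0
    return(out)
  }
  m <- blotchSpec@count
  if (m < 1) stop("area matching needs at least one blotch")
  r <- sqrt(target / (m * pi))
  for (it in 1:12) {
    sp <- blotchSpec; sp@radius <- r
    out <- generateBlotch(sp, canvas)
    got <- binaryArea(out)
    if (abs(got - target) / target <= tolerance) {
      attr(out, "radius") <- r
      return(out)
    }
    r <- r * sqrt(target / got)
    if (r < 1) stop("tolerance unreachable with requested blotch count")
  }
  stop("area matching did not converge to within the requested tolerance")
}

## inscribed elliptical ROI with a small margin
.eggMask <- function(H, W, margin = 3) {
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  a <- H / 2 - margin; b <- W / 2 - margin
  yy <- matrix(seq_len(H) - cy, H, W)
  xx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  (yy / a)^2 + (xx / b)^2 <= 1
}

#' Compose a synthetic egg image
#'
#' Builds an \linkS4class{IntensityImage} in the marking-intensity
#' convention: a smooth low-frequency background (base level plus a
#' broad cosine ripple), markings composited at their intensities,
#' Gaussian pixel noise, clipping to \eqn{[0,1]}, and an inscribed
#' elliptical egg ROI mask. With no markings, zero ripple and zero noise
#' the image is constant and flagged degenerate.
#'
#' @param canvas integer c(height, width), pixels.
#' @param markings list of \code{list(mask =, intensity =)} entries; the
#'   mask may be a \linkS4class{BinaryImage} or logical matrix.
#' @param backgroundLevel base background intensity (default 0.25).
#' @param backgroundAmp amplitude of the low-frequency background ripple
#'   (default 0.05).
#' @param noiseSd Gaussian pixel-noise sd (default 0.02).
#' @param seed RNG seed for the noise and ripple phase.
#' @return An \linkS4class{IntensityImage} with an elliptical ROI.
#' @examples
#' sc <- generateScribble(markingSpec("scribble", seed = 1), c(160, 120))
#' egg <- composeEgg(c(160, 120),
#'                   markings = list(list(mask = sc, intensity = 0.85)),
#'                   seed = 1)
#' @export
composeEgg <- function(canvas = c(160, 120), markings = list(),
                       backgroundLevel = 0.25, backgroundAmp = 0.05,
                       noiseSd = 0.02, seed = 1) {
  H <- canvas[1]; W <- canvas[2]
  px <- matrix(backgroundLevel, H, W)
  .withSeed(seed, {
    if (backgroundAmp > 0) {
      phy <- stats::runif(1, 0, 2 * pi); phx <- stats::runif(1, 0, 2 * pi)
      ry <- cos(2 * pi * seq_len(H) / H + phy)
      rx <- cos(2 * pi * seq_len(W) / W + phx)
      px <- px + backgroundAmp * outer(ry, rx)
    }
    for (mk in markings) {
      m <- .binPixels(mk$mask)
      if (!identical(dim(m), dim(px)))
        stop("marking mask dimensions do not match the canvas")
      px[m] <- pmax(px[m], mk$intensity)
    }
    if (noiseSd > 0)
      px <- px + matrix(stats::rnorm(H * W, 0, noiseSd), H, W)
  })
  px[px < 0] <- 0; px[px > 1] <- 1
  mask <- .eggMask(H, W)
  out <- IntensityImage(px, mask, meta = list(source = "synthetic"))
  out@meta$degenerate <- .isConstant(px, mask)
  out
}

#' Paint markings onto an existing egg image
#'
#' Emulates the egg-manipulation treatments: composite scribbles or
#' blotches onto the image at the paint intensity, or apply the
#' \code{"water"} handling-only control, which leaves the pixels
#' unchanged. The treatment is recorded in the image metadata.
#'
#' @param img a preprocessed \linkS4class{IntensityImage}.
#' @param kind \code{"scribbles"}, \code{"blotches"} or \code{"water"}.
#' @param count number of markings painted (default 5 scribbles /
#'   10 blotches, the treatment counts of the rejection experiment).
#' @param paintIntensity marking intensity of the paint (default 0.85,
#'   matching the generator's marking intensity: the field paint was
#'   colour-matched to natural markings).
#' @param targetTotalArea total painted area aimed for, pixels.
#' @param seed RNG seed.
#' @return The painted \linkS4class{IntensityImage};
#'   \code{imgMeta(x)$treatment} records the treatment.
#' @examples
#' egg <- composeEgg(c(96, 72), seed = 1)
#' identical(pixels(paintMarkings(egg, "water")), pixels(egg))
#' @export
paintMarkings <- function(img, kind = c("scribbles", "blotches", "water"),
                          count = NULL, paintIntensity = 0.85,
                          targetTotalArea = 2000, seed = 1) {
  stopifnot(is(img, "IntensityImage"))
  kind <- match.arg(kind)
  img@meta$treatment <- kind
  if (kind == "water") return(img)
  if (is.null(count)) count <- if (kind == "scribbles") 5 else 10
  if (count == 0) return(img)
  canvas <- dim(img@pixels)
  mk <- if (kind == "scribbles") {
    generateScribble(markingSpec("scribble", count = count,
                                 targetTotalArea = targetTotalArea,
                                 intensity = paintIntensity, seed = seed),
                     canvas)
  } else {
    generateBlotch(markingSpec("blotch", count = count,
                               targetTotalArea = targetTotalArea,
                               intensity = paintIntensity, seed = seed),
                   canvas)
  }
  m <- mk@pixels
  if (!is.null(img@mask)) m <- m & img@mask   # paint only the egg surface
  img@pixels[m] <- pmax(img@pixels[m], paintIntensity)
  img@meta$degenerate <- .isConstant(img@pixels, img@mask)
  img
}
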