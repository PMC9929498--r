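#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' IntensityImage: a normalized marking-intensity field
#'
#' The central image container of the package: a 2-D scalar field in
#' \eqn{[0,1]} following the marking-intensity convention (high values are
#' pattern markings, low values background), with an optional region of
#' interest (ROI) mask restricting analysis to, for example, the visible
#' egg surface. All threshold-sweep measures operate on this class.
#'
#' @slot pixels numeric matrix with values in \eqn{[0,1]} (inside the ROI).
#' @slot mask optional logical matrix of the same dimension; \code{TRUE}
#'   marks pixels inside the ROI. \code{NULL} means the whole frame.
#' @slot meta list of provenance fields: \code{source}, \code{degenerate}
#'   (constant in-ROI intensity), \code{inverted}, \code{sigma} (smoothing
#'   scale in pixels), \code{treatment}.
#'
#' @aliases IntensityImage
#' @exportClass IntensityImage
setClass("IntensityImage",
  representation(pixels = "matrix", mask = "matrixOrNULL", meta = "list"),
  prototype(meta = list())
)

setValidity("IntensityImage", function(object) {
  px <- object@pixels
  msk <- object@mask
  if (!is.numeric(px)) return("'pixels' must be a numeric matrix")
  if (!is.null(msk)) {
    if (!is.logical(msk)) return("'mask' must be a logical matrix")
    if (!identical(dim(msk), dim(px)))
      return("'mask' dimensions must match 'pixels'")
    if (!any(msk)) return("ROI mask selects no pixels")
    vals <- px[msk]
  } else {
    vals <- px
  }
  if (any(!is.finite(vals))) return("non-finite in-ROI pixel values")
  if (any(vals < -1e-9) || any(vals > 1 + 1e-9))
    return("in-ROI pixel values must lie in [0, 1]")
  TRUE
})

#' Construct an IntensityImage
#'
#' @param pixels numeric matrix; in-ROI values must lie in \eqn{[0,1]}.
#' @param mask optional logical ROI matrix of the same dimension.
#' @param meta list of provenance fields.
#' @return An \linkS4class{IntensityImage}.
#' @examples
#' img <- IntensityImage(matrix(runif(64), 8, 8))
#' dim(pixels(img))
#' @export
IntensityImage <- function(pixels, mask = NULL, meta = list()) {
  meta <- utils::modifyList(
    list(source = NA_character_, degenerate = FALSE, inverted = FALSE,
         sigma = NA_real_, treatment = NA_character_),
    meta)
  new("IntensityImage", pixels = pixels, mask = mask, meta = meta)
}

#' BinaryImage: one level set of a threshold sweep
#'
#' The foreground produced by retaining pixels whose intensity is strictly
#' greater than one threshold level (and inside the ROI). Units are pixels.
#'
#' @slot pixels logical matrix; \code{TRUE} is foreground.
#' @slot level the generating threshold (dimensionless intensity), or
#'   \code{NA} for masks not produced by a sweep.
#'
#' @aliases BinaryImage
#' @exportClass BinaryImage
setClass("BinaryImage",
  representation(pixels = "matrix", level = "numeric"),
  prototype(level = NA_real_)
)

setValidity("BinaryImage", function(object) {
  if (!is.logical(object@pixels)) return("'pixels' must be a logical matrix")
  if (length(object@level) != 1L) return("'level' must be a single value")
  TRUE
})

#' Construct a BinaryImage
#'
#' @param pixels logical matrix (foreground \code{TRUE}).
#' @param level generating threshold level, if any.
#' @return A \linkS4class{BinaryImage}.
#' @examples
#' b <- BinaryImage(matrix(c(TRUE, FALSE), 4, 4))
#' binaryArea(b)
#' @export
BinaryImage <- function(pixels, level = NA_real_) {
  if (is.numeric(pixels)) {
    storage.mode(pixels) <- "logical"
  }
  new("BinaryImage", pixels = pixels, level = as.numeric(level))
}

#' MinkowskiCurve: per-threshold Minkowski measures and their integrals
#'
#' Holds the perimeter \eqn{P(t)}, area \eqn{A(t)} and Euler characteristic
#' \eqn{\chi(t)} over the threshold grid, together with the integrated
#' (summed) summaries \eqn{\Sigma P}, \eqn{\Sigma A}, \eqn{\Sigma Euler}
#' and \eqn{\Sigma(P^2/A)}.
#'
#' @slot levels numeric vector of threshold levels (dimensionless).
#' @slot perimeter perimeter per level, pixel-edge length units.
#' @slot area foreground area per level, pixels.
#' @slot euler Euler characteristic per level (integer-valued).
#' @slot summaries named numeric: \code{sumP}, \code{sumA}, \code{sumEuler},
#'   \code{sumP2A}.
#' @slot method perimeter estimator used (\code{"crofton4"} or
#'   \code{"boundary_edges"}).
#' @slot connectivity foreground connectivity convention (8 or 4).
#'
#' @aliases MinkowskiCurve
#' @exportClass MinkowskiCurve
setClass("MinkowskiCurve",
  representation(levels = "numeric", perimeter = "numeric", area = "numeric",
                 euler = "numeric", summaries = "numeric",
                 method = "character", connectivity = "numeric")
)

setValidity("MinkowskiCurve", function(object) {
  n <- length(object@levels)
  if (length(object@perimeter) != n || length(object@area) != n ||
      length(object@euler) != n)
    return("levels, perimeter, area and euler must have equal length")
  if (n > 1 && any(diff(object@area) > 1e-9))
    return("area must be non-increasing with increasing level")
  if (any(abs(object@euler - round(object@euler)) > 1e-9))
    return("euler values must be integer-valued")
  need <- c("sumP", "sumA", "sumEuler", "sumP2A")
  if (!all(need %in% names(object@summaries)))
    return("summaries must contain sumP, sumA, sumEuler, sumP2A")
  if (object@summaries[["sumP2A"]] < -1e-9)
    return("sumP2A must be non-negative")
  TRUE
})

#' FDAModel: flexible discriminant analysis fit by optimal scoring
#'
#' Stores the discriminant directions obtained by regressing optimally
#' scored class indicators on (possibly basis-expanded) standardized
#' traits, together with everything needed to assign new specimens:
#' class centroids in discriminant space, eigenvalues, priors and the
#' standardization constants.
#'
#' @slot basis \code{"linear"} or \code{"polynomial2"}.
#' @slot classLevels class labels, in factor-level order.
#' @slot coefficients basis-column-by-discriminant matrix of standardized
#'   coefficients.
#' @slot intercepts per-discriminant intercepts.
#' @slot eigenvalues optimal-scoring eigenvalues (squared canonical
#'   correlations), one per discriminant, each in (0, 1).
#' @slot centroids class-by-discriminant matrix of centroid coordinates.
#' @slot priors training class proportions.
#' @slot center,scale. standardization constants for the raw traits.
#' @slot traitNames names of the raw trait columns.
#' @slot importance per-basis-column contribution to the first discriminant,
#'   percentages summing to 100.
#' @slot ridge ridge penalty used in the scoring regression (0 = none).
#' @slot nobs number of training rows.
#' @slot trainingSummary list with per-class resubstitution assignment
#'   rates (percent) and the scheme used to compute them.
#'
#' @aliases FDAModel
#' @exportClass FDAModel
setClass("FDAModel",
  representation(basis = "character", classLevels = "character",
                 coefficients = "matrix", intercepts = "numeric",
                 eigenvalues = "numeric", centroids = "matrix",
                 priors = "numeric", center = "numeric", scale. = "numeric",
                 traitNames = "character", importance = "numeric",
                 ridge = "numeric", nobs = "numeric",
                 trainingSummary = "list")
)

setValidity("FDAModel", function(object) {
  K <- length(object@classLevels)
  J <- ncol(object@coefficients)
  if (J > K - 1) return("at most (classes - 1) discriminants are allowed")
  if (abs(sum(object@importance) - 100) > 1e-9)
    return("coefficient importances must sum to 100")
  if (any(object@eigenvalues <= 0) || any(object@eigenvalues >= 1))
    return("eigenvalues must lie strictly in (0, 1)")
  if (nrow(object@centroids) != K)
    return("centroids must have one row per class")
  TRUE
})

#' GlmResult: Wald summary of a binomial logistic regression
#'
#' Coefficient table of a logit fit of a binary outcome on a categorical
#' treatment, in the reporting layout used for receiver-response
#' experiments: per-coefficient estimate (log-odds), standard error,
#' Wald Z and two-sided p, plus the reference level and residual df.
#'
#' @slot coefficients data.frame with columns \code{term}, \code{estimate},
#'   \code{se}, \code{z}, \code{p}.
#' @slot reference the treatment level absorbed into the intercept.
#' @slot residualDf residual degrees of freedom (n minus coefficients).
#' @slot nobs number of trials.
#' @slot separation TRUE if the fit showed signs of complete separation.
#' @slot fit the underlying \code{\link[stats]{glm}} object.
#'
#' @aliases GlmResult
#' @exportClass GlmResult
setClass("GlmResult",
  representation(coefficients = "data.frame", reference = "character",
                 residualDf = "numeric", nobs = "numeric",
                 separation = "logical", fit = "ANY")
)

setValidity("GlmResult", function(object) {
  need <- c("term", "estimate", "se", "z", "p")
  if (!all(need %in% names(object@coefficients)))
    return("coefficient table must have term, estimate, se, z, p")
  ok <- with(object@coefficients, abs(z - estimate / se) < 1e-6)
  if (!all(ok)) return("z must equal estimate/se")
  TRUE
})

#' MarkingSpec: parameters of a synthetic marking generator
#'
#' Describes one family of synthetic markings: long thin smooth strokes
#' ("scribbles") or compact elliptical discs ("blotches").
#'
#' @slot kind \code{"scribble"} or \code{"blotch"}.
#' @slot count number of markings.
#' @slot strokeWidth stroke width in pixels (scribbles).
#' @slot radius equivalent-circle radius in pixels (blotches); \code{NA}
#'   derives it from \code{targetTotalArea}.
#' @slot targetTotalArea total marking area to aim for, pixels.
#' @slot curvatureScale sd of the per-step heading increment, radians
#'   (scribbles).
#' @slot intensity marking intensity in \eqn{[0,1]}.
#' @slot seed RNG seed making the generator a pure function of the spec.
#'
#' @aliases MarkingSpec
#' @exportClass MarkingSpec
setClass("MarkingSpec",
  representation(kind = "character", count = "numeric",
                 strokeWidth = "numeric", radius = "numeric",
                 targetTotalArea = "numeric", curvatureScale = "numeric",
                 intensity = "numeric", seed = "numeric")
)

setValidity("MarkingSpec", function(object) {
  if (!object@kind %in% c("scribble", "blotch"))
    return("kind must be 'scribble' or 'blotch'")
  if (object@count < 0) return("count must be >= 0")
  if (!is.na(object@strokeWidth) && object@strokeWidth < 1)
    return("strokeWidth must be >= 1 pixel")
  if (!is.na(object@radius) && object@radius < 1)
    return("radius must be >= 1 pixel")
  if (object@intensity < 0 || object@intensity > 1)
    return("intensity must lie in [0, 1]")
  TRUE
})

#' Construct a MarkingSpec
#'
#' @param kind \code{"scribble"} or \code{"blotch"}.
#' @param count number of markings (default 5 scribbles / 10 blotches,
#'   mirroring the painting treatments).
#' @param strokeWidth scribble stroke width, pixels.
#' @param radius blotch equivalent radius, pixels; \code{NA} means derive
#'   from \code{targetTotalArea}.
#' @param targetTotalArea total marking area, pixels.
#' @param curvatureScale sd of the scribble heading increment per unit
#'   step, radians.
#' @param intensity marking intensity in \eqn{[0,1]}.
#' @param seed RNG seed.
#' @return A \linkS4class{MarkingSpec}.
#' @examples
#' markingSpec("scribble", count = 5, seed = 1)
#' @export
markingSpec <- function(kind = c("scribble", "blotch"),
                        count = if (kind == "scribble") 5 else 10,
                        strokeWidth = 3, radius = NA_real_,
                        targetTotalArea = 2000, curvatureScale = 0.2,
                        intensity = 0.85, seed = 1) {
  kind <- match.arg(kind)
  new("MarkingSpec", kind = kind, count = as.numeric(count),
      strokeWidth = as.numeric(strokeWidth), radius = as.numeric(radius),
      targetTotalArea = as.numeric(targetTotalArea),
      curvatureScale = as.numeric(curvatureScale),
      intensity = as.numeric(intensity), seed = as.numeric(seed))
}
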