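#' Accessors for package classes
#'
#' Extract the pixel matrix, ROI mask or metadata list of an
#' \linkS4class{IntensityImage} or \linkS4class{BinaryImage}; the
#' per-threshold sequences and integrated summaries of a
#' \linkS4class{MinkowskiCurve}; and the coefficient table of a
#' \linkS4class{GlmResult}.
#'
#' @param x an object of the documented class.
#' @return \code{pixels}: a matrix. \code{roiMask}: a logical matrix or
#'   \code{NULL}. \code{imgMeta}: a list. \code{sweepLevels},
#'   \code{areaCurve}, \code{perimeterCurve}, \code{eulerCurve}: numeric
#'   vectors over the threshold grid. \code{curveSummaries}: named numeric
#'   with \code{sumP}, \code{sumA}, \code{sumEuler}, \code{sumP2A}.
#'   \code{coefTable}: a data.frame.
#'
#' @name accessors
#' @aliases pixels roiMask imgMeta sweepLevels areaCurve perimeterCurve
#'   eulerCurve curveSummaries coefTable
#' @examples
#' img <- IntensityImage(matrix(runif(64), 8, 8))
#' range(pixels(img))
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))
#' @rdname accessors
#' @export
setGeneric("imgMeta", function(x) standardGeneric("imgMeta"))
#' @rdname accessors
#' @export
setGeneric("sweepLevels", function(x) standardGeneric("sweepLevels"))
#' @rdname accessors
#' @export
setGeneric("areaCurve", function(x) standardGeneric("areaCurve"))
#' @rdname accessors
#' @export
setGeneric("perimeterCurve", function(x) standardGeneric("perimeterCurve"))
#' @rdname accessors
#' @export
setGeneric("eulerCurve", function(x) standardGeneric("eulerCurve"))
#' @rdname accessors
#' @export
setGeneric("curveSummaries", function(x) standardGeneric("curveSummaries"))
#' @rdname accessors
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))

#' @rdname accessors
setMethod("pixels", "IntensityImage", function(x) x@pixels)
#' @rdname accessors
setMethod("pixels", "BinaryImage", function(x) x@pixels)
#' @rdname accessors
setMethod("roiMask", "IntensityImage", function(x) x@mask)
#' @rdname accessors
setMethod("imgMeta", "IntensityImage", function(x) x@meta)
#' @rdname accessors
setMethod("sweepLevels", "MinkowskiCurve", function(x) x@levels)
#' @rdname accessors
setMethod("areaCurve", "MinkowskiCurve", function(x) x@area)
#' @rdname accessors
setMethod("perimeterCurve", "MinkowskiCurve", function(x) x@perimeter)
#' @rdname accessors
setMethod("eulerCurve", "MinkowskiCurve", function(x) x@euler)
#' @rdname accessors
setMethod("curveSummaries", "MinkowskiCurve", function(x) x@summaries)
#' @rdname accessors
setMethod("coefTable", "GlmResult", function(x) x@coefficients)

setMethod("show", "IntensityImage", function(object) {
  d <- dim(object@pixels)
  nin <- if (is.null(object@mask)) prod(d) else sum(object@mask)
  cat(sprintf("IntensityImage %d x %d (%d in-ROI px)\n", d[1], d[2], nin))
  v <- if (is.null(object@mask)) object@pixels else object@pixels[object@mask]
  cat(sprintf("  intensity range [%.3f, %.3f]%s\n", min(v), max(v),
              if (isTRUE(object@meta$degenerate)) " (degenerate)" else ""))
  cat(sprintf("  inverted: %s, sigma: %s\n",
              isTRUE(object@meta$inverted),
              format(object@meta$sigma)))
})

setMethod("show", "BinaryImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BinaryImage %d x %d, %d foreground px, level %s\n",
              d[1], d[2], sum(object@pixels), format(object@level)))
})

setMethod("show", "MinkowskiCurve", function(object) {
  cat(sprintf("MinkowskiCurve over %d levels (%s perimeter, %d-connectivity)\n",
              length(object@levels), object@method, object@connectivity))
  s <- object@summaries
  cat(sprintf("  SigmaP = %.1f  SigmaA = %.0f  SigmaEuler = %.0f  Sigma(P2/A) = %.2f\n",
              s[["sumP"]], s[["sumA"]], s[["sumEuler"]], s[["sumP2A"]]))
})

setMethod("show", "FDAModel", function(object) {
  cat(sprintf("FDAModel (%s basis): %d classes, %d discriminant(s), n = %d\n",
              object@basis, length(object@classLevels),
              ncol(object@coefficients), object@nobs))
  imp <- sort(object@importance, decreasing = TRUE)
  cat("  first-discriminant importances (%):\n")
  for (nm in names(imp)) cat(sprintf("    %-28s %5.1f\n", nm, imp[[nm]]))
  ts <- object@trainingSummary
  if (length(ts$rates))
    cat(sprintf("  %s assignment rates: %s\n", ts$scheme,
                paste(sprintf("%s %.0f%%", names(ts$rates), ts$rates),
                      collapse = ", ")))
})

setMethod("show", "GlmResult", function(object) {
  cat(sprintf("Binomial logit fit, n = %d trials, reference level '%s'\n",
              object@nobs, object@reference))
  tab <- object@coefficients
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-22s %6.2f +/- %.2f  Z_%d = %.2f, p = %.2f\n",
                tab$term[i], tab$estimate[i], tab$se[i],
                object@residualDf, tab$z[i], tab$p[i]))
  if (object@separation) cat("  warning: separation detected\n")
})

setMethod("show", "MarkingSpec", function(object) {
  cat(sprintf("MarkingSpec: %d %s(s), target area %.0f px, intensity %.2f, seed %d\n",
              object@count, object@kind, object@targetTotalArea,
              object@intensity, object@seed))
})
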