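## Classification stage: principal-component reduction of trait blocks
## and flexible discriminant analysis (FDA) by optimal scoring. With the
## linear basis the fitted rule coincides exactly with classical linear
## discriminant analysis; the degree-2 polynomial basis provides FDA's
## flexibility for curved class boundaries.

#' Principal-component reduction of a trait table
#'
#' Standardizes the columns (centre, unit variance) and returns the
#' smallest number of principal components whose cumulative explained
#' variance reaches \code{varFraction}, together with the loadings and
#' per-component explained fractions.
#'
#' @param X numeric matrix or data.frame of traits (rows = specimens).
#' @param varFraction target cumulative explained-variance fraction in
#'   (0, 1] (e.g. 0.88 or 0.94 for the usual two-component reductions).
#' @return A list: \code{scores} (n x k), \code{loadings} (p x k),
#'   \code{explained} (all per-component fractions), \code{k}.
#' @examples
#' X <- matrix(rnorm(100), 20, 5)
#' pcaReduce(X, 0.9)$k
#' @export
pcaReduce <- function(X, varFraction = 0.9) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows")
  if (varFraction <= 0 || varFraction > 1)
    stop("varFraction must lie in (0, 1]")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant trait column(s): ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(explained) >= varFraction - 1e-12)[1]
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained = explained, k = k)
}

## basis expansion of standardized traits
.expandBasis <- function(Xs, basis) {
  if (basis == "linear") return(Xs)
  p <- ncol(Xs)
  nms <- colnames(Xs)
  sq <- Xs^2
  colnames(sq) <- paste0(nms, "^2")
  crosses <- NULL
  if (p >= 2) {
    cmb <- utils::combn(p, 2)
    crosses <- matrix(0, nrow(Xs), ncol(cmb))
    colnames(crosses) <- apply(cmb, 2, function(ij)
      paste0(nms[ij[1]], ":", nms[ij[2]]))
    for (c_ in seq_len(ncol(cmb)))
      crosses[, c_] <- Xs[, cmb[1, c_]] * Xs[, cmb[2, c_]]
  }
  cbind(Xs, sq, crosses)
}

#' Fit a flexible discriminant analysis by optimal scoring
#'
#' Regresses optimally scored class indicators on the (optionally
#' basis-expanded) standardized traits: the class-indicator matrix is
#' regressed on the basis, the resulting score matrix is
#' eigen-decomposed in the class-proportion metric, and the nontrivial
#' eigenvectors give the optimal scores and discriminant directions.
#' With the linear basis the resulting classification rule is exactly
#' classical linear discriminant analysis with proportional priors.
#'
#' Assignments minimize the within-class Mahalanobis distance to the
#' class centroid in discriminant space minus twice the log prior, with
#' the within-class metric scaled by \eqn{(n-K)/n} (the bias-corrected
#' pooled covariance).
#'
#' @param X numeric matrix or data.frame of traits (rows = specimens).
#' @param labels class labels (coerced to factor), one per row;
#'   at least 2 classes with at least 2 rows each.
#' @param basis \code{"linear"} (default) or \code{"polynomial2"}
#'   (adds squares and pairwise products).
#' @param ridge ridge penalty added to the scoring regression
#'   (default 0); use a small positive value if the fit reports a
#'   singular within-class structure.
#' @return An \linkS4class{FDAModel}.
#' @examples
#' X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 2), 20))
#' colnames(X) <- c("t1", "t2")
#' fitFDA(X, rep(c("a", "b"), each = 20))
#' @export
fitFDA <- function(X, labels, basis = c("linear", "polynomial2"),
                   ridge = 0) {
  basis <- match.arg(basis)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("trait", seq_len(ncol(X)))
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 rows")
  if (nrow(X) != length(y)) stop("X rows and labels differ in length")
  n <- nrow(X); K <- nlevels(y)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0))
    stop("constant trait column(s) after standardization: ",
         paste(colnames(X)[scl == 0], collapse = ", "))
  Xs <- scale(X, ctr, scl)
  Xb <- .expandBasis(Xs, basis)
  Y <- stats::model.matrix(~ y - 1)
  Xa <- cbind(`(Intercept)` = 1, Xb)
  G <- crossprod(Xa)
  if (ridge > 0) {
    pen <- diag(c(0, rep(ridge, ncol(Xb))))
    G <- G + pen
  }
  B <- tryCatch(solve(G, crossprod(Xa, Y)),
                error = function(e)
                  stop("singular within-class structure; ",
                       "refit with a positive 'ridge' value", call. = FALSE))
  Yhat <- Xa %*% B
  Pi <- colMeans(Y)
  M <- crossprod(Y, Yhat) / n
  S <- diag(1 / sqrt(Pi)) %*% M %*% diag(1 / sqrt(Pi))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  keep <- which(e$values < 1 - 1e-8 & e$values > 1e-8)
  if (!length(keep))
    stop("no informative discriminant directions; ",
         "classes may be indistinguishable or the fit degenerate")
  keep <- keep[seq_len(min(K - 1, length(keep)))]
  lam <- e$values[keep]
  Theta <- diag(1 / sqrt(Pi)) %*% e$vectors[, keep, drop = FALSE]
  coef <- B[-1, , drop = FALSE] %*% Theta
  rownames(coef) <- colnames(Xb)
  colnames(coef) <- paste0("D", seq_along(keep))
  int <- drop(B[1, , drop = FALSE] %*% Theta)
  eta <- Xb %*% coef + matrix(int, n, length(keep), byrow = TRUE)
  cent <- matrix(apply(eta, 2, function(cl) tapply(cl, y, mean)),
                 nrow = K,
                 dimnames = list(levels(y), colnames(coef)))
  a1 <- abs(coef[, 1])
  importance <- 100 * a1 / sum(a1)
  names(importance) <- rownames(coef)
  model <- new("FDAModel", basis = basis, classLevels = levels(y),
               coefficients = coef, intercepts = int, eigenvalues = lam,
               centroids = cent, priors = stats::setNames(Pi, levels(y)),
               center = ctr, scale. = scl, traitNames = colnames(X),
               importance = importance, ridge = ridge, nobs = n,
               trainingSummary = list())
  pred <- predictClasses(model, X)
  rates <- vapply(levels(y), function(k)
    100 * mean(pred[y == k] == k), numeric(1))
  model@trainingSummary <- list(scheme = "resubstitution", rates = rates)
  model
}

## discriminant-space distances; columns = classes
.fdaDistances <- function(model, X) {
  X <- as.matrix(X)
  if (!identical(colnames(X), model@traitNames)) {
    if (is.null(colnames(X)) && ncol(X) == length(model@traitNames)) {
      colnames(X) <- model@traitNames
    } else if (all(model@traitNames %in% colnames(X))) {
      X <- X[, model@traitNames, drop = FALSE]
    } else {
      stop("trait columns do not match the fitted model (expected: ",
           paste(model@traitNames, collapse = ", "), ")")
    }
  }
  Xs <- scale(X, model@center, model@scale.)
  Xb <- .expandBasis(Xs, model@basis)
  eta <- Xb %*% model@coefficients +
    matrix(model@intercepts, nrow(Xb), ncol(model@coefficients), byrow = TRUE)
  w <- 1 / (model@eigenvalues * (1 - model@eigenvalues))
  n <- model@nobs; K <- length(model@classLevels)
  scale_ <- (n - K) / n            # bias-corrected pooled-covariance metric
  d <- vapply(seq_len(K), function(k)
    scale_ * colSums(w * (t(eta) - model@centroids[k, ])^2) -
      2 * log(model@priors[k]),
    numeric(nrow(Xb)))
  if (nrow(Xb) == 1) d <- matrix(d, nrow = 1)
  colnames(d) <- model@classLevels
  d
}

#' Predict class assignments from a fitted FDA model
#'
#' @param model an \linkS4class{FDAModel}.
#' @param X trait matrix or data.frame with the model's trait columns.
#' @return Factor of assigned classes, one per row of \code{X}.
#' @export
predictClasses <- function(model, X) {
  if (!is(model, "FDAModel")) stop("expected a fitted FDAModel")
  d <- .fdaDistances(model, X)
  factor(model@classLevels[max.col(-d, ties.method = "first")],
         levels = model@classLevels)
}

#' Per-class correct-assignment rates
#'
#' Percentage of specimens of each class assigned to their own class,
#' under resubstitution (assign the training rows with the fitted model)
#' or leave-one-out cross-validation (refit n times without each row).
#' The scheme used is always recorded in the result, since reported
#' assignment rates are not comparable across schemes.
#'
#' @param X trait matrix or data.frame.
#' @param labels true class labels, one per row.
#' @param basis,ridge passed to \code{\link{fitFDA}}.
#' @param scheme \code{"resubstitution"} (default) or
#'   \code{"leave_one_out"}.
#' @return A list: \code{rates} (named percentages per class),
#'   \code{overall} (percentage), \code{scheme}, \code{assigned}
#'   (factor of assignments).
#' @examples
#' X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' colnames(X) <- c("t1", "t2")
#' assignmentRates(X, rep(c("a", "b"), each = 20))$rates
#' @export
assignmentRates <- function(X, labels, basis = "linear", ridge = 0,
                            scheme = c("resubstitution", "leave_one_out")) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  y <- factor(labels)
  if (scheme == "resubstitution") {
    model <- fitFDA(X, y, basis, ridge)
    pred <- predictClasses(model, X)
  } else {
    pred <- factor(rep(NA_character_, nrow(X)), levels = levels(y))
    for (i in seq_len(nrow(X))) {
      mi <- fitFDA(X[-i, , drop = FALSE], y[-i], basis, ridge)
      pred[i] <- predictClasses(mi, X[i, , drop = FALSE])
    }
  }
  rates <- vapply(levels(y), function(k)
    100 * mean(pred[y == k] == k, na.rm = TRUE), numeric(1))
  list(rates = rates, overall = 100 * mean(pred == y, na.rm = TRUE),
       scheme = scheme, assigned = pred)
}

#' Trait contributions to the first discriminant
#'
#' Absolute standardized first-discriminant coefficients, normalized to
#' sum to 100: the percentage contribution of each basis column to the
#' leading discriminant direction.
#'
#' @param model a fitted \linkS4class{FDAModel}.
#' @return Named numeric percentages summing to 100.
#' @examples
#' X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 2), 20))
#' colnames(X) <- c("t1", "t2")
#' sum(coefficientImportance(fitFDA(X, rep(c("a", "b"), each = 20))))
#' @export
coefficientImportance <- function(model) {
  if (!is(model, "FDAModel")) stop("expected a fitted FDAModel")
  model@importance
}
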