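## Receiver-response statistics: reconstructing trial counts from
## reported rejection frequencies, the binomial logistic regression of
## rejection on treatment, and the before/after matched-pairs t-test.

#' Reconstruct rejection counts from frequencies and sample sizes
#'
#' \code{count = round-half-up(frequency x n)}: recovers integer
#' rejection counts from per-treatment rejection proportions as printed
#' in a figure caption, given the treatment sample sizes.
#'
#' @param freqs rejection proportions per treatment, each in [0, 1].
#' @param ns positive integer sample sizes, same length (and names) as
#'   \code{freqs}.
#' @return Named integer vector of rejection counts.
#' @examples
#' reconstructCounts(c(scribbles = 0.65, blotches = 0.57, water = 0.62),
#'                   c(scribbles = 17, blotches = 14, water = 13))
#' @export
reconstructCounts <- function(freqs, ns) {
  if (any(freqs < 0) || any(freqs > 1)) stop("freqs must lie in [0, 1]")
  if (any(ns < 1) || any(ns != round(ns))) stop("ns must be positive integers")
  if (length(freqs) != length(ns)) stop("freqs and ns differ in length")
  counts <- as.integer(floor(freqs * ns + 0.5))   # round half up
  names(counts) <- if (!is.null(names(freqs))) names(freqs) else names(ns)
  counts
}

#' Expand counts into Bernoulli trial records
#'
#' Builds the trial-level data.frame consumed by
#' \code{\link{fitLogistic}}: one row per trial with the treatment level
#' and the binary rejection outcome.
#'
#' @param counts named rejection counts per treatment.
#' @param ns named sample sizes per treatment (same names).
#' @return A data.frame with columns \code{treatment} (factor, levels in
#'   alphabetical order) and \code{rejected} (0/1).
#' @examples
#' buildTrialRecords(c(scribbles = 11, blotches = 8, water = 8),
#'                   c(scribbles = 17, blotches = 14, water = 13))
#' @export
buildTrialRecords <- function(counts, ns) {
  if (is.null(names(counts)) || is.null(names(ns)))
    stop("counts and ns must be named by treatment")
  if (!setequal(names(counts), names(ns)))
    stop("counts and ns must have the same treatment names")
  ns <- ns[names(counts)]
  if (any(counts > ns)) stop("counts cannot exceed sample sizes")
  treatment <- rep(names(counts), ns)
  rejected <- unlist(lapply(seq_along(counts), function(i)
    c(rep(1L, counts[i]), rep(0L, ns[i] - counts[i]))))
  data.frame(treatment = factor(treatment), rejected = rejected)
}

#' Logistic regression of rejection on treatment
#'
#' Maximum-likelihood binomial logit fit (via \code{\link[stats]{glm}},
#' i.e. iteratively reweighted least squares) of the binary rejection
#' outcome on the categorical treatment, reported as Wald statistics:
#' per-coefficient log-odds estimate, standard error, Z and two-sided p.
#' For this saturated one-factor design the estimates equal closed-form
#' log-odds differences between treatment cells and the reference, and
#' the standard errors equal the square root of the summed reciprocal
#' cell counts. Complete separation (a cell with 0 or 100\% rejection)
#' is detected and flagged rather than silently diverging.
#'
#' @param records data.frame with columns \code{treatment} and
#'   \code{rejected} (0/1), as from \code{\link{buildTrialRecords}}.
#' @param reference treatment level to absorb into the intercept
#'   (default \code{"blotches"}; alphabetically first among the standard
#'   treatment labels, matching R's default factor ordering).
#' @return A \linkS4class{GlmResult}.
#' @examples
#' rec <- buildTrialRecords(c(blotches = 8, scribbles = 11, water = 8),
#'                          c(blotches = 14, scribbles = 17, water = 13))
#' coefTable(fitLogistic(rec))
#' @export
fitLogistic <- function(records, reference = "blotches") {
  if (!all(c("treatment", "rejected") %in% names(records)))
    stop("records need 'treatment' and 'rejected' columns")
  records$treatment <- factor(records$treatment)
  if (!reference %in% levels(records$treatment))
    stop("reference level '", reference, "' not present in the data")
  if (any(table(records$treatment) < 1))
    stop("every treatment level needs at least one record")
  records$treatment <- stats::relevel(records$treatment, ref = reference)
  fit <- stats::glm(rejected ~ treatment, family = stats::binomial(),
                    data = records,
                    control = stats::glm.control(epsilon = 1e-14,
                                                 maxit = 200))
  cells <- tapply(records$rejected, records$treatment, mean)
  separated <- any(cells %in% c(0, 1)) || !fit$converged ||
    any(abs(stats::coef(fit)) > 10)
  if (separated)
    warning("complete or quasi-complete separation detected; ",
            "Wald statistics are unreliable")
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)
  terms[terms != "(Intercept)"] <-
    sub("^treatment", "treatment-", terms[terms != "(Intercept)"])
  tab <- data.frame(term = terms, estimate = sm[, 1], se = sm[, 2],
                    z = sm[, 3], p = sm[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  new("GlmResult", coefficients = tab, reference = reference,
      residualDf = nrow(records) - nrow(tab), nobs = nrow(records),
      separation = separated, fit = fit)
}

#' Matched-pairs t-test
#'
#' Classical paired t-test on \code{after - before} differences
#' (\code{df = n - 1}), used to test whether a manipulation such as
#' painting scribbles raised a trait value. Differences that are all
#' exactly zero return \code{t = 0, p = 1} by convention (flagged);
#' constant nonzero differences have no valid t statistic and error.
#'
#' @param before,after numeric vectors of equal length \eqn{\ge 2};
#'   pairs are matched by position.
#' @return A list: \code{statistic} (t), \code{df}, \code{p.value}
#'   (two-sided), \code{estimate} (mean difference after - before),
#'   \code{zeroVariance} flag.
#' @examples
#' pairedTTest(c(1, 2, 3, 4), c(2, 2.5, 3.5, 5))
#' @export
pairedTTest <- function(before, after) {
  if (length(before) != length(after)) stop("before/after lengths differ")
  if (length(before) < 2) stop("need at least 2 pairs")
  d <- after - before
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(statistic = 0, df = length(d) - 1, p.value = 1,
                  estimate = 0, zeroVariance = TRUE))
    stop("zero-variance nonzero differences: paired t-test undefined")
  }
  ht <- stats::t.test(after, before, paired = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, estimate = unname(ht$estimate),
       zeroVariance = FALSE)
}
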