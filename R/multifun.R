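## Ecosystem multifunctionality: the averaging (mean Z-score) index and the
## multiple-threshold analysis with its five summary indices.

#' Z-score standardization of function columns
#'
#' Standardizes every function to mean 0 and sample sd 1 (n - 1
#' denominator) across plots, the first step of the averaging EMF index.
#' Positive affine transforms of a column leave its Z scores unchanged.
#'
#' @param functions a [FunctionMatrix-class] with at least 2 plots.
#' @return a [FunctionMatrix-class] of Z scores.
#' @export
zscoreColumns <- function(functions) {
  stopifnot(is(functions, "FunctionMatrix"))
  m <- functionValues(functions)
  if (nrow(m) < 2) stop("need at least 2 plots to standardize", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance function(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  FunctionMatrix(z)
}

#' Averaging multifunctionality index
#'
#' EMF of a plot is the mean of its per-function Z scores. By construction
#' the index averages to 0 over plots, and it is invariant to positive
#' affine rescaling of any function.
#'
#' @param functions a [FunctionMatrix-class].
#' @return named numeric vector of EMF values, one per plot.
#' @examples
#' fm <- FunctionMatrix(matrix(c(0, 2, 0, 2), 2, 2,
#'         dimnames = list(c("p1", "p2"), c("F1", "F2"))))
#' averagingEMF(fm)   # c(p1 = -0.7071, p2 = 0.7071)
#' @export
averagingEMF <- function(functions) {
  z <- functionValues(zscoreColumns(functions))
  rowMeans(z)
}

#' Per-function maxima as the mean of the top k values
#'
#' The reference "maximum" of each function is the mean of its k highest
#' observed values (k = 5 by default, which damps single-plot outliers).
#' With fewer than k plots, all values are averaged.
#'
#' @param functions a [FunctionMatrix-class].
#' @param k number of top values averaged.
#' @return named numeric vector of maxima, one per function.
#' @export
functionMaxima <- function(functions, k = 5) {
  stopifnot(is(functions, "FunctionMatrix"), k >= 1)
  m <- functionValues(functions)
  kk <- min(k, nrow(m))
  apply(m, 2, function(col) mean(sort(col, decreasing = TRUE)[seq_len(kk)]))
}

#' Number of functions meeting a threshold, per plot
#'
#' Counts, for each plot, the functions whose value is at or above t% of
#' that function's maximum ("exceed" is >=, so ties at the threshold
#' count). Functions with a non-positive maximum have no meaningful
#' percent-of-maximum threshold; they are excluded at that threshold with
#' a warning.
#'
#' @param functions a [FunctionMatrix-class].
#' @param maxima per-function maxima from [functionMaxima()].
#' @param t threshold in percent, 1 <= t <= 99.
#' @return integer vector of counts per plot, each in \[0, F\].
#' @export
thresholdCounts <- function(functions, maxima = functionMaxima(functions),
                            t) {
  stopifnot(is(functions, "FunctionMatrix"), length(t) == 1, t >= 1, t <= 99)
  m <- functionValues(functions)
  stopifnot(identical(sort(names(maxima)), sort(colnames(m))))
  maxima <- maxima[colnames(m)]
  usable <- maxima > 0
  if (any(!usable))
    warning("functions with non-positive maxima excluded from threshold counts: ",
            paste(colnames(m)[!usable], collapse = ", "), call. = FALSE)
  mm <- m[, usable, drop = FALSE]
  cuts <- (t / 100) * maxima[usable]
  counts <- as.integer(rowSums(sweep(mm, 2, cuts, ">=")))
  names(counts) <- rownames(m)
  attr(counts, "n_funcs_used") <- sum(usable)
  counts
}

.olsSlope <- function(x, y) {
  n <- length(x)
  if (stats::var(y) == 0) {
    # flat response: no evidence of an effect, not an error
    return(c(slope = 0, se = 0, ci_low = 0, ci_high = 0, p = 1))
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on numerically perfect fits; the p = 0 policy below
  # already covers that case
  cf <- suppressWarnings(summary(fit))$coefficients
  slope <- cf["x", "Estimate"]
  se <- cf["x", "Std. Error"]
  p <- if (se == 0) 0 else cf["x", "Pr(>|t|)"]
  halfw <- stats::qt(0.975, df = n - 2) * se
  c(slope = slope, se = se, ci_low = slope - halfw, ci_high = slope + halfw,
    p = p)
}

#' Slope-versus-threshold curve
#'
#' For each threshold t in `thresholds`, regresses the per-plot count of
#' functions meeting t on a diversity metric by OLS, recording slope,
#' standard error, 95% t-based confidence interval and two-sided p-value.
#' Thresholds where every plot has the same count (all 0 or all F) get a
#' slope of exactly 0 and p = 1.
#'
#' @param functions a [FunctionMatrix-class].
#' @param diversity named numeric vector of per-plot diversity (SR or
#'   FRic); names must match the function matrix plots. Plots with `NA`
#'   diversity (e.g. undefined FRic) are dropped with a message.
#' @param diversityName label stored in the curve.
#' @param k top-value count for [functionMaxima()].
#' @param thresholds integer percent thresholds (default 1:99).
#' @return a [ThresholdCurve-class].
#' @export
thresholdCurve <- function(functions, diversity,
                           diversityName = "diversity", k = 5,
                           thresholds = 1:99) {
  stopifnot(is(functions, "FunctionMatrix"),
            all(thresholds >= 1), all(thresholds <= 99))
  m <- functionValues(functions)
  if (is.null(names(diversity))) {
    stopifnot(length(diversity) == nrow(m))
    names(diversity) <- rownames(m)
  }
  stopifnot(all(rownames(m) %in% names(diversity)))
  diversity <- diversity[rownames(m)]
  if (anyNA(diversity)) {
    keep <- !is.na(diversity)
    message("dropping ", sum(!keep), " plot(s) with undefined ",
            diversityName, " from the threshold analysis")
    m <- m[keep, , drop = FALSE]
    diversity <- diversity[keep]
  }
  if (nrow(m) < 3)
    stop("need at least 3 plots with defined diversity", call. = FALSE)
  if (stats::var(diversity) == 0)
    stop(diversityName, " has no variance across plots", call. = FALSE)
  fm <- FunctionMatrix(m)
  maxima <- functionMaxima(fm, k = k)
  rows <- lapply(thresholds, function(t) {
    counts <- suppressWarnings(thresholdCounts(fm, maxima, t))
    fit <- .olsSlope(diversity, as.numeric(counts))
    data.frame(threshold = t, slope = fit["slope"], se = fit["se"],
               ci_low = fit["ci_low"], ci_high = fit["ci_high"],
               p = fit["p"], n_plots = nrow(m),
               n_funcs_used = attr(counts, "n_funcs_used"))
  })
  tb <- do.call(rbind, rows)
  rownames(tb) <- NULL
  if (any(tb$n_funcs_used < ncol(m)))
    warning("some thresholds exclude functions with non-positive maxima",
            call. = FALSE)
  new("ThresholdCurve", table = tb, nFuncs = ncol(m),
      diversityName = diversityName,
      diversityRange = max(diversity) - min(diversity))
}

#' Summary indices of a threshold curve
#'
#' Extracts the five indices of the multiple-threshold analysis:
#' \describe{
#'   \item{Tmin}{smallest threshold with a significantly positive slope
#'     (p < 0.05), where diversity begins to have an effect.}
#'   \item{Tmde}{threshold of the maximum diversity effect (argmax of the
#'     slope; first threshold on ties).}
#'   \item{Tmax}{first threshold beyond Tmde where the slope is no longer
#'     significantly different from zero; if significance persists through
#'     the last threshold, the largest significant threshold.}
#'   \item{Rmde}{the slope at Tmde, in functions per unit diversity.}
#'   \item{Pmde}{Rmde as a percentage of the steepest possible slope
#'     F / diversity range (counts running 0 to F across the observed
#'     diversity gradient).}
#' }
#' All indices are NA with `defined = FALSE` when no threshold shows a
#' significantly positive slope.
#'
#' @param curve a [ThresholdCurve-class].
#' @param diversityRange max - min of the diversity metric; defaults to
#'   the range stored in the curve.
#' @return a [ThresholdIndices-class].
#' @export
thresholdIndices <- function(curve, diversityRange = NULL) {
  stopifnot(is(curve, "ThresholdCurve"))
  if (is.null(diversityRange)) diversityRange <- curve@diversityRange
  tb <- curve@table
  sig <- tb$p < 0.05 & tb$slope > 0
  if (!any(sig))
    return(new("ThresholdIndices", tMin = NA_real_, tMax = NA_real_,
               tMde = NA_real_, rMde = NA_real_, pMde = NA_real_,
               nFuncs = curve@nFuncs, diversityRange = diversityRange,
               diversityName = curve@diversityName, defined = FALSE))
  tMin <- min(tb$threshold[sig])
  iMde <- which.max(tb$slope)
  tMde <- tb$threshold[iMde]
  rMde <- tb$slope[iMde]
  after <- which(tb$threshold > tMde & tb$p >= 0.05)
  tMax <- if (length(after)) tb$threshold[min(after)]
          else max(tb$threshold[sig])
  pMde <- 100 * rMde / (curve@nFuncs / diversityRange)
  new("ThresholdIndices", tMin = tMin, tMax = tMax, tMde = tMde,
      rMde = rMde, pMde = pMde, nFuncs = curve@nFuncs,
      diversityRange = diversityRange, diversityName = curve@diversityName,
      defined = TRUE)
}
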