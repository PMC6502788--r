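## Driver attribution: per-function OLS, standardized multiple regression
## of EMF on biotic + abiotic factors, and random-forest variable
## importance.

.fitRegression <- function(df, response) {
  predictors <- setdiff(names(df), response)
  fml <- stats::reformulate(sprintf("`%s`", predictors), response = sprintf("`%s`", response))
  fit <- stats::lm(fml, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    aliased <- names(cf)[is.na(cf)]
    stop("rank-deficient design; aliased predictor(s): ",
         paste(gsub("`", "", aliased), collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  terms <- gsub("`", "", rownames(sm))
  y <- df[[response]]
  sdy <- stats::sd(y)
  est <- sm[, "Estimate"]; names(est) <- terms
  std <- vapply(predictors, function(p) {
    unname(est[p]) * stats::sd(df[[p]]) / sdy
  }, numeric(1))
  se <- sm[, "Std. Error"]; names(se) <- terms
  tv <- sm[, "t value"]; names(tv) <- terms
  pv <- sm[, "Pr(>|t|)"]; names(pv) <- terms
  new("RegressionResult", response = response, predictors = predictors,
      coefficients = est, stdCoefficients = std, se = se, tValues = tv,
      pValues = pv, r2 = summary(fit)$r.squared, n = nrow(df))
}

#' Simple OLS regression of one variable on another
#'
#' Least-squares fit of `y ~ x` with slope, intercept, R-squared and a
#' two-sided p-value for the slope. For a single predictor the
#' standardized coefficient equals the Pearson correlation, and R-squared
#' equals its square.
#'
#' @param x per-plot predictor (variance > 0).
#' @param y per-plot response.
#' @param xName,yName labels for the result.
#' @return a [RegressionResult-class].
#' @export
simpleOLS <- function(x, y, xName = "x", yName = "y") {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete plots", call. = FALSE)
  if (stats::var(x) == 0) stop("predictor has zero variance", call. = FALSE)
  df <- stats::setNames(data.frame(x, y), c(xName, yName))
  .fitRegression(df, yName)
}

#' Standardized multiple regression of EMF on its drivers
#'
#' Multivariate linear regression of a response (typically the averaging
#' EMF index) on biotic and abiotic predictors (e.g. FRic, SR, MAT, MAP,
#' soil pH). Reports raw coefficients with SEs, t and p values, plus
#' standardized coefficients (b * sd(x) / sd(y)) whose magnitudes compare
#' the predictors' effects on a common scale; these are invariant to
#' affine rescaling of any predictor.
#'
#' @param response per-plot numeric response.
#' @param predictors data.frame of per-plot predictors, no exact
#'   collinearity.
#' @param responseName label for the result.
#' @return a [RegressionResult-class].
#' @export
standardizedRegression <- function(response, predictors,
                                   responseName = "EMF") {
  predictors <- as.data.frame(predictors)
  stopifnot(length(response) == nrow(predictors))
  keep <- stats::complete.cases(predictors) & !is.na(response)
  predictors <- predictors[keep, , drop = FALSE]
  response <- response[keep]
  if (nrow(predictors) <= ncol(predictors) + 1)
    stop("need more plots than predictors + 1", call. = FALSE)
  df <- cbind(stats::setNames(data.frame(response), responseName), predictors)
  .fitRegression(df, responseName)
}

#' Random-forest variable importance
#'
#' Grows a regression random forest and reports permutation importance
#' (the increase in out-of-bag MSE when each predictor is permuted,
#' normalized by its SD), the importance type that is robust to scale and
#' to impurity biases. Deterministic for a fixed seed.
#'
#' @param response per-plot numeric response with variance > 0.
#' @param predictors data.frame or matrix of per-plot predictors.
#' @param nTrees number of trees (>= 100; default 1000).
#' @param seed integer RNG seed (required for reproducibility).
#' @return an [ImportanceResult-class].
#' @export
rfImportance <- function(response, predictors, nTrees = 1000, seed) {
  predictors <- as.data.frame(predictors)
  stopifnot(length(response) == nrow(predictors), nTrees >= 100)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  keep <- stats::complete.cases(predictors) & !is.na(response)
  predictors <- predictors[keep, , drop = FALSE]
  response <- response[keep]
  if (length(response) < 10) stop("need at least 10 plots", call. = FALSE)
  if (stats::var(response) == 0)
    stop("response has zero variance", call. = FALSE)
  rf <- withSeed(seed, {
    randomForest::randomForest(x = predictors, y = response, ntree = nTrees,
                               importance = TRUE)
  })
  imp <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
  new("ImportanceResult", predictors = names(imp),
      importance = unname(imp),
      rank = as.integer(rank(-imp, ties.method = "first")),
      nTrees = as.integer(nTrees), seed = as.integer(seed))
}

#' Per-function diversity regressions
#'
#' Regresses every ecosystem function on each supplied diversity metric by
#' simple OLS, the per-function screening step of a BEMF analysis. Raw
#' p-values are reported alongside a Holm-adjusted column per metric.
#'
#' @param functions a [FunctionMatrix-class].
#' @param diversity a [DiversityTable-class] aligned with the functions.
#' @return data.frame with one row per function and, per metric,
#'   r (Pearson), R2, p and p_holm columns.
#' @export
perFunctionRegressions <- function(functions, diversity) {
  stopifnot(is(functions, "FunctionMatrix"), is(diversity, "DiversityTable"))
  stopifnot(identical(plotIds(functions), plotIds(diversity)))
  m <- functionValues(functions)
  metrics <- list(SR = as.numeric(diversity@SR), FRic = diversity@FRic)
  out <- data.frame(func = colnames(m), stringsAsFactors = FALSE)
  for (mn in names(metrics)) {
    x <- metrics[[mn]]
    if (all(is.na(x))) next
    fits <- lapply(seq_len(ncol(m)), function(j)
      simpleOLS(x, m[, j], xName = mn, yName = colnames(m)[j]))
    out[[paste0(mn, "_r")]] <- vapply(fits, function(f)
      sign(f@coefficients[mn]) * sqrt(f@r2), numeric(1))
    out[[paste0(mn, "_R2")]] <- vapply(fits, function(f) f@r2, numeric(1))
    p <- vapply(fits, function(f) f@pValues[mn], numeric(1))
    out[[paste0(mn, "_p")]] <- p
    out[[paste0(mn, "_p_holm")]] <- stats::p.adjust(p, method = "holm")
  }
  out
}
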