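#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core data containers. All four primary tables wrap a base numeric matrix
## whose dimnames carry the plot/species/function identifiers; identifiers are
## opaque strings matched exactly (case-sensitive).
## ---------------------------------------------------------------------------

#' Plot-by-species community matrix
#'
#' Abundances (stem counts or presences) of species across survey plots.
#' Rows are plots, columns are species; dimnames hold the identifiers.
#'
#' @slot .Data numeric matrix, plots x species, all values >= 0.
#' @name CommunityMatrix-class
#' @exportClass CommunityMatrix
setClass("CommunityMatrix", contains = "matrix")

#' Species-by-trait table
#'
#' Functional trait values per species. The canonical traits are specific
#' leaf area (SLA, mm^2 mg^-1), wood density (WD, g cm^-3) and leaf area
#' (LA, mm^2), but any numeric traits are accepted.
#'
#' @slot .Data numeric matrix, species x traits.
#' @slot units named character vector of units per trait (may be empty).
#' @name TraitTable-class
#' @exportClass TraitTable
setClass("TraitTable", contains = "matrix",
         representation(units = "character"),
         prototype(units = character(0)))

#' Plot-by-function matrix
#'
#' Measured ecosystem functions (or their proxies) per plot, e.g. plant
#' nitrogen/phosphorus, soil nutrient pools and woody plant biomass.
#'
#' @slot .Data numeric matrix, plots x functions; no missing values.
#' @name FunctionMatrix-class
#' @exportClass FunctionMatrix
setClass("FunctionMatrix", contains = "matrix")

#' Plot-level abiotic covariates
#'
#' Mean annual temperature (MAT, degrees C), mean annual precipitation
#' (MAP, mm) and soil pH per plot.
#'
#' @slot .Data numeric matrix, plots x {MAT, MAP, soil_pH}.
#' @name EnvironmentTable-class
#' @exportClass EnvironmentTable
setClass("EnvironmentTable", contains = "matrix")

setClassUnion("TraitTableOrNULL", c("TraitTable", "NULL"))
setClassUnion("EnvironmentTableOrNULL", c("EnvironmentTable", "NULL"))

#' Per-plot diversity metrics
#'
#' Species richness (SR) and convex-hull functional richness (FRic) per plot.
#' FRic is `NA` (with `FRicDefined = FALSE`) for plots whose species do not
#' span the trait space (fewer than dims + 1 affinely independent points).
#'
#' @slot plotIds character plot identifiers.
#' @slot SR integer species richness per plot.
#' @slot FRic numeric hull volume per plot (NA when undefined).
#' @slot FRicDefined logical flag per plot.
#' @name DiversityTable-class
#' @exportClass DiversityTable
setClass("DiversityTable",
         representation(plotIds = "character", SR = "integer",
                        FRic = "numeric", FRicDefined = "logical"))

#' Aligned bundle of community, function and environment tables
#'
#' Result of [alignTables()]: all tables restricted to the shared plot set,
#' rows in the canonical order of the community table. `dropped` records the
#' plot ids removed from each input.
#'
#' @slot community a [CommunityMatrix-class].
#' @slot traits a [TraitTable-class] or NULL.
#' @slot functions a [FunctionMatrix-class].
#' @slot environment an [EnvironmentTable-class] or NULL.
#' @slot dropped named list of character vectors of dropped plot ids.
#' @name BemfData-class
#' @exportClass BemfData
setClass("BemfData",
         representation(community = "CommunityMatrix",
                        traits = "TraitTableOrNULL",
                        functions = "FunctionMatrix",
                        environment = "EnvironmentTableOrNULL",
                        dropped = "list"))

## ---------------------------------------------------------------------------
## Result containers
## ---------------------------------------------------------------------------

#' Slope-versus-threshold curve from the multiple-threshold analysis
#'
#' For each threshold t (percent of each function's maximum) the per-plot
#' count of functions meeting the threshold is regressed on a diversity
#' metric by OLS; the curve stores the slope, its SE, 95% CI and p-value.
#'
#' @slot table data.frame with columns threshold, slope, se, ci_low,
#'   ci_high, p, n_plots, n_funcs_used.
#' @slot nFuncs integer, number of functions F.
#' @slot diversityName name of the diversity metric regressed on.
#' @slot diversityRange observed max - min of the diversity metric.
#' @name ThresholdCurve-class
#' @exportClass ThresholdCurve
setClass("ThresholdCurve",
         representation(table = "data.frame", nFuncs = "integer",
                        diversityName = "character",
                        diversityRange = "numeric"))

#' Summary indices of a threshold curve
#'
#' Tmin/Tmax: lowest/highest thresholds at which diversity has a significant
#' positive effect on the function count; Tmde: threshold of the maximum
#' diversity effect; Rmde: the slope there (functions per unit diversity);
#' Pmde: Rmde as a percentage of the steepest slope possible given F
#' functions over the observed diversity range. All NA when no threshold
#' shows a significant positive slope.
#'
#' @slot tMin,tMax,tMde thresholds in percent (NA when undefined).
#' @slot rMde realized maximum effect, functions per unit diversity.
#' @slot pMde percent of the maximum possible effect.
#' @slot nFuncs,diversityRange,diversityName metadata used in the definitions.
#' @slot defined logical, FALSE when no significant threshold exists.
#' @name ThresholdIndices-class
#' @exportClass ThresholdIndices
setClass("ThresholdIndices",
         representation(tMin = "numeric", tMax = "numeric", tMde = "numeric",
                        rMde = "numeric", pMde = "numeric", nFuncs = "integer",
                        diversityRange = "numeric", diversityName = "character",
                        defined = "logical"))

#' Standardized effect size of a statistic under a trait-shuffling null
#'
#' SES = (observed - mean(null)) / sd(null); positive values indicate
#' divergence from random. Flagged undefined when the null sd is zero.
#'
#' @slot statisticName label of the statistic.
#' @slot observed observed value of the statistic.
#' @slot nullMean,nullSd moments of the null ensemble.
#' @slot ses the standardized effect size (NA when undefined).
#' @slot nNull number of null draws; @slot seed RNG seed used.
#' @slot defined FALSE when nullSd == 0.
#' @slot nullValues the null ensemble itself.
#' @name SESResult-class
#' @exportClass SESResult
setClass("SESResult",
         representation(statisticName = "character", observed = "numeric",
                        nullMean = "numeric", nullSd = "numeric",
                        ses = "numeric", nNull = "integer", seed = "integer",
                        defined = "logical", nullValues = "numeric"))

#' OLS regression result with standardized coefficients
#'
#' @slot response name of the response variable.
#' @slot predictors predictor names (excluding the intercept).
#' @slot coefficients named raw coefficients including "(Intercept)".
#' @slot stdCoefficients standardized coefficients per predictor
#'   (b * sd(x) / sd(y)).
#' @slot se,tValues,pValues named per-coefficient statistics.
#' @slot r2 coefficient of determination; @slot n number of plots.
#' @name RegressionResult-class
#' @exportClass RegressionResult
setClass("RegressionResult",
         representation(response = "character", predictors = "character",
                        coefficients = "numeric", stdCoefficients = "numeric",
                        se = "numeric", tValues = "numeric",
                        pValues = "numeric", r2 = "numeric", n = "integer"))

#' Random-forest variable importance
#'
#' Permutation importance (mean increase in MSE when a predictor is
#' permuted out-of-bag) per predictor, with ranks (1 = most important).
#'
#' @slot predictors predictor names.
#' @slot importance numeric importance per predictor.
#' @slot rank integer ranks, a permutation of 1..p.
#' @slot nTrees number of trees grown; @slot seed RNG seed used.
#' @name ImportanceResult-class
#' @exportClass ImportanceResult
setClass("ImportanceResult",
         representation(predictors = "character", importance = "numeric",
                        rank = "integer", nTrees = "integer",
                        seed = "integer"))

#' Configuration for the synthetic plot-community generator
#'
#' Defaults emulate the shape of a 58-plot survey of a conifer-dominated
#' secondary forest: 54 woody species, 3 traits, 8 ecosystem functions, a
#' species-richness gradient and one strongly dominant species holding 90%
#' of the stems.
#'
#' @slot nPlots,nSpeciesPool,nTraits,nFunctions dataset dimensions.
#' @slot richnessRange integer min/max species richness per plot.
#' @slot traitCovariance nTraits x nTraits covariance of log-traits.
#' @slot effectFric,effectSr per-function effect sizes (sd of function per
#'   sd of the standardized driver).
#' @slot envEffects nFunctions x 3 matrix of MAT/MAP/pH effects.
#' @slot noiseSd per-function residual sd.
#' @slot dominance fraction of each plot's stems held by species 1.
#' @slot seed RNG seed; all generator randomness flows from it.
#' @name SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
         representation(nPlots = "integer", nSpeciesPool = "integer",
                        nTraits = "integer", nFunctions = "integer",
                        richnessRange = "integer", traitCovariance = "matrix",
                        effectFric = "numeric", effectSr = "numeric",
                        envEffects = "matrix", noiseSd = "numeric",
                        dominance = "numeric", seed = "integer"))

## ---------------------------------------------------------------------------
## Validity
## ---------------------------------------------------------------------------

.checkIds <- function(ids, what) {
  if (is.null(ids)) return(sprintf("%s identifiers are missing", what))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    return(sprintf("duplicate %s identifiers: %s", what,
                   paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(ids))) return(sprintf("empty %s identifier", what))
  NULL
}

setValidity("CommunityMatrix", function(object) {
  m <- object@.Data
  msgs <- c(.checkIds(rownames(m), "plot"), .checkIds(colnames(m), "species"))
  if (!is.numeric(m)) msgs <- c(msgs, "abundances must be numeric")
  else {
    if (anyNA(m) || any(!is.finite(m))) msgs <- c(msgs, "abundances must be finite")
    else {
      if (any(m < 0)) msgs <- c(msgs, "abundances must be >= 0")
      empty <- rownames(m)[rowSums(m > 0) == 0]
      if (length(empty))
        msgs <- c(msgs, sprintf("plots with no species present: %s",
                                paste(empty, collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

setValidity("TraitTable", function(object) {
  m <- object@.Data
  msgs <- c(.checkIds(rownames(m), "species"), .checkIds(colnames(m), "trait"))
  if (!is.numeric(m)) msgs <- c(msgs, "trait values must be numeric")
  else if (anyNA(m) || any(!is.finite(m)))
    msgs <- c(msgs, "trait values must be finite")
  else {
    # the canonical morphological traits are physically positive quantities
    for (tr in intersect(colnames(m), c("SLA", "WD", "LA")))
      if (any(m[, tr] <= 0))
        msgs <- c(msgs, sprintf("trait %s must be strictly positive", tr))
  }
  if (length(object@units) && is.null(names(object@units)))
    msgs <- c(msgs, "units must be named by trait")
  if (length(msgs)) msgs else TRUE
})

setValidity("FunctionMatrix", function(object) {
  m <- object@.Data
  msgs <- c(.checkIds(rownames(m), "plot"), .checkIds(colnames(m), "function"))
  if (!is.numeric(m)) msgs <- c(msgs, "function values must be numeric")
  else if (anyNA(m) || any(!is.finite(m)))
    msgs <- c(msgs, "function values must be finite (use fill policy on read)")
  if (length(msgs)) msgs else TRUE
})

setValidity("EnvironmentTable", function(object) {
  m <- object@.Data
  msgs <- .checkIds(rownames(m), "plot")
  need <- c("MAT", "MAP", "soil_pH")
  miss <- setdiff(need, colnames(m))
  if (length(miss))
    msgs <- c(msgs, sprintf("missing environment columns: %s",
                            paste(miss, collapse = ", ")))
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)))
    msgs <- c(msgs, "environment values must be finite numerics")
  if (length(msgs)) msgs else TRUE
})

setValidity("DiversityTable", function(object) {
  n <- length(object@plotIds)
  msgs <- .checkIds(object@plotIds, "plot")
  if (length(object@SR) != n || length(object@FRic) != n ||
      length(object@FRicDefined) != n)
    msgs <- c(msgs, "plotIds, SR, FRic and FRicDefined must share length")
  else {
    if (any(object@SR < 1)) msgs <- c(msgs, "SR must be >= 1")
    bad <- object@FRicDefined & (is.na(object@FRic) | object@FRic < 0)
    if (any(bad)) msgs <- c(msgs, "defined FRic values must be >= 0")
    if (any(!object@FRicDefined & !is.na(object@FRic)))
      msgs <- c(msgs, "undefined FRic must be NA")
  }
  if (length(msgs)) msgs else TRUE
})

setValidity("ThresholdCurve", function(object) {
  tb <- object@table
  need <- c("threshold", "slope", "se", "ci_low", "ci_high", "p",
            "n_plots", "n_funcs_used")
  if (!all(need %in% names(tb)))
    return(sprintf("curve table must have columns %s", paste(need, collapse = ", ")))
  if (any(tb$ci_low > tb$slope + 1e-12) || any(tb$ci_high < tb$slope - 1e-12))
    return("confidence interval must bracket the slope")
  TRUE
})

setValidity("SESResult", function(object) {
  if (object@defined && object@nullSd > 0) {
    expect <- (object@observed - object@nullMean) / object@nullSd
    if (!isTRUE(all.equal(expect, object@ses, tolerance = 1e-8)))
      return("ses must equal (observed - nullMean)/nullSd")
  }
  TRUE
})

setValidity("ImportanceResult", function(object) {
  p <- length(object@predictors)
  if (length(object@importance) != p || length(object@rank) != p)
    return("importance and rank must match predictors")
  if (!setequal(object@rank, seq_len(p)))
    return("rank must be a permutation of 1..p")
  if (any(!is.finite(object@importance)))
    return("importances must be finite")
  TRUE
})

setValidity("SimConfig", function(object) {
  msgs <- character(0)
  if (object@nPlots < 3) msgs <- c(msgs, "nPlots must be >= 3")
  rr <- object@richnessRange
  if (length(rr) != 2 || rr[1] > rr[2] || rr[1] < 1 || rr[2] > object@nSpeciesPool)
    msgs <- c(msgs, "richnessRange must be within [1, nSpeciesPool] with min <= max")
  if (any(object@noiseSd <= 0)) msgs <- c(msgs, "noiseSd must be > 0")
  if (object@dominance < 0 || object@dominance >= 1)
    msgs <- c(msgs, "dominance must be in [0, 1)")
  if (!identical(dim(object@traitCovariance),
                 c(object@nTraits, object@nTraits)))
    msgs <- c(msgs, "traitCovariance must be nTraits x nTraits")
  if (length(object@effectFric) != object@nFunctions ||
      length(object@effectSr) != object@nFunctions ||
      length(object@noiseSd) != object@nFunctions)
    msgs <- c(msgs, "per-function effect/noise vectors must have length nFunctions")
  if (!identical(dim(object@envEffects), c(object@nFunctions, 3L)))
    msgs <- c(msgs, "envEffects must be nFunctions x 3 (MAT, MAP, soil_pH)")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Constructors
## ---------------------------------------------------------------------------

.asNumericMatrix <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop(what, " must be a matrix or data.frame", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Construct a CommunityMatrix
#'
#' @param abundance plots x species numeric matrix (or data.frame) with
#'   plot ids as rownames and species ids as colnames.
#' @return a validated [CommunityMatrix-class].
#' @examples
#' m <- matrix(c(2, 0, 1, 1, 0, 3), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("p", 1:3), c("spA", "spB")))
#' CommunityMatrix(m)
#' @export
CommunityMatrix <- function(abundance) {
  new("CommunityMatrix", .asNumericMatrix(abundance, "abundance"))
}

#' Construct a TraitTable
#'
#' @param traits species x traits numeric matrix with species ids as
#'   rownames and trait names as colnames.
#' @param units optional named character vector of trait units.
#' @return a validated [TraitTable-class].
#' @export
TraitTable <- function(traits, units = character(0)) {
  new("TraitTable", .asNumericMatrix(traits, "traits"), units = units)
}

#' Construct a FunctionMatrix
#'
#' @param values plots x functions numeric matrix with plot ids as rownames.
#' @return a validated [FunctionMatrix-class].
#' @export
FunctionMatrix <- function(values) {
  new("FunctionMatrix", .asNumericMatrix(values, "values"))
}

#' Construct an EnvironmentTable
#'
#' @param values plots x covariates numeric matrix; must contain columns
#'   MAT, MAP and soil_pH.
#' @return a validated [EnvironmentTable-class].
#' @export
EnvironmentTable <- function(values) {
  new("EnvironmentTable", .asNumericMatrix(values, "values"))
}

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "CommunityMatrix", function(object) {
  cat(sprintf("CommunityMatrix: %d plots x %d species; %d occurrences\n",
              nrow(object), ncol(object), sum(object@.Data > 0)))
})

setMethod("show", "TraitTable", function(object) {
  u <- if (length(object@units))
    paste0(" [", paste(names(object@units), object@units, sep = ": ",
                       collapse = ", "), "]") else ""
  cat(sprintf("TraitTable: %d species x %d traits (%s)%s\n", nrow(object),
              ncol(object), paste(colnames(object), collapse = ", "), u))
})

setMethod("show", "FunctionMatrix", function(object) {
  cat(sprintf("FunctionMatrix: %d plots x %d functions (%s)\n", nrow(object),
              ncol(object), paste(colnames(object), collapse = ", ")))
})

setMethod("show", "EnvironmentTable", function(object) {
  cat(sprintf("EnvironmentTable: %d plots x %d covariates (%s)\n",
              nrow(object), ncol(object),
              paste(colnames(object), collapse = ", ")))
})

setMethod("show", "DiversityTable", function(object) {
  cat(sprintf("DiversityTable: %d plots; SR %d-%d; FRic defined for %d\n",
              length(object@plotIds), min(object@SR), max(object@SR),
              sum(object@FRicDefined)))
})

setMethod("show", "BemfData", function(object) {
  cat(sprintf("BemfData: %d aligned plots\n", nrow(object@community)))
  show(object@community)
  if (!is.null(object@traits)) show(object@traits)
  show(object@functions)
  if (!is.null(object@environment)) show(object@environment)
  nd <- sum(lengths(object@dropped))
  if (nd) cat(sprintf("  dropped %d plot id(s) during alignment\n", nd))
})

setMethod("show", "ThresholdCurve", function(object) {
  sig <- sum(object@table$p < 0.05 & object@table$slope > 0)
  cat(sprintf(
    "ThresholdCurve: count ~ %s over %d thresholds; %d with significant positive slope\n",
    object@diversityName, nrow(object@table), sig))
})

setMethod("show", "ThresholdIndices", function(object) {
  if (!object@defined) {
    cat(sprintf("ThresholdIndices (%s): undefined (no significant threshold)\n",
                object@diversityName))
  } else {
    cat(sprintf(
      "ThresholdIndices (%s): Tmin=%g%% Tmax=%g%% Tmde=%g%% Rmde=%.4g Pmde=%.4g%%\n",
      object@diversityName, object@tMin, object@tMax, object@tMde,
      object@rMde, object@pMde))
  }
})

setMethod("show", "SESResult", function(object) {
  if (object@defined)
    cat(sprintf("SESResult [%s]: observed=%.4g null=%.4g(sd %.4g) SES=%.4g (n_null=%d)\n",
                object@statisticName, object@observed, object@nullMean,
                object@nullSd, object@ses, object@nNull))
  else
    cat(sprintf("SESResult [%s]: undefined (null sd = 0)\n",
                object@statisticName))
})

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf("RegressionResult: %s ~ %s; R2=%.4f, n=%d\n", object@response,
              paste(object@predictors, collapse = " + "), object@r2, object@n))
  print(as.data.frame(object))
})

setMethod("show", "ImportanceResult", function(object) {
  ord <- order(object@rank)
  cat(sprintf("ImportanceResult (%d trees): %s\n", object@nTrees,
              paste(sprintf("%s=%.3g", object@predictors[ord],
                            object@importance[ord]), collapse = ", ")))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d plots, %d species, %d traits, %d functions; SR in [%d, %d]; dominance %.2f; seed %d\n",
    object@nPlots, object@nSpeciesPool, object@nTraits, object@nFunctions,
    object@richnessRange[1], object@richnessRange[2], object@dominance,
    object@seed))
})
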