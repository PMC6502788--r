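## Accessor generics. Slots are never reached into by user code.

#' Plot identifiers of a table
#' @param x a bemf data object
#' @return character vector of plot ids, in canonical (row) order
#' @export
setGeneric("plotIds", function(x) standardGeneric("plotIds"))

#' Species identifiers of a table
#' @param x a bemf data object
#' @return character vector of species ids
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' Abundance matrix of a community
#' @param x a [CommunityMatrix-class]
#' @return base numeric matrix, plots x species
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' Trait matrix of a trait table
#' @param x a [TraitTable-class]
#' @return base numeric matrix, species x traits
#' @export
setGeneric("traitMatrix", function(x) standardGeneric("traitMatrix"))

#' Trait units
#' @param x a [TraitTable-class]
#' @return named character vector of units (possibly empty)
#' @export
setGeneric("traitUnits", function(x) standardGeneric("traitUnits"))

#' Function value matrix
#' @param x a [FunctionMatrix-class]
#' @return base numeric matrix, plots x functions
#' @export
setGeneric("functionValues", function(x) standardGeneric("functionValues"))

#' Environment covariate matrix
#' @param x an [EnvironmentTable-class]
#' @return base numeric matrix, plots x {MAT, MAP, soil_pH}
#' @export
setGeneric("envValues", function(x) standardGeneric("envValues"))

#' Components of an aligned bundle
#' @param x a [BemfData-class]
#' @return the stored component
#' @export
setGeneric("community", function(x) standardGeneric("community"))

#' @rdname community
#' @export
setGeneric("traits", function(x) standardGeneric("traits"))

#' @rdname community
#' @export
setGeneric("functions", function(x) standardGeneric("functions"))

#' @rdname community
#' @export
setGeneric("environmentTable", function(x) standardGeneric("environmentTable"))

#' Plot ids dropped while aligning tables
#' @param x a [BemfData-class]
#' @return named list of character vectors
#' @export
setGeneric("droppedIds", function(x) standardGeneric("droppedIds"))

#' Per-threshold results of a threshold curve
#' @param x a [ThresholdCurve-class]
#' @return data.frame with one row per threshold
#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))

#' Standardized effect size value
#' @param x a [SESResult-class]
#' @return the SES (NA when undefined)
#' @export
setGeneric("sesValue", function(x) standardGeneric("sesValue"))

## ---------------------------------------------------------------------------

setMethod("plotIds", "CommunityMatrix", function(x) rownames(x@.Data))
setMethod("plotIds", "FunctionMatrix", function(x) rownames(x@.Data))
setMethod("plotIds", "EnvironmentTable", function(x) rownames(x@.Data))
setMethod("plotIds", "DiversityTable", function(x) x@plotIds)
setMethod("plotIds", "BemfData", function(x) rownames(x@community@.Data))

setMethod("speciesIds", "CommunityMatrix", function(x) colnames(x@.Data))
setMethod("speciesIds", "TraitTable", function(x) rownames(x@.Data))

setMethod("abundance", "CommunityMatrix", function(x) {
  m <- x@.Data
  attr(m, "class") <- NULL
  m
})
setMethod("traitMatrix", "TraitTable", function(x) {
  m <- x@.Data
  attr(m, "class") <- NULL
  m
})
setMethod("traitUnits", "TraitTable", function(x) x@units)
setMethod("functionValues", "FunctionMatrix", function(x) {
  m <- x@.Data
  attr(m, "class") <- NULL
  m
})
setMethod("envValues", "EnvironmentTable", function(x) {
  m <- x@.Data
  attr(m, "class") <- NULL
  m
})

setMethod("community", "BemfData", function(x) x@community)
setMethod("traits", "BemfData", function(x) x@traits)
setMethod("functions", "BemfData", function(x) x@functions)
setMethod("environmentTable", "BemfData", function(x) x@environment)
setMethod("droppedIds", "BemfData", function(x) x@dropped)

setMethod("curveTable", "ThresholdCurve", function(x) x@table)
setMethod("sesValue", "SESResult", function(x) x@ses)

## as.data.frame coercions for result containers --------------------------------

#' @export
as.data.frame.DiversityTable <- function(x, ...) {
  data.frame(plot_id = x@plotIds, SR = x@SR, FRic = x@FRic,
             FRic_defined = x@FRicDefined, stringsAsFactors = FALSE)
}

#' @export
as.data.frame.ThresholdCurve <- function(x, ...) x@table


#' @export
as.data.frame.ThresholdIndices <- function(x, ...) {
  data.frame(diversity = x@diversityName, T_min = x@tMin, T_max = x@tMax,
             T_mde = x@tMde, R_mde = x@rMde, P_mde = x@pMde,
             n_functions = x@nFuncs, diversity_range = x@diversityRange,
             defined = x@defined, stringsAsFactors = FALSE)
}

#' @export
as.data.frame.SESResult <- function(x, ...) {
  z <- stats::qnorm(0.975)
  data.frame(statistic = x@statisticName, observed = x@observed,
             null_mean = x@nullMean, null_sd = x@nullSd, ses = x@ses,
             null_ci_low = x@nullMean - z * x@nullSd,
             null_ci_high = x@nullMean + z * x@nullSd,
             n_null = x@nNull, defined = x@defined, stringsAsFactors = FALSE)
}

#' @export
as.data.frame.RegressionResult <- function(x, ...) {
  terms <- names(x@coefficients)
  data.frame(term = terms, estimate = unname(x@coefficients),
             std_estimate = unname(x@stdCoefficients[terms]),
             se = unname(x@se), t_value = unname(x@tValues),
             p_value = unname(x@pValues), stringsAsFactors = FALSE)
}

#' @export
as.data.frame.ImportanceResult <- function(x, ...) {
  data.frame(predictor = x@predictors, importance = x@importance,
             rank = x@rank, stringsAsFactors = FALSE)[order(x@rank), ]
}
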