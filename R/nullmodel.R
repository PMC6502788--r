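## Richness-controlled trait-shuffling null models and standardized effect
## sizes (SES). Shuffling reassigns whole trait vectors across species
## labels, so community composition — and hence every plot's species
## richness — is untouched, while the trait-space arrangement is randomized.

# Evaluate `code` under a fixed seed without disturbing the caller's RNG.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Shuffle trait vectors across species
#'
#' Permutes whole rows of the trait table across species labels: each
#' species receives another species' complete trait vector, preserving
#' every trait's multiset of values and the covariance among traits.
#' With `mode = "independent"` each trait column is permuted separately
#' instead (breaking trait covariance as well).
#'
#' @param traits a [TraitTable-class].
#' @param seed integer RNG seed; the same seed yields the same permutation.
#' @param mode `"rows"` (default) or `"independent"`.
#' @return a [TraitTable-class] with permuted values and the original
#'   species ids.
#' @export
shuffleTraits <- function(traits, seed, mode = c("rows", "independent")) {
  stopifnot(is(traits, "TraitTable"))
  mode <- match.arg(mode)
  m <- traitMatrix(traits)
  shuffled <- withSeed(seed, {
    if (mode == "rows") m[sample(nrow(m)), , drop = FALSE]
    else apply(m, 2, sample)
  })
  rownames(shuffled) <- speciesIds(traits)
  colnames(shuffled) <- colnames(m)
  TraitTable(shuffled, units = traitUnits(traits))
}

# Internal shuffle that reuses the current RNG stream (no per-draw seeding),
# so a single seed determines the whole null ensemble.
.shuffleTraitsStream <- function(traits, mode) {
  m <- traitMatrix(traits)
  shuffled <- if (mode == "rows") m[sample(nrow(m)), , drop = FALSE]
              else apply(m, 2, sample)
  rownames(shuffled) <- speciesIds(traits)
  colnames(shuffled) <- colnames(m)
  TraitTable(shuffled, units = traitUnits(traits))
}

#' Standardized effect size of a statistic under trait shuffling
#'
#' Computes a statistic on the observed data, re-computes it on `nNull`
#' trait-shuffled datasets, and reports
#' SES = (observed - mean(null)) / sd(null). Positive SES indicates
#' divergence from random; negative SES indicates clustering. If the
#' statistic is invariant under shuffling the null sd is zero and the
#' result is flagged undefined instead of dividing.
#'
#' @param statistic a function `(community, traits, functions) -> numeric(1)`,
#'   deterministic given its inputs.
#' @param community a [CommunityMatrix-class].
#' @param traits a [TraitTable-class].
#' @param functions a [FunctionMatrix-class] (passed through to the
#'   statistic; may be NULL if the statistic ignores it).
#' @param nNull number of null draws (>= 2); default 999.
#' @param seed integer RNG seed; `(seed, nNull)` fully determine the
#'   ensemble.
#' @param mode shuffling mode, see [shuffleTraits()].
#' @param statisticName label stored in the result.
#' @return an [SESResult-class].
#' @export
ses <- function(statistic, community, traits, functions = NULL,
                nNull = 999, seed = 1L, mode = c("rows", "independent"),
                statisticName = "statistic") {
  stopifnot(is.function(statistic), nNull >= 2)
  mode <- match.arg(mode)
  observed <- statistic(community, traits, functions)
  stopifnot(length(observed) == 1, is.finite(observed))
  nullValues <- withSeed(seed, {
    vapply(seq_len(nNull), function(i) {
      statistic(community, .shuffleTraitsStream(traits, mode), functions)
    }, numeric(1))
  })
  nullMean <- mean(nullValues)
  nullSd <- stats::sd(nullValues)
  defined <- nullSd > 0
  new("SESResult", statisticName = statisticName, observed = observed,
      nullMean = nullMean, nullSd = nullSd,
      ses = if (defined) (observed - nullMean) / nullSd else NA_real_,
      nNull = as.integer(nNull), seed = as.integer(seed),
      defined = defined, nullValues = nullValues)
}

## --------------------------------------------------------------------------
## SES table across (metric, target) pairs
## --------------------------------------------------------------------------

# Per-plot metric matrix: presence-based community means of each trait,
# plus FRic. Traits are taken as supplied (correlation is scale-free).
.metricMatrix <- function(presence, traitM, fricOpts, withFric) {
  sr <- rowSums(presence)
  means <- (presence %*% traitM) / sr
  if (!withFric) return(means)
  tm <- .standardizeTraits(traitM, fricOpts$standardize)
  fric <- vapply(seq_len(nrow(presence)), function(p) {
    convexHullVolume(tm[presence[p, ] > 0, , drop = FALSE])
  }, numeric(1))
  cbind(means, FRic = fric)
}

#' SES of trait metrics against functions and EMF
#'
#' For every pair of a per-plot metric (the community mean of each trait,
#' plus FRic) and a per-plot target (each ecosystem function, plus the
#' averaging EMF index), the linking statistic is the Pearson correlation
#' across plots; its SES under the trait-shuffling null is computed with a
#' shared null ensemble, one shuffle per draw for all pairs. Plots with
#' undefined FRic are excluded pairwise (complete observations).
#'
#' @param community a [CommunityMatrix-class].
#' @param traits a [TraitTable-class].
#' @param functions a [FunctionMatrix-class], plots aligned with the
#'   community.
#' @param nNull number of null draws; default 999.
#' @param seed integer RNG seed.
#' @param mode shuffling mode, see [shuffleTraits()].
#' @param includeEMF append the averaging EMF index as a target column.
#' @param includeFRic append FRic as a metric row.
#' @param fricOpts options for the FRic metric.
#' @return a data.frame with columns metric, target, observed, null_mean,
#'   null_sd, ses, n_null; attribute `"statistic"` records the linking
#'   statistic.
#' @export
sesTable <- function(community, traits, functions, nNull = 999, seed = 1L,
                     mode = c("rows", "independent"), includeEMF = TRUE,
                     includeFRic = TRUE, fricOpts = fricOptions()) {
  stopifnot(is(community, "CommunityMatrix"), is(traits, "TraitTable"),
            is(functions, "FunctionMatrix"))
  mode <- match.arg(mode)
  stopifnot(identical(plotIds(community), plotIds(functions)))
  ab <- abundance(community)
  presence <- (ab > 0) * 1
  # the species pool for the null is the set of species occurring anywhere
  presence <- presence[, colSums(presence) > 0, drop = FALSE]
  missing <- setdiff(colnames(presence), speciesIds(traits))
  if (length(missing))
    stop("species missing from trait table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  traitM <- traitMatrix(traits)[colnames(presence), , drop = FALSE]
  targets <- functionValues(functions)
  if (includeEMF) targets <- cbind(targets, EMF = averagingEMF(functions))
  corAll <- function(tm) {
    metrics <- .metricMatrix(presence, tm, fricOpts, includeFRic)
    suppressWarnings(stats::cor(metrics, targets, use = "pairwise.complete.obs"))
  }
  observed <- corAll(traitM)
  nullCors <- withSeed(seed, {
    lapply(seq_len(nNull), function(i) {
      perm <- if (mode == "rows") traitM[sample(nrow(traitM)), , drop = FALSE]
              else apply(traitM, 2, sample)
      rownames(perm) <- rownames(traitM)
      corAll(perm)
    })
  })
  nullArr <- array(unlist(nullCors),
                   dim = c(nrow(observed), ncol(observed), nNull))
  nullMean <- apply(nullArr, c(1, 2), mean)
  nullSd <- apply(nullArr, c(1, 2), stats::sd)
  sesMat <- (observed - nullMean) / nullSd
  sesMat[nullSd == 0] <- NA_real_
  out <- expand.grid(metric = rownames(observed), target = colnames(observed),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$observed <- as.vector(observed)
  out$null_mean <- as.vector(nullMean)
  out$null_sd <- as.vector(nullSd)
  out$ses <- as.vector(sesMat)
  out$n_null <- nNull
  attr(out, "statistic") <- "Pearson correlation across plots"
  attr(out, "seed") <- seed
  out
}

#' Reshape a long SES table into a metric-by-target matrix
#'
#' @param x the data.frame returned by [sesTable()].
#' @return numeric matrix of SES values, metrics as rows, targets as
#'   columns.
#' @export
sesMatrix <- function(x) {
  metrics <- unique(x$metric)
  targets <- unique(x$target)
  m <- matrix(x$ses, nrow = length(metrics), ncol = length(targets),
              dimnames = list(metrics, targets))
  m
}
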