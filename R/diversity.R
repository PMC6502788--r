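## Diversity metrics: species richness, convex-hull functional richness
## (FRic) and the trait-derivation helpers for needle-leaved conifers.

#' Options controlling the FRic computation
#'
#' @param standardize per-trait standardization applied across the whole
#'   species pool before hull construction: `"zscore"` (default; mean 0,
#'   sd 1 per trait, the usual practice for hull-based functional
#'   richness), `"range"` (min-max to \[0, 1\]) or `"none"`.
#' @param undefined policy for plots whose species do not span trait space
#'   (fewer than dims + 1 affinely independent trait points): `"flag"`
#'   (default) reports `NA` with `FRicDefined = FALSE`; `"zero"` reports a
#'   hull volume of 0 for such plots. Flagging keeps degenerate plots out
#'   of downstream regressions instead of silently anchoring them at zero.
#' @param reduceDims optional target dimensionality: traits are replaced by
#'   their first `reduceDims` principal components (after standardization)
#'   before the hull is built. Must not exceed the number of traits, and
#'   hulls are only computed in up to 3 dimensions.
#' @return a list of class `"FRicOptions"`.
#' @export
fricOptions <- function(standardize = c("zscore", "range", "none"),
                        undefined = c("flag", "zero"), reduceDims = NULL) {
  standardize <- match.arg(standardize)
  undefined <- match.arg(undefined)
  if (!is.null(reduceDims)) {
    reduceDims <- as.integer(reduceDims)
    stopifnot(reduceDims >= 1)
  }
  structure(list(standardize = standardize, undefined = undefined,
                 reduceDims = reduceDims), class = "FRicOptions")
}

#' Species richness per plot
#'
#' SR is the number of species with abundance > 0 in each plot.
#'
#' @param community a [CommunityMatrix-class].
#' @return a [DiversityTable-class] with the SR column filled and FRic
#'   undefined throughout.
#' @export
speciesRichness <- function(community) {
  stopifnot(is(community, "CommunityMatrix"))
  sr <- as.integer(rowSums(abundance(community) > 0))
  n <- length(sr)
  new("DiversityTable", plotIds = plotIds(community), SR = sr,
      FRic = rep(NA_real_, n), FRicDefined = rep(FALSE, n))
}

.standardizeTraits <- function(m, how) {
  switch(how,
         zscore = {
           sds <- apply(m, 2, stats::sd)
           if (any(sds == 0))
             stop("zero-variance trait(s): ",
                  paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
           scale(m)
         },
         range = {
           rng <- apply(m, 2, range)
           span <- rng[2, ] - rng[1, ]
           if (any(span == 0))
             stop("zero-range trait(s): ",
                  paste(colnames(m)[span == 0], collapse = ", "), call. = FALSE)
           sweep(sweep(m, 2, rng[1, ]), 2, span, "/")
         },
         none = m)
}

#' Functional richness (FRic) per plot
#'
#' FRic of a plot is the volume of the convex hull spanned by the trait
#' points of the species *present* there (presence-based: abundances are
#' ignored). Traits are standardized across the whole species pool first
#' (see [fricOptions()]), so plots are measured in a common trait space.
#' Plots whose species collapse to fewer than dims + 1 affinely
#' independent points have no defined hull and are flagged.
#'
#' @param community a [CommunityMatrix-class].
#' @param traits a [TraitTable-class] covering every species present.
#' @param options a [fricOptions()] list.
#' @return a [DiversityTable-class] with both SR and FRic columns filled.
#' @examples
#' com <- CommunityMatrix(matrix(1, 1, 3, dimnames = list("p1",
#'                        c("s1", "s2", "s3"))))
#' tr <- TraitTable(matrix(c(1, 3, 7), 3, 1,
#'                  dimnames = list(c("s1", "s2", "s3"), "SLA")))
#' as.data.frame(functionalRichness(com, tr,
#'               fricOptions(standardize = "none")))  # 1-D hull = range = 6
#' @export
functionalRichness <- function(community, traits, options = fricOptions()) {
  stopifnot(is(community, "CommunityMatrix"), is(traits, "TraitTable"),
            inherits(options, "FRicOptions"))
  ab <- abundance(community)
  present <- colnames(ab)[colSums(ab > 0) > 0]
  missing <- setdiff(present, speciesIds(traits))
  if (length(missing))
    stop("species missing from trait table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tm <- traitMatrix(traits)
  tm <- .standardizeTraits(tm, options$standardize)
  if (!is.null(options$reduceDims)) {
    if (options$reduceDims > ncol(tm))
      stop("reduceDims exceeds the number of traits", call. = FALSE)
    tm <- stats::prcomp(tm, center = TRUE, scale. = FALSE)$x[,
            seq_len(options$reduceDims), drop = FALSE]
    rownames(tm) <- speciesIds(traits)
  }
  if (ncol(tm) > 3)
    stop("FRic hulls are computed in up to 3 dimensions; use reduceDims",
         call. = FALSE)
  sr <- as.integer(rowSums(ab > 0))
  fric <- vapply(seq_len(nrow(ab)), function(p) {
    spp <- colnames(ab)[ab[p, ] > 0]
    convexHullVolume(tm[spp, , drop = FALSE])
  }, numeric(1))
  defined <- !is.na(fric)
  if (any(!defined)) {
    if (options$undefined == "zero") {
      fric[!defined] <- 0
      defined[] <- TRUE
    } else {
      warning(sum(!defined),
              " plot(s) with degenerate trait hulls flagged as undefined FRic",
              call. = FALSE)
    }
  }
  new("DiversityTable", plotIds = plotIds(community), SR = sr, FRic = fric,
      FRicDefined = defined)
}

#' Species richness and FRic together
#'
#' Convenience wrapper returning both diversity metrics in one
#' [DiversityTable-class].
#'
#' @inheritParams functionalRichness
#' @return a [DiversityTable-class].
#' @export
diversityMetrics <- function(community, traits, options = fricOptions()) {
  functionalRichness(community, traits, options)
}

## --------------------------------------------------------------------------
## Trait derivation formulas
## --------------------------------------------------------------------------

#' Needle leaf area from diameter and length
#'
#' Leaf area of a needle modelled as a cylinder-like solid:
#' LA = (2 * pi * sqrt(3) / 9) * d * L, with diameter d and length L in mm.
#'
#' @param d needle diameter, mm (> 0).
#' @param L needle length, mm (> 0).
#' @return leaf area in mm^2.
#' @examples
#' needleLeafArea(1, 1)   # 2*pi*sqrt(3)/9 = 1.2092
#' @export
needleLeafArea <- function(d, L) {
  if (any(d <= 0) || any(L <= 0))
    stop("needle diameter and length must be > 0", call. = FALSE)
  (2 * pi * sqrt(3) / 9) * d * L
}

#' Specific leaf area
#'
#' SLA = leaf area / leaf dry weight, mm^2 mg^-1.
#'
#' @param leafArea leaf area, mm^2.
#' @param dryWeight leaf dry weight, mg (> 0).
#' @return SLA in mm^2 mg^-1.
#' @export
specificLeafArea <- function(leafArea, dryWeight) {
  if (any(dryWeight <= 0)) stop("dry weight must be > 0", call. = FALSE)
  leafArea / dryWeight
}

#' Wood density
#'
#' WD = wood dry weight / wood volume, g cm^-3.
#'
#' @param dryWeight wood dry weight, g.
#' @param volume wood volume, cm^3 (> 0).
#' @return WD in g cm^-3.
#' @export
woodDensity <- function(dryWeight, volume) {
  if (any(volume <= 0)) stop("volume must be > 0", call. = FALSE)
  dryWeight / volume
}
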