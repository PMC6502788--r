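---
title: "Methods: diversity, multifunctionality indices, null models and drivers"
author: "bemf authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, multifunctionality indices, null models and drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bemf)
```

# Scope and data model

`bemf` analyses plot-based community surveys in which three aligned tables
describe the system: a plot × species abundance matrix (stem counts or
presences), a species × trait table, and a plot × ecosystem-function matrix;
a fourth, optional table carries plot-level abiotic covariates (mean annual
temperature in °C, mean annual precipitation in mm, soil pH). Identifiers
are opaque strings matched exactly and case-sensitively — silent case
folding corrupts joins — and the canonical plot order for every downstream
matrix is the order of the community table. Tables are aligned on the
intersection of their plot ids (`alignTables()`), with dropped ids reported;
missing function values are a hard error by default, with an explicit
row-drop option and never imputation, because the methods below all assume
complete per-plot function profiles.

# Diversity metrics

**Species richness** SR is the count of species with abundance > 0 in a
plot.

**Functional richness** FRic is the volume of the convex hull spanned by the
trait points of the species *present* in a plot. It is presence-based:
FRic asks how much of trait space a community covers, which abundance does
not change. Three choices deserve explanation:

* *Trait standardization.* Traits are measured in incommensurable units
  (mm²·mg⁻¹, g·cm⁻³, mm²), so a raw-unit hull volume is dominated by
  whichever trait has the largest numeric range. The default standardizes
  each trait to zero mean and unit variance across the whole species pool
  before hulls are built, the common practice for hull-based functional
  diversity; min–max range scaling and no scaling are available as options
  (`fricOptions(standardize=)`) because the literature is not unanimous.
* *Degenerate communities.* With T traits, a hull needs at least T + 1
  affinely independent points. Plots below that are *flagged undefined*
  (`NA`), not set to zero: a two-species plot has no 3-D hull at all, and
  anchoring it at zero would fabricate a datum at the extreme of the
  FRic gradient. Flagged plots are excluded (with a message) from
  downstream regressions. A `"zero"` policy exists for users who prefer the
  other convention. Per-plot dimensionality reduction was rejected: hull
  volumes computed in different dimensionalities are not comparable across
  plots.
* *No automatic ordination.* All canonical traits are numeric, so no
  PCoA/Gower step is applied; `reduceDims` offers a principal-component
  projection as an escape hatch for users with more than three traits
  (hulls are computed in at most three dimensions).

The hull volume itself (`convexHullVolume()`) is computed exactly: the range
in 1-D; the shoelace formula over the convex polygon in 2-D; and in 3-D a
brute-force supporting-plane enumeration — every plane through three points
with all remaining points on one side is a facet plane; coplanar supporting
triples are merged into a single facet polygon, which is triangulated from
the hull centroid. Point sets are species within a plot (tens of points at
most), so the O(n⁴) enumeration costs well under a millisecond. Exact
duplicate trait rows are removed first, and collinearity/coplanarity is
detected by the singular values of the centered point matrix with a
scale-aware tolerance of 1e-10 × max(1, |coordinates|). The implementation
is verified in the test suite against an independent qhull-based oracle to
a relative tolerance of 1e-9 on hundreds of random point sets.

Trait helpers implement the standard derivations for needle-leaved
conifers: needle leaf area LA = (2π√3/9)·d·L from needle diameter and
length in mm (the needle is treated as a cylinder-like solid), SLA =
leaf area / dry mass, WD = dry mass / volume. All reject non-positive
inputs.

# Multifunctionality indices

**Averaging index.** Each function is z-scored across plots (sample sd,
n − 1) and a plot's EMF is the mean of its z-scores. The index is invariant
to positive affine rescaling of any function — so unit choices do not
matter — and averages exactly to zero over plots. A zero-variance function
is an error naming the offender: it carries no information and silently
keeping it would dilute the index.

**Multiple-threshold analysis.** The "maximum" of each function is the mean
of its top five observed values, which damps single-plot outliers (`k` is
exposed; with fewer plots than `k` all values are averaged). For every
threshold t from 1 to 99%, the per-plot count of functions at or above
t% of their maxima is regressed on a diversity metric by OLS; the curve
stores slope, SE, 95% t-interval (n − 2 df) and two-sided p per threshold.
Numerical policies, stated for bit-reproducibility:

* "exceeds" is ≥, so ties at the threshold count — on continuous data the
  distinction has measure zero, but an explicit convention avoids
  platform-dependent behaviour;
* a threshold where all plots share one count (all 0 or all F) has slope
  exactly 0 and p = 1 (no evidence), never NaN;
* a numerically perfect fit (zero residual SE) gets p = 0;
* functions with non-positive maxima have no meaningful percent-of-maximum
  cutoff; they are excluded at that threshold with a warning and the
  per-threshold function count is recorded in the curve table;
* ordinary least squares is used for the count regressions rather than a
  count GLM; the slope-versus-threshold summaries below are defined in
  terms of linear slopes (functions gained per unit diversity), and OLS
  keeps them interpretable on that scale.

The curve is summarized by five indices. T_min is the smallest threshold
whose slope is significantly positive (p < 0.05); T_mde is the threshold of
the maximum diversity effect (argmax of the slope, first threshold on
ties); R_mde is the slope there; T_max is the first threshold beyond T_mde
at which the slope is no longer significantly different from zero — the
threshold past which diversity stops mattering — and, if significance
persists through 99%, the largest significant threshold, so the index is
always defined when any threshold is significant. P_mde expresses R_mde as
a percentage of the steepest slope possible in the design: counts can rise
at most from 0 to F across the observed diversity range, so the ceiling is
F/(max − min of diversity) and P_mde = 100·R_mde/(F/range). This
denominator convention is a genuine design decision — published analyses
rarely print the formula — so it is recorded in the CLI's JSON metadata
alongside the values, making results auditable. When no threshold is
significant all five indices are reported as undefined rather than forced
to a number.

# Null models and standardized effect sizes

The null model asks whether trait–function relationships are stronger than
expected *given the observed community structure*. Whole trait vectors are
reassigned at random among species (a row permutation of the trait table);
community composition is untouched, so every plot's SR is conserved
exactly, and each trait's multiset of values — and the covariance among
traits — is conserved by construction. This is the standard
richness-controlled null; an independent per-column shuffle is available as
an option for users who also want to break trait covariance.

For a statistic s (by default the Pearson correlation across plots between
a per-plot metric and a per-plot target), the standardized effect size is

SES = (s_obs − mean(s_null)) / sd(s_null),

positive when the observed pattern diverges from random. If the statistic
is invariant under shuffling the null sd is zero and the result is flagged
undefined instead of dividing. A single seed determines the whole null
ensemble — draws consume one RNG stream rather than being re-seeded — so
(seed, nNull) reproduce results exactly; the default ensemble size is 999
with a 95% normal interval on the null reported alongside.

`sesTable()` assembles the metric × target grid: metrics are the
presence-based community mean of each trait (consistent with the
presence-based FRic; abundance-weighted means would answer a different,
mass-ratio question) plus FRic; targets are each function plus the
averaging EMF. All pairs share the same null draws, which preserves the
dependence structure across the table. Which quantity a published SES
table standardizes (correlation, slope, or the metric itself) is often
unstated; the correlation was chosen for scale-freeness and is recorded in
the table's metadata.

Calibration: under exchangeable traits the SES should be approximately
standard normal. The test suite checks this on 200 seeded null datasets
(sample mean within ±0.2, sd within [0.7, 1.3]) — a property of the whole
chain (generator, shuffler, statistic), not of any single function.

# Driver attribution

Per-function OLS screens report r, R², and p for each diversity metric;
raw p-values are the primary output (matching how such tables are usually
presented) with a Holm-adjusted column added alongside, since eight
functions are tested per metric. The multivariate layer regresses EMF on
biotic (FRic, SR) and abiotic (MAT, MAP, pH) predictors; coefficients are
reported both raw (with SE, t, p) and standardized (b·sd(x)/sd(y)), the
latter comparable across predictors and invariant to affine rescaling.
Exact collinearity is an error naming the aliased predictors. Random-forest
importance uses *permutation* importance (increase in out-of-bag MSE when a
predictor is permuted, normalized) rather than impurity importance, which
is biased toward variables with many split points; 1000 trees by default
(errors stabilize well below that at these problem sizes) and a mandatory
seed. PLS-based partial coefficients are deliberately not implemented: the
procedure is under-specified in the literature this package follows
(components and scaling are rarely reported), and standardized OLS
coefficients answer the same comparative question transparently.

# The synthetic generator

`genDataset()` emulates the *statistical* structure of a conifer-dominated
secondary-forest survey, not its biogeochemistry. Defaults: 58 plots, a
54-species pool, 3 traits, 8 functions (named PN, PP, SHN, SAP, STN, STP,
STC, WPB after the usual nutrient-pool and biomass proxies). Species traits
are multivariate log-normal — log-scale sd 0.35/0.18/0.80 around typical
SLA ≈ 7 mm²·mg⁻¹, WD ≈ 0.55 g·cm⁻³, LA ≈ 1100 mm² values for a subtropical
woody flora, with a mild SLA–WD trade-off (r = −0.4) — guaranteeing the
positivity the trait table requires. Each plot draws SR uniformly from
4–20 (the lower bound keeps 3-D hulls defined; the upper bound gives the
richness gradient the analysis needs), always includes the dominant
species 1 when `dominance > 0`, and spreads stems (Poisson around 120 per
plot) as `dominance` (default 0.9) to species 1 and a geometric rank series
(k = 0.5) over the rest — emulating a stand in which a single pine holds
roughly nine tenths of the stems. Abiotic covariates are uniform over
MAT 15.7–18.2 °C, MAP 954–1202 mm, pH 4.5–6.5.

Functions are generated directly on the *standardized* drivers:
f = effect_sr·z(SR) + effect_fric·z(FRic) + env·z(covariates) + N(0, σ),
with σ = 1 by default, so effects are in interpretable sd-per-sd units.
Generating functions mechanistically from traits was rejected: the package
is validated on whether the analysis recovers a known statistical
structure, and planting that structure directly makes the truth record
exact. All randomness flows from one seed; `bemfFixture()` pins four named
configurations (tiny, paper_shape, null, strong_fric) used throughout the
tests, with `paper_shape` planting moderate FRic effects (0.25–0.58 sd/sd)
on the nutrient-related functions and none on biomass, and `strong_fric`
planting 1.5 sd/sd on every function with no direct SR effect.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: spatial structure and autocorrelation among
plots, trait–environment covariance (traits and climate are independent
here), non-linear or saturating diversity–function relationships,
measurement error structured by laboratory method, and phylogenetic
signal. Results on synthetic data demonstrate the *correctness and
calibration of the machinery*, not ecological conclusions.

# Problem sizes and reproducibility

The test suite and the acceptance script run everything at survey scale
(58 plots) with replicate counts chosen to keep a full run at a few
minutes on one CPU: 200 random communities against the hull oracle, 200
null datasets × 199 shuffles for SES calibration, 100 strong-effect
datasets for recovery (300-tree forests), and 100-dataset/50-replicate
analogues in `scripts/acceptance.R`. Every stochastic step — generator,
null draws, forests — takes an explicit seed, and the command-line
interface is byte-reproducible under a fixed seed, which the suite checks
with checksums.

# Known limitations

FRic hulls are limited to three dimensions (use `reduceDims` beyond that);
FRic inherits its known correlation with SR, so multivariate models that
include both must be read with that collinearity in mind (the generator's
assembly process reproduces this correlation, since richer plots span more
trait space); SES assumes the statistic is deterministic given its inputs;
and the threshold analysis treats functions symmetrically — no weighting
or function-group structure is offered.
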