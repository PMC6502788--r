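# bemf — biodiversity–ecosystem multifunctionality analysis

`bemf` is an R package for asking a central question of community ecology:
does biodiversity — and in particular *functional* diversity — drive the
ability of an ecosystem to sustain many functions at once? It is aimed at
plot-based survey data: a plot × species abundance table, a species × trait
table, a plot × ecosystem-function table and (optionally) plot-level abiotic
covariates (MAT, MAP, soil pH).

The package implements the full inference chain used in forest
biodiversity–ecosystem-multifunctionality (BEMF) studies:

- **Diversity metrics.** Species richness SR, and functional richness
  FRic — the volume of the convex hull spanned by a plot's species in
  (standardized) trait space. Trait helpers cover needle leaf area
  (LA = 2π√3⁄9 · d·L for cylinder-like conifer needles), specific leaf
  area (SLA = area/dry mass) and wood density (WD = dry mass/volume).
- **Multifunctionality indices.** The *averaging* index
  EMFᵢ = (1/F) Σ_f z(fᵢ_f), and the *multiple-threshold* analysis: for each
  threshold t ∈ {1, …, 99}% of each function's maximum (the mean of its top
  five values), count the functions each plot holds above t, regress the
  count on diversity by OLS, and summarize the slope-vs-threshold curve by
  T_min, T_max, T_mde, R_mde and P_mde = 100·R_mde/(F/diversity range).
- **Null models.** Richness-controlled trait shuffling (whole trait vectors
  permuted across species, community composition fixed) and standardized
  effect sizes SES = (observed − mean(null))/sd(null) for trait–function and
  FRic–function correlations.
- **Driver attribution.** Per-function OLS screens, standardized multiple
  regression of EMF on biotic (SR, FRic) and abiotic (MAT, MAP, pH) drivers,
  and random-forest permutation importance.
- **Synthetic data.** A seeded generator of survey-shaped datasets (58 plots,
  54 species, 3 traits, 8 functions, a richness gradient, one dominant
  species) with configurable planted effect sizes, so the whole chain can be
  exercised and calibrated without field data.

## Worked example

```r
library(bemf)

d <- bemfFixture("paper_shape")          # 58 plots, 54 species, 8 functions
div <- diversityMetrics(d$community, d$traits)
div
#> DiversityTable: 58 plots; SR 5-20; FRic defined for 58

emf <- averagingEMF(d$functions)
fit <- simpleOLS(div@FRic, emf, xName = "FRic", yName = "EMF")
fit
#> RegressionResult: EMF ~ FRic; R2=0.3962, n=58
#>          term    estimate std_estimate          se   t_value      p_value
#> 1 (Intercept) -0.31393210           NA 0.068398242 -4.589769 2.550249e-05
#> 2        FRic  0.05025686    0.6294759 0.008289998  6.062349 1.203281e-07
```

FRic explains ~40% of the variation in the averaging EMF index here; the
standardized coefficient (0.63) is the Pearson correlation, since FRic is the
sole predictor. The multiple-threshold view of the same data:

```r
cv <- thresholdCurve(d$functions, setNames(div@FRic, plotIds(div)), "FRic")
thresholdIndices(cv)
#> ThresholdIndices (FRic): Tmin=1% Tmax=99% Tmde=44% Rmde=0.2118 Pmde=52.37%
```

FRic has a significantly positive effect on the number of functions sustained
at every threshold from 1% to 99%; the effect peaks at the 44% threshold,
where one unit of FRic adds 0.21 functions — 52% of the steepest slope
possible given 8 functions over the observed FRic range. Null-model SES for
the trait and FRic correlations with selected functions and EMF:

```r
st <- sesTable(d$community, d$traits, d$functions, nNull = 199, seed = 42)
round(sesMatrix(st)[, c("PP", "SAP", "STN", "EMF")], 2)
#>         PP  SAP   STN   EMF
#> SLA   1.62 1.48 -0.71  2.62
#> WD   -0.51 0.65 -0.22 -0.46
#> LA    3.09 0.69  1.66  2.86
#> FRic  3.64 2.41  1.20  3.23
```

SES > 1.96 marks correlations stronger than expected when trait vectors are
reassigned at random among species: here FRic diverges from random for plant
phosphorus, soil available phosphorus and EMF, as planted by the generator.

A thin command-line front end is installed at `exec/emf`
(`emf validate|diversity|average|thresholds|ses|drivers|simulate`); every
subcommand is seeded and byte-reproducible.

## Documentation

The methods vignette (`vignettes/bemf-methods.Rmd`) describes the model and
its assumptions, the index definitions and their edge-case policies, the
null-model construction, and what the synthetic generator does and does not
emulate about real forest data.
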