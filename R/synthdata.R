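## Synthetic plot-community generator. Emulates the statistical structure a
## plot-based BEMF survey assumes — a species pool with covarying traits, a
## richness gradient across plots, one strongly dominant species, abiotic
## covariates, and ecosystem functions driven linearly by (standardized)
## SR and FRic plus Gaussian noise — so every stage of the inference chain
## can be exercised and calibrated without field data.

.defaultTraitCov <- function(nTraits) {
  # mild, realistic covariance among log-traits; for the canonical three
  # (SLA, WD, LA): SLA and WD trade off, SLA and LA covary weakly
  cv <- diag(nTraits)
  if (nTraits >= 2) cv[1, 2] <- cv[2, 1] <- -0.4
  if (nTraits >= 3) {
    cv[1, 3] <- cv[3, 1] <- 0.3
    cv[2, 3] <- cv[3, 2] <- -0.1
  }
  cv
}

#' Build a synthetic-data configuration
#'
#' Defaults reproduce the shape of a 58-plot conifer-forest survey: 54
#' woody species, 3 traits, 8 ecosystem functions, per-plot species
#' richness drawn uniformly from `richnessRange`, and a single dominant
#' species holding `dominance` of every plot's stems (0.9 by default,
#' matching a stand where one pine contributes over 90% of the biomass).
#' Effect sizes are per-function slopes on the *standardized* (z-scored
#' across plots) SR and FRic, in units of function-sd per driver-sd, so
#' `effectFric = 1` means one residual-sd of function change per sd of
#' FRic.
#'
#' @param nPlots,nSpeciesPool,nTraits,nFunctions dataset dimensions.
#' @param richnessRange length-2 integer range of per-plot SR.
#' @param traitCovariance covariance matrix of the latent log-traits.
#' @param effectFric,effectSr per-function effects (recycled to
#'   `nFunctions`).
#' @param envEffects `nFunctions x 3` matrix of effects of standardized
#'   MAT, MAP and soil pH (default all zero).
#' @param noiseSd per-function residual sd (recycled).
#' @param dominance fraction of each plot's stems held by species 1; 0
#'   disables dominance.
#' @param seed integer seed; all generator randomness flows from it.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nPlots = 58, nSpeciesPool = 54, nTraits = 3,
                      nFunctions = 8, richnessRange = c(4, 20),
                      traitCovariance = .defaultTraitCov(nTraits),
                      effectFric = 0, effectSr = 0, envEffects = NULL,
                      noiseSd = 1, dominance = 0.9, seed = 1L) {
  if (is.null(envEffects)) envEffects <- matrix(0, nFunctions, 3)
  new("SimConfig", nPlots = as.integer(nPlots),
      nSpeciesPool = as.integer(nSpeciesPool), nTraits = as.integer(nTraits),
      nFunctions = as.integer(nFunctions),
      richnessRange = as.integer(richnessRange),
      traitCovariance = traitCovariance,
      effectFric = rep_len(as.numeric(effectFric), nFunctions),
      effectSr = rep_len(as.numeric(effectSr), nFunctions),
      envEffects = envEffects,
      noiseSd = rep_len(as.numeric(noiseSd), nFunctions),
      dominance = as.numeric(dominance), seed = as.integer(seed))
}

.canonicalFunctionNames <- c("PN", "PP", "SHN", "SAP", "STN", "STP", "STC",
                             "WPB")
.canonicalTraitNames <- c("SLA", "WD", "LA")
# latent z -> positive trait scales typical of a subtropical woody flora
.traitScales <- list(SLA = c(meanlog = 2.0, sdlog = 0.35),   # ~7.4 mm2/mg
                     WD = c(meanlog = -0.6, sdlog = 0.18),   # ~0.55 g/cm3
                     LA = c(meanlog = 7.0, sdlog = 0.80))    # ~1100 mm2

#' Generate a synthetic BEMF dataset
#'
#' Draws species traits from a multivariate log-normal, assembles plot
#' communities along a richness gradient with geometric-series rank
#' abundances and an always-present dominant species, computes each
#' plot's FRic internally, and generates ecosystem functions as
#' `effectSr * z(SR) + effectFric * z(FRic) + envEffects * z(env) + noise`.
#' The returned truth record stores every planted parameter together with
#' the per-plot SR/FRic used, so recovery can be checked downstream.
#'
#' @param config a [SimConfig-class].
#' @param seed optional override of the config seed.
#' @return a list with elements `community`, `traits`, `functions`,
#'   `environment` (the four typed tables) and `truth` (a list).
#' @examples
#' d <- genDataset(simConfig(nPlots = 6, nSpeciesPool = 10, seed = 7))
#' d$community
#' @export
genDataset <- function(config, seed = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (!is.null(seed)) config@seed <- as.integer(seed)
  withSeed(config@seed, .genDatasetImpl(config))
}

.genDatasetImpl <- function(cfg) {
  S <- cfg@nSpeciesPool; P <- cfg@nPlots; Tn <- cfg@nTraits
  Fn <- cfg@nFunctions
  spIds <- sprintf("sp%02d", seq_len(S))
  plIds <- sprintf("plot%02d", seq_len(P))

  ## traits: multivariate normal latent, mapped to positive scales
  z <- MASS::mvrnorm(S, mu = rep(0, Tn), Sigma = cfg@traitCovariance)
  z <- matrix(z, nrow = S)
  trNames <- if (Tn == 3) .canonicalTraitNames else sprintf("trait%d", 1:Tn)
  tm <- vapply(seq_len(Tn), function(j) {
    sc <- if (trNames[j] %in% names(.traitScales)) .traitScales[[trNames[j]]]
          else c(meanlog = 0, sdlog = 1)
    exp(sc["meanlog"] + sc["sdlog"] * z[, j])
  }, numeric(S))
  tm <- matrix(tm, nrow = S)
  dimnames(tm) <- list(spIds, trNames)
  units <- if (Tn == 3) c(SLA = "mm2/mg", WD = "g/cm3", LA = "mm2")
           else character(0)
  traits <- TraitTable(tm, units = units)

  ## communities: SR gradient, dominant species 1, geometric-series ranks
  rr <- cfg@richnessRange
  if (rr[1] > S) stop("richness range infeasible for the species pool",
                      call. = FALSE)
  ab <- matrix(0, P, S, dimnames = list(plIds, spIds))
  srPlanted <- rr[1] + sample.int(rr[2] - rr[1] + 1L, P, replace = TRUE) - 1L
  for (p in seq_len(P)) {
    sr <- srPlanted[p]
    spp <- if (cfg@dominance > 0)
      c(1L, 1L + sample.int(S - 1L, sr - 1L)) else sample.int(S, sr)
    nStems <- max(sr, stats::rpois(1, 120))
    if (cfg@dominance > 0 && sr > 1) {
      nDom <- max(1L, round(cfg@dominance * nStems))
      rest <- nStems - nDom
      k <- 0.5   # geometric-series decay over the remaining ranks
      pr <- k * (1 - k)^(seq_len(sr - 1L) - 1)
      counts <- as.vector(stats::rmultinom(1, max(rest - (sr - 1L), 0),
                                           pr / sum(pr))) + 1L
      ab[p, spp] <- c(nDom, counts)
    } else {
      k <- 0.5
      pr <- k * (1 - k)^(seq_len(sr) - 1)
      counts <- as.vector(stats::rmultinom(1, max(nStems - sr, 0),
                                           pr / sum(pr))) + 1L
      ab[p, spp] <- counts
    }
  }
  com <- CommunityMatrix(ab)

  ## internal diversity (z-scored traits, default options)
  div <- suppressWarnings(functionalRichness(com, traits))
  srv <- as.numeric(div@SR)
  fric <- div@FRic
  zOf <- function(v) {
    if (stats::sd(v, na.rm = TRUE) == 0) rep(0, length(v))
    else (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  }
  zSR <- zOf(srv)
  zFRic <- zOf(fric)
  zFRic[is.na(zFRic)] <- 0   # degenerate plots carry no FRic signal

  ## abiotic covariates typical of the surveyed climate envelope
  env <- cbind(MAT = stats::runif(P, 15.7, 18.2),
               MAP = stats::runif(P, 954, 1202),
               soil_pH = stats::runif(P, 4.5, 6.5))
  rownames(env) <- plIds
  zEnv <- scale(env)

  ## functions: linear in the standardized drivers plus Gaussian noise
  fnNames <- if (Fn == 8) .canonicalFunctionNames else sprintf("F%d", 1:Fn)
  fv <- vapply(seq_len(Fn), function(j) {
    cfg@effectSr[j] * zSR + cfg@effectFric[j] * zFRic +
      as.vector(zEnv %*% cfg@envEffects[j, ]) +
      stats::rnorm(P, 0, cfg@noiseSd[j])
  }, numeric(P))
  fv <- matrix(fv, nrow = P)
  dimnames(fv) <- list(plIds, fnNames)

  list(community = com, traits = traits, functions = FunctionMatrix(fv),
       environment = EnvironmentTable(env),
       truth = list(config = cfg, SR = stats::setNames(srv, plIds),
                    FRic = stats::setNames(fric, plIds),
                    zSR = zSR, zFRic = zFRic,
                    effectFric = stats::setNames(cfg@effectFric, fnNames),
                    effectSr = stats::setNames(cfg@effectSr, fnNames)))
}

#' Canned synthetic fixtures
#'
#' Named dataset configurations used throughout the test and calibration
#' suite:
#' \describe{
#'   \item{tiny}{4 plots, 5 species, 4 functions; a smoke-test dataset.}
#'   \item{paper_shape}{the survey-shaped default: 58 plots, 54 species,
#'     3 traits, 8 functions, with moderate FRic effects on three
#'     nutrient-related functions.}
#'   \item{null}{survey-shaped with every planted effect zero; drives the
#'     SES calibration checks.}
#'   \item{strong_fric}{survey-shaped with a large FRic effect on every
#'     function and no direct SR effect; drives effect-recovery checks.}
#' }
#'
#' @param name fixture name.
#' @param seed optional seed override (each fixture has a fixed default).
#' @return as [genDataset()].
#' @export
bemfFixture <- function(name = c("tiny", "paper_shape", "null",
                                 "strong_fric"), seed = NULL) {
  if (!is.character(name) || !name[1] %in% c("tiny", "paper_shape", "null",
                                             "strong_fric"))
    stop("unknown fixture '", name[1],
         "'; available: tiny, paper_shape, null, strong_fric", call. = FALSE)
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = simConfig(nPlots = 4, nSpeciesPool = 5, nTraits = 3,
                     nFunctions = 4, richnessRange = c(4, 5),
                     effectFric = 0.8, seed = 101L),
    paper_shape = simConfig(
      effectFric = c(0, 0.577, 0.25, 0.505, 0.326, 0.25, 0.25, 0),
      seed = 2019L),
    null = simConfig(seed = 404L),
    strong_fric = simConfig(effectFric = 1.5, seed = 77L))
  genDataset(cfg, seed = seed)
}
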