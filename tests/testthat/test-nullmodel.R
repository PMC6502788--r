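test_that("trait shuffling conserves multisets and is seed-deterministic", {
  tr <- mkTraits(matrix(rnorm(30), 10, 3))
  sh1 <- shuffleTraits(tr, seed = 5)
  sh2 <- shuffleTraits(tr, seed = 5)
  expect_identical(traitMatrix(sh1), traitMatrix(sh2))
  expect_identical(speciesIds(sh1), speciesIds(tr))
  # every trait's multiset of values is preserved
  for (j in 1:3)
    expect_equal(unname(sort(traitMatrix(sh1)[, j])),
                 unname(sort(traitMatrix(tr)[, j])))
  # row shuffling keeps whole trait vectors together
  m0 <- traitMatrix(tr); m1 <- traitMatrix(sh1)
  rowKey <- function(m) unname(sort(apply(m, 1, paste, collapse = "|")))
  expect_identical(rowKey(m1), rowKey(m0))
  # independent mode breaks rows but still conserves each column
  shI <- shuffleTraits(tr, seed = 5, mode = "independent")
  for (j in 1:3)
    expect_equal(unname(sort(traitMatrix(shI)[, j])),
                 unname(sort(traitMatrix(tr)[, j])))
  # different seeds give different permutations (10 rows: collision unlikely)
  expect_false(identical(traitMatrix(shuffleTraits(tr, seed = 6)),
                         traitMatrix(sh1)))
})

test_that("SES follows its defining formula and flags degenerate nulls", {
  set.seed(88)
  abm <- matrix(rpois(40, 1), 4, 10)
  abm[, 1] <- abm[, 1] + 1   # keep every plot non-empty
  com <- mkCommunity(abm)
  tr <- mkTraits(matrix(rnorm(20), 10, 2))
  fm <- mkFunctions(matrix(rnorm(12), 4, 3))

  stat <- function(community, traits, functions) {
    cor(rowMeans((abundance(community) > 0) %*% traitMatrix(traits)),
        functionValues(functions)[, 1])
  }
  r <- ses(stat, com, tr, fm, nNull = 50, seed = 11)
  expect_true(r@defined)
  expect_equal(r@ses, (r@observed - r@nullMean) / r@nullSd)
  expect_length(r@nullValues, 50)
  # (seed, nNull) fully determine the ensemble
  r2 <- ses(stat, com, tr, fm, nNull = 50, seed = 11)
  expect_identical(r@nullValues, r2@nullValues)

  # a statistic blind to traits has null sd 0 and is flagged, not divided
  constStat <- function(community, traits, functions) 42
  rc <- ses(constStat, com, tr, fm, nNull = 10, seed = 1)
  expect_false(rc@defined)
  expect_true(is.na(sesValue(rc)))

  # arithmetic of the formula: observed 5, null mean 3, null sd 2 -> SES 1
  fake <- new("SESResult", statisticName = "x", observed = 5, nullMean = 3,
              nullSd = 2, ses = 1, nNull = 2L, seed = 1L, defined = TRUE,
              nullValues = c(1, 5))
  expect_equal(sesValue(fake), 1)
})

test_that("sesTable covers all metric-target pairs with shared nulls", {
  d <- bemfFixture("tiny")
  tab <- sesTable(d$community, d$traits, d$functions, nNull = 30, seed = 3)
  expect_setequal(unique(tab$metric), c("SLA", "WD", "LA", "FRic"))
  expect_setequal(unique(tab$target),
                  c(colnames(functionValues(d$functions)), "EMF"))
  expect_true(all(is.finite(tab$observed)))
  expect_true(all(tab$n_null == 30))
  # reproducible
  tab2 <- sesTable(d$community, d$traits, d$functions, nNull = 30, seed = 3)
  expect_equal(tab, tab2, ignore_attr = TRUE)
  # sign symmetry: negating a target negates observed correlation and SES
  fv <- functionValues(d$functions)
  fv[, 1] <- -fv[, 1]
  tabN <- sesTable(d$community, d$traits, FunctionMatrix(fv), nNull = 30,
                   seed = 3, includeEMF = FALSE)
  f1 <- colnames(fv)[1]
  expect_equal(tabN$ses[tabN$target == f1],
               -tab$ses[tab$target == f1], tolerance = 1e-10)
})

test_that("a planted trait-function link yields a large positive SES", {
  set.seed(202)
  hits <- 0
  for (rep in 1:10) {
    d <- genDataset(simConfig(nPlots = 40, nSpeciesPool = 30,
                              effectFric = 2, noiseSd = 0.5,
                              seed = 9000 + rep))
    stat <- function(community, traits, functions) {
      div <- suppressWarnings(functionalRichness(community, traits))
      cor(div@FRic, functionValues(functions)[, 1],
          use = "complete.obs")
    }
    r <- ses(stat, d$community, d$traits, d$functions, nNull = 49,
             seed = rep)
    if (r@defined && r@ses > 1.96) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
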