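test_that("Z-score columns have mean 0, sd 1 and are affine-invariant", {
  fm <- mkFunctions(matrix(c(1, 2, 3, 5, 1, 9), 3, 2))
  z <- functionValues(zscoreColumns(fm))
  expect_equal(unname(z[, 1]), c(-1, 0, 1))
  expect_equal(colMeans(z), c(F1 = 0, F2 = 0))
  expect_equal(apply(z, 2, sd), c(F1 = 1, F2 = 1))

  # positive affine transform of a column leaves its Z scores unchanged
  m2 <- functionValues(fm); m2[, 2] <- 3.7 * m2[, 2] + 11
  expect_equal(functionValues(zscoreColumns(mkFunctions(m2))), z)

  expect_error(zscoreColumns(mkFunctions(cbind(c(1, 1, 1), c(1, 2, 3)))),
               "zero-variance.*F1")
})

test_that("averaging EMF is the mean of per-function Z scores", {
  fm <- mkFunctions(matrix(c(0, 2, 0, 2), 2, 2))
  # hand-computed: each column z-scores to (-sqrt(2)/2, +sqrt(2)/2)
  expect_equal(unname(averagingEMF(fm)),
               c(-sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-12)
  # single function: EMF equals that function's Z scores
  one <- mkFunctions(matrix(c(4, 7, 1), 3, 1))
  expect_equal(averagingEMF(one),
               functionValues(zscoreColumns(one))[, 1])
  # permuting function columns changes nothing
  fm4 <- mkFunctions(matrix(rnorm(20), 5, 4))
  fmP <- FunctionMatrix(functionValues(fm4)[, c(3, 1, 4, 2)])
  expect_equal(averagingEMF(fmP), averagingEMF(fm4))
  # the index always averages to zero over plots
  expect_lt(abs(mean(averagingEMF(fm4))), 1e-9)
})

test_that("function maxima average the top k values", {
  fm <- mkFunctions(matrix(c(10, 8, 6, 4, 2, 0), 6, 1))
  expect_equal(unname(functionMaxima(fm, k = 5)), (10 + 8 + 6 + 4 + 2) / 5)
  # fewer plots than k: mean of all
  fm3 <- mkFunctions(matrix(c(3, 6, 9), 3, 1))
  expect_equal(unname(functionMaxima(fm3, k = 5)), 6)
  # constant column
  fmC <- mkFunctions(matrix(7, 6, 1))
  expect_equal(unname(functionMaxima(fmC)), 7)
})

test_that("threshold counts use >= and are non-increasing in t", {
  fm <- mkFunctions(rbind(c(10, 0), c(5, 10)))
  mx <- functionMaxima(fm, k = 1)
  expect_identical(as.integer(thresholdCounts(fm, mx, 50)), c(1L, 2L))
  # a value exactly at the threshold counts ("exceed" is >=)
  expect_identical(as.integer(thresholdCounts(fm, mx, 50))[2], 2L)

  set.seed(31)
  for (rep in 1:25) {
    fmR <- mkFunctions(matrix(runif(8 * 5, 0.1, 10), 8, 5))
    mxR <- functionMaxima(fmR)
    counts <- sapply(1:99, function(t) thresholdCounts(fmR, mxR, t))
    expect_true(all(apply(counts, 1, function(r) all(diff(r) <= 0))))
    expect_true(all(counts >= 0 & counts <= 5))
  }

  # non-positive maxima exclude the function with a warning
  fmN <- mkFunctions(cbind(c(-3, -1, -2), c(1, 2, 3)))
  expect_warning(ct <- thresholdCounts(fmN, functionMaxima(fmN), 50),
                 "non-positive")
  expect_identical(attr(ct, "n_funcs_used"), 1L)
})

test_that("threshold curve records per-threshold OLS fits", {
  # perfect linear fit: slope 1, essentially zero p
  fm <- mkFunctions(rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)))
  cv <- thresholdCurve(fm, c(p1 = 1, p2 = 2, p3 = 3), "SR", k = 1)
  tb <- curveTable(cv)
  expect_equal(nrow(tb), 99)
  at50 <- tb[tb$threshold == 50, ]
  expect_equal(at50$slope, 1)
  expect_lt(at50$p, 1e-10)
  # CI brackets the slope everywhere
  expect_true(all(tb$ci_low <= tb$slope + 1e-12 &
                  tb$slope <= tb$ci_high + 1e-12))
  expect_error(thresholdCurve(fm, c(p1 = 2, p2 = 2, p3 = 2), "SR"),
               "no variance")
  fm2 <- mkFunctions(matrix(c(1, 2), 2, 1))
  expect_error(thresholdCurve(fm2, c(p1 = 1, p2 = 2), "SR"), "3 plots")
})

test_that("threshold analysis is invariant to plot order", {
  set.seed(77)
  fm <- mkFunctions(matrix(runif(40, 1, 10), 8, 5))
  div <- setNames(runif(8, 1, 5), rownames(functionValues(fm)))
  cv1 <- thresholdCurve(fm, div, "FRic")
  perm <- sample(8)
  fmP <- FunctionMatrix(functionValues(fm)[perm, ])
  cv2 <- thresholdCurve(fmP, div[perm], "FRic")
  expect_equal(curveTable(cv1), curveTable(cv2))
  emf <- averagingEMF(fm)
  expect_equal(averagingEMF(fmP), emf[perm])
})

test_that("threshold indices extract Tmin/Tmax/Tmde/Rmde/Pmde", {
  fx <- linearCountFixture()
  cv <- thresholdCurve(fx$functions, fx$diversity, "SR", k = 1)
  tb <- curveTable(cv)
  # below the engineered threshold every plot holds all 8 functions,
  # so the count is constant and the slope exactly zero with p = 1
  expect_true(all(tb$slope[tb$threshold < 55] == 0))
  expect_true(all(tb$p[tb$threshold < 55] == 1))
  idx <- thresholdIndices(cv)
  expect_true(idx@defined)
  expect_equal(idx@tMde, 55)
  expect_equal(idx@tMin, 55)
  expect_equal(idx@rMde, 1, tolerance = 1e-9)
  expect_equal(idx@pMde, 100, tolerance = 1e-9)
  expect_true(idx@tMin <= idx@tMde && idx@tMde <= idx@tMax)

  # identically-zero slope curve: all indices undefined
  fmFlat <- mkFunctions(matrix(rep(c(5, 5, 5, 5), 3), 4, 3))
  suppressWarnings(
    cvFlat <- thresholdCurve(fmFlat, c(p1 = 1, p2 = 2, p3 = 3, p4 = 4), "SR"))
  idxFlat <- thresholdIndices(cvFlat)
  expect_false(idxFlat@defined)
  expect_true(is.na(idxFlat@tMin) && is.na(idxFlat@pMde))
})
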