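test_that("simple OLS recovers exact and null relationships", {
  r <- simpleOLS(1:3, 1:3)
  expect_equal(unname(r@coefficients["x"]), 1)
  expect_equal(r@r2, 1)
  # orthogonal response: slope and R2 are zero
  x <- c(-1, 0, 1, 2, -2)
  y <- c(1, -2, 1, 0, 0)  # constructed with cov(x, y) = 0
  stopifnot(abs(cov(x, y)) < 1e-12)
  r0 <- simpleOLS(x, y)
  expect_equal(unname(r0@coefficients["x"]), 0, tolerance = 1e-12)
  expect_equal(r0@r2, 0, tolerance = 1e-12)
  expect_error(simpleOLS(rep(2, 5), rnorm(5)), "zero variance")
})

test_that("OLS slope and R2 match their moment-based oracles", {
  set.seed(55)
  for (rep in 1:20) {
    x <- rnorm(15); y <- 0.6 * x + rnorm(15)
    r <- simpleOLS(x, y)
    expect_equal(unname(r@coefficients["x"]), cov(x, y) / var(x),
                 tolerance = 1e-12)
    expect_equal(r@r2, cor(x, y)^2, tolerance = 1e-12)
    # sole-predictor standardized coefficient is the Pearson correlation
    expect_equal(unname(r@stdCoefficients["x"]), cor(x, y),
                 tolerance = 1e-12)
  }
})

test_that("standardized regression scales coefficients and detects aliasing", {
  set.seed(4)
  x <- rnorm(30)
  r <- standardizedRegression(x, data.frame(x = x))
  expect_equal(unname(r@stdCoefficients["x"]), 1, tolerance = 1e-12)

  # standardized coefficients are invariant to affine predictor rescaling
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  y <- 0.8 * X$a - 0.5 * X$b + rnorm(30, 0, 0.3)
  r1 <- standardizedRegression(y, X)
  X2 <- transform(X, a = 100 * a + 7)
  r2 <- standardizedRegression(y, X2)
  expect_equal(r1@stdCoefficients, r2@stdCoefficients, tolerance = 1e-10)

  Xdup <- data.frame(a = X$a, b = X$a)
  expect_error(standardizedRegression(y, Xdup), "aliased.*b")
})

test_that("planted multivariate coefficients are recovered within 2 SE", {
  set.seed(19)
  hits <- 0; total <- 0
  for (rep in 1:25) {
    n <- 58
    X <- data.frame(FRic = rnorm(n), SR = rnorm(n), MAT = rnorm(n))
    beta <- c(FRic = 0.7, SR = 0.2, MAT = -0.3)
    y <- as.matrix(X) %*% beta + rnorm(n, 0, 0.5)
    r <- standardizedRegression(as.numeric(y), X)
    for (p in names(beta)) {
      total <- total + 1
      if (abs(r@coefficients[p] - beta[p]) <= 2 * r@se[p]) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("random-forest importance finds a dominant signal, reproducibly", {
  set.seed(99)
  n <- 40
  X <- data.frame(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- X$signal
  imp <- rfImportance(y, X, nTrees = 300, seed = 7)
  expect_identical(imp@predictors[imp@rank == 1L], "signal")
  expect_setequal(imp@rank, 1:3)
  # fixed seed: identical importances on re-run
  imp2 <- rfImportance(y, X, nTrees = 300, seed = 7)
  expect_identical(imp@importance, imp2@importance)
  expect_error(rfImportance(rep(1, n), X, nTrees = 300, seed = 1),
               "zero variance")
  expect_error(rfImportance(y[1:5], X[1:5, ], nTrees = 300, seed = 1),
               "at least 10")
})

test_that("per-function regressions report r, R2 and Holm-adjusted p", {
  d <- bemfFixture("paper_shape")
  div <- diversityMetrics(d$community, d$traits)
  tab <- perFunctionRegressions(d$functions, div)
  expect_identical(tab$func, colnames(functionValues(d$functions)))
  expect_true(all(tab$FRic_R2 >= 0 & tab$FRic_R2 <= 1))
  expect_equal(tab$SR_r^2, tab$SR_R2, tolerance = 1e-12)
  expect_true(all(tab$FRic_p_holm >= tab$FRic_p - 1e-15))
  # the planted FRic effects put PP and SAP among the strongest responses
  strongest <- tab$func[order(-tab$FRic_R2)][1:3]
  expect_true("PP" %in% strongest || "SAP" %in% strongest)
})
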