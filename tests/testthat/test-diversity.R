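test_that("species richness counts species with positive abundance", {
  com <- mkCommunity(matrix(c(2, 0, 1,
                              1, 1, 0,
                              0, 3, 0), 3, 3, byrow = TRUE))
  expect_identical(speciesRichness(com)@SR, c(2L, 2L, 1L))

  # presence/absence matrix of ones: SR = S everywhere
  ones <- mkCommunity(matrix(1, 4, 6))
  expect_identical(speciesRichness(ones)@SR, rep(6L, 4))
})

test_that("hull volume matches closed forms in 1 and 2 dimensions", {
  expect_equal(convexHullVolume(matrix(c(1, 3, 7))), 6)
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(convexHullVolume(tri), 0.5)
  # interior point leaves the hull unchanged
  expect_equal(convexHullVolume(rbind(tri, c(0.2, 0.2))), 0.5)
  # unit tetrahedron
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(convexHullVolume(tet), 1 / 6)
  # unit cube, with coplanar facets that must not be double counted
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convexHullVolume(cube), 1)
  expect_equal(convexHullVolume(rbind(cube, c(0.5, 0.5, 0.5))), 1)
  # degenerate sets are NA, not zero
  expect_true(is.na(convexHullVolume(rbind(c(0, 0), c(1, 1), c(2, 2)))))
  expect_true(is.na(convexHullVolume(rbind(c(0, 0, 0), c(1, 0, 0),
                                           c(0, 1, 0), c(1, 1, 0)))))
})

test_that("hull volume agrees with the qhull oracle on random point sets", {
  set.seed(1234)
  cases <- lapply(1:60, function(i) {
    d <- sample(1:3, 1)
    n <- sample((d + 1):10, 1)
    matrix(rnorm(n * d), n, d)
  })
  mine <- vapply(cases, convexHullVolume, numeric(1))
  oracle <- hullOracleVolumes(cases)
  expect_identical(is.na(mine), is.na(oracle))
  ok <- !is.na(mine)
  expect_lt(max(abs(mine[ok] - oracle[ok]) / oracle[ok]), 1e-9)
})

test_that("FRic is presence-based, order-invariant and monotone", {
  set.seed(9)
  tr <- mkTraits(matrix(rnorm(24), 8, 3))
  com <- mkCommunity(rbind(c(5, 1, 1, 1, 0, 0, 0, 0),
                           c(1, 1, 1, 1, 1, 0, 0, 0)))
  opts <- fricOptions(standardize = "none")
  f <- functionalRichness(com, tr, opts)
  expect_true(all(f@FRicDefined))
  # abundances are ignored: scaling counts changes nothing
  com10 <- mkCommunity(10 * abundance(com))
  expect_equal(functionalRichness(com10, tr, opts)@FRic, f@FRic)
  # adding a species never decreases the hull volume
  expect_gte(f@FRic[2], f@FRic[1])
  # species column order is irrelevant
  perm <- sample(8)
  comP <- CommunityMatrix(abundance(com)[, perm])
  expect_equal(functionalRichness(comP, tr, opts)@FRic, f@FRic)
  # duplicated trait rows are deduplicated, not degenerate
  com3 <- mkCommunity(rbind(c(1, 1, 1, 1, 1, 0, 0, 0)))
  trDup <- traitMatrix(tr); trDup[5, ] <- trDup[1, ]
  f3 <- functionalRichness(com3, TraitTable(trDup), opts)
  com4 <- mkCommunity(rbind(c(1, 1, 1, 1, 0, 0, 0, 0)))
  expect_equal(f3@FRic, functionalRichness(com4, tr, opts)@FRic)
})

test_that("FRic flags plots that cannot span trait space", {
  tr <- mkTraits(matrix(rnorm(15), 5, 3))
  com <- mkCommunity(rbind(c(1, 1, 1, 0, 0),    # 3 species in 3-D: no hull
                           c(1, 1, 1, 1, 1)))
  expect_warning(f <- functionalRichness(com, tr, fricOptions()),
                 "undefined")
  expect_false(f@FRicDefined[1])
  expect_true(is.na(f@FRic[1]))
  expect_true(f@FRicDefined[2])
  expect_true(all(f@SR[f@FRicDefined] >= 3 + 1))  # defined => SR >= dims + 1
  # the zero policy anchors degenerate plots at 0 instead
  f0 <- functionalRichness(com, tr, fricOptions(undefined = "zero"))
  expect_identical(f0@FRic[1], 0)
  # missing species are named
  comBad <- mkCommunity(matrix(1, 1, 6))
  expect_error(functionalRichness(comBad, tr, fricOptions()), "s6")
})

test_that("trait formulas follow their definitions", {
  expect_equal(needleLeafArea(1, 1), 2 * pi * sqrt(3) / 9)
  expect_equal(needleLeafArea(1, 1), 1.2092, tolerance = 1e-4)
  # bilinear in both arguments
  expect_equal(needleLeafArea(2 * 1.3, 0.7), 2 * needleLeafArea(1.3, 0.7))
  expect_error(needleLeafArea(0, 1), "> 0")

  expect_equal(specificLeafArea(100, 10), 10)
  expect_equal(specificLeafArea(3 * 100, 3 * 10), specificLeafArea(100, 10))
  expect_error(specificLeafArea(100, 0), "> 0")
  expect_equal(woodDensity(0.5, 1), 0.5)
  expect_error(woodDensity(1, -2), "> 0")
})
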