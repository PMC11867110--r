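test_that("tract enumeration matches the brute-force count", {
  d1 <- toyDesign(1)
  expect_length(enumerateTracts(TRUE, d1), 1L)
  d2 <- toyDesign(2)
  ## both active: singles at 1 (j1 in {1,2}), singles at 2 (j0 in {1,2}),
  ## the double cut (1,1,2,2): five classes
  tr <- enumerateTracts(c(TRUE, TRUE), d2)
  expect_length(tr, 5L)
  keys <- sort(vapply(tr, paste, "", collapse = ","))
  expect_equal(keys, sort(c("1,1,1,1", "1,1,1,2", "2,2,2,2",
                            "1,2,2,2", "1,1,2,2")))
  ## target 1 inactive: only the focal class at 2 remains
  tr2 <- enumerateTracts(c(FALSE, TRUE), d2)
  expect_length(tr2, 1L)
  expect_equal(unclass(tr2[[1L]]), c(2L, 2L, 2L, 2L), ignore_attr = TRUE)
  ## long-trim variants require a non-empty long range: a very narrow
  ## spacing leaves no room
  dTight <- toyDesign(2, 4L, 1L)  # long-left range empty at target 2
  trT <- enumerateTracts(c(TRUE, TRUE), dTight)
  expect_false(any(vapply(trT, function(tt) tt[1L] < tt[2L], TRUE)))
})

test_that("tract hazards follow the rate algebra", {
  p0 <- toyParams(2, doubleCutWeight = 0.5, longTrimLeft = 0, longTrimRight = 0)
  expect_equal(tractHazard(targetTract(1, 1, 1, 1), p0), 1)
  expect_equal(tractHazard(targetTract(1, 1, 2, 2), p0), 0.5 * (1 + 1))
  ## unequal rates: omega * (lam_j + lam_j')
  p12 <- toyParams(2, doubleCutWeight = 0.5, longTrimLeft = 0,
                   longTrimRight = 0, cutRates = c(1, 2) / 1.5)
  expect_equal(tractHazard(targetTract(1, 1, 2, 2), p12),
               0.5 * sum(c(1, 2) / 1.5))
  ## gamma0 = 1: long and short left variants of the same cut are
  ## equally likely
  p1 <- toyParams(2, longTrimLeft = 1)
  expect_equal(tractHazard(targetTract(1, 2, 2, 2), p1),
               tractHazard(targetTract(2, 2, 2, 2), p1))
  ## total hazard equals the lumped chain's leaving rate
  d <- toyDesign(2)
  rm <- statusRateMatrix(d, p1)
  expect_equal(-rm$Q[1L, 1L], totalHazard(c(TRUE, TRUE), d, p1))
  for (i in seq_along(rm$states))
    expect_equal(-rm$Q[i, i], totalHazard(rm$stateActive[[i]], d, p1))
})

test_that("repair-detail probabilities normalize per tract", {
  d <- toyDesign(2, 6L, 2L)
  p <- toyParams(2, insertMean = 0.3, maxInsertLen = 1L)
  u <- enumerateIndelUniverse(d, p)
  tractsU <- lapply(u, tractOfIndel, design = d)
  for (tt in enumerateTracts(c(TRUE, TRUE), d)) {
    s <- 0
    for (i in seq_along(u))
      if (all(unclass(tractsU[[i]]) == unclass(tt)))
        s <- s + exp(detailLogProbability(u[[i]], tt, d, p))
    expect_equal(s, 1, tolerance = 1e-9)
  }
})

test_that("insert content is uniform and trim laws are truncated Poisson", {
  d <- toyDesign(2, 6L, 2L)
  p <- toyParams(2, insertMean = 1.2, maxInsertLen = 6L)
  tt <- targetTract(1, 1, 1, 1)
  i1 <- indel(cutSites(d)[1L], 0, "ACGT", design = d)
  i2 <- indel(cutSites(d)[1L], 0, "AAAA", design = d)
  expect_equal(detailLogProbability(i1, tt, d, p),
               detailLogProbability(i2, tt, d, p))
  ## truncated-Poisson mass at zero on the short-left range 0..3
  ## (cut offset 2 within a 6 bp target -> boundary c - s = 4)
  d3 <- barcodeDesign("ACGTACG", rbind(c(0, 7)), 3)
  p3 <- editingParams(cutRates = 1, trimMeans = c(shortLeft = 1, longLeft = 3,
                                                  shortRight = 1, longRight = 3),
                      insertMean = 0, maxInsertLen = 0L)
  b <- trimBounds(d3)
  expect_equal(b[1L, "shortLeftMax"], 3L, ignore_attr = TRUE)
  pm <- gestaltphylo:::dtpois(0L, 1, 0L, 3L)
  expect_equal(pm, dpois(0, 1) / sum(dpois(0:3, 1)))
  ## mismatched tract is a contract violation
  expect_error(detailLogProbability(i1, targetTract(2, 2, 2, 2), d, p),
               "does not match")
})

test_that("indels map deterministically to tracts", {
  d <- toyDesign(3, 6L, 2L)   # cuts at 4, 10, 16
  ## focal deletion strictly inside target 2
  expect_equal(unclass(tractOfIndel(indel(9, 2, design = d), d)),
               c(2L, 2L, 2L, 2L), ignore_attr = TRUE)
  ## deletion from inside target 1 through the cut of target 3
  expect_equal(unclass(tractOfIndel(indel(3, 13, design = d), d)),
               c(1L, 1L, 3L, 3L), ignore_attr = TRUE)
  ## pure insertion at a cut bond
  expect_equal(unclass(tractOfIndel(indel(10, 0, "A", design = d), d)),
               c(2L, 2L, 2L, 2L), ignore_attr = TRUE)
  ## long left trim reaching into the neighbour
  expect_equal(unclass(tractOfIndel(indel(5, 6, design = d), d)),
               c(1L, 2L, 2L, 2L), ignore_attr = TRUE)
})

test_that("transition matrices are stochastic, irreversible and clocked", {
  d <- toyDesign(2)
  p <- toyParams(2, longTrimLeft = 0.2, longTrimRight = 0.2)
  rm <- statusRateMatrix(d, p)
  expect_true(all(abs(rowSums(rm$Q)) < 1e-12))
  P0 <- transitionProbabilityMatrix(rm, r = 0.3, t = 0)
  expect_equal(P0, diag(nrow(rm$Q)), ignore_attr = TRUE, tolerance = 1e-12)
  P <- transitionProbabilityMatrix(rm, r = 0.3, t = 2.5)
  expect_true(all(abs(rowSums(P) - 1) < 1e-10))
  expect_true(all(P >= -1e-12 & P <= 1 + 1e-12))
  ## irreversibility: an entry toward a strictly more-editable status is 0
  nact <- vapply(rm$stateActive, sum, 0L)
  for (i in seq_along(nact)) for (j in seq_along(nact))
    if (nact[j] > nact[i]) expect_identical(P[i, j], 0)
  ## single-target closed form
  d1 <- toyDesign(1)
  p1 <- toyParams(1)
  rm1 <- statusRateMatrix(d1, p1)
  h <- totalHazard(TRUE, d1, p1)
  P1 <- transitionProbabilityMatrix(rm1, r = 0.2, t = 3)
  expect_equal(P1["1", "1"], exp(-h * 0.2 * 3), tolerance = 1e-12)
})

test_that("editing parameters serialize to JSON and back", {
  p <- editingParams(clockRate = 0.017, cutRates = c(1.2, 0.8),
                     doubleCutWeight = 0.07, longTrimLeft = 0.04,
                     longTrimRight = 0.09, insertMean = 1.1,
                     maxInsertLen = 8L)
  f <- withr::local_tempfile(fileext = ".json")
  writeEditingParams(p, f)
  p2 <- readEditingParams(f)
  expect_equal(p2@clockRate, p@clockRate)
  expect_equal(p2@cutRates, p@cutRates)
  expect_equal(p2@trimMeans, p@trimMeans)
  expect_equal(p2@maxInsertLen, p@maxInsertLen)
})
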