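test_that("birth-death simulation conditions on tip counts and is seeded", {
  cfg <- birthDeathSimConfig(birthRate = 0.5, duration = 5, nMin = 4,
                             nMax = 8, seed = 11L)
  phy <- simulateBirthDeathTree(cfg)
  expect_s3_class(phy, "phylo")
  n <- length(phy$tip.label)
  expect_true(n >= 4 && n <= 8)
  validateLineageTree(phy)
  ## contemporaneous tips at the experiment end; origin time recorded
  expect_equal(treeHeight(phy) + attr(phy, "origin.time"), 5)
  ## determinism under the seed
  phy2 <- simulateBirthDeathTree(cfg)
  expect_identical(ape::write.tree(phy), ape::write.tree(phy2))
  ## impossible conditioning errors out with diagnostics
  expect_error(simulateBirthDeathTree(
    birthDeathSimConfig(birthRate = 0.01, duration = 1, nMin = 50,
                        nMax = 60, seed = 1L)), "rejections")
})

test_that("mean sampled tip count tracks e^{(beta-delta)T}", {
  set.seed(33)
  beta <- 0.8; T <- 3
  cfg <- birthDeathSimConfig(birthRate = beta, duration = T, nMin = 2,
                             nMax = Inf)
  ## condition only on survival with >= 2 tips; compare to the
  ## survival-conditioned expectation of a Yule population:
  ## N | N >= 2 where N ~ Geometric with mean e^{beta T}
  nrep <- 400
  tips <- replicate(nrep, length(simulateBirthDeathTree(cfg)$tip.label))
  q <- exp(-beta * T)                      # P(N = n) = q (1-q)^{n-1}
  condMean <- (exp(beta * T) - q) / (1 - q)  # E[N | N >= 2]
  se <- sd(tips) / sqrt(nrep)
  expect_lt(abs(mean(tips) - condMean), 3 * se + 1e-9)
})

test_that("clock zero leaves every tip unedited", {
  d <- toyDesign(2)
  p <- toyParams(2, clockRate = 0)
  phy <- simulateBirthDeathTree(birthDeathSimConfig(0.5, duration = 4,
                                                    nMin = 4, nMax = 8,
                                                    seed = 3L))
  aln <- simulateAlignment(phy, d, p)
  expect_true(all(vapply(alleles(aln), length, 0L) == 0L))
})

test_that("alignment simulation is seed-deterministic", {
  d <- toyDesign(3)
  p <- toyParams(3, clockRate = 0.3)
  phy <- simulateBirthDeathTree(birthDeathSimConfig(0.5, duration = 4,
                                                    nMin = 5, nMax = 5,
                                                    seed = 8L))
  a1 <- simulateAlignment(phy, d, p, seed = 42L)
  a2 <- simulateAlignment(phy, d, p, seed = 42L)
  expect_identical(vapply(alleles(a1), gestaltphylo:::alleleKey, ""),
                   vapply(alleles(a2), gestaltphylo:::alleleKey, ""))
})

test_that("single-target unedited survival matches e^{-h r t}", {
  d <- toyDesign(1)
  p <- toyParams(1, clockRate = 0.15)
  h <- totalHazard(TRUE, d, p)
  t <- 2.5
  nrep <- 10000
  set.seed(99)
  st0 <- list(al = list(), active = TRUE)
  unedited <- vapply(seq_len(nrep), function(i)
    length(gestaltphylo:::simulateBranch(st0, t, d, p)$al) == 0L, TRUE)
  pEmp <- mean(unedited)
  pTheo <- exp(-h * p@clockRate * t)
  se <- sqrt(pTheo * (1 - pTheo) / nrep)
  expect_lt(abs(pEmp - pTheo), 3 * se)
})

test_that("first-event tract classes follow the hazard ratios", {
  d <- toyDesign(2)
  p <- toyParams(2, clockRate = 1)
  tracts <- enumerateTracts(c(TRUE, TRUE), d)
  haz <- vapply(tracts, tractHazard, 0, params = p)
  keys <- vapply(tracts, paste, "", collapse = ",")
  set.seed(17)
  st0 <- list(al = list(), active = c(TRUE, TRUE))
  nev <- 10000
  got <- character(nev)
  i <- 0L
  while (i < nev) {
    res <- gestaltphylo:::simulateBranch(st0, 5, d, p)
    if (!length(res$events)) next
    i <- i + 1L
    got[i] <- paste(res$events[[1L]], collapse = ",")
  }
  obs <- table(factor(got, levels = keys))
  chi <- suppressWarnings(chisq.test(obs, p = haz / sum(haz)))
  expect_gt(chi$p.value, 0.001)
})

test_that("single-branch allele frequencies match the transition law", {
  ## total-variation distance between empirical allele frequencies and
  ## the analytic branch transition probabilities, M = 1, bounded details
  d <- toyDesign(1)
  p <- toyParams(1, clockRate = 0.25)
  t <- 2
  u <- enumerateIndelUniverse(d, p)
  states <- c(list(allele(list())), lapply(u, function(i) allele(list(i), d)))
  pTheo <- vapply(states, function(b)
    exp(branchTransitionLogProbability(allele(list()), b, t, d, p)), 0)
  expect_equal(sum(pTheo), 1, tolerance = 1e-9)
  set.seed(71)
  nrep <- 10000
  st0 <- list(al = list(), active = TRUE)
  keys <- vapply(states, gestaltphylo:::alleleKey, "")
  got <- vapply(seq_len(nrep), function(i) {
    res <- gestaltphylo:::simulateBranch(st0, t, d, p)
    gestaltphylo:::alleleKey(allele(res$al))
  }, "")
  emp <- as.numeric(table(factor(got, levels = keys))) / nrep
  tv <- 0.5 * sum(abs(emp - pTheo))
  expect_lt(tv, 0.03)
})

test_that("editability is monotone non-increasing along lineages", {
  d <- toyDesign(3)
  p <- toyParams(3, clockRate = 0.5)
  set.seed(2)
  st0 <- list(al = list(), active = rep(TRUE, 3))
  for (rep in 1:50) {
    res <- gestaltphylo:::simulateBranch(st0, 6, d, p)
    act <- rep(TRUE, 3)
    for (tt in res$events) {
      act2 <- act
      act2[tt[1L]:tt[4L]] <- FALSE
      expect_true(all(act2 <= act))
      act <- act2
    }
  }
})

test_that("alignment summaries report occupancy and diversity", {
  d <- toyDesign(2)
  unedited <- allele(list())
  aln <- barcodeAlignment(d, list(a = unedited, b = unedited))
  s <- summarizeAlignment(aln)
  expect_equal(s$meanIndelsPerSite, 0)
  expect_equal(s$uniqueAlleles, 1L)
  ## every cell with every target hit by focal indels: occupancy one
  full <- allele(list(indel(1, 2, design = d), indel(5, 2, design = d)), d)
  aln2 <- barcodeAlignment(d, list(a = full, b = full))
  s2 <- summarizeAlignment(aln2)
  expect_equal(s2$meanIndelsPerSite, 1)
  expect_equal(unname(s2$targetEditFrequency), c(1, 1))
})

test_that("the validation regime yields about half an indel per site", {
  ## 4-target shortened array, clock 0.02 indels/site/day over a 25-day
  ## recording window
  set.seed(123)
  design <- v7BarcodeDesign(4)
  params <- editingParams(clockRate = 0.02, cutRates = rep(1, 4),
                          doubleCutWeight = 0.05, longTrimLeft = 0.05,
                          longTrimRight = 0.05)
  ## stem edits are shared by all cells, so single-experiment occupancy is
  ## variable; average a few experiments
  occ <- vapply(1:4, function(i) {
    phy <- simulateBirthDeathTree(birthDeathSimConfig(
      birthRate = log(70) / 25, duration = 25, nMin = 50, nMax = 100))
    aln <- simulateAlignment(phy, design, params,
                             originTime = attr(phy, "origin.time"))
    summarizeAlignment(aln)$meanIndelsPerSite
  }, 0)
  expect_gt(mean(occ), 0.25)
  expect_lt(mean(occ), 0.8)
})
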