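test_that("effective sample size behaves like the spectral formula", {
  set.seed(1)
  x <- rnorm(10000)
  ess <- effectiveSampleSize(x)
  expect_gt(ess, 8000)
  expect_lt(ess, 12000)
  ## AR(1) with coefficient 0.9: ESS ~ n (1 - phi) / (1 + phi)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 10000))
  essAR <- effectiveSampleSize(ar)
  theo <- 10000 * (1 - 0.9) / (1 + 0.9)
  expect_gt(essAR, theo / 1.5)
  expect_lt(essAR, theo * 1.5)
  ## duplicating every sample halves the ESS fraction
  dup <- rep(x[1:4000], each = 2)
  expect_lt(effectiveSampleSize(dup) / 8000, 0.75)
  ## a constant series is defined to have ESS n
  expect_equal(effectiveSampleSize(rep(3.2, 50)), 50)
})

test_that("HPD intervals are the narrowest covering windows", {
  expect_equal(hpdInterval(rep(5, 20), 0.9), c(5, 5))
  set.seed(2)
  u <- runif(100000)
  expect_equal(diff(hpdInterval(u, 0.95)), 0.95, tolerance = 0.02)
  z <- rnorm(100000)
  h <- hpdInterval(z, 0.95)
  expect_equal(h[1L], -1.96, tolerance = 0.05)
  expect_equal(h[2L], 1.96, tolerance = 0.05)
  ## skewed distribution: HPD beats the central interval in width
  g <- rgamma(100000, shape = 2)
  expect_lt(diff(hpdInterval(g, 0.9)),
            diff(quantile(g, c(0.05, 0.95))) + 1e-9)
})

test_that("scale-move MH with Jacobian targets the right distribution", {
  ## one-parameter toy target: lognormal(0, 0.7); a missing Jacobian
  ## would visibly skew the sampled quantiles
  set.seed(3)
  x <- 1
  lp <- function(v) dlnorm(v, 0, 0.7, log = TRUE)
  out <- numeric(60000)
  for (i in seq_along(out)) {
    pr <- gestaltphylo:::proposeScale(x, 1.2)
    if (log(runif(1)) < lp(pr$value) - lp(x) + pr$logHR) x <- pr$value
    out[i] <- x
  }
  ## thin to near-independence: the chi-square requires it
  out <- out[seq(2001, 60000, by = 10)]
  qs <- quantile(out, c(0.1, 0.25, 0.5, 0.75, 0.9))
  ref <- qlnorm(c(0.1, 0.25, 0.5, 0.75, 0.9), 0, 0.7)
  expect_true(all(abs(log(qs) - log(ref)) < 0.1))
  chi <- suppressWarnings(chisq.test(
    table(cut(plnorm(out, 0, 0.7), seq(0, 1, 0.1)))))
  expect_gt(chi$p.value, 0.001)
})

test_that("prior-only sampling reproduces the prior quantiles", {
  set.seed(4)
  design <- toyDesign(2)
  params <- toyParams(2)
  priors <- defaultPriors(2)
  phy <- simulateBirthDeathTree(birthDeathSimConfig(0.5, duration = 4,
                                                    nMin = 4, nMax = 4))
  aln <- simulateAlignment(phy, design, params)
  tr <- runMcmc(list(mode = "fixed-topology", alignment = aln, tree = phy,
                     params = params, priors = priors, chainLength = 4e5,
                     thin = 40, likelihoodOff = TRUE, seed = 10))
  post <- discardBurnIn(tr, 0.2)@trace
  expect_gt(nrow(post), 5000)
  ks <- suppressWarnings(ks.test(post$clockRate, plnorm,
                                 priors$clockRate[1L], priors$clockRate[2L]))
  expect_gt(ks$p.value, 0.01)
  ks2 <- suppressWarnings(ks.test(post$longTrimLeft, plnorm,
                                  priors$longTrimLeft[1L],
                                  priors$longTrimLeft[2L]))
  expect_gt(ks2$p.value, 0.01)
  ## cut rates keep their mean-one constraint throughout
  expect_true(all(abs(rowMeans(post[, c("cutRate1", "cutRate2")]) - 1) < 1e-9))
})

test_that("fixed-topology runs keep the topology fixed", {
  set.seed(5)
  design <- toyDesign(2)
  params <- toyParams(2)
  phy <- simulateBirthDeathTree(birthDeathSimConfig(0.4, duration = 5,
                                                    nMin = 5, nMax = 5))
  aln <- simulateAlignment(phy, design, params)
  tr <- runMcmc(list(mode = "fixed-topology", alignment = aln, tree = phy,
                     params = params, estimate = c("clockRate", "nodeTimes"),
                     treePrior = list(model = "birthDeath", deathRate = 0,
                                      rho = 1, birthRate = 0.4),
                     chainLength = 400, thin = 20, seed = 6))
  hashes <- vapply(traceTrees(tr), gestaltphylo:::topologyHash, "")
  expect_length(unique(hashes), 1L)
  expect_true(all(is.finite(traceTable(tr)$posterior)))
})

test_that("full-tree runs explore topologies and stay finite", {
  set.seed(6)
  design <- toyDesign(2)
  params <- toyParams(2)
  phy <- simulateBirthDeathTree(birthDeathSimConfig(0.4, duration = 5,
                                                    nMin = 5, nMax = 5))
  aln <- simulateAlignment(phy, design, params)
  tr <- runMcmc(list(mode = "full-tree", alignment = aln, tree = phy,
                     params = params,
                     estimate = c("clockRate", "cutRates", "nodeTimes",
                                  "topology", "birthRate", "originTime"),
                     treePrior = list(model = "birthDeath", deathRate = 0,
                                      rho = 1, birthRate = 0.1),
                     chainLength = 600, thin = 30, seed = 7))
  tt <- traceTable(tr)
  expect_true(all(is.finite(tt$posterior)))
  expect_true(all(diff(tt$iteration) > 0))
  for (ph in traceTrees(tr)) validateLineageTree(ph)
})

test_that("pooled replicates sharpen the shared-parameter posterior", {
  ## low-editing regime: the clock stays informative, so replicates add
  ## information and the shared-parameter posterior narrows
  set.seed(7)
  design <- v7BarcodeDesign(2)
  params <- editingParams(clockRate = 0.02, cutRates = rep(1, 2),
                          doubleCutWeight = 0.05, longTrimLeft = 0.05,
                          longTrimRight = 0.05)
  priors <- defaultPriors(2)
  wins <- 0L
  nrep <- 5L
  for (i in seq_len(nrep)) {
    phy <- simulateBirthDeathTree(birthDeathSimConfig(
      log(8) / 25, duration = 25, nMin = 6, nMax = 8))
    aln <- simulateAlignment(phy, design, params)
    one <- runMcmc(list(mode = "fixed-topology", alignment = aln, tree = phy,
                        params = params, priors = priors,
                        chainLength = 3e4, thin = 30))
    pooled <- runMcmc(list(mode = "pooled",
                           alignment = list(aln, aln, aln),
                           tree = list(phy, phy, phy), params = params,
                           priors = priors, chainLength = 3e4, thin = 30))
    w1 <- diff(hpdInterval(discardBurnIn(one, 0.3)@trace$clockRate, 0.95))
    w3 <- diff(hpdInterval(discardBurnIn(pooled, 0.3)@trace$clockRate, 0.95))
    if (w3 < w1) wins <- wins + 1L
  }
  expect_gte(wins, nrep - 1L)
})

test_that("MCC trees summarize posterior clade frequencies", {
  t1 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  t2 <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1);")
  ## all samples identical
  mcc <- mccTree(rep(list(t1), 10))
  expect_equal(gestaltphylo:::topologyHash(mcc),
               gestaltphylo:::topologyHash(t1))
  expect_true(all(attr(mcc, "cladeSupport") == 1))
  ## 90/10 mixture selects the majority topology
  mix <- c(rep(list(t1), 18), rep(list(t2), 2))
  mcc2 <- mccTree(mix)
  expect_equal(gestaltphylo:::topologyHash(mcc2),
               gestaltphylo:::topologyHash(t1))
  sup <- attr(mcc2, "cladeSupport")
  expect_true(all(sup >= 0 & sup <= 1))
  expect_equal(max(sup), 1)           # the root clade is always present
  ## median heights: stretched copies give the median root height
  t3 <- t1; t3$edge.length <- t3$edge.length * 3
  mcc3 <- mccTree(c(rep(list(t1), 5), rep(list(t3), 6)), heights = "median")
  expect_equal(treeHeight(mcc3), 6)   # median of 5 x height2, 6 x height6
})

test_that("trace and tree logs round-trip and burn-in removal is idempotent", {
  set.seed(8)
  design <- toyDesign(2)
  params <- toyParams(2)
  phy <- simulateBirthDeathTree(birthDeathSimConfig(0.4, duration = 5,
                                                    nMin = 4, nMax = 4))
  aln <- simulateAlignment(phy, design, params)
  tr <- runMcmc(list(mode = "fixed-topology", alignment = aln, tree = phy,
                     params = params, chainLength = 2000, thin = 100,
                     seed = 9))
  f <- withr::local_tempfile(fileext = ".log")
  writeTraceLog(tr, f)
  tr2 <- readTraceLog(f)
  expect_equal(traceTable(tr2)$posterior, traceTable(tr)$posterior)
  expect_equal(traceTable(tr2)$clockRate, traceTable(tr)$clockRate)
  b1 <- discardBurnIn(tr, 0.3)
  b2 <- discardBurnIn(b1, 0.3)
  expect_equal(traceTable(b2), traceTable(b1))
  trees <- rep(list(phy), 4)
  f2 <- withr::local_tempfile(fileext = ".trees")
  writeTreeLog(trees, f2)
  back <- readTreeLog(f2)
  expect_length(back, 4L)
  expect_equal(sort(back[[1L]]$tip.label), sort(phy$tip.label))
})

test_that("a non-finite initial state is reported", {
  design <- toyDesign(2)
  params <- toyParams(2)
  phy <- simulateBirthDeathTree(birthDeathSimConfig(0.4, duration = 5,
                                                    nMin = 4, nMax = 4,
                                                    seed = 12L))
  aln <- simulateAlignment(phy, design, params, seed = 1L)
  ## an impossible fixed tree: zero length everywhere but edited tips
  if (any(vapply(alleles(aln), length, 0L) > 0L)) {
    phy0 <- phy
    phy0$edge.length[] <- 0
    expect_error(runMcmc(list(mode = "fixed-topology", alignment = aln,
                              tree = phy0, params = params,
                              chainLength = 100, thin = 10)),
                 "non-finite")
  } else succeed()
})
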