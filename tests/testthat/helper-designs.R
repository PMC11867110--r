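## Shared fixtures: tiny contiguous barcode designs whose full detail
## space is enumerable (for oracle comparisons) and editing parameters in
## various regimes. Everything is built in code.

toyDesign <- function(m = 2L, width = 4L, cutOffset3p = 2L) {
  seq <- paste(rep(c("A", "C", "G", "T"), length.out = m * width),
               collapse = "")
  starts <- (seq_len(m) - 1L) * width
  barcodeDesign(seq, cbind(starts, starts + width),
                rep(cutOffset3p, m), cutConvention = "offset3p")
}

## detail space finite and tiny: trims bounded by the narrow targets, no
## insertions unless asked for
toyParams <- function(m = 2L, clockRate = 0.15, doubleCutWeight = 0.5,
                      longTrimLeft = 0.3, longTrimRight = 0.3,
                      insertMean = 0, maxInsertLen = 0L,
                      cutRates = rep(1, m)) {
  editingParams(clockRate = clockRate, cutRates = cutRates,
                doubleCutWeight = doubleCutWeight,
                longTrimLeft = longTrimLeft, longTrimRight = longTrimRight,
                trimMeans = c(shortLeft = 1, longLeft = 3,
                              shortRight = 1, longRight = 3),
                insertMean = insertMean, maxInsertLen = maxInsertLen)
}

randomToyInstance <- function(m = sample(2:3, 1), nLeaves = sample(3:4, 1),
                              withInserts = FALSE) {
  design <- toyDesign(m)
  mi <- if (withInserts) 1L else 0L
  params <- toyParams(m,
                      clockRate = stats::runif(1, 0.05, 0.3),
                      doubleCutWeight = stats::runif(1, 0.2, 0.8),
                      longTrimLeft = stats::runif(1, 0.05, 0.5),
                      longTrimRight = stats::runif(1, 0.05, 0.5),
                      insertMean = 0.2 * mi, maxInsertLen = mi,
                      cutRates = exp(stats::runif(m, -0.3, 0.3)))
  phy <- simulateBirthDeathTree(birthDeathSimConfig(
    birthRate = 0.4, duration = 4, nMin = nLeaves, nMax = nLeaves))
  aln <- simulateAlignment(phy, design, params)
  list(design = design, params = params, phy = phy, aln = aln)
}

## does any leaf deletion strictly contain another leaf's indel?
hasMaskingPattern <- function(aln) {
  als <- alleles(aln)
  inds <- unlist(lapply(als, unclass), recursive = FALSE)
  if (length(inds) < 2L) return(FALSE)
  for (i in seq_along(inds)) for (j in seq_along(inds))
    if (i != j && gestaltphylo:::strictlyInside(inds[[i]], inds[[j]]))
      return(TRUE)
  FALSE
}

cherryTree <- function(t = 1) {
  ape::read.tree(text = sprintf("(a:%.10g,b:%.10g);", t, t))
}

## Independent Kingman-coalescent density used as an oracle: pairwise
## rates, written directly from the exponential waiting times.
kingmanLogDensityOracle <- function(phy, N) {
  n <- length(phy$tip.label)
  ages <- sort(gestaltphylo:::internalAges(phy))
  ll <- 0
  lo <- 0
  k <- n
  for (a in ages) {
    ll <- ll - choose(k, 2) * (a - lo) / N + log(1 / N)
    lo <- a
    k <- k - 1L
  }
  ll
}

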