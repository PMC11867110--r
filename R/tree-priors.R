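## Phylodynamic tree priors: the constant-rate birth-death-sampling
## process and the coalescent with deterministic exponential growth. Node
## times are stored forward (root earliest); densities convert to ages
## (time before the contemporaneous tips) internally.

## Extinction and single-sampled-descendant probabilities of one lineage
## over time t under (beta, delta) with present-day sampling rho.
bdP0P1 <- function(t, beta, delta, rho) {
  r0 <- beta - delta
  if (abs(r0) < 1e-12) {
    den <- 1 + rho * beta * t
    list(p0 = 1 - rho / den, p1 = rho / den^2)
  } else {
    A <- rho * beta + (beta * (1 - rho) - delta) * exp(-r0 * t)
    list(p0 = 1 - rho * r0 / A, p1 = rho * r0^2 * exp(-r0 * t) / A^2)
  }
}

#' Birth-death-sampling log-density of a time tree
#'
#' Constant-rate birth-death process with sampling probability `rho` at
#' present, conditioned on survival (at least one sampled lineage).
#' Conditioning is on the origin by default (the process starts with one
#' lineage `originTime` before present, a free parameter in inference) or
#' on the root split (`conditioning = "root"`, both root lineages leaving
#' sampled descendants). `conditionOnTips` additionally conditions on the
#' observed number of tips (origin conditioning only), making the density
#' integrate to one over the node-time space of an n-tip tree.
#'
#' @param phy Validated lineage tree with contemporaneous tips.
#' @param birthRate Division rate beta (> 0).
#' @param deathRate Death rate delta (>= 0).
#' @param rho Sampling probability at present (0 < rho <= 1).
#' @param originTime Time from the origin to the present; defaults to the
#'   tree's `origin.time` attribute. Required for `conditioning =
#'   "origin"` and must exceed the root age.
#' @param conditioning `"origin"` or `"root"`.
#' @param conditionOnTips Condition on the sampled tip count.
#' @return Log-density, with the conditioning recorded in attributes.
#' @export
birthDeathLogDensity <- function(phy, birthRate, deathRate = 0, rho = 1,
                                 originTime = NULL,
                                 conditioning = c("origin", "root"),
                                 conditionOnTips = FALSE) {
  conditioning <- match.arg(conditioning)
  validateLineageTree(phy)
  stopifnot(birthRate > 0, deathRate >= 0, rho > 0, rho <= 1)
  n <- length(phy$tip.label)
  ages <- internalAges(phy)          # root first
  rootAge <- ages[1L]
  ll <- 0
  if (conditioning == "origin") {
    if (is.null(originTime)) {
      stem <- attr(phy, "origin.time")
      if (is.null(stem)) stop("origin conditioning requires originTime")
      originTime <- stem + rootAge
    }
    if (!is.finite(originTime)) stop("origin conditioning requires originTime")
    if (originTime < rootAge) return(structure(-Inf, conditioning = conditioning))
    pT <- bdP0P1(originTime, birthRate, deathRate, rho)
    ll <- log(pT$p1) - log(1 - pT$p0)
    for (a in ages) {
      pa <- bdP0P1(a, birthRate, deathRate, rho)
      ll <- ll + log(birthRate) + log(pa$p1)
    }
    if (conditionOnTips) {
      u <- 1 - pT$p1 / (1 - pT$p0)
      ll <- ll - (log(1 - u) + (n - 1) * log(u))
    }
  } else {
    if (conditionOnTips)
      stop("conditionOnTips is implemented for origin conditioning")
    pr <- bdP0P1(rootAge, birthRate, deathRate, rho)
    ll <- 2 * log(pr$p1) - 2 * log(1 - pr$p0)
    if (n > 2L) for (a in ages[-1L]) {
      pa <- bdP0P1(a, birthRate, deathRate, rho)
      ll <- ll + log(birthRate) + log(pa$p1)
    }
  }
  structure(ll, conditioning = conditioning,
            conditionOnTips = conditionOnTips)
}

#' Exponential-growth coalescent log-density of a time tree
#'
#' Coalescent with deterministic population trajectory `N(t) = Npresent *
#' exp(-g * a)` at age `a` before present (equivalently `N(t) = e^{g t}`
#' forward from `N = 1` at the origin with `Npresent = e^{g T}`). With
#' `growthRate = 0` this is exactly the constant-size Kingman coalescent.
#'
#' @param phy Validated lineage tree with contemporaneous tips.
#' @param growthRate Growth rate g (>= 0 for a growing population; any
#'   finite value accepted).
#' @param popSize Scaled population size at present (> 0).
#' @return Log-density.
#' @export
coalescentExpLogDensity <- function(phy, growthRate, popSize) {
  validateLineageTree(phy)
  stopifnot(popSize > 0)
  n <- length(phy$tip.label)
  ages <- sort(internalAges(phy))    # increasing coalescent ages
  g <- growthRate
  invN <- function(a) exp(g * a) / popSize        # 1 / N(age a)
  cumInt <- function(u, w) {                      # int_u^w da / N(a)
    if (abs(g) < 1e-14) (w - u) / popSize
    else (exp(g * w) - exp(g * u)) / (g * popSize)
  }
  ll <- 0
  lo <- 0
  k <- n
  for (a in ages) {
    ll <- ll - choose(k, 2) * cumInt(lo, a) + log(invN(a))
    lo <- a
    k <- k - 1L
  }
  ll
}

#' Expected population size under birth-death growth
#'
#' `N(t) = exp((beta - delta) * t)` starting from one cell.
#'
#' @param beta Division rate.
#' @param delta Death rate.
#' @param t Elapsed time (>= 0).
#' @export
expectedPopulationSize <- function(beta, delta, t) {
  stopifnot(t >= 0)
  exp((beta - delta) * t)
}

#' Sampling proportion implied by a coalescent-growth fit
#'
#' With `s` sampled cells and deterministic population `N(t) = exp(g t)`,
#' the fraction of the population sequenced is `s / exp(g t)`. (At `g = 0`
#' the convention `N = 1` makes the ratio degenerate and simply returns
#' `s`.)
#'
#' @param s Number of sampled cells (>= 1).
#' @param g Growth rate.
#' @param t Experiment duration (> 0).
#' @export
coalescentSamplingProportion <- function(s, g, t) {
  stopifnot(s >= 1, t > 0)
  s / exp(g * t)
}
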