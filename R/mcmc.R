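## Metropolis-Hastings machinery: diagnostics (ESS, HPD), maximum clade
## credibility summarization, trace/tree logs, and the sampler itself.
## Two execution paths share one configuration interface: a compiled
## fixed-tree path (editing parameters only; used by the calibration
## study, prior-only validation and pooled-replicate analyses) and a
## general R path with node-time and topology moves plus phylodynamic
## parameters.

#' Effective sample size of an MCMC series
#'
#' `ESS = n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated
#' at the first non-positive autocorrelation. A constant series is defined
#' to have ESS `n`.
#'
#' @param x Numeric vector (>= 10 samples).
#' @return Effective sample size.
#' @export
effectiveSampleSize <- function(x) {
  n <- length(x)
  if (n < 10L) stop("need at least 10 samples")
  if (stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 2000L), plot = FALSE,
                   demean = TRUE)$acf[-1L]
  s <- 0
  for (r in ac) {
    if (r <= 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' Highest posterior density interval
#'
#' The narrowest contiguous interval containing `ceiling(level * n)` of
#' the sorted samples.
#'
#' @param x Numeric vector (>= 10 samples).
#' @param level Credibility level in (0, 1).
#' @return Numeric `c(lower, upper)`.
#' @export
hpdInterval <- function(x, level = 0.95) {
  stopifnot(level > 0, level < 1, length(x) >= 10L)
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(level * n)
  if (m >= n) return(c(xs[1L], xs[n]))
  widths <- xs[m:n] - xs[1L:(n - m + 1L)]
  i <- which.min(widths)
  c(xs[i], xs[i + m - 1L])
}

#' Maximum clade credibility tree
#'
#' Selects, from a posterior tree sample, the sampled tree maximizing the
#' product of the posterior frequencies of its clades; node heights are
#' set to the per-clade median height over the samples containing the
#' clade, and node labels carry the clade posterior probabilities.
#'
#' @param trees List of `ape::phylo` (or `multiPhylo`) with identical tip
#'   sets.
#' @param burnIn Fraction of initial samples to discard.
#' @param heights `"median"` (per-clade median, default) or `"keep"`
#'   (retain the selected sample's own heights).
#' @return The summary tree with `node.label` = clade support.
#' @export
mccTree <- function(trees, burnIn = 0, heights = c("median", "keep")) {
  heights <- match.arg(heights)
  trees <- unclass(trees)
  stopifnot(length(trees) >= 1L, burnIn >= 0, burnIn < 1)
  drop <- floor(burnIn * length(trees))
  trees <- trees[(drop + 1L):length(trees)]
  tipU <- sort(trees[[1L]]$tip.label)
  nTrees <- length(trees)
  cladeCount <- new.env(parent = emptyenv())
  cladeAges <- new.env(parent = emptyenv())
  treeClades <- vector("list", nTrees)
  for (i in seq_len(nTrees)) {
    phy <- trees[[i]]
    masks <- cladeMasks(phy, tipU)
    ages <- nodeAges(phy)
    n <- length(phy$tip.label)
    keys <- character(phy$Nnode)
    for (v in (n + 1L):(n + phy$Nnode)) {
      k <- paste(as.integer(masks[[v]]), collapse = "")
      keys[v - n] <- k
      cladeCount[[k]] <- (if (is.null(cladeCount[[k]])) 0L else cladeCount[[k]]) + 1L
      cladeAges[[k]] <- c(cladeAges[[k]], ages[v])
    }
    treeClades[[i]] <- keys
  }
  scores <- vapply(seq_len(nTrees), function(i)
    sum(log(vapply(treeClades[[i]], function(k) cladeCount[[k]], 0L) / nTrees)),
    0)
  best <- which.max(scores)
  phy <- trees[[best]]
  n <- length(phy$tip.label)
  keys <- treeClades[[best]]
  support <- vapply(keys, function(k) cladeCount[[k]] / nTrees, 0)
  phy$node.label <- format(support, digits = 3)
  if (heights == "median") {
    ages <- nodeAges(phy)
    for (v in (n + 1L):(n + phy$Nnode))
      ages[v] <- stats::median(cladeAges[[keys[v - n]]])
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
      phy$edge.length[e] <- ages[p] - ages[ch]
    }
  }
  attr(phy, "cladeSupport") <- support
  phy
}

#' Write / read a BEAST-style trace log
#'
#' Tab-separated text with a `Sample` column followed by posterior,
#' likelihood, prior and the scalar parameters; re-loadable with
#' `readTraceLog`.
#'
#' @param trace A [PosteriorTrace-class].
#' @param path File path.
#' @export
writeTraceLog <- function(trace, path) {
  tr <- trace@trace
  out <- cbind(Sample = tr$iteration,
               tr[, setdiff(colnames(tr), "iteration"), drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraceLog
#' @export
readTraceLog <- function(path) {
  tr <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  colnames(tr)[colnames(tr) == "Sample"] <- "iteration"
  new("PosteriorTrace", trace = tr, trees = list(), config = list())
}

#' Write / read a Nexus tree log
#'
#' @param trees List of `ape::phylo`.
#' @param path File path.
#' @export
writeTreeLog <- function(trees, path) {
  class(trees) <- "multiPhylo"
  ape::write.nexus(trees, file = path)
  invisible(path)
}

#' @rdname writeTreeLog
#' @export
readTreeLog <- function(path) {
  tr <- ape::read.nexus(path)
  if (inherits(tr, "phylo")) return(list(tr))
  tips <- attr(tr, "TipLabel")   # shared-label compressed storage
  out <- unclass(tr)
  if (!is.null(tips))
    out <- lapply(out, function(p) { p$tip.label <- tips; p })
  out
}

#' Remove burn-in from a posterior trace
#'
#' Drops the first `fraction` of sampled iterations (idempotent when the
#' trace was already truncated to the same absolute iteration).
#'
#' @param trace A [PosteriorTrace-class].
#' @param fraction Burn-in fraction of the *chain length* (default 0.3).
#' @export
discardBurnIn <- function(trace, fraction = 0.3) {
  tr <- trace@trace
  cut <- fraction * max(tr$iteration)
  keep <- tr$iteration >= cut
  new("PosteriorTrace", trace = tr[keep, , drop = FALSE],
      trees = if (length(trace@trees)) trace@trees[keep] else list(),
      config = trace@config)
}

## log-scale random-walk proposal; Hastings-Jacobian log(s)
proposeScale <- function(x, lambda) {
  s <- exp(lambda * (stats::runif(1L) - 0.5))
  list(value = x * s, logHR = log(s))
}

dlnormOr <- function(x, spec) {
  if (x <= 0) return(-Inf)
  stats::dlnorm(x, spec[1L], spec[2L], log = TRUE)
}

#' Default priors for the sampler
#'
#' Lognormal priors for the positive scalars and a symmetric Dirichlet for
#' the mean-one cut-rate vector; centred on the editing regime of a
#' V7-like barcode (clock about 0.02 indels per site per day over a
#' 25-day recording window).
#'
#' @param m Number of targets.
#' @return Named list of prior specifications.
#' @export
defaultPriors <- function(m = 4L) {
  list(
    clockRate = c(meanlog = log(0.02), sdlog = 0.5),
    doubleCutWeight = c(meanlog = log(0.05), sdlog = 0.5),
    longTrimLeft = c(meanlog = log(0.05), sdlog = 0.5),
    longTrimRight = c(meanlog = log(0.05), sdlog = 0.5),
    cutRatesAlpha = rep(10, m),
    birthRate = c(meanlog = log(0.1), sdlog = 0.75),
    growthRate = c(meanlog = log(0.1), sdlog = 0.75),
    originTime = c(meanlog = log(30), sdlog = 0.5)
  )
}

#' Draw editing parameters from the priors
#'
#' @param priors As from [defaultPriors()].
#' @param template An [EditingParams-class] supplying the fixed detail-law
#'   parameters.
#' @return An [EditingParams-class].
#' @export
sampleEditingParamsFromPrior <- function(priors, template) {
  m <- length(template@cutRates)
  alpha <- rep(priors$cutRatesAlpha, length.out = m)
  g <- stats::rgamma(m, shape = alpha)
  lam <- m * g / sum(g)
  editingParams(
    clockRate = stats::rlnorm(1L, priors$clockRate[1L], priors$clockRate[2L]),
    cutRates = lam,
    doubleCutWeight = stats::rlnorm(1L, priors$doubleCutWeight[1L],
                                    priors$doubleCutWeight[2L]),
    longTrimLeft = stats::rlnorm(1L, priors$longTrimLeft[1L],
                                 priors$longTrimLeft[2L]),
    longTrimRight = stats::rlnorm(1L, priors$longTrimRight[1L],
                                  priors$longTrimRight[2L]),
    trimMeans = template@trimMeans,
    insertMean = template@insertMean,
    maxInsertLen = template@maxInsertLen,
    normalizeCutRates = FALSE)
}

editingScalars <- c("clockRate", "doubleCutWeight", "longTrimLeft",
                    "longTrimRight")

#' Run the Metropolis-Hastings sampler
#'
#' Samples editing parameters and optionally node times, tree topology and
#' phylodynamic parameters. The configuration list understands:
#' \describe{
#'   \item{mode}{`"fixed-topology"` (default), `"full-tree"`, or
#'     `"pooled"` (list of alignments/trees sharing editing parameters).}
#'   \item{alignment, tree}{A [BarcodeAlignment-class] and `ape::phylo`
#'     (lists of them in pooled mode). The tree is the fixed tree or the
#'     starting state.}
#'   \item{params}{Initial [EditingParams-class]; its trim/insert means
#'     stay fixed.}
#'   \item{priors}{See [defaultPriors()].}
#'   \item{estimate}{Character vector among `clockRate`,
#'     `doubleCutWeight`, `longTrimLeft`, `longTrimRight`, `cutRates`,
#'     `nodeTimes`, `topology`, `birthRate`, `growthRate`, `originTime`.}
#'   \item{treePrior}{`NULL`, or `list(model = "birthDeath", deathRate,
#'     rho, birthRate, originTime)` or `list(model = "coalescentExp",
#'     growthRate)`; listed rate parameters are starting values.}
#'   \item{chainLength, thin, burninFrac, seed}{Chain controls; proposal
#'     scales auto-tune during the burn-in fraction only.}
#'   \item{likelihoodOff}{Sample from the prior only.}
#'   \item{hazardScale}{Cut-rate scaling for misspecification studies.}
#' }
#' Fixed-topology (and pooled fixed-topology) runs restricted to editing
#' parameters execute in compiled code.
#'
#' @param config Configuration list.
#' @return A [PosteriorTrace-class].
#' @export
runMcmc <- function(config) {
  cfg <- config
  cfg$mode <- if (is.null(cfg$mode)) "fixed-topology" else cfg$mode
  stopifnot(cfg$mode %in% c("fixed-topology", "full-tree", "pooled"))
  if (is.null(cfg$estimate)) cfg$estimate <- c(editingScalars, "cutRates")
  if (is.null(cfg$thin)) cfg$thin <- max(1L, cfg$chainLength %/% 1000L)
  cfg$chainLength <- (cfg$chainLength %/% cfg$thin) * cfg$thin
  if (is.null(cfg$burninFrac)) cfg$burninFrac <- 0.3
  if (is.null(cfg$likelihoodOff)) cfg$likelihoodOff <- FALSE
  if (is.null(cfg$hazardScale)) cfg$hazardScale <- 1
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  alns <- if (cfg$mode == "pooled") cfg$alignment else list(cfg$alignment)
  trees <- if (cfg$mode == "pooled") cfg$tree else list(cfg$tree)
  m <- length(cfg$params@cutRates)
  if (is.null(cfg$priors)) cfg$priors <- defaultPriors(m)
  treeish <- c("nodeTimes", "topology", "birthRate", "growthRate", "originTime")
  compiledOK <- !any(treeish %in% cfg$estimate) && is.null(cfg$treePrior) &&
    cfg$mode != "full-tree"
  if (compiledOK) runMcmcCompiled(cfg, alns, trees)
  else runMcmcGeneral(cfg, alns, trees)
}

runMcmcCompiled <- function(cfg, alns, trees) {
  m <- length(cfg$params@cutRates)
  progs <- lapply(seq_along(alns), function(i) {
    ev <- compileTreeLikelihood(trees[[i]], alns[[i]], cfg$params,
                                maxStates = cfg$maxStates %||% 256L)
    list(flat = ev$flat, pairOff = as.integer(ev$pairOff),
         pairTask = as.integer(ev$pairTask),
         edgeParent = as.integer(ev$edgeParent),
         edgeChild = as.integer(ev$edgeChild),
         candCount = as.integer(ev$candCount),
         postNodes = as.integer(ev$postNodes),
         childEdges = as.integer(ev$childEdges),
         root = as.integer(ev$root), nTips = as.integer(ev$nTips),
         tEdge = as.numeric(trees[[i]]$edge.length * ev$branchRates))
  })
  pr <- cfg$priors
  lnPrior <- rbind(pr$clockRate, pr$doubleCutWeight,
                   pr$longTrimLeft, pr$longTrimRight)
  alpha <- rep(pr$cutRatesAlpha, length.out = m)
  lamLogConst <- lgamma(sum(alpha)) - sum(lgamma(alpha))
  init <- c(cfg$params@clockRate, cfg$params@doubleCutWeight,
            cfg$params@longTrimLeft, cfg$params@longTrimRight,
            cfg$params@cutRates)
  ## moves on parameters not being estimated get zero weight
  w <- c(as.numeric("clockRate" %in% cfg$estimate),
         as.numeric("doubleCutWeight" %in% cfg$estimate),
         as.numeric("longTrimLeft" %in% cfg$estimate),
         as.numeric("longTrimRight" %in% cfg$estimate),
         as.numeric("cutRates" %in% cfg$estimate) * 2)
  res <- cpp_mcmc_fixed(progs, init, lnPrior, alpha, lamLogConst,
                        as.integer(cfg$chainLength), as.integer(cfg$thin),
                        cfg$burninFrac, w, !cfg$likelihoodOff,
                        cfg$hazardScale)
  tr <- as.data.frame(res$trace)
  colnames(tr) <- c("iteration", "posterior", "likelihood", "prior",
                    editingScalars, paste0("cutRate", seq_len(m)))
  new("PosteriorTrace", trace = tr, trees = list(), config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
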