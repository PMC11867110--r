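#' Configuration for birth-death tree simulation
#'
#' @param birthRate Division rate beta (> 0, per time unit).
#' @param deathRate Apoptosis rate delta (>= 0).
#' @param rho Present-day sampling probability (0 < rho <= 1).
#' @param duration Experiment duration T (> 0, time units).
#' @param nMin,nMax Accepted range of sampled tip counts (rejection
#'   sampling conditions the tree on this range).
#' @param condition `"time"`: run to `duration`, sample survivors with
#'   `rho`, reject until the tip count falls in `[nMin, nMax]`.
#'   `"tips"`: stop the moment the population first reaches `nMin`
#'   (requires `nMin == nMax`) and cut all lineages there; useful for
#'   tree-shape studies, where the topology law is the same.
#' @param seed Optional RNG seed.
#' @return A validated list of class `"birthDeathSimConfig"`.
#' @export
birthDeathSimConfig <- function(birthRate, deathRate = 0, rho = 1,
                                duration = 1, nMin = 2L, nMax = Inf,
                                condition = c("time", "tips"), seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(birthRate > 0, deathRate >= 0, rho > 0, rho <= 1,
            duration > 0, nMin <= nMax, nMin >= 2)
  if (condition == "tips" && nMin != nMax)
    stop("condition = 'tips' requires nMin == nMax")
  structure(list(birthRate = birthRate, deathRate = deathRate, rho = rho,
                 duration = duration, nMin = nMin, nMax = nMax,
                 condition = condition, seed = seed),
            class = "birthDeathSimConfig")
}

#' Simulate a birth-death lineage tree
#'
#' Forward Gillespie simulation from a single lineage: each extant lineage
#' divides at rate `birthRate` and dies at rate `deathRate`; at the end of
#' the experiment each survivor is retained with probability `rho` and the
#' tree is pruned to the sampled tips. Simulations are repeated until the
#' sampled tip count falls in the accepted range (an error reports the
#' acceptance problem after 1000 consecutive rejections). The returned
#' tree is rooted at the first division ancestral to all sampled tips; the
#' time from origin to that root is stored in the `origin.time` attribute.
#'
#' @param config A [birthDeathSimConfig()].
#' @return An `ape::phylo` with contemporaneous tips labelled
#'   `cell1, cell2, ...`.
#' @export
simulateBirthDeathTree <- function(config) {
  stopifnot(inherits(config, "birthDeathSimConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  for (attempt in seq_len(1000L)) {
    res <- simulateBDOnce(config)
    if (!is.null(res)) return(res)
  }
  stop("1000 consecutive rejections; tip-count range [", config$nMin, ", ",
       config$nMax, "] has near-zero acceptance under beta = ",
       config$birthRate, ", delta = ", config$deathRate, ", rho = ",
       config$rho, ", duration = ", config$duration)
}

simulateBDOnce <- function(config) {
  beta <- config$birthRate; delta <- config$deathRate
  Tend <- config$duration
  ## segment arrays; segment = lineage between birth and split/death/end
  parent <- c(NA_integer_); tb <- c(0); te <- c(NA_real_)
  kid1 <- c(NA_integer_); kid2 <- c(NA_integer_)
  alive <- 1L
  t <- 0
  hardCap <- max(20000L, 200L * config$nMax)
  if (!is.finite(hardCap)) hardCap <- 200000L
  repeat {
    n <- length(alive)
    if (n == 0L) break
    if (config$condition == "tips" && n >= config$nMin) { Tend <- t; break }
    rate <- n * (beta + delta)
    t2 <- t + stats::rexp(1L, rate)
    if (config$condition == "time" && t2 > Tend) break
    t <- t2
    pick <- alive[sample.int(n, 1L)]
    if (stats::runif(1L) < beta / (beta + delta)) {
      te[pick] <- t
      for (k in 1:2) {
        parent <- c(parent, pick); tb <- c(tb, t); te <- c(te, NA_real_)
        kid1 <- c(kid1, NA_integer_); kid2 <- c(kid2, NA_integer_)
      }
      kid1[pick] <- length(tb) - 1L; kid2[pick] <- length(tb)
      alive <- c(alive[alive != pick], length(tb) - 1L, length(tb))
      if (length(tb) > hardCap) return(NULL)  # runaway population
    } else {
      te[pick] <- t
      alive <- alive[alive != pick]
    }
  }
  if (config$condition == "time") {
    survivors <- alive
    sampled <- survivors[stats::runif(length(survivors)) < config$rho]
  } else {
    sampled <- alive
  }
  if (length(sampled) < config$nMin || length(sampled) > config$nMax ||
      length(sampled) < 2L) return(NULL)
  te[sampled] <- Tend
  isSampled <- logical(length(tb)); isSampled[sampled] <- TRUE
  labels <- character(length(tb))
  labels[sampled] <- paste0("cell", seq_along(sampled))
  build <- function(i) {
    if (isSampled[i]) return(list(str = labels[i], len = Tend - tb[i]))
    if (is.na(kid1[i])) return(NULL)
    r1 <- build(kid1[i]); r2 <- build(kid2[i])
    seg <- te[i] - tb[i]
    if (is.null(r1) && is.null(r2)) return(NULL)
    if (is.null(r2)) return(list(str = r1$str, len = r1$len + seg))
    if (is.null(r1)) return(list(str = r2$str, len = r2$len + seg))
    list(str = sprintf("(%s:%.10g,%s:%.10g)", r1$str, r1$len, r2$str, r2$len),
         len = seg)
  }
  res <- build(1L)
  if (is.null(res)) return(NULL)
  phy <- ape::read.tree(text = paste0(res$str, ";"))
  attr(phy, "origin.time") <- Tend - treeHeight(phy)
  phy
}

#' Simulate a GESTALT alignment along a time-scaled tree
#'
#' Forward simulation of the editing process: starting unedited at the
#' root, each branch runs a competing-exponentials (Gillespie) simulation
#' over the target tracts available in the current editability status,
#' with per-event hazards `tractHazard * clockRate * branch multiplier`.
#' Each event draws trim/insert details from the configured truncated
#' Poisson laws (the unobservable all-zero repair of single cuts is
#' rejected and redrawn) and applies the resulting indel, physically
#' removing any earlier indel lying strictly inside a spanning deletion
#' (masking). Target statuses are monotone non-increasing along every
#' lineage.
#'
#' @param phy A validated lineage tree.
#' @param design A [BarcodeDesign-class].
#' @param params An [EditingParams-class].
#' @param branchRates Optional per-edge clock multipliers (order of
#'   `phy$edge`).
#' @param seed Optional RNG seed.
#' @param originTime Optional stem length above the root: editing then
#'   starts that long before the first division (the recorder is active
#'   from the founding cell onward), matching the `originTime` option of
#'   the likelihood.
#' @return A [BarcodeAlignment-class] with one allele per tip.
#' @export
simulateAlignment <- function(phy, design, params, branchRates = NULL,
                              seed = NULL, originTime = NULL) {
  validateLineageTree(phy)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(branchRates)) branchRates <- rep(1, nrow(phy$edge))
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  kidsOf <- vector("list", nn)
  edgeOfChild <- integer(nn)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]
    kidsOf[[p]] <- c(kidsOf[[p]], phy$edge[e, 2L])
    edgeOfChild[phy$edge[e, 2L]] <- e
  }
  tipAllele <- vector("list", n)
  recurse <- function(node, state) {
    if (node <= n) { tipAllele[[node]] <<- state$al; return(invisible()) }
    for (child in kidsOf[[node]]) {
      e <- edgeOfChild[child]
      st2 <- simulateBranch(state, phy$edge.length[e] * branchRates[e],
                            design, params)
      recurse(child, st2)
    }
  }
  root <- n + 1L
  rootState <- list(al = list(), active = rep(TRUE, numTargets(design)))
  if (!is.null(originTime) && originTime > 0)
    rootState <- simulateBranch(rootState, originTime, design, params)
  recurse(root, rootState)
  als <- lapply(tipAllele, function(inds) allele(inds, design))
  barcodeAlignment(design, als, phy$tip.label)
}

simulateBranch <- function(state, t, design, params) {
  al <- state$al; active <- state$active
  r <- params@clockRate
  elapsed <- 0
  events <- list()
  repeat {
    tracts <- enumerateTracts(active, design)
    if (!length(tracts)) break
    haz <- vapply(tracts, tractHazard, 0, params = params)
    total <- sum(haz) * r
    if (total <= 0) break
    elapsed <- elapsed + stats::rexp(1L, total)
    if (elapsed > t) break
    tt <- tracts[[sample.int(length(tracts), 1L, prob = haz)]]
    ind <- drawIndelDetails(tt, design, params)
    keep <- !vapply(al, function(q) strictlyInside(q, ind), TRUE)
    al <- c(al[keep], list(ind))
    active[tt[1L]:tt[4L]] <- FALSE
    events[[length(events) + 1L]] <- tt
  }
  list(al = al, active = active, events = events)
}

drawIndelDetails <- function(tt, design, params) {
  bounds <- trimBounds(design)
  j0 <- tt[1L]; j <- tt[2L]; jp <- tt[3L]; j1 <- tt[4L]
  tm <- params@trimMeans
  rngL <- if (j0 < j) c(bounds[j, "longLeftMin"], bounds[j, "longLeftMax"])
          else c(0L, bounds[j, "shortLeftMax"])
  rngR <- if (j1 > jp) c(bounds[jp, "longRightMin"], bounds[jp, "longRightMax"])
          else c(0L, bounds[jp, "shortRightMax"])
  meanL <- if (j0 < j) tm[["longLeft"]] else tm[["shortLeft"]]
  meanR <- if (j1 > jp) tm[["longRight"]] else tm[["shortRight"]]
  repeat {
    l0 <- rtpois(1L, meanL, rngL[1L], rngL[2L])
    l1 <- rtpois(1L, meanR, rngR[1L], rngR[2L])
    L <- rtpois(1L, params@insertMean, 0L, params@maxInsertLen)
    if (!(j == jp && j0 == j && j1 == jp && l0 == 0L && l1 == 0L && L == 0L))
      break  # the all-zero repair of a single cut is unobservable
  }
  ins <- if (L > 0L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  else ""
  start <- design@cuts[j] - l0
  del <- (design@cuts[jp] + l1) - start
  indel(start, del, ins, design = design)
}

#' Summary statistics of a barcode alignment
#'
#' @param alignment A [BarcodeAlignment-class].
#' @return A list: `nCells`, `indelsPerCell` (integer vector),
#'   `meanIndelsPerSite` (edited-target occupancies over `M * nCells`),
#'   `uniqueAlleles`, and `targetEditFrequency` (per-target fraction of
#'   cells in which the target is edited).
#' @export
summarizeAlignment <- function(alignment) {
  design <- alignment@design
  m <- numTargets(design)
  n <- length(alignment@cellIds)
  statuses <- vapply(alignment@alleles, targetStatus, logical(m),
                     design = design)
  if (m == 1L) statuses <- matrix(statuses, nrow = 1L)
  edited <- !statuses
  list(
    nCells = n,
    indelsPerCell = vapply(alignment@alleles, length, 0L),
    meanIndelsPerSite = sum(edited) / (m * n),
    uniqueAlleles = length(unique(vapply(alignment@alleles, alleleKey, ""))),
    targetEditFrequency = rowMeans(edited)
  )
}
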