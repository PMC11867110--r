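## Branch state spaces.
##
## The transition probability between an ancestral allele `a` and a
## descendant constraint `b` over a branch marginalizes, besides the order
## and timing of the observed new indels D = b \ a, all *hidden* editing
## events: indels introduced and then physically removed ("masked") by an
## observed inter-target deletion introduced later on the same branch. A
## branch state is a pair (A, H): A = subset of D already introduced, H =
## set of targets deactivated by hidden events. Everything incompatible
## with reaching `b` flows to an absorbing sink. The chain is finite and
## acyclic, and its generator entries are simple products of the editing
## parameters, which is what makes fast re-evaluation under new parameters
## possible.

## Is indel `d` strictly inside the deleted interval of deletion `D`?
strictlyInside <- function(d, D) {
  if (D$del == 0L) return(FALSE)
  a <- D$start; b <- D$start + D$del
  if (d$del == 0L) a < d$start && d$start < b
  else a < d$start && (d$start + d$del) < b
}

## Ancestral compatibility: every indel of `a` is identically present in
## `b`, or masked (strictly inside) by a deletion of b \ a. Returns NULL
## if incompatible, else list(D = new indels, masked = masked indels of a).
alleleTransitionSets <- function(a, b) {
  keysA <- vapply(a, indelKey, "")
  keysB <- vapply(b, indelKey, "")
  D <- b[!(keysB %in% keysA)]
  lost <- a[!(keysA %in% keysB)]
  for (d in lost) {
    covered <- any(vapply(D, function(Dd) strictlyInside(d, Dd), TRUE))
    if (!covered) return(NULL)
  }
  list(D = D, masked = lost)
}

## Targets deactivated by an allele under the tract convention (range
## j0..j1 of each indel's tract).
tractDeactivated <- function(al, design) {
  inactive <- rep(FALSE, numTargets(design))
  for (ind in al) {
    tt <- tractOfIndel(ind, design)
    inactive[tt[1L]:tt[4L]] <- TRUE
  }
  inactive
}

## Marginal probability that a tract's repair details produce a footprint
## fitting strictly inside the deleted interval of observed deletion
## `dObs`. Insert length is marginalized fully (inserted bases vanish with
## the hidden indel); trim lengths are summed over the values keeping the
## deletion strictly inside; the excluded all-zero outcome of single cuts
## is accounted for.
pfitTract <- function(tract, dObs, design, params) {
  if (dObs$del == 0L) return(0)
  bounds <- trimBounds(design)
  j0 <- tract[1L]; j <- tract[2L]; jp <- tract[3L]; j1 <- tract[4L]
  cl <- design@cuts[j]; cr <- design@cuts[jp]
  s0 <- dObs$start; e0 <- dObs$start + dObs$del
  tm <- params@trimMeans
  rngL <- if (j0 < j) c(bounds[j, "longLeftMin"], bounds[j, "longLeftMax"])
          else c(0L, bounds[j, "shortLeftMax"])
  rngR <- if (j1 > jp) c(bounds[jp, "longRightMin"], bounds[jp, "longRightMax"])
          else c(0L, bounds[jp, "shortRightMax"])
  meanL <- if (j0 < j) tm[["longLeft"]] else tm[["shortLeft"]]
  meanR <- if (j1 > jp) tm[["longRight"]] else tm[["shortRight"]]
  hiL <- min(rngL[2L], cl - s0 - 1L)
  hiR <- min(rngR[2L], e0 - cr - 1L)
  if (hiL < rngL[1L] || hiR < rngR[1L]) return(0)
  SL <- sum(dtpois(rngL[1L]:hiL, meanL, rngL[1L], rngL[2L]))
  SR <- sum(dtpois(rngR[1L]:hiR, meanR, rngR[1L], rngR[2L]))
  p <- SL * SR
  if (j == jp && j0 == j && j1 == jp) {
    p0 <- dtpois(0L, meanL, rngL[1L], rngL[2L]) *
          dtpois(0L, meanR, rngR[1L], rngR[2L]) *
          dtpois(0L, params@insertMean, 0L, params@maxInsertLen)
    p <- (p - p0) / (1 - p0)   # exclude the unobservable null repair
  }
  max(p, 0)
}

## Hazard-term and transition encoding of one tract: type 1 = single cut,
## 2 = double cut; eL/eR flag the long class.
tractTerm <- function(tt) {
  c(type = if (tt[2L] == tt[3L]) 1L else 2L,
    j = tt[2L], jp = tt[3L],
    eL = as.integer(tt[1L] < tt[2L]), eR = as.integer(tt[4L] > tt[3L]))
}

#' Build the branch state space between two alleles
#'
#' Constructs the finite continuous-time chain whose initial state is the
#' ancestral allele `a` and whose accepting states carry all new observed
#' indels of `b`, marginalizing hidden masked events through target-set
#' states. Used internally by the likelihood; exported for inspection.
#'
#' @param a,b Ancestor and descendant `"gestaltAllele"` objects.
#' @param design A [BarcodeDesign-class].
#' @param params An [EditingParams-class] (detail laws enter through the
#'   observed indels' detail probabilities and hidden-fit marginals).
#' @param maxStatesPerBranch Hard cap on the branch state count.
#' @return `NULL` when `a` is not ancestrally compatible with `b`;
#'   otherwise a list with `nstate`, `accept` (logical), per-state hazard
#'   terms and transitions, and `detconst` (the summed detail
#'   log-probabilities of the new observed indels; `-Inf` when some
#'   observed detail is inadmissible).
#' @export
buildBranchStateSpace <- function(a, b, design, params, maxStatesPerBranch = 512L) {
  sets <- alleleTransitionSets(a, b)
  if (is.null(sets)) return(NULL)
  D <- sets$D
  nD <- length(D)
  m <- numTargets(design)
  initInactive <- tractDeactivated(a, design)
  tractsD <- lapply(D, tractOfIndel, design = design)
  reqD <- lapply(tractsD, function(tt) unique(c(tt[1L], tt[2L], tt[3L], tt[4L])))
  detconst <- 0
  for (i in seq_along(D))
    detconst <- detconst + detailLogProbability(D[[i]], tractsD[[i]], design, params)

  key <- function(A, H) paste(paste(as.integer(A), collapse = ""),
                              paste(as.integer(H), collapse = ""), sep = "|")
  states <- list(list(A = rep(FALSE, nD), H = rep(FALSE, m)))
  index <- structure(1L, names = key(states[[1L]]$A, states[[1L]]$H))
  hterms <- list()
  trans <- list()
  i <- 1L
  while (i <= length(states)) {
    st <- states[[i]]
    active <- !initInactive & !st$H
    for (k in seq_len(nD)) if (st$A[k]) {
      tt <- tractsD[[k]]
      active[tt[1L]:tt[4L]] <- FALSE
    }
    tracts <- enumerateTracts(active, design)
    ht <- matrix(0L, nrow = length(tracts), ncol = 5L,
                 dimnames = list(NULL, c("type", "j", "jp", "eL", "eR")))
    tr <- NULL
    remaining <- which(!st$A)
    reqRemaining <- unique(unlist(reqD[remaining]))
    for (ti in seq_along(tracts)) {
      tt <- tracts[[ti]]
      term <- tractTerm(tt)
      ht[ti, ] <- term
      rng <- tt[1L]:tt[4L]
      ## observed channel: the tract of a not-yet-introduced indel of D
      obsK <- remaining[vapply(remaining, function(k)
        all(unclass(tractsD[[k]]) == unclass(tt)), TRUE)]
      if (length(obsK) == 1L) {
        A2 <- st$A; A2[obsK] <- TRUE
        k2 <- key(A2, st$H)
        to <- index[k2]
        if (is.na(to)) {
          states[[length(states) + 1L]] <- list(A = A2, H = st$H)
          to <- length(states)
          index[k2] <- to
          if (to > maxStatesPerBranch)
            stop("branch state space exceeds ", maxStatesPerBranch, " states")
        }
        tr <- rbind(tr, c(to, term, w = 1))
      }
      ## hidden channel: masked by a not-yet-introduced observed deletion,
      ## without deactivating any target still needed by remaining
      ## observed indels
      if (!length(intersect(rng, reqRemaining))) {
        pfit <- 0
        for (k in remaining)
          pfit <- pfit + pfitTract(tt, D[[k]], design, params)
        if (pfit > 0) {
          H2 <- st$H; H2[rng] <- TRUE
          k2 <- key(st$A, H2)
          to <- index[k2]
          if (is.na(to)) {
            states[[length(states) + 1L]] <- list(A = st$A, H = H2)
            to <- length(states)
            index[k2] <- to
            if (to > maxStatesPerBranch)
              stop("branch state space exceeds ", maxStatesPerBranch, " states")
          }
          tr <- rbind(tr, c(to, term, w = pfit))
        }
      }
    }
    hterms[[i]] <- ht
    trans[[i]] <- if (is.null(tr)) matrix(0, 0L, 7L) else tr
    i <- i + 1L
  }
  accept <- vapply(states, function(st) all(st$A), TRUE)
  list(nstate = length(states), accept = accept, states = states,
       hterms = hterms, trans = trans, detconst = detconst, nD = nD)
}

## Hazard of one encoded term row under parameters.
termHazard <- function(term, params, hazardScale = 1) {
  lam <- params@cutRates * hazardScale
  base <- if (term[[1L]] == 1L) lam[term[[2L]]]
          else params@doubleCutWeight * (lam[term[[2L]]] + lam[term[[3L]]])
  g0 <- params@longTrimLeft; g1 <- params@longTrimRight
  pl <- if (term[[4L]]) g0 / (1 + g0) else 1 / (1 + g0)
  pr <- if (term[[5L]]) g1 / (1 + g1) else 1 / (1 + g1)
  base * pl * pr
}

## Dense (sub-stochastic) generator of a branch state space, in hazard
## units; multiply by r * t before exponentiating. Reference path.
branchGenerator <- function(space, params, hazardScale = 1) {
  n <- space$nstate
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ht <- space$hterms[[i]]
    htot <- 0
    if (nrow(ht)) for (r_ in seq_len(nrow(ht)))
      htot <- htot + termHazard(ht[r_, ], params, hazardScale)
    tr <- space$trans[[i]]
    if (nrow(tr)) for (r_ in seq_len(nrow(tr))) {
      h <- termHazard(tr[r_, 2:6], params, hazardScale) * tr[r_, 7L]
      Q[i, tr[r_, 1L]] <- Q[i, tr[r_, 1L]] + h
    }
    Q[i, i] <- Q[i, i] - htot
  }
  Q
}

#' Log transition probability along one branch
#'
#' The log-probability that a lineage starting with allele `a` ends with
#' exactly allele `b` after calendar time `t` under clock rate
#' `r = params@clockRate * rateMultiplier`: the (init, accept) entry of the
#' branch chain's matrix exponential plus the detail log-probabilities of
#' the new observed indels. Incompatible pairs give `-Inf`.
#'
#' @param a,b Ancestor and descendant alleles.
#' @param t Branch length (time units), `>= 0`.
#' @param design A [BarcodeDesign-class].
#' @param params An [EditingParams-class].
#' @param rateMultiplier Optional branch-specific clock multiplier.
#' @param hazardScale Internal scaling of all cut rates (used by
#'   model-misspecification experiments); leave at 1.
#' @return Log-probability (`<= 0`, possibly `-Inf`).
#' @export
branchTransitionLogProbability <- function(a, b, t, design, params,
                                           rateMultiplier = 1,
                                           hazardScale = 1) {
  stopifnot(t >= 0)
  space <- buildBranchStateSpace(a, b, design, params)
  if (is.null(space)) return(-Inf)
  if (!is.finite(space$detconst)) return(-Inf)
  Q <- branchGenerator(space, params, hazardScale)
  rt <- params@clockRate * rateMultiplier * t
  if (space$nstate == 1L) {
    if (!space$accept[1L]) return(-Inf)
    return(Q[1L, 1L] * rt + space$detconst)
  }
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * rt, sparse = FALSE)))
  p <- sum(P[1L, space$accept])
  if (p <= 0) return(-Inf)
  log(p) + space$detconst
}

#' Enumerate the indel universe admissible under a design
#'
#' Lists every indel the editing model can generate: all target tracts
#' combined with every admissible trim-length pair and insertion (lengths
#' up to `params@maxInsertLen`, content enumerated over A/C/G/T). Only
#' usable when the detail space is small (toy designs); intended for the
#' exact candidate-state universe and the brute-force oracle.
#'
#' @param design A [BarcodeDesign-class].
#' @param params An [EditingParams-class] (`maxInsertLen <= 2` enforced).
#' @param maxIndels Hard cap on the universe size.
#' @return List of [indel()] objects.
#' @export
enumerateIndelUniverse <- function(design, params, maxIndels = 5000L) {
  if (params@maxInsertLen > 2L)
    stop("indel universe enumeration requires maxInsertLen <= 2")
  m <- numTargets(design)
  bounds <- trimBounds(design)
  ct <- design@cuts
  inserts <- ""
  if (params@maxInsertLen >= 1L) inserts <- c(inserts, c("A", "C", "G", "T"))
  if (params@maxInsertLen >= 2L)
    inserts <- c(inserts, as.vector(outer(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T"), paste0)))
  out <- list()
  allTracts <- enumerateTracts(rep(TRUE, m), design)
  for (tt in allTracts) {
    j0 <- tt[1L]; j <- tt[2L]; jp <- tt[3L]; j1 <- tt[4L]
    rngL <- if (j0 < j) bounds[j, "longLeftMin"]:bounds[j, "longLeftMax"]
            else 0L:bounds[j, "shortLeftMax"]
    rngR <- if (j1 > jp) bounds[jp, "longRightMin"]:bounds[jp, "longRightMax"]
            else 0L:bounds[jp, "shortRightMax"]
    for (l0 in rngL) for (l1 in rngR) for (ins in inserts) {
      if (j == jp && l0 == 0L && l1 == 0L && !nzchar(ins)) next  # null repair
      start <- ct[j] - l0
      del <- (ct[jp] + l1) - start
      ind <- indel(start, del, ins, design = design)
      implied <- tractOfIndel(ind, design)
      if (!all(unclass(implied) == unclass(tt))) next  # boundary-coincident class
      out[[length(out) + 1L]] <- ind
      if (length(out) > maxIndels)
        stop("indel universe exceeds ", maxIndels, " indels; shrink the design")
    }
  }
  ## de-duplicate (distinct tracts can imply the same physical indel only
  ## through the class filter above, but be safe)
  keys <- vapply(out, indelKey, "")
  out[!duplicated(keys)]
}

#' Candidate ancestral allele sets for every node
#'
#' For each internal node, the candidate indels are those that every leaf
#' below either carries identically or masks (footprint strictly inside one
#' of its deletions); candidate alleles are all mutually compatible subsets
#' (disjoint footprints and touched targets), ordered by indel count with
#' the unedited allele first. Leaves carry exactly their observed allele.
#'
#' @param phy A validated lineage tree (`ape::phylo`); tip labels must
#'   match the alignment's cell ids.
#' @param alignment A [BarcodeAlignment-class].
#' @param stateUniverse `"observed"` draws candidate indels from those seen
#'   in the alignment (the standard parsimony-guided scheme);
#'   `"bounded"` from the design's full admissible indel space (exact, toy
#'   designs only).
#' @param maxStates Cap on candidate alleles per node; exceeding it is an
#'   error asking to raise the cap (never a silent truncation).
#' @param params Needed for `stateUniverse = "bounded"`.
#' @return List over nodes (ape numbering) of lists of alleles.
#' @export
ancestralStateSets <- function(phy, alignment,
                               stateUniverse = c("observed", "bounded"),
                               maxStates = 256L, params = NULL) {
  stateUniverse <- match.arg(stateUniverse)
  design <- alignment@design
  n <- length(phy$tip.label)
  pos <- match(phy$tip.label, alignment@cellIds)
  if (anyNA(pos)) stop("tree tip labels do not match alignment cell ids")
  leafAllele <- alignment@alleles[pos]
  universe <- if (stateUniverse == "observed") {
    u <- unlist(lapply(leafAllele, function(al) unclass(al)), recursive = FALSE)
    if (length(u)) u[!duplicated(vapply(u, indelKey, ""))] else list()
  } else {
    if (is.null(params)) stop("stateUniverse = 'bounded' requires params")
    enumerateIndelUniverse(design, params)
  }
  nn <- n + phy$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(n)) sets[[i]] <- list(leafAllele[[i]])
  ## tips below each internal node
  below <- vector("list", nn)
  for (i in seq_len(n)) below[[i]] <- i
  poE <- phy$edge[postorderEdges(phy), , drop = FALSE]
  for (e in seq_len(nrow(poE))) {
    p <- poE[e, 1L]; c_ <- poE[e, 2L]
    below[[p]] <- c(below[[p]], below[[c_]])
  }
  presentOrMasked <- function(d, al) {
    dk <- indelKey(d)
    for (ind in al) {
      if (indelKey(ind) == dk) return(TRUE)
      if (strictlyInside(d, ind)) return(TRUE)
    }
    FALSE
  }
  for (v in (n + 1L):nn) {
    tips <- below[[v]]
    cand <- universe[vapply(universe, function(d)
      all(vapply(tips, function(tp) presentOrMasked(d, leafAllele[[tp]]), TRUE)),
      TRUE)]
    sets[[v]] <- compatibleSubsetAlleles(cand, design, maxStates)
  }
  sets
}

## All alleles formed from mutually compatible subsets of `cand` indels:
## pairwise disjoint footprints and touched-target sets. Ordered by size
## (unedited first), deterministic within size by indel keys.
compatibleSubsetAlleles <- function(cand, design, maxStates) {
  k <- length(cand)
  if (k == 0L) return(list(allele(list())))
  keys <- vapply(cand, indelKey, "")
  ord <- order(vapply(cand, `[[`, 1L, "start"),
               vapply(cand, `[[`, 1L, "del"), keys)
  cand <- cand[ord]
  touched <- lapply(cand, touchedTargets, design = design)
  fp <- t(vapply(cand, indelFootprint, c(0, 0)))
  compat <- matrix(TRUE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    overlap <- fp[i, 1L] < fp[j, 2L] && fp[j, 1L] < fp[i, 2L]
    shared <- length(intersect(touched[[i]], touched[[j]])) > 0L
    compat[i, j] <- !(overlap || shared)
  }
  results <- list(integer(0))
  grow <- function(chosen, startAt) {
    for (i in startAt:k) {
      if (i > k) break
      if (all(compat[chosen, i]) || !length(chosen)) {
        newSet <- c(chosen, i)
        results[[length(results) + 1L]] <<- newSet
        if (length(results) > maxStates)
          stop("ancestral candidate set exceeds maxStates = ", maxStates,
               "; raise maxStates to proceed")
        if (i < k) grow(newSet, i + 1L)
      }
    }
  }
  grow(integer(0), 1L)
  sizes <- vapply(results, length, 0L)
  results <- results[order(sizes)]
  lapply(results, function(idx) allele(cand[idx]))
}
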