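## Pruning likelihood.
##
## The tree likelihood is assembled in two stages. `compileTreeLikelihood`
## does all structural work once per (tree, alignment): candidate ancestral
## allele sets per node, one branch state space per (parent candidate,
## child candidate) pair per edge (de-duplicated through a registry), all
## flattened into plain integer/double vectors. Evaluation under concrete
## editing parameters then reduces to filling in hazards, exponentiating
## each small acyclic generator (closed form or uniformization, in C) and
## running Felsenstein pruning over the candidate sets; per-edge values are
## cached so that a move touching one branch only recomputes that branch.

compileFlatten <- function(taskList) {
  nT <- length(taskList)
  tNState <- integer(nT); tStateOff <- integer(nT); tDetConst <- numeric(nT)
  sAccept <- integer(0); sHtOff <- integer(0); sHtN <- integer(0)
  sTrOff <- integer(0); sTrN <- integer(0)
  ht <- matrix(0L, 0L, 5L); trI <- matrix(0L, 0L, 6L); trW <- numeric(0)
  sOff <- 0L
  for (t in seq_len(nT)) {
    sp <- taskList[[t]]
    tNState[t] <- sp$nstate
    tStateOff[t] <- sOff
    tDetConst[t] <- sp$detconst
    for (i in seq_len(sp$nstate)) {
      sAccept <- c(sAccept, as.integer(sp$accept[i]))
      h <- sp$hterms[[i]]
      sHtOff <- c(sHtOff, nrow(ht)); sHtN <- c(sHtN, nrow(h))
      ht <- rbind(ht, h)
      tr <- sp$trans[[i]]
      sTrOff <- c(sTrOff, nrow(trI)); sTrN <- c(sTrN, nrow(tr))
      if (nrow(tr)) {
        trI <- rbind(trI, cbind(tr[, 1L, drop = FALSE],
                                tr[, 2:6, drop = FALSE]))
        trW <- c(trW, tr[, 7L])
      }
    }
    sOff <- sOff + sp$nstate
  }
  list(tNState = tNState, tStateOff = tStateOff, tDetConst = tDetConst,
       sAccept = sAccept, sHtOff = sHtOff, sHtN = sHtN,
       sTrOff = sTrOff, sTrN = sTrN,
       htType = as.integer(ht[, 1L]), htJ = as.integer(ht[, 2L]),
       htJp = as.integer(ht[, 3L]), htEL = as.integer(ht[, 4L]),
       htER = as.integer(ht[, 5L]),
       trTo = as.integer(trI[, 1L]), trType = as.integer(trI[, 2L]),
       trJ = as.integer(trI[, 3L]), trJp = as.integer(trI[, 4L]),
       trEL = as.integer(trI[, 5L]), trER = as.integer(trI[, 6L]),
       trW = trW)
}

#' Compile a reusable tree-likelihood evaluator
#'
#' Performs the structural (parameter-independent) part of the pruning
#' likelihood once, returning an evaluator that can be re-evaluated cheaply
#' under new editing parameters, branch-rate multipliers or branch lengths
#' — the work pattern of an MCMC run. Partial results are cached per edge
#' and recomputed only for edges marked dirty (all edges when parameters
#' change).
#'
#' @inheritParams ancestralStateSets
#' @param params An [EditingParams-class]; its trim/insert length means fix
#'   the detail laws baked into the compiled structure (re-compile to
#'   change them).
#' @param originTime Optional stem length above the root (time units)
#'   during which the barcode must stay unedited.
#' @param branchRates Optional per-edge clock multipliers (order of
#'   `phy$edge`); default 1.
#' @return An object of class `"gestaltLikelihoodEvaluator"`.
#' @export
compileTreeLikelihood <- function(phy, alignment, params,
                                  stateUniverse = c("observed", "bounded"),
                                  maxStates = 256L, originTime = NULL,
                                  branchRates = NULL) {
  stateUniverse <- match.arg(stateUniverse)
  validateLineageTree(phy)
  design <- alignment@design
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  root <- n + 1L
  cand <- ancestralStateSets(phy, alignment, stateUniverse, maxStates, params)
  cand[[root]] <- list(allele(list()))  # editing starts unedited at the root
  candCount <- vapply(cand, length, 0L)

  registry <- new.env(parent = emptyenv())
  taskList <- list()
  getTask <- function(x, y) {
    k <- paste(alleleKey(x), alleleKey(y), sep = "=>")
    id <- registry[[k]]
    if (!is.null(id)) return(id)
    sp <- buildBranchStateSpace(x, y, design, params)
    id <- if (is.null(sp) || !is.finite(sp$detconst)) 0L else {
      taskList[[length(taskList) + 1L]] <<- sp
      length(taskList)
    }
    registry[[k]] <- id
    id
  }
  nE <- nrow(phy$edge)
  pairOff <- integer(nE); pairTask <- integer(0)
  for (e in seq_len(nE)) {
    p <- phy$edge[e, 1L]; c_ <- phy$edge[e, 2L]
    pairOff[e] <- length(pairTask)
    for (x in cand[[p]]) for (y in cand[[c_]])
      pairTask <- c(pairTask, getTask(x, y))
  }
  postNodes <- postorderNodes(phy)  # children before parents
  edgeOfChild <- integer(nn)
  edgeOfChild[phy$edge[, 2L]] <- seq_len(nE)
  childEdges <- t(vapply(postNodes, function(u)
    edgeOfChild[phy$edge[phy$edge[, 1L] == u, 2L]], c(0L, 0L)))

  ev <- new.env(parent = emptyenv())
  ev$phy <- phy
  ev$design <- design
  ev$alignment <- alignment
  ev$cand <- cand
  ev$candCount <- candCount
  ev$taskList <- taskList
  ev$flat <- compileFlatten(taskList)
  ev$pairOff <- pairOff
  ev$pairTask <- pairTask
  ev$edgeParent <- phy$edge[, 1L]
  ev$edgeChild <- phy$edge[, 2L]
  ev$postNodes <- as.integer(postNodes)
  ev$childEdges <- childEdges
  ev$root <- root
  ev$nTips <- n
  ev$vals <- rep(NA_real_, length(pairTask))
  ev$paramFingerprint <- NULL
  ev$detailFingerprint <- c(params@trimMeans, params@insertMean,
                            as.numeric(params@maxInsertLen))
  ev$originTime <- originTime
  ev$branchRates <- if (is.null(branchRates)) rep(1, nE) else branchRates
  ev$stateUniverse <- stateUniverse
  class(ev) <- "gestaltLikelihoodEvaluator"
  ev
}

#' @export
print.gestaltLikelihoodEvaluator <- function(x, ...) {
  cat("compiled tree likelihood:", length(x$phy$tip.label), "tips,",
      length(x$taskList), "unique branch state spaces,",
      length(x$pairTask), "edge transitions\n")
  invisible(x)
}

#' Evaluate a compiled tree likelihood
#'
#' @param ev A `"gestaltLikelihoodEvaluator"`.
#' @param params An [EditingParams-class]; detail-law parameters must match
#'   the ones the evaluator was compiled with.
#' @param edgeLengths Optional replacement branch lengths (order of
#'   `phy$edge`); defaults to the compiled tree's.
#' @param dirtyEdges Integer vector of edge indices whose cached values
#'   must be recomputed; `NULL` recomputes everything. Ignored (treated as
#'   all-dirty) when parameters changed since the last evaluation.
#' @param hazardScale Internal cut-rate scaling for misspecification
#'   experiments; leave at 1.
#' @return Log-likelihood (may be `-Inf`).
#' @export
evalTreeLikelihood <- function(ev, params, edgeLengths = NULL,
                               dirtyEdges = NULL, hazardScale = 1) {
  fp <- c(params@clockRate, params@cutRates, params@doubleCutWeight,
          params@longTrimLeft, params@longTrimRight, hazardScale)
  det <- c(params@trimMeans, params@insertMean, as.numeric(params@maxInsertLen))
  if (any(det != ev$detailFingerprint))
    stop("detail-law parameters changed; recompile the evaluator")
  if (is.null(edgeLengths)) edgeLengths <- ev$phy$edge.length
  paramsSame <- !is.null(ev$paramFingerprint) &&
    length(fp) == length(ev$paramFingerprint) && all(fp == ev$paramFingerprint)
  if (!paramsSame || anyNA(ev$vals)) dirtyEdges <- NULL
  dirty <- if (is.null(dirtyEdges)) seq_len(nrow(ev$phy$edge)) else
    as.integer(dirtyEdges)
  rt <- params@clockRate * ev$branchRates * edgeLengths
  ll <- cpp_eval_loglik(ev$flat,
                        as.numeric(params@cutRates), params@doubleCutWeight,
                        params@longTrimLeft, params@longTrimRight,
                        as.numeric(rt), as.numeric(hazardScale),
                        as.integer(ev$pairOff), as.integer(ev$pairTask),
                        as.integer(ev$edgeParent), as.integer(ev$edgeChild),
                        as.integer(ev$candCount), as.integer(ev$postNodes),
                        as.integer(ev$childEdges), as.integer(ev$root),
                        as.integer(ev$nTips), ev$vals, as.integer(dirty))
  ev$paramFingerprint <- fp
  if (!is.null(ev$originTime)) {
    h0 <- totalHazard(rep(TRUE, numTargets(ev$design)), ev$design, params) *
      hazardScale
    ll <- ll - h0 * params@clockRate * ev$originTime
  }
  ll
}

#' Phylogenetic log-likelihood of a barcode alignment on a time tree
#'
#' Felsenstein pruning over candidate ancestral allele sets, with the
#' branch transition probabilities of
#' [branchTransitionLogProbability()]: ancestral states are propagated as
#' sets of observed indels, and editing events masked by later inter-target
#' deletions are marginalized within each branch's state space. The root
#' state is the unedited barcode.
#'
#' @inheritParams compileTreeLikelihood
#' @param engine `"compiled"` (C implementation) or `"reference"` (plain R
#'   matrix exponentials; slow, used for cross-checks).
#' @param hazardScale Internal cut-rate scaling; leave at 1.
#' @return Log-likelihood (`<= 0` up to floating point, possibly `-Inf`).
#' @examples
#' design <- v7BarcodeDesign(2)
#' params <- editingParams(clockRate = 0.02, cutRates = c(1, 1))
#' phy <- ape::read.tree(text = "(a:10,b:10);")
#' aln <- barcodeAlignment(design, list(a = allele(list()), b = allele(list())))
#' treeLogLikelihood(phy, aln, params)  # pure survival: -h * r * total time
#' @export
treeLogLikelihood <- function(phy, alignment, params,
                              stateUniverse = c("observed", "bounded"),
                              maxStates = 256L, originTime = NULL,
                              branchRates = NULL,
                              engine = c("compiled", "reference"),
                              hazardScale = 1) {
  engine <- match.arg(engine)
  ev <- compileTreeLikelihood(phy, alignment, params, stateUniverse,
                              maxStates, originTime, branchRates)
  if (engine == "compiled")
    return(evalTreeLikelihood(ev, params, hazardScale = hazardScale))
  referenceEval(ev, params, hazardScale)
}

## Reference evaluation: identical pruning, but per-branch transition
## probabilities through Matrix::expm in R.
referenceEval <- function(ev, params, hazardScale = 1) {
  phy <- ev$phy
  nE <- nrow(phy$edge)
  rt <- params@clockRate * ev$branchRates * phy$edge.length
  vals <- numeric(length(ev$pairTask))
  for (e in seq_len(nE)) {
    ccp <- ev$candCount[ev$edgeParent[e]]
    ccc <- ev$candCount[ev$edgeChild[e]]
    for (xi in seq_len(ccp)) for (yi in seq_len(ccc)) {
      idx <- ev$pairOff[e] + (xi - 1L) * ccc + yi
      tid <- ev$pairTask[idx]
      if (tid == 0L) { vals[idx] <- -Inf; next }
      sp <- ev$taskList[[tid]]
      Q <- branchGenerator(sp, params, hazardScale)
      v <- if (sp$nstate == 1L) {
        if (sp$accept[1L]) Q[1L, 1L] * rt[e] else -Inf
      } else {
        P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * rt[e], sparse = FALSE)))
        p <- sum(P[1L, sp$accept])
        if (p <= 0) -Inf else log(p)
      }
      vals[idx] <- v + sp$detconst
    }
  }
  nn <- ev$nTips + phy$Nnode
  logL <- vector("list", nn)
  for (i in seq_len(ev$nTips)) logL[[i]] <- 0
  for (k in seq_along(ev$postNodes)) {
    u <- ev$postNodes[k]
    acc <- rep(0, ev$candCount[u])
    for (e in ev$childEdges[k, ]) {
      v <- ev$edgeChild[e]
      ccc <- ev$candCount[v]
      for (xi in seq_len(ev$candCount[u])) {
        terms <- vapply(seq_len(ccc), function(yi)
          vals[ev$pairOff[e] + (xi - 1L) * ccc + yi] + logL[[v]][yi], 0)
        mx <- max(terms)
        acc[xi] <- acc[xi] +
          if (is.finite(mx)) mx + log(sum(exp(terms - mx))) else -Inf
      }
    }
    logL[[u]] <- acc
  }
  ll <- logL[[ev$root]][1L]
  if (!is.null(ev$originTime)) {
    h0 <- totalHazard(rep(TRUE, numTargets(ev$design)), ev$design, params) *
      hazardScale
    ll <- ll - h0 * params@clockRate * ev$originTime
  }
  ll
}

#' Brute-force likelihood over the complete allele space
#'
#' Independent reference computation for tiny instances: enumerates every
#' allele reachable under the design's full admissible indel space, builds
#' the dense allele-level generator (events deactivate their tract range
#' and physically remove masked indels), exponentiates it per branch and
#' sums over all internal-node state assignments by pruning over the full
#' space. Exact under the configured laws; cost grows combinatorially, so
#' designs must be tiny (M <= 3, narrow targets, `maxInsertLen <= 1`).
#'
#' @inheritParams treeLogLikelihood
#' @param maxAlleles Hard cap on the allele-space size.
#' @return Log-likelihood.
#' @export
bruteForceLogLikelihood <- function(phy, alignment, params,
                                    branchRates = NULL, originTime = NULL,
                                    maxAlleles = 4000L) {
  validateLineageTree(phy)
  design <- alignment@design
  m <- numTargets(design)
  if (m > 3L) stop("brute-force oracle restricted to designs with M <= 3")
  universe <- enumerateIndelUniverse(design, params)
  tractsU <- lapply(universe, tractOfIndel, design = design)
  detailU <- vapply(seq_along(universe), function(i)
    exp(detailLogProbability(universe[[i]], tractsU[[i]], design, params)), 0)

  ## enumerate reachable alleles (sets of indel indices) by BFS
  keyOf <- function(idx) paste0("k", paste(sort(idx), collapse = ","))
  states <- list(integer(0))
  index <- new.env(parent = emptyenv())
  assign(keyOf(integer(0)), 1L, envir = index)
  trans <- list()  # per state: matrix (to, rate)
  i <- 1L
  while (i <= length(states)) {
    idx <- states[[i]]
    al <- allele(universe[idx])
    inactive <- rep(FALSE, m)
    for (k in idx) {
      tt <- tractsU[[k]]
      inactive[tt[1L]:tt[4L]] <- TRUE
    }
    rows <- NULL
    for (k in seq_along(universe)) {
      tt <- tractsU[[k]]
      req <- unique(c(tt[1L], tt[2L], tt[3L], tt[4L]))
      if (any(inactive[req])) next
      newInd <- universe[[k]]
      ## masked: existing indels strictly inside the new deletion
      keep <- idx[!vapply(idx, function(q)
        strictlyInside(universe[[q]], newInd), TRUE)]
      ## physical consistency: the new event must not clash with surviving
      ## indels (impossible under the trim caps, but guard anyway)
      ok <- TRUE
      fpN <- indelFootprint(newInd)
      for (q in keep) {
        fpQ <- indelFootprint(universe[[q]])
        if (fpN[1L] < fpQ[2L] && fpQ[1L] < fpN[2L]) { ok <- FALSE; break }
      }
      if (!ok) next
      idx2 <- sort(c(keep, k))
      k2 <- keyOf(idx2)
      to <- get0(k2, envir = index)
      if (is.null(to)) {
        states[[length(states) + 1L]] <- idx2
        to <- length(states)
        assign(k2, to, envir = index)
        if (to > maxAlleles)
          stop("brute-force allele space exceeds ", maxAlleles, " states")
      }
      rate <- tractHazard(tractsU[[k]], params) * detailU[k]
      rows <- rbind(rows, c(to, rate))
    }
    trans[[i]] <- if (is.null(rows)) matrix(0, 0L, 2L) else rows
    i <- i + 1L
  }
  nS <- length(states)
  Q <- matrix(0, nS, nS)
  for (s in seq_len(nS)) {
    rows <- trans[[s]]
    if (nrow(rows)) for (r_ in seq_len(nrow(rows)))
      Q[s, rows[r_, 1L]] <- Q[s, rows[r_, 1L]] + rows[r_, 2L]
    Q[s, s] <- -sum(Q[s, -s])
  }

  n <- length(phy$tip.label)
  pos <- match(phy$tip.label, alignment@cellIds)
  if (anyNA(pos)) stop("tree tip labels do not match alignment cell ids")
  leafState <- vapply(seq_len(n), function(i) {
    al <- alignment@alleles[[pos[i]]]
    ks <- vapply(al, indelKey, "")
    uks <- vapply(universe, indelKey, "")
    idx <- match(ks, uks)
    if (anyNA(idx)) return(NA_integer_)
    get0(keyOf(sort(idx)), envir = index, ifnotfound = NA_integer_)
  }, 1L)
  if (anyNA(leafState))
    stop("a leaf allele is outside the enumerable allele space")

  if (is.null(branchRates)) branchRates <- rep(1, nrow(phy$edge))
  rt <- params@clockRate * branchRates * phy$edge.length
  Pexp <- lapply(seq_len(nrow(phy$edge)), function(e)
    as.matrix(Matrix::expm(Matrix::Matrix(Q * rt[e], sparse = FALSE))))

  nn <- n + phy$Nnode
  Lpart <- vector("list", nn)
  for (i in seq_len(n)) {
    v <- numeric(nS); v[leafState[i]] <- 1
    Lpart[[i]] <- list(v = v, s = 0)
  }
  edgeOfChild <- integer(nn)
  edgeOfChild[phy$edge[, 2L]] <- seq_len(nrow(phy$edge))
  for (u in postorderNodes(phy)) {
    kids <- phy$edge[phy$edge[, 1L] == u, 2L]
    v <- rep(1, nS); sc <- 0
    for (c_ in kids) {
      e <- edgeOfChild[c_]
      msg <- Pexp[[e]] %*% Lpart[[c_]]$v
      v <- v * as.numeric(msg)
      sc <- sc + Lpart[[c_]]$s
    }
    mx <- max(v)
    if (mx > 0) { v <- v / mx; sc <- sc + log(mx) }
    Lpart[[u]] <- list(v = v, s = sc)
  }
  rootIdx <- 1L  # unedited
  lp <- Lpart[[n + 1L]]
  ll <- if (lp$v[rootIdx] > 0) log(lp$v[rootIdx]) + lp$s else -Inf
  if (!is.null(originTime)) {
    h0 <- totalHazard(rep(TRUE, m), design, params)
    ll <- ll - h0 * params@clockRate * originTime
  }
  ll
}
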