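## General sampler path: editing parameters plus node times, topology and
## phylodynamic parameters on a single alignment. Likelihood evaluations
## go through the compiled evaluator (full recompute per proposal; the
## problem sizes this path is meant for make that cheap); topology
## proposals compile a fresh evaluator for the proposed tree.

edgeLengthsFromAges <- function(phy, ages) {
  ages[phy$edge[, 1L]] - ages[phy$edge[, 2L]]
}

## ---- topology proposals (operate on the edge matrix + ages) ----

proposeNarrowExchange <- function(phy, ages) {
  n <- length(phy$tip.label)
  root <- n + 1L
  ## internal non-root nodes
  vs <- setdiff(unique(phy$edge[, 1L]), root)
  if (!length(vs)) return(NULL)
  v <- if (length(vs) == 1L) vs else sample(vs, 1L)
  u <- phy$edge[phy$edge[, 2L] == v, 1L]
  sibs <- setdiff(phy$edge[phy$edge[, 1L] == u, 2L], v)
  s <- sibs[1L]
  kids <- phy$edge[phy$edge[, 1L] == v, 2L]
  c_ <- kids[sample.int(2L, 1L)]
  ## after the swap v must stay older than s
  if (ages[v] <= ages[s]) return(NULL)
  phy2 <- phy
  phy2$edge[phy$edge[, 1L] == u & phy$edge[, 2L] == s, 2L] <- c_
  phy2$edge[phy$edge[, 1L] == v & phy$edge[, 2L] == c_, 2L] <- s
  phy2$edge.length <- edgeLengthsFromAges(phy2, ages)
  list(phy = phy2, logHR = 0)
}

proposeWilsonBalding <- function(phy, ages) {
  n <- length(phy$tip.label)
  root <- n + 1L
  nn <- n + phy$Nnode
  ## pick a node i whose parent p is not the root
  parentOf <- integer(nn)
  parentOf[phy$edge[, 2L]] <- phy$edge[, 1L]
  cand <- which(parentOf != 0L & parentOf != root)
  i <- cand[sample.int(length(cand), 1L)]
  p <- parentOf[i]
  g <- parentOf[p]
  j <- setdiff(phy$edge[phy$edge[, 1L] == p, 2L], i)
  ## subtree of i (cannot regraft inside it)
  inSub <- logical(nn); inSub[i] <- TRUE
  po <- phy$edge[postorderEdges(phy), , drop = FALSE]
  for (e in rev(seq_len(nrow(po)))) # preorder pass
    if (inSub[po[e, 1L]]) inSub[po[e, 2L]] <- TRUE
  ## candidate target edges (a -> b) in the tree with p removed
  edges <- phy$edge
  keep <- !(edges[, 2L] %in% c(i, j, p)) & edges[, 1L] != p
  edges <- edges[keep, , drop = FALSE]
  edges <- rbind(edges, c(g, j))  # bypass edge after pruning p
  ok <- !inSub[edges[, 2L]] & !inSub[edges[, 1L]]
  edges <- edges[ok, , drop = FALSE]
  if (!nrow(edges)) return(NULL)
  pick <- sample.int(nrow(edges), 1L)
  a <- edges[pick, 1L]; b <- edges[pick, 2L]
  lo <- max(ages[b], ages[i])
  hiNew <- ages[a]
  Lnew <- hiNew - lo
  if (Lnew <= 0) return(NULL)
  tNew <- lo + stats::runif(1L) * Lnew
  Lold <- ages[g] - max(ages[j], ages[i])
  if (Lold <= 0) return(NULL)
  ages2 <- ages
  ages2[p] <- tNew
  phy2 <- phy
  if (a == g && b == j) {  # re-attachment onto the original (bypass) edge
    phy2$edge.length <- edgeLengthsFromAges(phy2, ages2)
    if (any(phy2$edge.length < 0)) return(NULL)
    return(list(phy = phy2, ages = ages2, logHR = log(Lnew) - log(Lold)))
  }
  E <- phy2$edge
  E[E[, 1L] == g & E[, 2L] == p, 2L] <- j    # g -> j
  E[E[, 1L] == p & E[, 2L] == j, 2L] <- b    # p -> b
  ## a -> b becomes a -> p
  E[E[, 1L] == a & E[, 2L] == b & !(E[, 1L] == p), ] <-
    matrix(c(a, p), nrow = sum(E[, 1L] == a & E[, 2L] == b & !(E[, 1L] == p)),
           ncol = 2L, byrow = TRUE)
  phy2$edge <- E
  phy2$edge.length <- edgeLengthsFromAges(phy2, ages2)
  if (any(phy2$edge.length < 0)) return(NULL)
  list(phy = phy2, ages = ages2, logHR = log(Lnew) - log(Lold))
}

## ---- general driver ----

runMcmcGeneral <- function(cfg, alns, trees) {
  if (length(alns) != 1L)
    stop("pooled mode supports editing parameters on fixed trees only")
  aln <- alns[[1L]]
  phy <- trees[[1L]]
  validateLineageTree(phy)
  params <- cfg$params
  m <- length(params@cutRates)
  pr <- cfg$priors
  est <- cfg$estimate
  n <- length(phy$tip.label)
  ages <- nodeAges(phy)
  tp <- cfg$treePrior
  theta <- list(
    birthRate = if (!is.null(tp$birthRate)) tp$birthRate else NULL,
    growthRate = if (!is.null(tp$growthRate)) tp$growthRate else NULL,
    originTime = if (!is.null(tp$originTime)) tp$originTime
                 else if (!is.null(tp) && tp$model == "birthDeath")
                   1.2 * max(ages) else NULL)

  compileEv <- function(ph) compileTreeLikelihood(
    ph, aln, params, stateUniverse = cfg$stateUniverse %||% "observed",
    maxStates = cfg$maxStates %||% 256L)
  ev <- compileEv(phy)

  loglik <- function(evx, par) {
    if (cfg$likelihoodOff) return(0)
    evalTreeLikelihood(evx, par, hazardScale = cfg$hazardScale)
  }
  logprior <- function(par, th, ph) {
    lp <- dlnormOr(par@clockRate, pr$clockRate) +
      dlnormOr(par@doubleCutWeight, pr$doubleCutWeight) +
      dlnormOr(par@longTrimLeft, pr$longTrimLeft) +
      dlnormOr(par@longTrimRight, pr$longTrimRight)
    alpha <- rep(pr$cutRatesAlpha, length.out = m)
    if (any(par@cutRates <= 0)) return(-Inf)
    lp <- lp + sum((alpha - 1) * log(par@cutRates / m)) +
      lgamma(sum(alpha)) - sum(lgamma(alpha))
    if (!is.null(tp)) {
      if (tp$model == "birthDeath") {
        if ("birthRate" %in% est) lp <- lp + dlnormOr(th$birthRate, pr$birthRate)
        if ("originTime" %in% est) lp <- lp + dlnormOr(th$originTime, pr$originTime)
        bd <- birthDeathLogDensity(ph, th$birthRate, tp$deathRate %||% 0,
                                   tp$rho %||% 1, originTime = th$originTime,
                                   conditioning = tp$conditioning %||% "origin")
        lp <- lp + as.numeric(bd)
      } else if (tp$model == "coalescentExp") {
        if ("growthRate" %in% est) lp <- lp + dlnormOr(th$growthRate, pr$growthRate)
        g <- th$growthRate
        lp <- lp + coalescentExpLogDensity(ph, g, popSize = exp(g * max(nodeAges(ph))))
      }
    }
    lp
  }

  moves <- c("clockRate", "doubleCutWeight", "longTrimLeft", "longTrimRight",
             "cutRates", "nodeSlide", "rootScale", "narrow", "wilsonBalding",
             "birthRate", "growthRate", "originTime")
  w <- c(as.numeric("clockRate" %in% est), as.numeric("doubleCutWeight" %in% est),
         as.numeric("longTrimLeft" %in% est), as.numeric("longTrimRight" %in% est),
         2 * as.numeric("cutRates" %in% est),
         (n - 2) * as.numeric("nodeTimes" %in% est),
         as.numeric("nodeTimes" %in% est),
         (n / 2) * as.numeric("topology" %in% est),
         (n / 2) * as.numeric("topology" %in% est),
         as.numeric("birthRate" %in% est), as.numeric("growthRate" %in% est),
         as.numeric("originTime" %in% est))
  if (sum(w) <= 0) stop("no moves selected: nothing to estimate")
  lambda <- 0.8

  lp <- logprior(params, theta, phy)
  ll <- loglik(ev, params)
  if (!is.finite(lp)) stop("non-finite initial prior")
  if (!is.finite(ll)) stop("non-finite initial likelihood")

  nIter <- cfg$chainLength; thin <- cfg$thin
  rows <- list(); treeLog <- list()
  paramCols <- function(par, th, ph)
    c(clockRate = par@clockRate, doubleCutWeight = par@doubleCutWeight,
      longTrimLeft = par@longTrimLeft, longTrimRight = par@longTrimRight,
      stats::setNames(par@cutRates, paste0("cutRate", seq_len(m))),
      if (!is.null(th$birthRate)) c(birthRate = th$birthRate),
      if (!is.null(th$growthRate)) c(growthRate = th$growthRate),
      if (!is.null(th$originTime)) c(originTime = th$originTime),
      treeHeight = max(nodeAges(ph)))
  rec <- function(it) {
    rows[[length(rows) + 1L]] <<- c(iteration = it, posterior = lp + ll,
                                    likelihood = ll, prior = lp,
                                    paramCols(params, theta, phy))
    treeLog[[length(treeLog) + 1L]] <<- phy
  }
  rec(0L)

  setPar <- function(par, name, value) {
    slot(par, name) <- value
    par
  }

  for (it in seq_len(nIter)) {
    mv <- sample.int(length(moves), 1L, prob = w)
    mvName <- moves[mv]
    accepted <- FALSE
    if (mvName %in% editingScalars) {
      prop <- proposeScale(slot(params, mvName), lambda)
      par2 <- setPar(params, mvName, prop$value)
      lp2 <- logprior(par2, theta, phy)
      if (is.finite(lp2)) {
        ll2 <- loglik(ev, par2)
        if (accept(lp2 + ll2 - lp - ll + prop$logHR)) {
          params <- par2; lp <- lp2; ll <- ll2; accepted <- TRUE
        }
      }
    } else if (mvName == "cutRates") {
      lam <- params@cutRates
      ij <- sample.int(m, 2L)
      d <- 0.3 * (stats::runif(1L) - 0.5) * 2
      lam[ij[1L]] <- lam[ij[1L]] + d
      lam[ij[2L]] <- lam[ij[2L]] - d
      if (all(lam > 0)) {
        par2 <- setPar(params, "cutRates", lam)
        lp2 <- logprior(par2, theta, phy)
        ll2 <- loglik(ev, par2)
        if (accept(lp2 + ll2 - lp - ll)) {
          params <- par2; lp <- lp2; ll <- ll2; accepted <- TRUE
        }
      }
    } else if (mvName %in% c("birthRate", "growthRate", "originTime")) {
      prop <- proposeScale(theta[[mvName]], lambda)
      th2 <- theta; th2[[mvName]] <- prop$value
      lp2 <- logprior(params, th2, phy)
      if (is.finite(lp2) && accept(lp2 - lp + prop$logHR)) {
        theta <- th2; lp <- lp2; accepted <- TRUE
      }
    } else if (mvName == "nodeSlide") {
      internal <- setdiff((n + 2L):(n + phy$Nnode), integer(0))
      if (length(internal)) {
        v <- if (length(internal) == 1L) internal else sample(internal, 1L)
        parentOf <- phy$edge[match(v, phy$edge[, 2L]), 1L]
        kids <- phy$edge[phy$edge[, 1L] == v, 2L]
        hi <- ages[parentOf]; lo <- max(ages[kids])
        if (hi > lo) {
          ages2 <- ages
          ages2[v] <- lo + stats::runif(1L) * (hi - lo)
          phy2 <- phy
          phy2$edge.length <- edgeLengthsFromAges(phy2, ages2)
          lp2 <- logprior(params, theta, phy2)
          ll2 <- if (cfg$likelihoodOff) 0 else {
            evalTreeLikelihood(ev, params, edgeLengths = phy2$edge.length,
                               hazardScale = cfg$hazardScale)
          }
          if (is.finite(lp2) && accept(lp2 + ll2 - lp - ll)) {
            ages <- ages2; phy <- phy2; lp <- lp2; ll <- ll2; accepted <- TRUE
          }
        }
      }
    } else if (mvName == "rootScale") {
      root <- n + 1L
      kids <- phy$edge[phy$edge[, 1L] == root, 2L]
      prop <- proposeScale(ages[root], 0.3)
      if (prop$value > max(ages[kids])) {
        ages2 <- ages; ages2[root] <- prop$value
        phy2 <- phy
        phy2$edge.length <- edgeLengthsFromAges(phy2, ages2)
        lp2 <- logprior(params, theta, phy2)
        ll2 <- if (cfg$likelihoodOff) 0 else {
          evalTreeLikelihood(ev, params, edgeLengths = phy2$edge.length,
                             hazardScale = cfg$hazardScale)
        }
        if (is.finite(lp2) && accept(lp2 + ll2 - lp - ll + prop$logHR)) {
          ages <- ages2; phy <- phy2; lp <- lp2; ll <- ll2; accepted <- TRUE
        }
      }
    } else if (mvName %in% c("narrow", "wilsonBalding")) {
      res <- if (mvName == "narrow") proposeNarrowExchange(phy, ages)
             else proposeWilsonBalding(phy, ages)
      if (!is.null(res)) {
        ages2 <- res$ages %||% ages
        ev2 <- compileEv(res$phy)
        lp2 <- logprior(params, theta, res$phy)
        ll2 <- if (cfg$likelihoodOff) 0 else loglik(ev2, params)
        if (is.finite(lp2) && is.finite(ll2) &&
            accept(lp2 + ll2 - lp - ll + res$logHR)) {
          phy <- res$phy; ages <- ages2; ev <- ev2
          lp <- lp2; ll <- ll2; accepted <- TRUE
        }
      }
    }
    if (!accepted) invisible(NULL)
    if (it %% thin == 0L) rec(it)
  }
  tr <- as.data.frame(do.call(rbind, rows))
  new("PosteriorTrace", trace = tr, trees = treeLog, config = cfg)
}

accept <- function(logRatio) {
  is.finite(logRatio) && (logRatio >= 0 || log(stats::runif(1L)) < logRatio)
}
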