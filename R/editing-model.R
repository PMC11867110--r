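#' Construct editing-model parameters
#'
#' Builds an [EditingParams-class]. The per-target cut rates are
#' constrained to mean 1 so that the overall time scale is carried by the
#' clock rate alone (with a free clock the scale of the cut-rate vector is
#' not identifiable); `normalizeCutRates = TRUE` rescales any positive
#' vector accordingly.
#'
#' Trim and insertion lengths follow truncated Poisson laws on their
#' admissible ranges (see [trimBounds()]); the default means are sized for
#' 23 bp target sites.
#'
#' @param clockRate Clock rate r, indels per target site per time unit.
#' @param cutRates Positive per-target relative cut rates (length M).
#' @param doubleCutWeight Double-cut weight omega (> 0).
#' @param longTrimLeft,longTrimRight Long-trim odds factors gamma0, gamma1.
#' @param trimMeans Named numeric: `shortLeft`, `longLeft`, `shortRight`,
#'   `longRight` truncated-Poisson means (bases).
#' @param insertMean Truncated-Poisson mean of insertion length.
#' @param maxInsertLen Enumeration bound on insertion length.
#' @param normalizeCutRates Rescale `cutRates` to mean 1.
#' @return An [EditingParams-class].
#' @export
editingParams <- function(clockRate = 0.02,
                          cutRates = rep(1, 4),
                          doubleCutWeight = 0.3,
                          longTrimLeft = 0.1,
                          longTrimRight = 0.1,
                          trimMeans = c(shortLeft = 2, longLeft = 20,
                                        shortRight = 2, longRight = 10),
                          insertMean = 1.5,
                          maxInsertLen = 10L,
                          normalizeCutRates = TRUE) {
  cutRates <- as.numeric(cutRates)
  if (normalizeCutRates && all(cutRates > 0))
    cutRates <- cutRates / mean(cutRates)
  new("EditingParams",
      clockRate = as.numeric(clockRate), cutRates = cutRates,
      doubleCutWeight = as.numeric(doubleCutWeight),
      longTrimLeft = as.numeric(longTrimLeft),
      longTrimRight = as.numeric(longTrimRight),
      trimMeans = trimMeans[c("shortLeft", "longLeft", "shortRight", "longRight")],
      insertMean = as.numeric(insertMean),
      maxInsertLen = as.integer(maxInsertLen))
}

#' Read / write editing parameters as JSON
#'
#' Serialized with keys `clock_rate`, `cut_rates`, `double_cut_weight`,
#' `long_trim_left`, `long_trim_right`, `trim_means` (named object),
#' `insert_mean`, `max_insert_len`.
#'
#' @param path File path.
#' @return `readEditingParams` returns an [EditingParams-class].
#' @export
readEditingParams <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  tm <- unlist(x$trim_means)
  editingParams(clockRate = x$clock_rate, cutRates = x$cut_rates,
                doubleCutWeight = x$double_cut_weight,
                longTrimLeft = x$long_trim_left,
                longTrimRight = x$long_trim_right,
                trimMeans = c(shortLeft = unname(tm[["shortLeft"]]),
                              longLeft = unname(tm[["longLeft"]]),
                              shortRight = unname(tm[["shortRight"]]),
                              longRight = unname(tm[["longRight"]])),
                insertMean = x$insert_mean,
                maxInsertLen = x$max_insert_len,
                normalizeCutRates = FALSE)
}

#' @rdname readEditingParams
#' @param params An [EditingParams-class].
#' @export
writeEditingParams <- function(params, path) {
  obj <- list(
    clock_rate = params@clockRate,
    cut_rates = params@cutRates,
    double_cut_weight = params@doubleCutWeight,
    long_trim_left = params@longTrimLeft,
    long_trim_right = params@longTrimRight,
    trim_means = list(shortLeft = unname(params@trimMeans[["shortLeft"]]),
                      longLeft = unname(params@trimMeans[["longLeft"]]),
                      shortRight = unname(params@trimMeans[["shortRight"]]),
                      longRight = unname(params@trimMeans[["longRight"]])),
    insert_mean = params@insertMean,
    max_insert_len = params@maxInsertLen
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a target tract
#'
#' A target tract `(j0, j, j', j1)` is the lumped class of editing events
#' that cut targets `j..j'` (`j == j'` for a single cut) and deactivate
#' targets `j0..j1`; `j0 == j - 1` marks a long left trim reaching into the
#' left neighbour and `j1 == j' + 1` a long right trim.
#'
#' @param j0,j,jp,j1 1-based target indices with
#'   `j0 %in% c(j-1, j)`, `j1 %in% c(jp, jp+1)`, `j <= jp`.
#' @return An integer 4-vector of class `"gestaltTract"`.
#' @export
targetTract <- function(j0, j, jp, j1) {
  tt <- as.integer(c(j0, j, jp, j1))
  if (tt[2L] > tt[3L] || !(tt[1L] %in% c(tt[2L] - 1L, tt[2L])) ||
      !(tt[4L] %in% c(tt[3L], tt[3L] + 1L)) || tt[1L] < 1L)
    stop("invalid target tract (", paste(tt, collapse = ","), ")")
  structure(tt, class = "gestaltTract")
}

#' @export
print.gestaltTract <- function(x, ...) {
  cat(sprintf("tract (%d,%d,%d,%d)%s\n", x[1L], x[2L], x[3L], x[4L],
              if (x[2L] == x[3L]) " [single cut]" else " [double cut]"))
  invisible(x)
}

#' Admissible trim-length bounds of a design
#'
#' For each target j, short trims stay within the target (left:
#' `0..c(j) - start_j`; right: `0..end_j - c(j)`) while long trims reach
#' past the target edge but stop one bond short of the adjacent cut site
#' (left: `..c(j) - c(j-1) - 1`; right: `..c(j+1) - c(j) - 1`). A long
#' class with an empty range (e.g. at the barcode ends) is unavailable.
#'
#' @param design A [BarcodeDesign-class].
#' @return Matrix with one row per target and columns `shortLeftMax`,
#'   `longLeftMin`, `longLeftMax`, `shortRightMax`, `longRightMin`,
#'   `longRightMax` (`NA` where no adjacent target exists).
#' @export
trimBounds <- function(design) {
  tg <- design@targets
  ct <- design@cuts
  m <- nrow(tg)
  slmax <- ct - tg[, 1L]
  srmax <- tg[, 2L] - ct
  llmax <- c(NA_integer_, ct[-1L] - ct[-m] - 1L)
  lrmax <- c(ct[-1L] - ct[-m] - 1L, NA_integer_)
  cbind(shortLeftMax = slmax,
        longLeftMin = slmax + 1L, longLeftMax = llmax,
        shortRightMax = srmax,
        longRightMin = srmax + 1L, longRightMax = lrmax)
}

## Is the long-left (resp. long-right) class geometrically available at
## target j (a neighbour exists and the long range is non-empty)?
longClassAvailable <- function(bounds, j, side) {
  if (side == "left") {
    !is.na(bounds[j, "longLeftMax"]) &&
      bounds[j, "longLeftMax"] >= bounds[j, "longLeftMin"]
  } else {
    !is.na(bounds[j, "longRightMax"]) &&
      bounds[j, "longRightMax"] >= bounds[j, "longRightMin"]
  }
}

#' Enumerate the target tracts available from an editability status
#'
#' Lists every editing-event class that can occur while the given targets
#' are active: single cuts at each active target and double cuts at each
#' active pair, each combined with short/long trim variants. A long-trim
#' variant requires the adjacent target to exist, to be active, and the
#' long trim range to be non-empty. A double cut requires only its two cut
#' targets (and any long-trim neighbours) to be active: intermediate
#' targets may already carry edits, which the spanning deletion masks.
#'
#' @param status Logical vector of length M (`TRUE` = active), e.g. from
#'   [targetStatus()].
#' @param design A [BarcodeDesign-class].
#' @return List of [targetTract()] objects.
#' @export
enumerateTracts <- function(status, design) {
  m <- numTargets(design)
  stopifnot(length(status) == m)
  bounds <- trimBounds(design)
  act <- which(status)
  out <- list()
  for (j in act) for (jp in act[act >= j]) {
    j0s <- j
    if (j > 1L && status[j - 1L] && longClassAvailable(bounds, j, "left"))
      j0s <- c(j - 1L, j)
    j1s <- jp
    if (jp < m && status[jp + 1L] && longClassAvailable(bounds, jp, "right"))
      j1s <- c(jp, jp + 1L)
    for (j0 in j0s) for (j1 in j1s)
      out[[length(out) + 1L]] <- targetTract(j0, j, jp, j1)
  }
  out
}

#' Instantaneous hazard of a target tract
#'
#' Single cuts occur at rate `lambda_j`, double cuts at
#' `omega * (lambda_j + lambda_j')`; the short/long trim-class
#' probabilities `gamma / (1 + gamma)` (long) and `1 / (1 + gamma)`
#' (short) on each side are folded into the hazard so that tract classes
#' are mutually exclusive competing events.
#'
#' @param tract A [targetTract()].
#' @param params An [EditingParams-class].
#' @return Non-negative rate (per unit of `clockRate * time`).
#' @export
tractHazard <- function(tract, params) {
  lam <- params@cutRates
  j0 <- tract[1L]; j <- tract[2L]; jp <- tract[3L]; j1 <- tract[4L]
  base <- if (j == jp) lam[j] else params@doubleCutWeight * (lam[j] + lam[jp])
  g0 <- params@longTrimLeft; g1 <- params@longTrimRight
  pl <- if (j0 < j) g0 / (1 + g0) else 1 / (1 + g0)
  pr <- if (j1 > jp) g1 / (1 + g1) else 1 / (1 + g1)
  base * pl * pr
}

#' Total leaving hazard of an editability status
#'
#' Sum of [tractHazard()] over [enumerateTracts()]; equals the total
#' leaving rate of the corresponding lumped state of the editing chain.
#'
#' @inheritParams enumerateTracts
#' @param params An [EditingParams-class].
#' @export
totalHazard <- function(status, design, params) {
  sum(vapply(enumerateTracts(status, design), tractHazard, 0, params = params))
}

## Truncated Poisson pmf on lo..hi. mean <= 0 degenerates to a point mass
## at lo.
dtpois <- function(x, mean, lo, hi) {
  if (hi < lo) stop("empty truncation range")
  if (mean <= 0) return(as.numeric(x == lo))
  sup <- lo:hi
  p <- stats::dpois(x, mean) / sum(stats::dpois(sup, mean))
  p[x < lo | x > hi] <- 0
  p
}

rtpois <- function(n, mean, lo, hi) {
  sup <- lo:hi
  if (mean <= 0) return(rep(lo, n))
  w <- stats::dpois(sup, mean)
  sup[sample.int(length(sup), n, replace = TRUE, prob = w)]
}

#' Classify an indel as a target tract
#'
#' Deterministically maps an observed indel to its generating event class:
#' the cut targets are the extreme targets whose cut sites lie in the
#' deleted interval (the insertion bond's target for a pure insertion), and
#' the trim is long on a side exactly when the deletion reaches into the
#' adjacent target's interval.
#'
#' @param ind An [indel()].
#' @param design A [BarcodeDesign-class].
#' @return A [targetTract()].
#' @export
tractOfIndel <- function(ind, design) {
  span <- indelTargetSpan(ind, design)
  j <- span[1L]; jp <- span[2L]
  touched <- touchedTargets(ind, design)
  if (length(touched) && (min(touched) < j - 1L || max(touched) > jp + 1L))
    stop("indel reaches beyond the adjacent target; not representable as a tract")
  j0 <- if ((j - 1L) %in% touched) j - 1L else j
  j1 <- if ((jp + 1L) %in% touched) jp + 1L else jp
  targetTract(j0, j, jp, j1)
}

## Trim lengths (left, right) and insert length of an indel relative to
## its tract's cut bonds.
indelDetail <- function(ind, design) {
  span <- indelTargetSpan(ind, design)
  cl <- design@cuts[span[1L]]
  cr <- design@cuts[span[2L]]
  if (ind$del == 0L) {
    c(left = 0L, right = 0L, ins = nchar(ind$insert))
  } else {
    c(left = cl - ind$start,
      right = ind$start + ind$del - cr,
      ins = nchar(ind$insert))
  }
}

#' Log-probability of an indel's details given its tract
#'
#' Conditional on the event class (the tract), the repair outcome is the
#' left trim length, right trim length and insertion, drawn independently
#' from truncated Poisson laws on the class's admissible range with
#' insertion bases uniform over A/C/G/T. For single cuts the all-zero
#' outcome (no trims, no insertion) is excluded and the law renormalized,
#' since it would leave the barcode unchanged. Summed over all admissible
#' details of a tract the probability is 1.
#'
#' @param ind An [indel()] whose implied tract equals `tract`.
#' @param tract The [targetTract()] the indel is conditioned on.
#' @param design A [BarcodeDesign-class].
#' @param params An [EditingParams-class].
#' @return Log-probability (`-Inf` for inadmissible details).
#' @export
detailLogProbability <- function(ind, tract, design, params) {
  implied <- tractOfIndel(ind, design)
  if (!all(unclass(implied) == unclass(tract)))
    stop("indel's implied tract (", paste(implied, collapse = ","),
         ") does not match the supplied tract (",
         paste(tract, collapse = ","), ")")
  det <- indelDetail(ind, design)
  p <- detailLengthProbability(det[["left"]], det[["right"]], det[["ins"]],
                               tract, design, params)
  if (p <= 0) return(-Inf)
  log(p) + det[["ins"]] * log(0.25)
}

## P(left trim = l0, right trim = l1, insert length = L | tract), insert
## *content* excluded (multiply by (1/4)^L for a specific sequence).
detailLengthProbability <- function(l0, l1, L, tract, design, params) {
  bounds <- trimBounds(design)
  j0 <- tract[1L]; j <- tract[2L]; jp <- tract[3L]; j1 <- tract[4L]
  tm <- params@trimMeans
  rngL <- if (j0 < j) c(bounds[j, "longLeftMin"], bounds[j, "longLeftMax"])
          else c(0L, bounds[j, "shortLeftMax"])
  rngR <- if (j1 > jp) c(bounds[jp, "longRightMin"], bounds[jp, "longRightMax"])
          else c(0L, bounds[jp, "shortRightMax"])
  meanL <- if (j0 < j) tm[["longLeft"]] else tm[["shortLeft"]]
  meanR <- if (j1 > jp) tm[["longRight"]] else tm[["shortRight"]]
  pL <- dtpois(l0, meanL, rngL[1L], rngL[2L])
  pR <- dtpois(l1, meanR, rngR[1L], rngR[2L])
  pI <- dtpois(L, params@insertMean, 0L, params@maxInsertLen)
  p <- pL * pR * pI
  if (j == jp && j0 == j && j1 == jp) {
    p0 <- dtpois(0L, meanL, rngL[1L], rngL[2L]) *
          dtpois(0L, meanR, rngR[1L], rngR[2L]) *
          dtpois(0L, params@insertMean, 0L, params@maxInsertLen)
    if (l0 == 0 && l1 == 0 && L == 0) return(0)
    p <- p / (1 - p0)
  }
  p
}

#' Rate matrix of the lumped editability chain
#'
#' Builds the generator Q of the continuous-time Markov chain over target
#' editability statuses: each tract from a status deactivates its range
#' `j0..j1`, moving to a strictly-less-editable status. The chain is
#' irreversible, so Q is triangular under the returned state order and the
#' fully inactive status is absorbing.
#'
#' @param design A [BarcodeDesign-class] (at most 8 targets; the lattice
#'   has `2^M` states).
#' @param params An [EditingParams-class].
#' @return A list of class `"gestaltRateMatrix"` with elements `Q`
#'   (matrix, rows summing to zero), `states` (character labels, `"1"` =
#'   active) and `stateActive` (list of logical vectors).
#' @export
statusRateMatrix <- function(design, params) {
  m <- numTargets(design)
  if (m > 8L) stop("status lattice too large (M > 8); use the branch state spaces")
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), m))
  states <- lapply(seq_len(nrow(combos)), function(i) as.logical(combos[i, ]))
  ord <- order(vapply(states, function(s) sum(!s), 0L),
               vapply(states, function(s) paste(as.integer(s), collapse = ""), ""))
  states <- states[ord]
  labels <- vapply(states, function(s) paste(as.integer(s), collapse = ""), "")
  n <- length(states)
  idx <- structure(seq_len(n), names = labels)
  Q <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    st <- states[[i]]
    for (tt in enumerateTracts(st, design)) {
      dest <- st
      dest[tt[1L]:tt[4L]] <- FALSE
      jlab <- paste(as.integer(dest), collapse = "")
      Q[i, idx[[jlab]]] <- Q[i, idx[[jlab]]] + tractHazard(tt, params)
    }
    Q[i, i] <- Q[i, i] - sum(Q[i, -i])
  }
  structure(list(Q = Q, states = labels, stateActive = states),
            class = "gestaltRateMatrix")
}

#' @export
print.gestaltRateMatrix <- function(x, ...) {
  cat("editability-chain rate matrix:", length(x$states), "states\n")
  invisible(x)
}

#' Clock-scaled transition probability matrix
#'
#' Computes `P = expm(Q * r * t)`: the probability of moving between lumped
#' editing states over a branch of calendar length `t` under clock rate
#' `r`. Rows sum to one; entries from more-edited to less-edited states
#' are exactly zero (editing is irreversible).
#'
#' @param rateMatrix A `"gestaltRateMatrix"` (or plain generator matrix
#'   with zero row sums).
#' @param r Clock rate (> 0).
#' @param t Branch length in time units (>= 0).
#' @return Row-stochastic matrix.
#' @export
transitionProbabilityMatrix <- function(rateMatrix, r, t) {
  Q <- if (inherits(rateMatrix, "gestaltRateMatrix")) rateMatrix$Q else rateMatrix
  stopifnot(t >= 0, r > 0)
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * r * t, sparse = FALSE)))
  dimnames(P) <- dimnames(Q)
  P
}
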