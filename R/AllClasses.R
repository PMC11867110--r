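#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib gestaltphylo, .registration = TRUE
NULL

#' BarcodeDesign: an unedited GESTALT barcode
#'
#' Describes the unedited recording construct: its DNA sequence, the M
#' CRISPR/Cas9 target-site intervals laid along it, and the Cas9 cut
#' positions. Coordinates are 0-based; target intervals are half-open
#' `[start, end)` over barcode bases and cut positions are inter-base bond
#' indices (the bond `c` sits between bases `c - 1` and `c`).
#'
#' @slot sequence Character scalar, the unedited barcode over A/C/G/T.
#' @slot targets Integer matrix with M rows and columns `start`, `end`:
#'   non-overlapping, strictly increasing target intervals.
#' @slot cuts Integer vector of M cut-bond positions, one inside each
#'   target (`start <= cut < end`), strictly increasing.
#'
#' @seealso [barcodeDesign()], [readBarcodeDesign()]
#' @export
setClass("BarcodeDesign",
  representation(
    sequence = "character",
    targets  = "matrix",
    cuts     = "integer"
  )
)

setValidity("BarcodeDesign", function(object) {
  seq <- object@sequence
  tg  <- object@targets
  ct  <- object@cuts
  if (length(seq) != 1L || is.na(seq)) return("sequence must be a single string")
  if (nchar(seq) < 1L) return("sequence must be non-empty")
  if (grepl("[^ACGT]", seq)) return("sequence must be over A/C/G/T")
  if (!is.numeric(tg) || ncol(tg) != 2L) return("targets must be an M x 2 matrix")
  m <- nrow(tg)
  if (m < 1L) return("at least one target is required")
  if (length(ct) != m) return("one cut position per target is required")
  if (any(tg[, 1L] < 0L) || any(tg[, 2L] > nchar(seq)))
    return("target intervals must lie within the barcode")
  if (any(tg[, 2L] <= tg[, 1L])) return("target intervals must be non-empty")
  if (m > 1L) {
    if (any(tg[-1L, 1L] < tg[-m, 2L]))
      return("targets must be non-overlapping and strictly increasing")
    if (any(diff(ct) <= 0L)) return("cut positions must be strictly increasing")
  }
  if (any(ct < tg[, 1L]) || any(ct >= tg[, 2L]))
    return("each cut position must satisfy start <= cut < end of its target")
  TRUE
})

#' EditingParams: parameters of the barcode editing process
#'
#' The full parameterization of the target-tract editing chain: a molecular
#' clock rate converting branch lengths to expected edits, per-target
#' relative cut rates, the double-cut weight, long-trim class factors, and
#' the trim/insert length-law means.
#'
#' @slot clockRate Clock rate r: indels per target site per time unit.
#' @slot cutRates Numeric vector of per-target relative cut rates
#'   (lambda), constrained to mean 1 so the time scale lives in `clockRate`.
#' @slot doubleCutWeight Weight omega of double-cut (inter-target) events
#'   relative to single-cut events.
#' @slot longTrimLeft,longTrimRight Factors gamma0, gamma1: odds of a long
#'   versus short deletion left/right of a cut.
#' @slot trimMeans Named numeric vector with entries `shortLeft`,
#'   `longLeft`, `shortRight`, `longRight`: means of the truncated-Poisson
#'   trim-length laws, in bases.
#' @slot insertMean Mean of the truncated-Poisson insertion-length law.
#' @slot maxInsertLen Upper enumeration bound on insertion length.
#'
#' @seealso [editingParams()]
#' @export
setClass("EditingParams",
  representation(
    clockRate       = "numeric",
    cutRates        = "numeric",
    doubleCutWeight = "numeric",
    longTrimLeft    = "numeric",
    longTrimRight   = "numeric",
    trimMeans       = "numeric",
    insertMean      = "numeric",
    maxInsertLen    = "integer"
  )
)

setValidity("EditingParams", function(object) {
  if (length(object@clockRate) != 1L || object@clockRate < 0)
    return("clockRate must be a single non-negative number")
  lam <- object@cutRates
  if (length(lam) < 1L || any(lam <= 0)) return("cutRates must be positive")
  if (abs(mean(lam) - 1) > 1e-8)
    return("cutRates must have mean 1 (the scale belongs to clockRate)")
  for (nm in c("doubleCutWeight", "longTrimLeft", "longTrimRight")) {
    v <- slot(object, nm)
    if (length(v) != 1L || v < 0) return(paste(nm, "must be a single number >= 0"))
  }
  if (object@doubleCutWeight <= 0) return("doubleCutWeight must be > 0")
  tm <- object@trimMeans
  need <- c("shortLeft", "longLeft", "shortRight", "longRight")
  if (!all(need %in% names(tm))) return("trimMeans must name shortLeft/longLeft/shortRight/longRight")
  if (any(tm < 0)) return("trim means must be >= 0")
  if (object@insertMean < 0) return("insertMean must be >= 0")
  if (object@maxInsertLen < 0L) return("maxInsertLen must be >= 0")
  TRUE
})

#' BarcodeAlignment: a set of cells with observed barcode alleles
#'
#' Container pairing a [BarcodeDesign-class] with one observed allele (sorted
#' list of indels) per sequenced cell.
#'
#' @slot design A [BarcodeDesign-class].
#' @slot cellIds Character vector of unique cell identifiers.
#' @slot alleles List of alleles (one per cell), each a list of indels as
#'   produced by [indel()] and validated against the design.
#'
#' @seealso [barcodeAlignment()], [parseAlleleTable()]
#' @export
setClass("BarcodeAlignment",
  representation(
    design  = "BarcodeDesign",
    cellIds = "character",
    alleles = "list"
  )
)

setValidity("BarcodeAlignment", function(object) {
  if (length(object@cellIds) != length(object@alleles))
    return("one allele per cell id is required")
  if (anyDuplicated(object@cellIds)) return("cell ids must be unique")
  for (i in seq_along(object@alleles)) {
    msg <- tryCatch({
      validateAllele(object@alleles[[i]], object@design)
      TRUE
    }, error = function(e) paste0("cell '", object@cellIds[i], "': ", conditionMessage(e)))
    if (!isTRUE(msg)) return(msg)
  }
  TRUE
})

#' PosteriorTrace: logged output of an MCMC run
#'
#' @slot trace Data frame of sampled iterations: `iteration`, `posterior`,
#'   `likelihood`, `prior`, then one column per scalar parameter.
#' @slot trees List of sampled trees (`ape::phylo`), possibly empty, aligned
#'   with the rows of `trace`.
#' @slot config The run configuration list the sampler was called with.
#'
#' @seealso [runMcmc()]
#' @export
setClass("PosteriorTrace",
  representation(
    trace  = "data.frame",
    trees  = "list",
    config = "list"
  )
)

setValidity("PosteriorTrace", function(object) {
  tr <- object@trace
  need <- c("iteration", "posterior", "likelihood", "prior")
  if (!all(need %in% colnames(tr)))
    return("trace must have iteration/posterior/likelihood/prior columns")
  if (nrow(tr) > 1L && any(diff(tr$iteration) <= 0))
    return("iterations must be strictly increasing")
  if (length(object@trees) > 0L && length(object@trees) != nrow(tr))
    return("tree log length must match the trace")
  TRUE
})

#' CalibrationReport: result of a simulation-based calibration study
#'
#' @slot coverage Data frame with columns `parameter`, `level`, `coverage`,
#'   `ci_lower`, `ci_upper`, `n`: empirical HPD coverage per credibility
#'   level with exact binomial confidence bounds.
#' @slot replicates Data frame of per-replicate truths, posterior summaries
#'   and ESS convergence flags.
#' @slot config Configuration list of the study.
#'
#' @seealso [runCalibration()]
#' @export
setClass("CalibrationReport",
  representation(
    coverage   = "data.frame",
    replicates = "data.frame",
    config     = "list"
  )
)

setValidity("CalibrationReport", function(object) {
  cv <- object@coverage
  if (!all(c("parameter", "level", "coverage") %in% colnames(cv)))
    return("coverage table must have parameter/level/coverage columns")
  if (nrow(cv) && (any(cv$coverage < 0) || any(cv$coverage > 1)))
    return("coverage must lie in [0, 1]")
  TRUE
})
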