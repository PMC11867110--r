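#' @rdname BarcodeDesign-class
#' @param x,object A `BarcodeDesign`.
#' @export
setGeneric("numTargets", function(x) standardGeneric("numTargets"))

#' @rdname BarcodeDesign-class
#' @export
setGeneric("barcodeSequence", function(x) standardGeneric("barcodeSequence"))

#' @rdname BarcodeDesign-class
#' @export
setGeneric("targetBounds", function(x) standardGeneric("targetBounds"))

#' @rdname BarcodeDesign-class
#' @export
setGeneric("cutSites", function(x) standardGeneric("cutSites"))

#' @rdname BarcodeAlignment-class
#' @param x,object A `BarcodeAlignment`.
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname BarcodeAlignment-class
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @rdname BarcodeAlignment-class
#' @export
setGeneric("designOf", function(x) standardGeneric("designOf"))

#' @rdname PosteriorTrace-class
#' @param x,object A `PosteriorTrace`.
#' @export
setGeneric("traceTable", function(x) standardGeneric("traceTable"))

#' @rdname PosteriorTrace-class
#' @export
setGeneric("traceTrees", function(x) standardGeneric("traceTrees"))

#' @rdname CalibrationReport-class
#' @param x,object A `CalibrationReport`.
#' @export
setGeneric("coverageTable", function(x) standardGeneric("coverageTable"))

#' @rdname BarcodeDesign-class
setMethod("numTargets", "BarcodeDesign", function(x) nrow(x@targets))

#' @rdname BarcodeDesign-class
setMethod("barcodeSequence", "BarcodeDesign", function(x) x@sequence)

#' @rdname BarcodeDesign-class
setMethod("targetBounds", "BarcodeDesign", function(x) x@targets)

#' @rdname BarcodeDesign-class
setMethod("cutSites", "BarcodeDesign", function(x) x@cuts)

#' @rdname BarcodeAlignment-class
setMethod("cellIds", "BarcodeAlignment", function(x) x@cellIds)

#' @rdname BarcodeAlignment-class
setMethod("alleles", "BarcodeAlignment", function(x) x@alleles)

#' @rdname BarcodeAlignment-class
setMethod("designOf", "BarcodeAlignment", function(x) x@design)

#' @rdname PosteriorTrace-class
setMethod("traceTable", "PosteriorTrace", function(x) x@trace)

#' @rdname PosteriorTrace-class
setMethod("traceTrees", "PosteriorTrace", function(x) x@trees)

#' @rdname CalibrationReport-class
setMethod("coverageTable", "CalibrationReport", function(x) x@coverage)

#' @rdname BarcodeDesign-class
setMethod("show", "BarcodeDesign", function(object) {
  cat("BarcodeDesign:", nchar(object@sequence), "bp,",
      nrow(object@targets), "target sites\n")
  cat("  cut bonds:", paste(object@cuts, collapse = ", "), "\n")
})

#' @rdname BarcodeAlignment-class
setMethod("show", "BarcodeAlignment", function(object) {
  n <- length(object@cellIds)
  ni <- vapply(object@alleles, length, 1L)
  cat("BarcodeAlignment:", n, "cells on a",
      numTargets(object@design), "target design\n")
  cat("  indels per cell: min", if (n) min(ni) else NA,
      "median", if (n) stats::median(ni) else NA,
      "max", if (n) max(ni) else NA, "\n")
})

#' @rdname EditingParams-class
#' @param object An `EditingParams`.
setMethod("show", "EditingParams", function(object) {
  cat("EditingParams: clock", format(object@clockRate),
      "| omega", format(object@doubleCutWeight),
      "| gamma", format(object@longTrimLeft), "/",
      format(object@longTrimRight), "\n")
  cat("  cut rates:", paste(format(object@cutRates, digits = 3), collapse = " "), "\n")
})

#' @rdname PosteriorTrace-class
setMethod("show", "PosteriorTrace", function(object) {
  cat("PosteriorTrace:", nrow(object@trace), "samples,",
      ncol(object@trace) - 4L, "parameters",
      if (length(object@trees)) "(+ tree log)" else "", "\n")
})

#' @rdname CalibrationReport-class
setMethod("show", "CalibrationReport", function(object) {
  np <- length(unique(object@coverage$parameter))
  cat("CalibrationReport:", np, "parameters,",
      length(unique(object@coverage$level)), "credibility levels,",
      length(unique(object@replicates$replicate)), "replicates\n")
})
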