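#' Construct a barcode design
#'
#' @param sequence Unedited barcode DNA string (A/C/G/T).
#' @param targets M x 2 matrix (or list of length-2 vectors) of 0-based
#'   half-open target intervals `[start, end)`, non-overlapping and in
#'   increasing order.
#' @param cutPositions Cut-site locations, one per target. With
#'   `cutConvention = "absolute"` these are absolute bond indices; with
#'   `"offset3p"` they are offsets from each target's 3' end (the convention
#'   barcode metadata is usually distributed in), i.e. the cut bond is
#'   `end - offset`. Stored absolute.
#' @param cutConvention Either `"absolute"` or `"offset3p"`.
#'
#' @return A [BarcodeDesign-class].
#' @examples
#' d <- barcodeDesign(
#'   sequence = paste(rep("ACGTACGTAC", 2), collapse = ""),
#'   targets = rbind(c(0, 10), c(10, 20)),
#'   cutPositions = c(3, 3), cutConvention = "offset3p"
#' )
#' cutSites(d) # bonds 7 and 17
#' @export
barcodeDesign <- function(sequence, targets, cutPositions,
                          cutConvention = c("absolute", "offset3p")) {
  cutConvention <- match.arg(cutConvention)
  if (is.list(targets)) targets <- do.call(rbind, lapply(targets, as.integer))
  targets <- matrix(as.integer(targets), ncol = 2L,
                    dimnames = list(NULL, c("start", "end")))
  cutPositions <- as.integer(cutPositions)
  cuts <- if (cutConvention == "offset3p") targets[, 2L] - cutPositions else cutPositions
  new("BarcodeDesign", sequence = as.character(sequence),
      targets = targets, cuts = as.integer(cuts))
}

#' A V7-like GESTALT barcode design
#'
#' The designs used in zebrafish GESTALT experiments tile M contiguous
#' target sites of 23 bp (20 bp protospacer + 3 bp PAM); Cas9 cuts 3 bp
#' upstream of the PAM, i.e. at bond `end - 6` of each site. This helper
#' builds such an array with a deterministic filler sequence, defaulting to
#' the 4-target shortened array used throughout the package's validation
#' studies.
#'
#' @param nTargets Number of target sites (10 for the full-length array).
#' @param targetWidth Width of each site in bp.
#' @param cutOffset3p Cut-bond offset from each site's 3' end.
#' @return A [BarcodeDesign-class].
#' @export
v7BarcodeDesign <- function(nTargets = 4L, targetWidth = 23L, cutOffset3p = 6L) {
  nTargets <- as.integer(nTargets)
  base <- c("G", "A", "T", "C")
  seq <- paste(rep(base, length.out = nTargets * targetWidth), collapse = "")
  starts <- (seq_len(nTargets) - 1L) * targetWidth
  barcodeDesign(seq, cbind(starts, starts + targetWidth),
                rep(cutOffset3p, nTargets), cutConvention = "offset3p")
}

#' Read / write a barcode design as JSON
#'
#' The on-disk format is a JSON object with keys `sequence`, `targets` (list
#' of `[start, end)` pairs) and `cut_positions` (absolute bond indices), plus
#' an optional `cut_convention` of `"absolute"` (default) or `"offset3p"`.
#'
#' @param path File path.
#' @return `readBarcodeDesign` returns a [BarcodeDesign-class];
#'   `writeBarcodeDesign` returns `path` invisibly.
#' @export
readBarcodeDesign <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  conv <- if (!is.null(x$cut_convention)) x$cut_convention else "absolute"
  barcodeDesign(x$sequence, x$targets, x$cut_positions, cutConvention = conv)
}

#' @rdname readBarcodeDesign
#' @param design A [BarcodeDesign-class].
#' @export
writeBarcodeDesign <- function(design, path) {
  stopifnot(is(design, "BarcodeDesign"))
  obj <- list(
    sequence = design@sequence,
    targets = unname(design@targets),
    cut_positions = design@cuts,
    cut_convention = "absolute"
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
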