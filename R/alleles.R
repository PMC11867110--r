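## Indels and alleles.
##
## An indel is a plain classed list: start (0-based coordinate of the first
## deleted base, or of the insertion bond when delLen = 0), delLen (>= 0),
## insert (possibly empty DNA string), tmin/tmax (1-based indices of the
## extreme targets whose cut bonds lie inside the event). An allele is a
## list of indels sorted by start, pairwise non-overlapping in unedited
## barcode coordinates. Target indices are 1..M throughout (R indexing; the
## allele-table format uses the same convention).

#' Construct a single indel
#'
#' @param start 0-based barcode coordinate of the first deleted base, or of
#'   the insertion bond for a pure insertion (`delLen = 0`).
#' @param delLen Deletion length in bases, `>= 0`.
#' @param insert Inserted DNA sequence (possibly empty).
#' @param minTarget,maxTarget 1-based indices of the extreme targets whose
#'   cut sites fall inside the event; computed from `design` when omitted.
#' @param design Optional [BarcodeDesign-class] used to fill in and check
#'   the target span.
#' @return A classed list of class `"gestaltIndel"`.
#' @examples
#' d <- v7BarcodeDesign(2)
#' indel(10, 15, "ACG", design = d)
#' @export
indel <- function(start, delLen, insert = "", minTarget = NULL,
                  maxTarget = NULL, design = NULL) {
  ind <- structure(
    list(start = as.integer(start), del = as.integer(delLen),
         insert = toupper(as.character(insert)),
         tmin = if (is.null(minTarget)) NA_integer_ else as.integer(minTarget),
         tmax = if (is.null(maxTarget)) NA_integer_ else as.integer(maxTarget)),
    class = "gestaltIndel"
  )
  if (!is.null(design)) {
    span <- indelTargetSpan(ind, design)
    if (is.na(ind$tmin)) ind$tmin <- span[1L]
    if (is.na(ind$tmax)) ind$tmax <- span[2L]
    validateIndel(ind, design)
  }
  ind
}

#' @export
print.gestaltIndel <- function(x, ...) {
  cat(sprintf("indel @%d del=%d ins='%s' targets %s-%s\n",
              x$start, x$del, x$insert, x$tmin, x$tmax))
  invisible(x)
}

## Does the deletion interval [a, a + del) of `ind` contain cut bond c?
## Bonds are inter-base indices; a nonzero deletion [a, b) destroys the
## bond c whenever a <= c <= b (the cut that generated a trim always sits
## at one of its edges).
cutInDeletion <- function(ind, cut) {
  ind$del > 0L && ind$start <= cut && cut <= ind$start + ind$del
}

## 1-based target owning a bond strictly in its interior.
targetOfBond <- function(bond, design) {
  tg <- design@targets
  k <- which(tg[, 1L] < bond & bond < tg[, 2L])
  if (length(k) != 1L)
    stop("insertion bond ", bond, " does not fall strictly inside a target site")
  k
}

## (tmin, tmax): extreme targets whose cut bonds lie inside the event.
indelTargetSpan <- function(ind, design) {
  if (ind$del == 0L) {
    k <- targetOfBond(ind$start, design)
    return(c(k, k))
  }
  cov <- which(vapply(design@cuts, function(cc) cutInDeletion(ind, cc), TRUE))
  if (length(cov) == 0L)
    stop("deletion [", ind$start, ", ", ind$start + ind$del,
         ") covers no target cut site")
  range(cov)
}

validateIndel <- function(ind, design) {
  L <- nchar(design@sequence)
  if (ind$del < 0L) stop("negative deletion length")
  if (ind$del == 0L && !nzchar(ind$insert))
    stop("an indel must delete or insert at least one base")
  if (nzchar(ind$insert) && grepl("[^ACGT]", ind$insert))
    stop("insert sequence must be over A/C/G/T")
  if (ind$start < 0L || ind$start + ind$del > L)
    stop("indel [", ind$start, ", ", ind$start + ind$del,
         ") lies outside the barcode [0, ", L, ")")
  span <- indelTargetSpan(ind, design)
  if (is.na(ind$tmin) || is.na(ind$tmax) ||
      ind$tmin != span[1L] || ind$tmax != span[2L])
    stop("declared target span ", ind$tmin, "-", ind$tmax,
         " does not match the event footprint (", span[1L], "-", span[2L], ")")
  invisible(TRUE)
}

## Closed-footprint interval of an indel (used for overlap/merge tests):
## [start, start + del]; a pure insertion is the degenerate point [b, b].
indelFootprint <- function(ind) c(ind$start, ind$start + ind$del)

## Targets whose interval the event physically touches (deletion interval
## intersects [s, e), or insertion bond strictly inside).
touchedTargets <- function(ind, design) {
  tg <- design@targets
  if (ind$del == 0L) {
    which(tg[, 1L] < ind$start & ind$start < tg[, 2L])
  } else {
    a <- ind$start; b <- ind$start + ind$del
    which(a < tg[, 2L] & tg[, 1L] < b)
  }
}

#' Build an allele from a list of indels
#'
#' Sorts the indels by start coordinate and (when a design is supplied)
#' validates the allele invariants: indels pairwise non-overlapping, each
#' target's cut site affected by at most one indel.
#'
#' @param indels A list of [indel()] objects (possibly empty = unedited).
#' @param design Optional [BarcodeDesign-class] to validate against.
#' @return A classed list of class `"gestaltAllele"`.
#' @export
allele <- function(indels = list(), design = NULL) {
  stopifnot(is.list(indels))
  if (length(indels)) {
    ord <- order(vapply(indels, `[[`, 1L, "start"),
                 vapply(indels, `[[`, 1L, "del"))
    indels <- indels[ord]
  }
  al <- structure(indels, class = "gestaltAllele")
  if (!is.null(design)) validateAllele(al, design)
  al
}

#' @export
print.gestaltAllele <- function(x, ...) {
  if (!length(x)) {
    cat("unedited allele\n")
  } else {
    cat("allele with", length(x), "indel(s):\n")
    for (ind in x) print(ind)
  }
  invisible(x)
}

validateAllele <- function(al, design) {
  if (!length(al)) return(invisible(TRUE))
  for (ind in al) validateIndel(ind, design)
  fp <- t(vapply(al, indelFootprint, c(0, 0)))
  if (length(al) > 1L) {
    ord <- order(fp[, 1L])
    fp <- fp[ord, , drop = FALSE]
    if (any(fp[-1L, 1L] < fp[-nrow(fp), 2L]))
      stop("allele has overlapping indels")
  }
  cov <- unlist(lapply(al, function(ind)
    which(vapply(design@cuts, function(cc) cutInDeletion(ind, cc), TRUE))))
  if (anyDuplicated(cov))
    stop("a target cut site is covered by more than one indel")
  invisible(TRUE)
}

#' Normalize a set of raw indels into a valid allele
#'
#' Allele pre-processing: raw indels whose footprints overlap (or abut), or
#' which affect the same target site, are merged into a single spanning
#' indel whose deleted interval is the union hull and whose insert
#' sequences are concatenated in barcode order. Target spans are
#' recomputed from the covered cut sites. The operation is idempotent.
#'
#' @param rawIndels List of [indel()] objects, individually valid against
#'   `design` but possibly overlapping or sharing a target.
#' @param design A [BarcodeDesign-class].
#' @return A valid `"gestaltAllele"`.
#' @export
normalizeAllele <- function(rawIndels, design) {
  if (!length(rawIndels)) return(allele(list(), design))
  n <- length(rawIndels)
  fp <- t(vapply(rawIndels, indelFootprint, c(0, 0)))
  touched <- lapply(rawIndels, touchedTargets, design = design)
  ## union-find over the merge relation
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    overlap <- fp[i, 1L] <= fp[j, 2L] && fp[j, 1L] <= fp[i, 2L]
    shared <- length(intersect(touched[[i]], touched[[j]])) > 0L
    if (overlap || shared) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  ## closure: merging can create new overlaps, so iterate to fixpoint
  groups <- split(seq_len(n), vapply(seq_len(n), find, 1L))
  merged <- lapply(groups, function(idx) {
    members <- rawIndels[idx]
    ord <- order(vapply(members, `[[`, 1L, "start"))
    members <- members[ord]
    a <- min(vapply(members, `[[`, 1L, "start"))
    b <- max(vapply(members, function(m) m$start + m$del, 1L))
    ins <- paste(vapply(members, `[[`, "", "insert"), collapse = "")
    if (length(members) == 1L) return(members[[1L]])
    indel(a, b - a, ins, design = design)
  })
  out <- allele(unname(merged), NULL)
  if (length(out) < n) return(normalizeAllele(out, design))
  allele(unname(merged), design)
}

#' Per-target editability status of an allele
#'
#' A target site is inactive (no longer editable) once any indel's deleted
#' interval intersects its interval, or an insertion bond falls strictly
#' inside it: either destroys complementarity with the guide RNA, and
#' editing is irreversible.
#'
#' @param al A `"gestaltAllele"`.
#' @param design A [BarcodeDesign-class].
#' @return Logical vector of length M; `TRUE` = target still active.
#' @export
targetStatus <- function(al, design) {
  active <- rep(TRUE, numTargets(design))
  for (ind in al) active[touchedTargets(ind, design)] <- FALSE
  active
}

#' Reconstruct the edited barcode sequence
#'
#' Applies an allele to the unedited design sequence: deleted intervals are
#' removed and insert sequences are placed at their bond.
#'
#' @param design A [BarcodeDesign-class].
#' @param al A valid `"gestaltAllele"`.
#' @return The edited DNA string.
#' @export
applyAllele <- function(design, al) {
  seq <- design@sequence
  if (!length(al)) return(seq)
  pieces <- character(0)
  pos <- 0L
  for (ind in al) {
    pieces <- c(pieces, substr(seq, pos + 1L, ind$start), ind$insert)
    pos <- ind$start + ind$del
  }
  pieces <- c(pieces, substr(seq, pos + 1L, nchar(seq)))
  paste(pieces, collapse = "")
}

## Canonical string key of an allele (assumes sorted indels).
alleleKey <- function(al) {
  if (!length(al)) return("")
  paste(vapply(al, function(ind)
    paste(ind$start, ind$del, ind$insert, ind$tmin, ind$tmax, sep = ":"),
    ""), collapse = ",")
}

indelKey <- function(ind)
  paste(ind$start, ind$del, ind$insert, ind$tmin, ind$tmax, sep = ":")

#' Assemble a barcode alignment
#'
#' @param design A [BarcodeDesign-class].
#' @param alleleList Named list of `"gestaltAllele"` objects (names are the
#'   cell ids), or an unnamed list accompanied by `cellIds`.
#' @param cellIds Optional character vector of cell ids.
#' @return A [BarcodeAlignment-class].
#' @export
barcodeAlignment <- function(design, alleleList, cellIds = names(alleleList)) {
  if (is.null(cellIds))
    cellIds <- paste0("cell", seq_along(alleleList))
  new("BarcodeAlignment", design = design, cellIds = as.character(cellIds),
      alleles = unname(alleleList))
}

#' Read / write allele tables
#'
#' The allele-table dialect is UTF-8 TSV with header `cell_id<TAB>indels`;
#' the `indels` field is a comma-separated list of
#' `start:del_len:insert:min_target:max_target` tokens (0-based start
#' coordinate, 1-based target indices), and the empty string denotes an
#' unedited barcode. Alleles are normalized (see [normalizeAllele()]) on
#' input; writing a parsed alignment reproduces the file.
#'
#' @param path Path to a TSV file, or for `parseAlleleTable` a character
#'   vector of the table's lines.
#' @param design A [BarcodeDesign-class].
#' @return `parseAlleleTable` returns a [BarcodeAlignment-class];
#'   `writeAlleleTable` returns `path` invisibly.
#' @export
parseAlleleTable <- function(path, design) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, encoding = "UTF-8") else path
  if (!length(lines)) stop("empty allele table")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[1L] != "cell_id" || header[2L] != "indels")
    stop("allele table parse error at line 1: expected header 'cell_id\tindels'")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  ids <- character(length(body))
  als <- vector("list", length(body))
  for (i in seq_along(body)) {
    lineno <- i + 1L
    fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 1L || !nzchar(fields[1L]))
      stop("allele table parse error at line ", lineno, ": missing cell_id")
    ids[i] <- fields[1L]
    tokenStr <- if (length(fields) >= 2L) fields[2L] else ""
    raw <- list()
    if (nzchar(tokenStr)) {
      tokens <- strsplit(tokenStr, ",", fixed = TRUE)[[1L]]
      raw <- lapply(tokens, function(tok) {
        parts <- strsplit(tok, ":", fixed = TRUE)[[1L]]
        if (length(parts) == 4L) parts <- c(parts[1:2], "", parts[3:4])
        if (length(parts) != 5L)
          stop("allele table parse error at line ", lineno,
               ": malformed indel token '", tok, "'")
        num <- suppressWarnings(as.integer(parts[c(1L, 2L, 4L, 5L)]))
        if (anyNA(num))
          stop("allele table parse error at line ", lineno,
               ": non-numeric field in token '", tok, "'")
        indel(num[1L], num[2L], parts[3L], num[3L], num[4L])
      })
    }
    als[[i]] <- tryCatch(
      normalizeAllele(raw, design),
      error = function(e) stop("invalid allele for cell '", ids[i], "': ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  barcodeAlignment(design, als, ids)
}

#' @rdname parseAlleleTable
#' @param alignment A [BarcodeAlignment-class].
#' @export
writeAlleleTable <- function(alignment, path) {
  stopifnot(is(alignment, "BarcodeAlignment"))
  rows <- vapply(seq_along(alignment@cellIds), function(i) {
    al <- alignment@alleles[[i]]
    paste0(alignment@cellIds[i], "\t", alleleKey(al))
  }, "")
  writeLines(c("cell_id\tindels", rows), path, useBytes = TRUE)
  invisible(path)
}
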