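## Time-scaled lineage trees are plain `ape::phylo` objects: rooted,
## strictly bifurcating, edge lengths in absolute time units, all tips
## contemporaneous. Node times run forward (root smallest); tip ages are 0
## looking backwards.

#' Validate a time-scaled lineage tree
#'
#' Checks that a tree can serve as a cell lineage tree: rooted and strictly
#' bifurcating, non-negative branch lengths, and all tips contemporaneous
#' (within `tol`, relative to tree height).
#'
#' @param phy An `ape::phylo`.
#' @param tol Relative tolerance on tip-time spread.
#' @return `phy`, invisibly; errors otherwise.
#' @export
validateLineageTree <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (any(phy$edge.length < 0)) stop("tree has a negative branch length")
  n <- length(phy$tip.label)
  if (n < 2L) stop("tree must have at least 2 tips")
  if (phy$Nnode != n - 1L)
    stop("tree must be strictly bifurcating and rooted (Nnode == ntips - 1)")
  tab <- tabulate(phy$edge[, 1L])
  if (any(tab[tab > 0L] != 2L)) stop("tree must be strictly bifurcating")
  d <- nodeDepths(phy)
  tipd <- d[seq_len(n)]
  h <- max(d)
  if (h > 0 && (max(tipd) - min(tipd)) > tol * h)
    stop("tips must be contemporaneous")
  invisible(phy)
}

## Edge indices in postorder (every child's subtree before its parent
## edge); robust to arbitrary edge-row order.
postorderEdges <- function(phy) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  kids <- vector("list", nn)
  edgeOf <- integer(nn)
  for (e in seq_len(nrow(phy$edge))) {
    kids[[phy$edge[e, 1L]]] <- c(kids[[phy$edge[e, 1L]]], phy$edge[e, 2L])
    edgeOf[phy$edge[e, 2L]] <- e
  }
  out <- integer(0)
  visit <- function(v) {
    for (k in kids[[v]]) {
      if (k > n) visit(k)
      out[[length(out) + 1L]] <<- edgeOf[k]
    }
  }
  visit(n + 1L)
  out
}

## Internal nodes in postorder: every internal node after all internal
## nodes below it.
postorderNodes <- function(phy) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  kids <- vector("list", nn)
  for (e in seq_len(nrow(phy$edge)))
    kids[[phy$edge[e, 1L]]] <- c(kids[[phy$edge[e, 1L]]], phy$edge[e, 2L])
  out <- integer(0)
  visit <- function(v) {
    for (k in kids[[v]]) if (k > n) visit(k)
    out[[length(out) + 1L]] <<- v
  }
  visit(n + 1L)
  out
}

## Depth (time since root) of every node, root = 0. Returns vector indexed
## by ape node number (tips 1..n, root n+1, ...).
nodeDepths <- function(phy) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  depth <- numeric(nn)
  po <- postorderEdges(phy)
  for (i in rev(po)) {  # preorder: parents before children
    e <- phy$edge[i, ]
    depth[e[2L]] <- depth[e[1L]] + phy$edge.length[i]
  }
  depth
}

## Ages (time before present) of every node: height - depth.
nodeAges <- function(phy) {
  d <- nodeDepths(phy)
  max(d[seq_len(length(phy$tip.label))]) - d
}

#' Tree height (root-to-tip time)
#' @param phy An `ape::phylo`.
#' @export
treeHeight <- function(phy) {
  d <- nodeDepths(phy)
  max(d[seq_len(length(phy$tip.label))])
}

## Internal-node ages sorted decreasingly (root first).
internalAges <- function(phy) {
  a <- nodeAges(phy)
  n <- length(phy$tip.label)
  sort(a[(n + 1L):(n + phy$Nnode)], decreasing = TRUE)
}

## Deterministic topology fingerprint (ignores branch lengths).
topologyHash <- function(phy) {
  canon <- function(node) {
    kids <- phy$edge[phy$edge[, 1L] == node, 2L]
    if (!length(kids)) return(phy$tip.label[node])
    sub <- sort(vapply(kids, canon, ""))
    paste0("(", paste(sub, collapse = ","), ")")
  }
  n <- length(phy$tip.label)
  canon(n + 1L)
}

## Clade bitmask (over sorted tip labels) for every node.
cladeMasks <- function(phy, tipUniverse = sort(phy$tip.label)) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  masks <- vector("list", nn)
  tipPos <- match(phy$tip.label, tipUniverse)
  for (i in seq_len(n)) {
    v <- logical(length(tipUniverse)); v[tipPos[i]] <- TRUE
    masks[[i]] <- v
  }
  poE <- phy$edge[postorderEdges(phy), , drop = FALSE]
  for (i in seq_len(nrow(poE))) {
    e <- poE[i, ]
    if (is.null(masks[[e[1L]]])) masks[[e[1L]]] <- logical(length(tipUniverse))
    masks[[e[1L]]] <- masks[[e[1L]]] | masks[[e[2L]]]
  }
  masks
}
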