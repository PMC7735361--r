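#' Root-to-tip node count
#'
#' Number of internal nodes on the path from the root to a tip.  By
#' default the root is counted and the tip is not, so the minimum node
#' count is 1 (a tree's root exists even when no time has elapsed, so a
#' lineage leaving the root has already passed one node).  Multifurcating
#' nodes count once each, like bifurcations.  Set `count_tip = TRUE` for
#' the alternative convention that also counts the tip itself.
#'
#' @param tree a `"phylo"`.
#' @param tips tip labels (default: all tips, in tip order).
#' @param count_tip also count the terminal node (default `FALSE`).
#' @return named integer vector of node counts.
#' @export
node_count <- function(tree, tips = tree$tip.label, count_tip = FALSE) {
  validate_phylo(tree)
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) stop("unknown tip label: '", unknown[1L], "'")
  paths <- ape::nodepath(tree)  # root-to-tip node sequences, tip included
  nc <- lengths(paths) - 1L
  names(nc) <- tree$tip.label
  if (count_tip) nc <- nc + 1L
  nc[tips]
}

#' Root-to-tip time elapsed
#'
#' Sum of branch lengths (Myr) along the path from the root to each tip.
#' On a dated tree this equals `root age - tip age`.
#'
#' @param tree a `"phylo"` with branch lengths.
#' @param tips tip labels (default: all tips, in tip order).
#' @return named numeric vector of root-to-tip distances (Myr).
#' @export
time_elapsed <- function(tree, tips = tree$tip.label) {
  validate_phylo(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) stop("unknown tip label: '", unknown[1L], "'")
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d[tips]
}

#' Phylogenetic variance-covariance matrix
#'
#' `A[i, j]` is the shared root-to-MRCA path length (Myr) of tips `i` and
#' `j`; the diagonal holds root-to-tip distances.  This is the covariance
#' structure of a Brownian-style phylogenetically correlated random
#' effect.  With `scale = TRUE` the matrix is divided by its largest
#' diagonal entry so the deepest tip has unit variance.
#'
#' @param tree a `"phylo"` with branch lengths.
#' @param scale divide by the maximum root-to-tip depth (default `FALSE`,
#'   leaving the matrix in Myr).
#' @return symmetric positive semi-definite matrix with tip labels as
#'   dimnames, rows/columns in tip order.
#' @export
phylo_vcv <- function(tree, scale = FALSE) {
  validate_phylo(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  A <- ape::vcv.phylo(tree)
  A <- A[tree$tip.label, tree$tip.label]  # enforce tip order
  if (scale) {
    m <- max(diag(A))
    if (m <= 0) stop("cannot scale: tree has zero depth")
    A <- A / m
  }
  A
}

#' Per-tip node counts and times elapsed
#'
#' One row per tip, in the same tip order as [phylo_vcv()], pairing the
#' model response (node count) with its covariate (time elapsed).
#'
#' @param tree a dated `"phylo"` with branch lengths.
#' @param count_tip passed to [node_count()].
#' @return data.frame `taxon`, `node_count`, `time_elapsed`.
#' @export
extract_table <- function(tree, count_tip = FALSE) {
  data.frame(taxon = tree$tip.label,
             node_count = unname(node_count(tree, count_tip = count_tip)),
             time_elapsed = unname(time_elapsed(tree)),
             row.names = NULL, stringsAsFactors = FALSE)
}
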