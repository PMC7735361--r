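#' @useDynLib ncdiv, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rexp rnorm rpois runif setNames quantile median acf
#' @importFrom utils read.csv write.csv
NULL

#' Read a phylogeny from Newick
#'
#' Thin wrapper around [ape::read.tree()] that additionally validates the
#' invariants the rest of the package relies on: a single rooted tree,
#' unique non-empty tip labels, and finite non-negative branch lengths
#' (when present).  Labels are taken literally (no underscore-to-space
#' translation) so that taxon names match age tables byte-for-byte.
#' Multifurcations are preserved.
#'
#' @param text a Newick string (one tree).  Exactly one of `text`/`file`.
#' @param file path to a Newick file (first tree is read).
#' @return an object of class `"phylo"`.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  if (!grepl(";", text, fixed = TRUE))
    stop("Newick parse error: no terminating ';' found (position ",
         nchar(text), ")")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop("Newick parse error: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, "')')")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: ape could not parse the string")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  validate_phylo(tr)
  tr
}

#' Write a phylogeny as Newick
#'
#' Branch lengths are rendered with 15 significant digits so that
#' write/parse round-trips are lossless at double precision.
#'
#' @param tree a `"phylo"` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  validate_phylo(tree)
  s <- ape::write.tree(tree, digits = 15)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Validate the tree invariants used throughout the package
#'
#' @param tree a `"phylo"` object.
#' @return `tree`, invisibly.  Errors describe the violated invariant.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  lab <- tree$tip.label
  if (any(!nzchar(lab))) stop("empty tip label at position ",
                              which(!nzchar(lab))[1L])
  if (anyDuplicated(lab))
    stop("duplicate tip label: '", lab[duplicated(lab)][1L], "'")
  if (!is.null(tree$edge.length)) {
    bl <- tree$edge.length
    if (any(!is.finite(bl))) stop("non-finite branch length")
    if (any(bl < 0)) stop("negative branch length: ", min(bl))
  }
  # exactly one root: nodes that never appear as a child
  kids <- tree$edge[, 2L]
  parents <- unique(tree$edge[, 1L])
  roots <- setdiff(parents, kids)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  if (anyDuplicated(kids)) stop("a node has more than one parent")
  invisible(tree)
}

#' Node ages of a dated tree
#'
#' A dated tree is a `"phylo"` whose branch lengths are durations in Myr
#' and which carries a `root.time` attribute: the age of the root in Ma
#' before present (the convention used by paleotree).  Ages decrease from
#' root to tips; `age = root.time - distance from root`.
#'
#' @param tree a dated `"phylo"` with `$root.time`.
#' @return numeric vector of ages (Ma) for all nodes in ape numbering
#'   (tips `1..n`, then internal nodes).
#' @export
node_ages <- function(tree) {
  if (is.null(tree$root.time))
    stop("tree is not dated: missing 'root.time'")
  depth <- ape::node.depth.edgelength(tree)
  tree$root.time - depth
}

#' Tip ages of a dated tree
#'
#' @param tree a dated `"phylo"` with `$root.time`.
#' @return named numeric vector of tip ages (Ma), in tip order.
#' @export
tip_ages <- function(tree) {
  a <- node_ages(tree)[seq_along(tree$tip.label)]
  names(a) <- tree$tip.label
  a
}

# Set branch lengths from a full vector of node ages (ape numbering) and
# stamp root.time.  Internal.
set_ages <- function(tree, ages) {
  tree$edge.length <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
  if (any(tree$edge.length < -1e-9))
    stop("node ages violate parent >= child")
  tree$edge.length[tree$edge.length < 0] <- 0
  tree$root.time <- ages[ape::Ntip(tree) + 1L]
  tree
}

#' Test whether two trees are equal up to child ordering
#'
#' Topology is compared with [ape::all.equal.phylo()] (rotation-invariant)
#' and branch lengths to a tolerance.
#'
#' @param a,b `"phylo"` objects.
#' @param tol absolute tolerance on branch lengths (default `1e-9`).
#' @return logical.
#' @export
trees_equal <- function(a, b, tol = 1e-9) {
  isTRUE(ape::all.equal.phylo(a, b, use.edge.length = !is.null(a$edge.length),
                              tolerance = tol))
}
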