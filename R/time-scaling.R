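#' Dating configuration
#'
#' @param mbl minimum branch duration in Myr (default 1).
#' @param reps number of dating replicates per topology (default 100).
#' @param base_seed integer; replicate `r` uses seed `base_seed + r`.
#' @return a list of class `"dating_config"`.
#' @export
dating_config <- function(mbl = 1, reps = 100L, base_seed = 1L) {
  stopifnot(mbl > 0, reps >= 1)
  structure(list(mbl = mbl, reps = as.integer(reps),
                 base_seed = as.integer(base_seed)),
            class = "dating_config")
}

#' Read a taxon age-range table
#'
#' Expects a CSV with header `taxon,max_age,min_age` (Ma).  Validates
#' `max_age >= min_age >= 0`.
#'
#' @param file path to the CSV.
#' @return data.frame with the three columns.
#' @export
read_age_ranges <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  validate_age_ranges(d)
}

validate_age_ranges <- function(ranges) {
  need <- c("taxon", "max_age", "min_age")
  if (!all(need %in% names(ranges)))
    stop("age-range table must have columns ", paste(need, collapse = ", "))
  bad <- which(!(ranges$max_age >= ranges$min_age & ranges$min_age >= 0))
  if (length(bad))
    stop("invalid age range for taxon '", ranges$taxon[bad[1L]],
         "': need max_age >= min_age >= 0")
  ranges
}

#' Sample point ages uniformly within taxon age ranges
#'
#' Each taxon's age is drawn `Uniform(min_age, max_age)`, independently
#' across taxa.  Degenerate ranges return their single value exactly.
#'
#' @param ranges data.frame `taxon`, `max_age`, `min_age`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return named numeric vector of ages (Ma).
#' @export
sample_taxon_ages <- function(ranges, seed = NULL) {
  validate_age_ranges(ranges)
  if (!is.null(seed)) set.seed(seed)
  a <- ranges$min_age + runif(nrow(ranges)) * (ranges$max_age - ranges$min_age)
  setNames(a, ranges$taxon)
}

#' Basic time-scaling: each node at its oldest descendant's age
#'
#' Places every tip at its supplied age and every internal node at the
#' maximum age over its descendant tips, so branch lengths
#' (`parent age - child age`) are non-negative but may be zero.
#'
#' @param tree a `"phylo"` (branch lengths, if any, are ignored).
#' @param ages named numeric vector of tip ages (Ma); every tip label must
#'   be present.
#' @return a dated `"phylo"` with `$root.time`.
#' @export
date_tree_basic <- function(tree, ages) {
  validate_phylo(tree)
  miss <- setdiff(tree$tip.label, names(ages))
  if (length(miss))
    stop("missing age for taxon '", miss[1L], "'")
  n <- ape::Ntip(tree)
  node_age <- c(unname(ages[tree$tip.label]), rep(-Inf, tree$Nnode))
  tree <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(tree$edge))) {   # children precede parents
    p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    if (node_age[ch] > node_age[p]) node_age[p] <- node_age[ch]
  }
  set_ages(tree, node_age)
}

#' Impose a minimum branch duration
#'
#' Post-order pass that raises each internal node's age to
#' `max(current age, child age + mbl)` over its children, children before
#' parents, so every branch in the output is at least `mbl` Myr long.
#' Tip ages never change and node ages never decrease; topology is
#' untouched.  Idempotent on trees that already comply.
#'
#' @param tree a dated `"phylo"` with `$root.time`.
#' @param mbl minimum branch duration (Myr), `> 0`.
#' @return the adjusted dated `"phylo"`.
#' @export
enforce_mbl <- function(tree, mbl = 1) {
  stopifnot(mbl > 0)
  ages <- node_ages(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    if (ages[ch] + mbl > ages[p]) ages[p] <- ages[ch] + mbl
  }
  set_ages(tree, ages)
}

#' Date a cladogram many times from its taxon age ranges
#'
#' Replicate `r` samples tip ages with seed `base_seed + r`, applies
#' [date_tree_basic()] and then [enforce_mbl()], reproducing the standard
#' fossil-tree dating protocol (uniform age draw, minimum branch duration).
#'
#' @param tree an undated `"phylo"` cladogram.
#' @param ranges data.frame `taxon`, `max_age`, `min_age` covering every tip.
#' @param config a [dating_config()].
#' @return list of dated `"phylo"` trees, length `config$reps`.
#' @export
date_ensemble <- function(tree, ranges, config = dating_config()) {
  stopifnot(inherits(config, "dating_config"))
  lapply(seq_len(config$reps), function(r) {
    a <- sample_taxon_ages(ranges, seed = config$base_seed + r)
    enforce_mbl(date_tree_basic(tree, a), config$mbl)
  })
}

#' Root-age bias diagnostic
#'
#' Minimum-branch-duration enforcement can only push nodes older, so the
#' root may end up older than any taxon could possibly be.  This reports
#' `root age - oldest max_age` and flags trees where the overshoot exceeds
#' a threshold.
#'
#' @param dated a dated `"phylo"`.
#' @param ranges the age-range table used for dating.
#' @param threshold overshoot (Myr) beyond which the flag is raised;
#'   default 10.
#' @return data.frame `root_age`, `oldest_max_age`, `difference`, `flagged`.
#' @export
root_age_diagnostic <- function(dated, ranges, threshold = 10) {
  validate_age_ranges(ranges)
  root_age <- unname(node_ages(dated)[ape::Ntip(dated) + 1L])
  oldest <- max(ranges$max_age)
  data.frame(root_age = root_age, oldest_max_age = oldest,
             difference = root_age - oldest,
             flagged = (root_age - oldest) > threshold)
}
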