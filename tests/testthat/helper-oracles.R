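# Independent brute-force implementations used as oracles.  These
# deliberately share no code with the package: everything works from the
# raw edge matrix with parent-pointer walks.

# parent of every node (0 for the root)
parent_vec <- function(tree) {
  p <- integer(ape::Ntip(tree) + tree$Nnode)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

# node indices on the path root -> node, endpoints included
walk_to_root <- function(tree, node) {
  p <- parent_vec(tree)
  path <- node
  while (p[node] != 0L) {
    node <- p[node]
    path <- c(node, path)
  }
  path
}

# oracle node count: internal nodes on root->tip path (root in, tip out)
oracle_node_count <- function(tree, tip_idx) {
  length(walk_to_root(tree, tip_idx)) - 1L
}

# oracle root-to-tip distance via explicit edge-length lookup
oracle_time_elapsed <- function(tree, tip_idx) {
  path <- walk_to_root(tree, tip_idx)
  len <- 0
  for (k in seq_len(length(path) - 1L)) {
    e <- which(tree$edge[, 1L] == path[k] & tree$edge[, 2L] == path[k + 1L])
    len <- len + tree$edge.length[e]
  }
  len
}

# oracle phylogenetic covariance: shared path length = summed lengths of
# edges common to the two root->tip paths
oracle_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  paths <- lapply(seq_len(n), function(i) walk_to_root(tree, i))
  A <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  edge_len <- function(path) {
    sapply(seq_len(length(path) - 1L), function(k)
      tree$edge.length[which(tree$edge[, 1L] == path[k] &
                             tree$edge[, 2L] == path[k + 1L])])
  }
  for (i in seq_len(n)) {
    for (j in i:n) {
      pi <- paths[[i]]; pj <- paths[[j]]
      m <- 0L
      while (m < min(length(pi), length(pj)) && pi[m + 1L] == pj[m + 1L])
        m <- m + 1L
      shared <- if (m >= 2L) sum(edge_len(pi[seq_len(m)])) else 0
      A[i, j] <- A[j, i] <- shared
    }
  }
  diag(A) <- sapply(seq_len(n), function(i) oracle_time_elapsed(tree, i))
  A
}

# oracle basic dating: every node at the max age over its descendant tips
oracle_date_ages <- function(tree, tip_age) {
  n <- ape::Ntip(tree)
  ages <- c(unname(tip_age[tree$tip.label]), rep(NA_real_, tree$Nnode))
  for (v in (n + 1L):(n + tree$Nnode)) {
    desc <- descendant_tips(tree, v)
    ages[v] <- max(tip_age[tree$tip.label[desc]])
  }
  ages
}

descendant_tips <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(node)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, descendant_tips, tree = tree))
}

# random non-ultrametric test tree with positive branch lengths
random_tree <- function(n_tips, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n_tips)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 10)
  tr
}

# a reproducible birth-death tree with a tip count inside [lo, hi]
bd_fixture <- function(lo = 80, hi = 130, lambda0 = 0.1, mu = 0.03,
                       duration = 45, seed_from = 1L) {
  for (s in seq(seed_from, seed_from + 200L)) {
    x <- simulate_bd_tree(lambda0, mu, duration = duration, seed = s)
    if (!bd_failed(x) && ape::Ntip(x) >= lo && ape::Ntip(x) <= hi) return(x)
  }
  stop("no fixture tree found")
}
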