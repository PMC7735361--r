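#' Simulate a birth-death tree with a time-decaying speciation rate
#'
#' Grows a tree forward in time for `duration` Myr from a single stem
#' lineage.  The per-lineage speciation rate declines with clade age as
#' `lambda(t) = lambda0 * exp(-k * t)` (`k = 0` gives the constant-rate
#' process); extinction runs at constant rate `mu`.  The decline is tied to
#' clade age, not lineage age, because the slowdown hypotheses being tested
#' are clade-wide temporal declines.  Extinct lineages are retained as tips
#' with their extinction ages, mimicking fossil trees in which most taxa
#' are extinct; extant tips sit at `age_at_end`.
#'
#' The first speciation event becomes the root of the returned tree (the
#' stem segment is discarded), so along a lineage traced tipward from the
#' root the number of splits, root included, has mean close to
#' `lambda0 * duration` for the pure-birth constant-rate process.
#'
#' Time-varying rates are handled by thinning: since `lambda(t)` is
#' non-increasing, the current total rate bounds the future rate until the
#' next accepted event.
#'
#' @param lambda0 speciation rate at the root (events/lineage/Myr), `> 0`.
#' @param mu extinction rate (events/lineage/Myr), `>= 0`.
#' @param k exponential decline coefficient of the speciation rate
#'   (per Myr), `>= 0`; `0` means constant rate.
#' @param duration total simulated time span T (Myr), `> 0`.
#' @param max_tips cap on the number of live lineages; growth stops early
#'   when it is reached (safety valve for explosive parameter choices).
#' @param age_at_end age in Ma assigned to the end of the simulation
#'   (default `0` = the present); all node ages are offset by it.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a dated `"phylo"` (with `$root.time`, ages in Ma) on success, or
#'   an object of class `"bd_failure"` when every lineage went extinct
#'   before T or no speciation occurred (a single-lineage run cannot form a
#'   rooted tree).  Test with [bd_failed()]; callers typically retry with
#'   the next seed.
#' @export
simulate_bd_tree <- function(lambda0, mu = 0, k = 0, duration,
                             max_tips = 10000L, age_at_end = 0,
                             seed = NULL) {
  stopifnot(lambda0 > 0, mu >= 0, k >= 0, duration > 0, max_tips >= 2)
  if (!is.null(seed)) set.seed(seed)

  # lineage ledger; lineage 1 is the stem
  born <- 0          # birth times
  ended <- NA_real_  # split/extinction time; NA while alive
  parent <- NA_integer_
  split <- FALSE     # TRUE if the lineage ended by speciating
  alive <- TRUE
  t <- 0
  repeat {
    live <- which(alive)
    n_live <- length(live)
    if (n_live == 0L || n_live >= max_tips) break
    bound <- n_live * (lambda0 * exp(-k * t) + mu)
    t_prop <- t + rexp(1L, bound)
    if (t_prop >= duration) break
    t <- t_prop
    lam_t <- lambda0 * exp(-k * t)
    rate_t <- n_live * (lam_t + mu)
    if (runif(1L) > rate_t / bound) next  # thinned: no event
    who <- live[sample.int(n_live, 1L)]
    if (runif(1L) < lam_t / (lam_t + mu)) {
      # speciation: lineage 'who' ends, two daughters born
      ended[who] <- t; split[who] <- TRUE; alive[who] <- FALSE
      for (d in 1:2) {
        born <- c(born, t); ended <- c(ended, NA_real_)
        parent <- c(parent, who); split <- c(split, FALSE)
        alive <- c(alive, TRUE)
      }
    } else {
      ended[who] <- t; alive[who] <- FALSE  # extinction
    }
  }
  if (!any(alive))
    return(structure(list(reason = "all lineages extinct before T"),
                     class = "bd_failure"))
  if (!split[1L])
    return(structure(list(reason = "no speciation: single-lineage result"),
                     class = "bd_failure"))
  ended[alive] <- duration  # survivors run to T

  # assemble a phylo: split lineages -> internal nodes, others -> tips;
  # the stem (lineage 1) supplies the root node, its edge is dropped
  is_int <- split
  n_tip <- sum(!is_int)
  idx <- integer(length(born))
  idx[!is_int] <- seq_len(n_tip)
  idx[is_int] <- n_tip + seq_len(sum(is_int))
  nonstem <- which(seq_along(born) != 1L)
  edge <- cbind(idx[parent[nonstem]], idx[nonstem])
  ages <- numeric(n_tip + sum(is_int))
  ages[idx] <- age_at_end + (duration - ended)
  tr <- structure(list(
    edge = edge,
    tip.label = paste0("t", seq_len(n_tip)),
    Nnode = sum(is_int)
  ), class = "phylo")
  tr$edge.length <- ages[edge[, 1L]] - ages[edge[, 2L]]
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr$root.time <- ages[n_tip + 1L]
  validate_phylo(tr)
  tr
}

#' Did a birth-death simulation fail?
#'
#' @param x result of [simulate_bd_tree()].
#' @return logical.
#' @export
bd_failed <- function(x) inherits(x, "bd_failure")

#' Generate stratigraphic age ranges around true tip ages
#'
#' Emulates "age range overall" occurrence extracts: each tip gets an
#' interval `[min_age, max_age]` that contains its true age, with width
#' drawn from an exponential distribution of mean `range_width_mean` and
#' the true age placed uniformly within the interval.  When the interval
#' would cross zero it is shifted to `[0, width]` (still containing the
#' true age), keeping `min_age >= 0`.  Widths are independent across taxa.
#'
#' @param tree a dated `"phylo"` with `$root.time`.
#' @param range_width_mean mean interval width (Myr); `0` gives degenerate
#'   ranges equal to the true ages.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a data.frame with columns `taxon`, `max_age`, `min_age` (Ma).
#' @export
generate_age_ranges <- function(tree, range_width_mean, seed = NULL) {
  stopifnot(range_width_mean >= 0)
  age <- tip_ages(tree)  # errors if the tree is undated
  if (!is.null(seed)) set.seed(seed)
  n <- length(age)
  w <- if (range_width_mean == 0) rep(0, n) else rexp(n, 1 / range_width_mean)
  u <- runif(n)
  lo <- age - u * w
  hi <- age + (1 - u) * w
  shift <- lo < 0
  hi[shift] <- w[shift]
  lo[shift] <- 0
  data.frame(taxon = names(age), max_age = hi, min_age = lo,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate per-tip counts from the phylogenetic Poisson GLMM
#'
#' The generative mirror of the fitted model: with `t_i` the root-to-tip
#' time elapsed of tip `i` and `x_i` the design row for the requested model
#' form (see [build_design()]),
#' `u ~ N(0, sig2_a * A)` with `A` the phylogenetic covariance matrix,
#' `e_i ~ N(0, sig2_e)`, and `y_i ~ Poisson(exp(x_i' beta + u_i + e_i))`.
#'
#' By default `A` is depth-scaled (unit diagonal at the deepest tip, see
#' [phylo_vcv()]), so `sig2_a` is a per-unit-depth variance directly
#' comparable to `sig2_e` and across trees of different ages; set
#' `scale_vcv = FALSE` to interpret it per Myr of shared branch length.
#'
#' @param tree a dated `"phylo"`.
#' @param beta fixed-effect coefficients on the latent (log) scale; length
#'   2 for `"null"`/`"asymptote"`, 3 for `"downturn"` (intercept first).
#' @param sig2_a phylogenetic variance, `>= 0`.
#' @param sig2_e residual (overdispersion) variance, `>= 0`.
#' @param form model form: `"null"`, `"asymptote"` or `"downturn"`.
#' @param scale_vcv draw `u` against the depth-scaled covariance
#'   (default `TRUE`).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a data.frame `taxon`, `time_elapsed`, `count` in tip order.
#' @export
simulate_glmm_counts <- function(tree, beta, sig2_a = 0, sig2_e = 0,
                                 form = c("null", "asymptote", "downturn"),
                                 scale_vcv = TRUE, seed = NULL) {
  form <- match.arg(form)
  stopifnot(sig2_a >= 0, sig2_e >= 0)
  p_expect <- if (form == "downturn") 3L else 2L
  if (length(beta) != p_expect)
    stop("beta must have length ", p_expect, " for form '", form, "'")
  tt <- time_elapsed(tree)
  X <- cbind(1, switch(form,
                       null = cbind(tt),
                       asymptote = cbind(sqrt(tt)),
                       downturn = cbind(tt, tt^2)))
  n <- length(tt)
  if (!is.null(seed)) set.seed(seed)
  u <- rep(0, n)
  if (sig2_a > 0) {
    A <- phylo_vcv(tree, scale = scale_vcv)
    eg <- eigen(A, symmetric = TRUE)
    if (min(eg$values) < -1e-8)
      stop("phylogenetic covariance not positive definite: eigenvalue ",
           format(min(eg$values)))
    lam <- pmax(eg$values, 0)
    u <- as.vector(eg$vectors %*% (sqrt(sig2_a * lam) * rnorm(n)))
  }
  e <- if (sig2_e > 0) rnorm(n, 0, sqrt(sig2_e)) else rep(0, n)
  ell <- as.vector(X %*% beta) + u + e
  data.frame(taxon = tree$tip.label, time_elapsed = tt,
             count = rpois(n, exp(ell)),
             row.names = NULL, stringsAsFactors = FALSE)
}
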