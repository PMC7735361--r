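---
title: "Testing speciation slowdowns with node-count GLMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing speciation slowdowns with node-count GLMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the statistic

Whether a clade's speciation rate was declining toward the end of its
history is hard to read from raw taxon counts, which are distorted by
uneven sampling of the fossil record.  An alternative uses the shape of a
dated phylogeny itself: for each tip, count the internal nodes on the
path from the root to that tip (*node count*, the cumulative number of
splitting events the lineage has passed) and measure the *time elapsed*
(root-to-tip distance, Myr).  If per-lineage speciation rates are roughly
constant, node count grows linearly with time elapsed.  A rate slowdown
that levels off bends the relationship like a square root; a continual
downturn bends it over quadratically.  `ncdiv` fits these three candidate
curves and asks which one the tree supports:

* **null** — `log E[y] = b0 + b1 t`
* **slowdown to asymptote** — `log E[y] = b0 + b1 sqrt(t)`
* **downturn** — `log E[y] = b0 + b1 t + b2 t^2`

with `y` the node count and `t` the time elapsed of a tip.

Node counts are small integers, and neighbouring tips share most of
their root-to-tip path, so observations are neither Gaussian nor
independent.  Both features are modelled directly: counts get Poisson
errors with a log link, and a phylogenetically correlated random effect
absorbs the shared-path dependence,

```
y_i ~ Poisson(exp(l_i)),   l_i = x_i' beta + o_i + u_i + e_i
u ~ N(0, sig2_a * A),      e_i ~ N(0, sig2_e)
```

where `A[i, j]` is the shared root-to-MRCA path length of tips `i` and
`j` (`phylo_vcv()`).  `e` is an ordinary overdispersion term.

### The intercept at the root

When no time has elapsed a lineage has no tips, but the tree does have a
root node, so the "true" node count at `t = 0` is arguably 1 (hence this
package's root-inclusive, tip-exclusive counting convention: the minimum
node count is 1, and `node_count()` exposes the alternative under a
flag).  Because the right intercept is genuinely ambiguous, models can be
fitted with the intercept estimated, fixed at 0, or fixed at 1.  Fixing
is applied on the latent (log) scale as an offset — `fixed_zero` means
`E[y] = 1` at the root and `fixed_one` means `E[y] = e` — because a
log-link model has no intercept on the response scale to fix; the
response-scale alternative would be a different model class.

## Time-scaling cladograms

Fossil cladograms come undated; `ncdiv` dates them from per-taxon
stratigraphic age ranges (`taxon, max_age, min_age` in Ma):

1. `sample_taxon_ages()` draws each taxon's age uniformly between its
   bounds (independently across taxa; ages are treated as point
   occurrences and tips placed exactly at them).
2. `date_tree_basic()` puts each internal node at the age of its oldest
   descendant tip, which leaves zero-length branches wherever a node's
   oldest descendants tie.
3. `enforce_mbl()` removes those zero-length branches by a post-order
   pass that raises each parent to at least `child age + mbl`
   (default `mbl = 1` Myr).  Children are processed before parents, only
   ancestors move, and they only move older, so tip ages are preserved
   and the pass is deterministic and idempotent on compliant trees.

Because age sampling is stochastic, `date_ensemble()` repeats this
(default 100 times, replicate `r` seeded `base_seed + r`) and the whole
analysis is run on the ensemble.  Pushing ancestors older can inflate
the root age beyond any taxon's possible age; `root_age_diagnostic()`
reports `root age - oldest max_age` and flags overshoots above a
threshold (default 10 Myr — small overshoots of order `mbl` times the
depth of nested ties are routine and harmless; tens of Myr suggest the
minimum-branch rule is dominating the data and the tree's dates should
not be over-interpreted).

## The sampler

Fits are by a purpose-built Metropolis-within-Gibbs sampler (C++ core):

* The latent predictors `l_i` are updated one site at a time by
  random-walk Metropolis against the Poisson likelihood times the
  Gaussian `N(x_i' beta + o_i + u_i, sig2_e)` prior.  Proposal step
  sizes adapt toward 0.44 acceptance during burn-in only and are frozen
  afterwards, preserving detailed balance in the retained phase.
* Given the latents, the decomposition into `beta`, `u` and `e` is a
  Gaussian linear model, so `beta` (jointly with the parameter-expansion
  scalar) and `u` are redrawn from their exact conditionals.  `A` is
  eigendecomposed once per fit, making the `u` update diagonal in the
  rotated basis — each sweep costs O(n^2).
* Variances are inverse-Gamma Gibbs draws.  The phylogenetic variance
  uses parameter expansion: `u = alpha * eta` with
  `eta ~ N(0, sig2_eta A)`, `alpha ~ N(0, 25^2)` and
  `sig2_eta ~ IG(nu/2, nu V/2)` with `V = 1, nu = 1`, so
  `sig2_a = alpha^2 sig2_eta` gets a heavy-tailed scaled-F prior that
  mixes well near zero.  The residual variance prior is the conventional
  weakly-informative `V = 1, nu = 0.002`; fixed effects get
  `N(0, 1e10)`.  All priors are knobs of `prior_spec()`.

Default chain settings (`mcmc_settings()`) are 5e5 iterations, thinning
1e3, burn-in 5e4 — 450 retained samples — and on ~100-tip datasets the
mean effective sample size across parameters comfortably exceeds the
usual quality bar of 200 (fits warn when it does not).  ESS is estimated
by `N / (1 + 2 sum rho_k)` with Geyer's initial-positive-sequence
truncation, clipped to `[0, N]` (`compute_ess()`).

Numerical details worth knowing:

* Eigenvalues of `A` below 1e-8 are raised to 1e-8 (consensus trees with
  zero-length shared branches are numerically borderline); an eigenvalue
  below -1e-8 is an error naming the value.
* A non-finite latent aborts the chain with a diagnostic rather than
  returning garbage.
* `fit_mcmc()` can hold either variance fixed at any positive value
  (used by the validation suite to pin variances at 1e-4 and recover the
  plain Poisson-GLM solution).  Exactly zero is not supported: the
  latent decomposition degenerates there, and a separate sampler for
  that boundary case is not worth its complexity.
* One seed drives the whole chain; pipeline fits derive per-fit seeds by
  hashing `(tree id, model form, intercept mode)` with the base seed, so
  partial re-runs reproduce exactly.

## DIC and the decision rule

Model comparison uses DIC computed from the deviance *conditional on the
latent predictors* (`compute_dic()`): `Dbar` is the posterior mean of
`-2 log Poisson(y | exp(l))`, `Dhat` the deviance at the posterior-mean
latents, `pD = Dbar - Dhat`, `DIC = Dbar + pD`.  DIC variants for
hierarchical models differ in where they put the "focus"; the
conditional choice is standard when the marginal likelihood is
intractable.  Absolute DIC values are therefore implementation-specific,
while DIC *differences* between models fitted to the same data are the
meaningful quantity.

`classify_dic()` applies the decision rule: the best model is the
smallest DIC, and models within 4 units of it are indistinguishable.
One candidate gives an unambiguous winner; `{downturn, asymptote}`
together support some form of slowdown; and whenever the *null* model is
among the candidates, nothing is favoured — if the simplest model cannot
be told apart from the best one, claiming a slowdown would overreach.
This parsimony reading of ambiguous cases is deliberate (the obvious
alternative, breaking ties by parameter significance, systematically
favours the quadratic model because quadratic terms are almost always
"significant"); the threshold is a config value, and exact ties resolve
toward the simpler model so output is deterministic.

`run_pipeline()` drives everything: dates each topology, fits 3 models x
requested intercept modes per dated tree, classifies, writes per-fit
JSON sidecars (skipping fits whose sidecar already exists, so
interrupted ensembles resume), and tabulates category counts and
percentages per source tree and intercept mode (`summarize_outcomes()`).
`plan_fits()` reports the bookkeeping up front: e.g. 9 topologies dated
100 times plus 9 pre-dated trees is 909 dated trees and 2727 fits per
intercept mode.

## The synthetic data generator

`simulate_bd_tree()` grows forward-time birth-death trees with
per-lineage speciation rate `lambda0 * exp(-k t)` (clade age `t`, so
`k > 0` is a clade-wide temporal downturn — the hypothesis under test —
rather than a lineage-age effect) and constant extinction `mu`,
via thinning (the declining rate is bounded by its current value).
Extinct lineages are kept as fossil-style tips; the first split becomes
the root.  `generate_age_ranges()` wraps each true tip age in an
exponential-width stratigraphic interval (true age uniform within it,
clipped at 0 by shifting, never by shrinking), emulating ragged
occurrence-range precision.  `simulate_glmm_counts()` draws counts from
exactly the fitted model.

Variance components in the generator are interpreted against the
*depth-scaled* covariance (`scale_vcv = TRUE` by default): `sig2_a` is
then the latent variance of the deepest tip, directly comparable to
`sig2_e` and across trees of different ages, and values like 0.05-0.1
mean moderate phylogenetic signal.  Against raw Myr-unit covariances the
same numbers would imply latent noise with a standard deviation of
several log units on a 100-Myr tree — overwhelming any fixed effect —
so per-Myr variances of realistic analyses are orders of magnitude
smaller; the flag is exposed for that reading.

What the generator does *not* emulate: stratigraphically structured
sampling (fossilization pulses, FBD-style sampling-through-time),
correlated age-range widths, topological error in the input cladogram,
or trait-dependent rates.  Passing the validation suite therefore shows
the machinery is correct and the test has power against its own
generative assumptions — not that any empirical clade satisfies them.

## Validation suite and problem sizes

The package's tests validate each stage against independent brute-force
oracles (parent-pointer walks for node counts and distances,
path-intersection covariance, descendant-scan dating), closed forms
(Poisson split counts along traced lineages, AR(1) effective sample
size, prior moments under likelihood-free sampling, the Poisson-GLM
limit with pinned variances), and end-to-end statistical properties:
with 20 replicate datasets on a ~100-tip, 45-Myr tree
(`sig2_a = sig2_e = 0.1`), true coefficients fall inside their 95%
credible intervals in at least 18; with a quadratic downturn
(`beta = (0, 0.2, -0.002)`, `sig2 = 0.05`) planted on a 150-tip,
~110-Myr tree the downturn model beats the null by >= 4 DIC units in at
least 80% of replicates, while constant-rate data trips that criterion
in at most 20%.  The 110-Myr span matters: `0.2 t - 0.002 t^2` only
expresses its downturn over spans approaching the vertex at `t = 50`
and beyond, which is the natural scale of Mesozoic clades.  Validation
fits use shortened chains (4e4-6e4 iterations) whose ESS (~100-200) is
ample for interval and DIC checks; production defaults retain the full
5e5-iteration settings.

## Limitations

* Node counts respond to anything that changes apparent splitting rates
  along paths, including unresolved consensus regions and uneven taxon
  sampling; the model cannot distinguish these from true rate variation.
* DIC is computed at the latent level; its absolute values are not
  comparable across packages, and `pD` can occasionally be slightly
  negative by Monte-Carlo error on near-degenerate posteriors.
* Dating by oldest-descendant ages plus a minimum branch duration is a
  point protocol, not a posterior over trees; the ensemble spreads age
  uncertainty but not topological uncertainty.
* Prior-only sampling (a correctness diagnostic) mixes slowly when
  covariate lever arms are long; diffuse priors on deep trees make that
  mode impractical, which is a property of the parameterization, not of
  the fitted posteriors.
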