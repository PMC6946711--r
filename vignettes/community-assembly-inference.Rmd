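---
title: "Inferring community assembly processes from mycobiome tables"
author: "mycoassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes from mycobiome tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycoassembly)
```

## The inference problem

Fungal communities on a crop assemble through four processes: selection
(deterministic filtering by host compartment, development and environment),
dispersal, diversification (negligible within a season), and ecological
drift - the stochastic fluctuation of abundances that drives chance
extinction, strongest when communities are small. Telling drift apart from
the other processes in observational data is the hard part, because two of
the others also carry stochastic components.

This package implements the null-model strategy for that inference on OTU
abundance tables. Two indices are computed per pair of samples:

* **bNTI** (beta nearest taxon index): the z-score of the observed
  abundance-weighted beta mean nearest taxon distance (bMNTD) against a
  null in which tip labels are shuffled across the whole phylogeny.
  `bNTI <= -2` indicates phylogenetic clustering beyond chance
  (homogeneous selection), `bNTI >= 2` overdispersion (variable
  selection).
* **RCI** (Raup-Crick index): a quantile score in `[-1, 1]` comparing
  observed compositional similarity with null assemblages that preserve
  each sample's richness and draw taxa by occupancy frequency.
  `RCI <= -0.95` means ecological clustering without phylogenetic signal;
  `RCI >= 0.95` means more turnover than chance (dispersal limitation).

Pairs with `|bNTI| < 2` and `|RCI| < 0.95` are *stochastic, undominated*:
neither selection nor dispersal dominates, and the remaining explanation is
drift plus stochastic colonisation. The fraction of such pairs per
compartment-week-treatment group, regressed on community size with a
compartment random intercept, is the drift test: drift predicts a negative
size-stochasticity relationship.

A complementary question is whether different communities share *universal*
ecological dynamics. The dissimilarity-overlap curve (DOC) plots, for every
sample pair, the root Jensen-Shannon divergence of the two compositions
renormalised over their shared taxa against the overlap (the mean total
abundance invested in shared taxa). A negative slope at high overlap -
communities that share more taxa being more similar on those taxa - supports
universal dynamics; the fraction of pairs beyond the change point is `Fns`.

## The synthetic generator as ground truth

Because field-scale amplicon data require a sequencing pipeline upstream of
any statistics, the package validates its inference on simulated communities
whose assembly process is known. The generator mirrors a sorghum-like field
study: up to four compartments (leaf, root, rhizosphere, soil), weekly time
points 0-17, three irrigation treatments, and replicate plots, with a
deterministic child seed per design cell so any subset reproduces alone.

* **Metacommunity.** `S` taxa with lognormal relative abundances
  (`lognormalSigma = 1` by default; fungal OTU inventories are strongly
  uneven). A synthetic ranked taxonomy (about `S/3` genera with lognormally
  skewed sizes, `S/6` families, nested orders/classes/phyla) is converted
  to a cladogram with one unit-length edge per rank - the same construction
  applied to real ranked lineages, where only relative patristic distances
  matter because bNTI standardises against a null.
* **Traits.** Brownian motion along the cladogram with a depth-dependent
  rate: 30 per unit branch at the root, decaying geometrically (factor 0.3
  per level) and suppressed a hundredfold below the family rank. The result
  is phylogenetic niche conservatism: genera within a family are
  functionally near-identical while families and higher clades differ
  strongly. This is a deliberate design choice, not a neutral default. With
  a uniform Brownian rate, Gaussian selection either fixes a single winner
  in every replicate (and a pair of one-taxon communities has so wide a
  tip-shuffle null that `bNTI <= -2` is unreachable) or retains a broad
  trait band with no phylogenetic structure; a scale-free geometric decay
  without the conservation floor instead produces chance trait convergence
  between distant clades. Niche conservatism at clade level is also the
  documented assumption under which nearest-taxon metrics carry information
  about selection in the first place, so the generator emulates the regime
  the method is designed for.
* **Assembly.** Each replicate is seeded by one multinomial draw of `N`
  individuals from the pool and updated for `generations` Wright-Fisher
  steps: resampling weights are `(1 - m) x local + m x metacommunity`,
  multiplied by `exp(-s (trait - optimum)^2)` under selection. Homogeneous
  selection shares one optimum across replicates (by default the trait of
  one abundance-weighted random pool taxon - selection favours a clade, not
  the pool average); variable selection draws per-plot optima. Dispersal
  limitation seeds each replicate from its own uniform random 10% pool
  subset and sets `m = 0`; homogenizing dispersal exchanges migrants among
  replicates at rate `m` instead of immigrating from the pool.

What the generator does *not* emulate: sequencing noise (primer bias,
chimeras, read-depth variation beyond multinomial sampling), spatial
autocorrelation between plots, temporal autocorrelation of the same plot
across weeks, and taxa entering mid-season. Passing recovery tests on these
simulations therefore shows the inference machinery is correct and
well-calibrated under its own assumptions - not that field data meet those
assumptions.

## A worked run

```{r example, eval = FALSE}
meta <- sampleMetacommunity(200, lognormalSigma = 1, seed = 1)
design <- fieldDesign(compartments = "leaf", weeks = 1L,
                      treatments = "control", replicates = 12,
                      scenario = assemblyScenario("drift", N = 50,
                                                  generations = 50,
                                                  m = 0.1), seed = 1)
sim <- simulateFieldDesign(design, meta)
b <- bNTI(sim$table, meta@tree, reps = 999, seed = 501)
r <- raupCrick(sim$table, reps = 999, seed = 601)
classifyProcesses(b, r)$summary
```

On this drift-only cell, 88% of the 66 within-group pairs fall in the
stochastic class; rerunning with `homogeneous_selection` (`s = 100`) pushes
79% of pairs to `bNTI <= -2` instead.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `reps` (bNTI/RCI) | 999 | null replicates; score resolution is `2/reps` for RCI |
| `weighted` (bMNTD) | `TRUE` | abundance-weight nearest-taxon terms |
| RCI `variant` | `presence_occupancy` | Chase-style presence null; `abundance_bray` preserves totals and compares Bray-Curtis |
| `branchLengthPerRank` | 1 | cladogram edge length; bNTI is invariant to its scale |
| rarefaction `depth` | - | 362 mirrors the smallest library in the motivating design |
| CLR `zeroMethod` | `min_fraction_multiplicative` | half the minimum observed proportion; exactly scale-invariant (the count-based CZM prior `0.5/total` is available but breaks exact perturbation invariance on zero cells) |
| DOC `span` | 0.2 | lowess span; the method cited for the DOC publishes no smoothing constant |
| DOC `bootstrapReps` | 1000 | sample-level bootstrap for the change point |
| network `rThreshold`, `phiThreshold` | 0.8, 0.1 | co-abundance edge rule `r > 0.8` and `phi < 0.1` |
| forest `numTrees` | 500 | regression forest size for the age-delay protocol |

Null replicate counts, smoothing spans and thresholds are deliberately
explicit arguments: every randomised routine takes a `seed` and is exactly
reproducible.

## Numerical and design choices

* **Sequential PERMANOVA** partitions the Gower-centred matrix in the order
  terms are given (the classic `adonis` convention); order sensitivity is
  real and surfaced by the output. Permutation p-values are
  `(b + 1) / (m + 1)`, never zero, and an explicit permutation matrix can
  be supplied for complete enumeration on small designs.
* **Degenerate nulls.** When the bNTI null standard deviation falls below
  1e-12 (a star phylogeny, or two samples whose presence sets coincide),
  the pair is flagged and classified on RCI alone. RCI pairs with constant
  nulls keep their quantile score but carry the same flag.
* **DOC bootstrap** resamples *samples*, not pairs, because pairs sharing a
  sample are dependent; self-pairs created by resampled duplicates are
  dropped. The change point of one curve is the smallest overlap from which
  the fitted slope stays negative through the maximum overlap; the
  reported change point is the bootstrap median, and significance requires
  95% of bootstrap curves to end with a negative slope. Near-tied overlap
  values are merged on the fitted grid before slopes are taken, which
  avoids spurious near-infinite slopes between floating-point twins.
* **Raup-Crick power.** With fully exchangeable replicates the
  occupancy-preserving null is almost unbiased for random-subset dispersal
  limitation, so absolute `RCI >= 0.95` calls need structure (shared local
  pools, regional contrast) in the data; the package's tests therefore
  check *elevation* of RCI under dispersal limitation against a matched
  drift baseline.
* **Unknown ranks** truncate a lineage at the first unresolved rank; the
  tip attaches below its deepest known rank, avoiding zero-information
  one-child chains.
* **Mixed model R-squared** follows the Nakagawa decomposition computed
  directly from the `lme4` variance components; with a zero random
  intercept variance the conditional and marginal values coincide.
* **Age-delay protocol.** The 50/50 control split is stratified by week;
  feature count for the sparse forest is chosen by out-of-bag error over a
  small grid (5, 10, 20, 40, all) when `topK = "cv_select"`.

## Problem sizes used in the packaged checks

The packaged validation runs use a 200-taxon metacommunity with 12
replicates per cell and 999 null replicates for single-cell process
recovery; the size-stochasticity analysis uses a 4-compartment by 5-size
grid (N in 10...1000, 10 replicates, 299 null replicates per cell); the DOC
false-positive check uses 20 independent drift data sets of 15 samples with
200 bootstrap curves each. These sizes give stable fractions while keeping
a full run in the order of minutes on one core.

## Known limitations

* The process classification is the threshold scheme on (bNTI, RCI) pairs;
  no per-taxon quantitative partitioning of process contributions is
  attempted.
* bNTI on a ranked-taxonomy cladogram inherits the taxonomy's resolution:
  selection acting strictly within genera is invisible, since congeners are
  equidistant.
* The blue class (`|bNTI| < 2`, `RCI <= -0.95`) is intrinsically ambiguous
  between homogeneous selection and homogenizing dispersal; the package
  reports it as `selection_or_dispersal_ambiguous` and leaves the
  ecological argument (e.g. observed strong host effects) to the analyst.
* DOC significance is a bootstrap criterion on the terminal slope; it does
  not identify *which* shared dynamics produce the negative slope.
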