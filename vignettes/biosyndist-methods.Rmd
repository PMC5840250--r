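---
title: "Biosynthetically informed distances: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biosynthetically informed distances: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biosyndist)
```

## The model

A secondary-metabolite profile is a vector of quantities over compounds.
Compounds are not independent variables: a plant that emits limonene almost
certainly runs the full MEP pathway and is one terminal synthase away from
emitting α-pinene, whereas indole requires a disjoint enzymatic route.
`biosyndist` encodes this dependence as a tree and measures sample
differences through the tree's branch lengths, the same device UniFrac uses
for microbial communities over a phylogeny: where UniFrac reads "shared
evolutionary history" off a phylogeny, we read "shared biosynthetic
machinery" off a dendrogram of enzyme overlap.

The pipeline in `biosyn_dist()` has three stages.

**Compound dissimilarity.** For compounds $X$, $Y$ with feature sets (enzyme
complements) of sizes $|X| = a + b$, $|Y| = a + c$ and $a$ shared features,
the Sørensen dissimilarity is
$$ d_{XY} \;=\; 1 - \frac{2a}{2a + b + c} \in [0, 1]. $$
It is 0 exactly for identical feature sets — which really happens, because
multi-product enzymes such as a pinene synthase make several compounds with
one annotation row — and 1 exactly for disjoint pathways. Features are
binary; using an enzyme twice in a route is not modelled, matching how
enzyme annotations are compiled in practice.

**Biosynthesis tree.** The Sørensen matrix is clustered
(`stats::hclust`) and the dendrogram converted to a rooted ultrametric
`"phylo"` tree. Internal nodes sit at `height_scale` × merge height; with
the default `height_scale = 0.5` the tip-to-tip path length equals the
cophenetic merge height, so the tree reproduces the clustering metric
exactly. Because the UniFrac ratio is invariant under uniform rescaling of
all branch lengths (numerator and denominator are both linear in the edge
lengths — the suite verifies this to 1e-12), `height_scale` is purely
presentational.

**Sample distance.** Each sample is normalised to proportions (absolute
quantities and presence/absence are therefore equally acceptable inputs),
each edge $i$ carries the proportion $p_i^S$ of sample $S$ descending from
it, and
$$ d_{A,B} \;=\;
  \frac{\sum_i b_i\,(p_i^A + p_i^B)^{\alpha}\,
        \bigl|p_i^A - p_i^B\bigr| / (p_i^A + p_i^B)}
       {\sum_i b_i\,(p_i^A + p_i^B)^{\alpha}} , $$
summing over edges with $p_i^A + p_i^B > 0$ (the $0/0$ edge convention of
the generalized form: unoccupied lineages contribute to neither sum).

## Tunable parameters

* **`alpha`** (dimensionless, in $[0,1]$, default **0.5**): the exponent on
  the combined proportion. $\alpha = 1$ is classical weighted UniFrac, fully
  abundance-weighted; small $\alpha$ flattens abundance differences. The
  half-power default gives neither dominant nor trace compounds excessive
  weight, the balanced setting recommended for generalized UniFrac; the
  suite checks that results vary continuously in $\alpha$ and that
  $\alpha = 1$ matches an independently coded classical form.
* **`linkage`** (default **complete**): the clustering rule. Complete
  linkage is the `stats::hclust` default and keeps cross-pathway compounds
  maximally separated until the final merges; average/single/Ward are
  exposed because the choice is genuinely open — changing it changes branch
  lengths and hence distances, so it should be reported with results.
  Tie-breaking between equal-height merge candidates follows `hclust`'s
  deterministic, input-order-dependent rule; given a fixed input ordering,
  results are reproducible across platforms.
* **`height_scale`** (tree units per merge-height unit, default **0.5**):
  see above; provably inconsequential downstream.
* **`w`** (dimensionless, in $[0,1]$, default **0.878** in `merge_dist()`):
  the fusion weight $mDist = w\,\cdot$BioSynDist$' + (1-w)\,\cdot$Dist$'$,
  where $'$ is `standardize_dist()` ($d' = d/\max d$; applied inside every
  call, so the operation is idempotent). The default is a starting point
  only — it is the optimum for one particular worked dataset, not a law;
  `scan_weight()` re-derives the optimum for any dataset on an inclusive
  grid (step 0.001, fine enough to resolve a third decimal; ties break
  toward smaller $w$, i.e. toward the conventional measure).
* **`n_perm`** (default **999**) and **`seed`**: all permutation p-values
  use the add-one estimator $p = (\#\{r_{perm} \ge r_{obs}\} + 1)/(n_{perm}+1)$,
  never exactly zero; 999 permutations resolve $p = 0.001$.
* **NMDS**: monotone stress-1 NMDS via `vegan::metaMDS` with 20 random
  starts by default; the species-fit $r^2 = 1 - SS_{within}/SS_{total}$ on
  the ordination coordinates is the conventional factor goodness of fit.

## Numerical choices and degenerate inputs

* Zero-height merges (identical feature sets) produce zero-length edges with
  distinct tips; all downstream code tolerates them.
* A tree whose edges are all zero (every compound identical) cannot support
  UniFrac and is rejected rather than returning 0/0.
* Compounds present in the sample table but missing from the feature table
  are a hard error by default; `missing_compounds = "drop"` removes them
  with a warning, because silently dropping mass would change distances
  invisibly.
* Distance standardization of an all-zero matrix, Mantel tests against a
  constant matrix, and factor fits with a single group are errors, not NaNs.
* Blank cells in a sample CSV are absences (0); blank cells in a feature
  CSV are errors — presence/absence must be asserted.
* Newick output single-quotes labels containing syntax characters
  (`(E)-β-ocimene`, `2,3-butanediol`), doubling embedded quotes, so
  round-trips through external parsers preserve names verbatim.

## The synthetic datasets

The package generates its own test data; no download is required.

`make_hypothetical_dataset()` is a fixed 13 × 13 design: five monoterpenes
(two of them products of the same synthase, one differing only in its
terminal enzyme), five aromatics, three fatty-acid derivatives; per pathway
a shared enzyme backbone (8/6/3 enzymes) plus one terminal enzyme per
compound, and no enzymes shared across pathways. The profile pairs are
constructed to exhibit the qualitative situations where a biosynthetic
measure must disagree with Bray–Curtis: (C,D) same pathways with disjoint
compound sets, (E,F) a multi-product-enzyme swap, (G,H) one-third compound
overlap within a pathway, and (I–L) identical compound sets at shuffled
quantities, with the quantitative variation kept mostly inside the
monoterpene clade so that it is quantitative, not biosynthetic, variation.
The quantities themselves are round numbers chosen for legibility; what the
fixture fixes is the structure and the direction of each contrast, and the
suite asserts exactly those orderings on standardized matrices.

`make_two_species_dataset(seed, n_per_species = 9)` simulates a two-species
floral-scent comparison over 40 compounds partitioned 25/4/11
(exclusive-A / exclusive-B / shared). Design choices, fixed once:

* Pathway layout: the shared pool is monoterpene-heavy and species A
  additionally carries a six-compound sesquiterpene (MVA) block the other
  species lacks — the typical picture for an Asteraceae vs Brassicaceae
  pair, and the structural reason the two species differ *biosynthetically*
  and not merely in compound identity.
* Abundances are log-normal around per-compound means (`sdlog` 0.8 within
  samples, 0.7 across compounds); the shared monoterpenes and each species'
  characteristic exclusive block sit among the dominant compounds, so both
  bouquets are monoterpene-dominated while remaining species-diagnostic.
* Detection probability rises with mean abundance (0.4–0.98): dominant
  compounds occur in every sample, trace compounds sporadically, which is
  how chromatographic detection behaves.
* Every compound is forced into at least one sample of each species that
  emits it, so the 40/25/4/11 bookkeeping is exact by construction, for
  every seed.

What these generators do **not** emulate: real enzyme annotations (counts
and overlaps are stylised), correlated pathway regulation, measurement error
structure of chromatography, and between-individual covariance. Passing
tests therefore demonstrate the algebraic and statistical behaviour of the
measures on realistically *shaped* data, not agreement with any particular
published dataset.

## What the checks compute

The test suite validates every stage against independent oracles: UniFrac
against a brute-force edge enumeration on random trees of up to 8 tips
(agreement to 1e-10), Sørensen against `vegan::vegdist` and a direct
set-formula, cophenetic distances against path sums, the Mantel p-value
against exhaustive enumeration of all 24 permutations at $n = 4$, and the
factor fit against `vegan::envfit` and a closed-form variance ratio. On the
built-in datasets, the end-to-end checks run with 13 hypothetical profiles,
the 1001-point weight scan, and an 18-sample two-species simulation with
999-permutation tests and 20-start NMDS — sizes chosen so the whole suite
executes in well under a minute while still exercising every code path.
The species-fit $r^2$ is asserted only as a stability band across seeded
NMDS restarts, since ordination configurations are not unique.

## Known limitations

* The distance inherits every limitation of the feature annotation: coarse
  or partly postulated enzyme lists flatten the tree. The class-based
  variant plus Bray–Curtis fusion is the designed fallback, and the scanned
  optimal $w$ is dataset-specific.
* The dendrogram is a hierarchical summary of enzyme overlap, not a true
  metabolic network; shared intermediates between pathways (e.g. terpenoid
  precursors feeding both mono- and sesquiterpenes through different
  compartments) are only represented insofar as the annotation lists shared
  enzymes.
* For questions where receivers respond to individual compounds rather than
  to biosynthetic machinery — most behavioural work — a conventional
  measure remains the right tool; the biosynthetic distance answers
  questions about enzymatic equipment, chemotaxonomy and evolution.
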