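---
title: "Methods: co-occurrence webs and phi specialization in a broken-stick design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence webs and phi specialization in a broken-stick design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeweb)
```

## The design and why subsampling is needed

A broken-stick planting design recursively halves a pool of 16 tree
species into communities of 8, 4, 2 and 1 species: 16 monocultures, 8
two-species plots, 4 four-species, 2 eight-species and 1 sixteen-species
plot (31 plots). Five soil samples are collected per tree species per plot,
so sampling effort per plot *increases* with diversity while plot number
*decreases*. Comparing diversity levels on the raw data would confound
diversity with replication. The remedy implemented here: the 4-, 8- and
16-species plots are pooled into one "high diversity" class (7 plots,
matching the 8 two-species and 16 monoculture plots in order of magnitude),
and every analysis is run on balanced *subsampling combinations* of 7 tree
species and 7 plots per class, one species sampled per plot.

Enumeration is driven by the two-species level: all choices of 7 of the 8
two-species plots and one planted species per chosen plot. Because the
two-species plots partition the pool, each choice yields 7 distinct
species; their monocultures are then forced, and the high-diversity cells
are a perfect matching of the 7 species onto the 7 high-diversity plots
containing them. This gives 8 × 2⁷ = 1024 combinations, or 576 when one
species must be excluded — the realistic situation when a planted species
largely fails to establish. Both counts, and the 128 arising when two co-planted species
are excluded, are verified against brute-force enumeration in the tests.

Two choices here were genuinely open:

* **High-plot assignment.** Nothing fixes *which* high-diversity plot each
  species is sampled from when several matchings exist. We use the
  deterministic lexicographically smallest perfect matching (species in
  order, each taking the smallest feasible plot id subject to the rest
  remaining matchable, via augmenting-path maximum matching). Determinism
  makes enumeration identical across runs and platforms; a Hall-condition
  argument shows a matching always exists in the intact broken-stick
  design, so no combinations are silently lost.
* **Pool generality.** The machinery accepts any power-of-2 pool ≥ 8 with
  k = n/2 − 1 plots and species per level; n = 16 reproduces the 7/7
  scheme. This lets the fast 8-species test preset exercise the identical
  code path.

## Preprocessing

Fixed order, matching standard amplicon practice: (1) OTUs with total
count ≤ 3 (singletons–tripletons) are discarded from the raw table; (2)
samples are rarefied to 700 reads by uniform subsampling without
replacement — samples under depth are dropped (a flag keeps them
unrarefied instead; the dropping rule keeps column sums uniform); (3) OTUs
with fewer than 10 reads in the rarefied table are pruned; (4) counts
become incidence (presence/absence). Rarefaction draws one subsample per
sample from a per-sample RNG stream derived from the sample id plus the
global seed, so results are invariant to column order; the hypergeometric
expectation of the draw is verified empirically in the tests.

## Webs and network statistics

For one combination, level and threshold t ∈ 1..5, the web links tree
species s to OTU f when f is present in ≥ t of the 5 samples of s's cell;
OTU columns with no links are dropped (the reported "OTUs in network" is
therefore post-drop). Statistics per web:

* connectance L/(I·J);
* generality as the link-weighted (Bersier-type) mean of effective
  partner numbers, Σd²/L for binary webs — with 7 trees and connectance
  near 0.2 this sits near 2, the magnitude the unweighted mean degree
  (≈ 1.5) cannot reach;
* Stone–Roberts C score with per-pair normalization by r_f·r_g, bounding
  it in [0, 1] (1 = full segregation);
* NODF with strict decreasing fill — ties contribute zero — and a single
  mean over all row and column pairs; the implementation agrees with
  vegan's `nestednodf` to 1e-10 on random webs and is permutation
  invariant because sorting is internal;
* Barber bipartite modularity maximized by label propagation: random
  initial row partitions, alternating Q-optimal reassignment of each
  side's labels, greedy merging of module pairs with the largest positive
  gain, and propagation/agglomeration repeated until Q stabilizes; the
  best of 20 seeded restarts is kept. A node whose best affinity is
  negative stays in its own module, so a complete web yields Q = 0 with
  one module and m equal disjoint complete blocks yield Q = 1 − 1/m. On
  webs small enough for exhaustive search (row set-partitions with
  per-column optimal assignment — Q is column-separable given the row
  partition) the optimizer attains the exact optimum in the test suite;
* pooled alpha diversity over the level's 35 samples: richness and
  Shannon entropy (natural log) on pooled rarefied counts.

Differences between diversity levels are assessed with the tie-corrected
Kruskal–Wallis test across the combination values, with Siegel–Castellan
mean-rank post hoc comparisons. Both plain Bonferroni and step-down Holm
corrections are available ("Bonferroni–Holm" is the reading we adopt of
the hyphenated correction name conventional in this literature); Holm is
the reporting default. P-values below 1e-15 are formatted as "<1e-15".

## Null model

The post-preprocessing count table is shuffled *before* division into
subsets, holding all row and column sums fixed (Patefield's algorithm, via
base R's `r2dtable`; a single-row or single-column table is forced by its
margins and returned unchanged). The identical downstream pipeline then
recomputes NODF per combination, and observed and null NODF distributions
are compared by two-sample Wilcoxon rank-sum (exact by enumeration for
n ≤ 12 without ties, otherwise normal approximation with tie and
continuity corrections). The number of null replicates behind the original
tables is not documented; one replicate per run is the default with a
`reps` option. Pairing is likewise unstated; the unpaired test is used.

## Phi specialization

Within one combination and level, an OTU is present in a plot when it
occurs in ≥ 1 of the plot's 5 samples (`presence_min`, exposed for
sensitivity analysis; the link threshold t plays no role here). For each
OTU present somewhere and each of the 7 species: a = presence in the
species' plot (0/1), b = presences among the other 6 plots, c = 1 − a,
d = 6 − b, and phi = (ad − bc)/√((a+b)(c+d)(a+c)(b+d)), which equals
± √(X²/N). A zero margin (e.g. an OTU in all 7 plots) leaves phi
undefined; undefined values are excluded from medians and group tests.
Per combination the specialization summary is the median of the strictly
positive phi values. Guild contrasts run Kruskal–Wallis with Bonferroni
post hoc on positive phi; the top-200 specialists (maximum phi per OTU,
ties broken by id) are arranged by average-linkage hierarchical clustering
on Euclidean distances (the distance is conventional here; the linkage was
open and average linkage is the robust default). An OTU is *frequent* at a
level if some combination finds it in all 7 plots; occupancy is evaluated
within level (7 plots), matching the per-level reporting of the analysis,
not pooled across levels.

## The synthetic generator

`generate_design()` builds a random nested halving of the pool (the true
species-to-plot assignment of the original experiment is unpublished) and
emits 5 sample records per cell — 400 samples for 16 species, or 394 with
`drop_samples = 6`, emulating the six samples lost to the failing species
(drops are spread across that species' plots, highest replicate first, so
no cell is emptied). `generate_counts()` plants occurrence structure:

* every OTU has an activity rate `p_focal` (default 0.5), its per-sample
  presence probability where it thrives;
* *generalists* thrive everywhere; *specialists* (default 30% of OTUs)
  thrive only in plots containing their preferred species and are
  suppressed to `p_bg` (default 0.05) elsewhere.

This asymmetry is deliberate. A positive phi record's value depends only
on the OTU's plot occupancy m (since a ∈ {0, 1}), and decreases in m.
Ecologically a generalist is a *broadly occurring* organism; modeling
generalists as sparse background noise would give them the *lowest*
occupancy and hence the highest phi, inverting the planted signal. With
broadly occurring generalists, specialists concentrate on few plots and
carry the high phi values, and the null configuration `p_focal == p_bg`
makes the two groups exactly exchangeable — the property the calibration
tests rely on. Defaults give a 10-fold enrichment; rates much above ~0.7
push generalists into all 7 plots, where phi is undefined and group
comparisons degenerate.

Conditional on presence, abundance is 1 + negative binomial scaled by a
lognormal per-OTU parameter, and each sample is multinomially resampled to
a depth uniform on [700, 3000] — zero-inflated occurrence is what the webs
and phi detect; abundance matters only through rarefaction survival, and
resampling preserves the support direction. Guild labels follow the
observed community composition (31% saprotroph, 7% EcM, 5% AM, 5%
pathogen, 46% unknown, 6% other).

What the generator does *not* emulate: spatial autocorrelation, soil
covariates, dispersal limitation, within-plot sample heterogeneity beyond
Bernoulli noise, taxonomic abundance distributions of real communities,
and niche overlap between co-planted species (the feature that would be
needed to reproduce a monoculture > high > two-species ordering of median
phi by construction). Passing tests therefore demonstrate correctness of
the machinery and recoverability of occurrence-based specialization — not
that real soil communities satisfy the model. No level ordering is
hard-coded anywhere: on the null preset the pipeline's level contrasts
stay near their nominal behavior.

## Problem sizes and numerical choices

The test suite and acceptance script run entirely on generated data: the
8-species preset (15 plots, 160 samples, 200 OTUs, 32 combinations) for
end-to-end checks, the 16-species study-shaped preset (31 plots, 394
samples, 2000 OTUs) with 200 combinations at threshold 3/5 for pipeline
medians, 50 communities of 300 OTUs for the specialist-recovery
experiment, 10,000 simulations for Kruskal–Wallis type-I calibration and
Patefield uniformity — sizes chosen so the whole validation completes in
minutes on one core while keeping Monte-Carlo error well inside the
asserted tolerances. Other conventions: all label matching is exact and
case-sensitive; result TSVs serialize numerics at 6 significant digits so
repeated writes are byte-identical; combination ids are 0-based in sorted
(plot ids, species) order so results join across modules; seeds split
hierarchically (master → stage → per-combination) and are recorded in the
run manifest; modularity comparisons use a 1e-12 improvement tolerance to
keep the greedy merge deterministic.

## Known limitations

* The modularity optimizer is a stochastic heuristic; on large webs the
  reported Q is a lower bound on the optimum (restarts trade time for
  tightness).
* One Patefield replicate per run understates null-distribution spread;
  raise `reps` for inference-grade null comparisons.
* Rarefaction is a single draw; multiple-rarefaction averaging and
  alternative normalizations are out of scope.
* Webs are binary by design; weighted variants (quantitative generality,
  weighted NODF) are not provided.
* The BIOM reader requires the optional biomformat package and is
  read-only; TSV is the canonical interchange format.
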