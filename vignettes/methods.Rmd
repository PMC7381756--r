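---
title: "Methods: phylogenetic structure and composition of two-habitat communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic structure and composition of two-habitat communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrubphylo)
```

## The analysis in one paragraph

Given a rooted phylogeny with branch lengths and a site-by-species
presence/absence table split across two habitats, the pipeline computes per
site: species richness (SR), Faith's phylogenetic diversity (PD), and the
standardized structure indices NRI and NTI under a richness-preserving null
model; ordinates the phylogeny-weighted composition of the sites (PCPS);
and then contrasts habitats (Wilcoxon rank-sum), tests mean NRI/NTI against
zero (one-sample t), correlates diversity and structure with environmental
covariates (Pearson), and partitions the variation in PD among three
mean-annual-temperature anomalies (adjusted-R² inclusion-exclusion).

## Model and assumptions

**Incidence is canonical.** The sampling design records which species occur
at a site (the union of subplots), not how abundant they are, so all
metrics are unweighted. Abundance inputs are accepted but binarized with a
warning.

**The species pool is the site union.** Null communities are drawn from the
set of species observed anywhere in the study, each species with equal
probability, keeping the focal site's richness. This is deliberately the
plain "richness" null rather than an occupancy-weighted or matrix-swap
null: it answers "are these species more related than a random draw of the
same size from the regional list?", and it is what the index definitions
above assume. Swap-type nulls that preserve species occupancy frequencies
would be the natural robustness check and are out of scope.

**Sign convention.** Both indices are *negated* standardized effect sizes:
`NRI = -(MPD_obs - mean(MPD_null))/SD(MPD_null)`, likewise NTI with MNTD.
Positive values indicate clustering (co-occurring species closer on the
tree than expected), negative values overdispersion. NRI is driven by deep
tree structure, NTI by terminal structure; the two need not agree, and
`MNTD <= MPD` does **not** hold in general, so the code never assumes it.

**One set of draws, two metrics.** For each site the same 999 null
communities feed both the MPD and the MNTD ensembles. Marginally each index
has exactly the distribution it would have with independent randomizations;
only the (never-used) joint distribution differs. This halves the dominant
cost of the pipeline.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_null` | 999 | draws | conventional size; quantile resolution 1/1000 |
| `alpha` | 0.05 | — | one-tailed, in the direction of the observed sign |
| `include_root` | `TRUE` | — | PD of the whole pool then equals total tree length |
| PCoA distance | `sqrt_bray` | — | rows of P are compositional; the square root makes Bray-Curtis near-Euclidean |
| graft rule | MRCA of congeners | branch-length units | see below |

Significance of a site's structure is read off the null quantile
one-tailed: a clustered site (index > 0) is significant when its observed
distance falls at or below the `alpha` quantile of the nulls, an
overdispersed site when it falls at or above `1 - alpha`. The quantile uses
midranks for ties and the `(r + 1)/(n + 1)` convention so it never reaches
0 or 1. An index of exactly 0 tie-breaks to "overdispersed_ns".

## Megatree pruning and grafting

Study species are matched to tree tips case-insensitively after replacing
spaces with underscores. Pruning collapses degree-2 nodes and sums their
branch lengths, so patristic distances among retained species are conserved
exactly (tested to 1e-9). A species absent from the reference tree whose
genus has tips is grafted as a polytomy child of the most recent common
ancestor (MRCA) of its congeners, with pendant length equal to the mean
path length from that MRCA to the congener tips — this places the new tip
at the typical depth of its relatives without assuming the tree is
ultrametric. Two boundary cases the rule itself does not fix:

* *one congener*: the MRCA of a single tip is that tip, and hanging a child
  under a tip would create a zero-length cherry; instead the new species is
  attached at the congener's parent with the congener's own pendant length,
  so the pair sit at the same depth;
* *no congeners*: the species is dropped and reported (status `dropped` in
  the pruning report); the pipeline aborts if any study species ends up
  unresolved, because silently losing species would bias PD and the pool.

Zero-length branches are legal (reference megatrees contain them), so tied
distances are expected and handled throughout.

## PCPS: construction and numerical choices

From the cophenetic matrix, similarities `s = 1 - d/d_max` are standardized
by **row** to give the fuzzy weights Q (each species' unit incidence is
spread over its relatives). The source framework is ambiguous about the
standardization orientation; row standardization keeps Q row-stochastic so
that P = W'Q (W' the row-normalized incidence) is row-stochastic too —
every site remains a composition summing to 1, which is what the
Bray-Curtis dissimilarity then expects. Both rows of Q and rows of P are
tested to sum to 1 within 1e-12.

The principal coordinates step is the classical Gower procedure: square the
dissimilarities, double-center, eigendecompose; scores are eigenvectors
scaled by the square root of their eigenvalues. Axes with eigenvalues at or
below `1e-10 * max(eigenvalue)` are discarded (square-root Bray-Curtis can
still produce small negative eigenvalues; they carry no usable geometry),
and axis percentages are taken over the retained positive eigenvalues.
Because eigenvectors are sign-arbitrary, each axis is flipped, if needed,
so the lexicographically smallest site id scores non-negatively; outputs
are therefore reproducible across runs and site orderings.

Species scores are P-weighted averages of site scores; clade centroids are
unweighted means of their member species' scores, matching the spider-plot
convention. The clade map is supplied as data (species → clade), not
inferred from the tree, except in the synthetic generator where three
pseudo-clades are cut at the deepest splits.

## Statistical layer

*Wilcoxon rank-sum*: exact two-sided p by full enumeration of rank
assignments when the pooled sample size is at most 16 and there are no
ties (the 16 is our threshold; enumeration is `choose(16, 8) = 12870`
cases at worst), otherwise a normal approximation with tie correction and
continuity correction. The suite checks both paths against
`stats::wilcox.test` and the exact `pwilcox` distribution.

*Variation partitioning*: adjusted R² by default (raw available via a
flag). Adjusted R² is the standard choice because raw R² inflates shared
fractions with predictor count; negative fractions are a known consequence
and are reported as-is, never clipped. The seven fractions are obtained by
inclusion-exclusion over the seven OLS submodels and satisfy
`sum(fractions) = R²_adj(full)` to 1e-10 by construction; the suite also
cross-checks against `vegan::varpart`.

*Degenerate inputs*: a site equal to the whole pool has zero null SD and
gets an undefined index (logged); single-species sites get undefined
MPD/MNTD and are excluded from tallies with a note; identical samples give
Wilcoxon p = 1; constant vectors are errors for t and correlation.

## The synthetic generator: what it emulates, and what it does not

The generator is a stated world mirroring the motivating study's shape:

* a 285-species pool on a pure-birth tree (rate 1, so expected depth
  `sum_{k=2..285} 1/k ≈ 5.20`);
* 20 "desert" and 41 "alpine" sites with per-site richness
  `2 + Poisson(mean - 2)` around means 12.35 and 33.39;
* assembly by a sequential kernel: after a uniform (or seeded) first
  species, species *j* joins with probability proportional to
  `exp(-λ · mean distance to current members)`. λ = +3 (desert) clusters,
  λ = -3 (alpine) overdisperses, λ = 0 is exactly the uniform null. The
  exponential kernel is a choice of convenience — any monotone kernel
  produces the same qualitative regimes — made for its single
  interpretable strength parameter;
* desert sites are seeded from the largest pseudo-clade with probability
  0.9, emulating the eudicot-dominated desert communities, which is what
  makes PCPS axis 1 separate habitats;
* environmental covariates are per-habitat Gaussians chosen as realistic
  values for a high-plateau desert/alpine contrast (e.g. MAT 7.5 ± 1.2 vs
  1.0 ± 1.5 °C; MAP 150 ± 30 vs 420 ± 60 mm; the current-minus-LGM anomaly
  4.5 ± 0.5 vs 6.2 ± 0.6 °C, larger in the alpine habitat), with
  `Anomaly3 = Anomaly2 - Anomaly1 + N(0, 0.1)` because the three periods
  satisfy that identity physically.

Two deliberate artificialities. First, covariates are independent of
assembly *given habitat*: correlations between, say, NRI and temperature
arise only through the habitat contrast, mimicking the confounding inherent
in the observational design — a green correlation test therefore
establishes the plumbing, not any causal structure. Second, the few species
that assembly never draws are parked in one random alpine site each so the
observed pool equals the full 285; this perturbs at most a handful of
occurrences but guarantees the pool-size contract. The generator does not
emulate spatial autocorrelation, dispersal limitation, occupancy-frequency
structure (all species are equally common a priori), or trait evolution.

## Reproducibility

Every stochastic step takes a seed. Per-site null ensembles are seeded with
a hash of the global seed and the site id, so per-site results are
identical regardless of processing order or subsetting; the test suite
asserts byte-identical pipeline outputs across reruns. All seeds stay below
2^31.

Null-model calibration is verified on uniformly assembled communities
(pool 100, 999 nulls): mean NRI/NTI within ±0.1, SD within [0.85, 1.15],
and each 5% tail flagged at 5% ± 2%. The check uses 400 sites — the stated
invariant is "at least 200", and at 400 the binomial Monte-Carlo error of a
tail fraction (≈1.1%) sits comfortably inside the ±2% band; this was fixed
a priori, not tuned.

## Known limitations

* Only the richness null is implemented; occupancy-preserving swap nulls
  are out of scope, so robustness of NRI/NTI to uneven species frequencies
  is untested here.
* NRI/NTI significance is one-tailed per direction at a fixed α with no
  multiple-testing correction across sites or across the correlation table
  (matching the analysis being reproduced).
* PCPS axes are reported without significance testing or axis-selection
  procedures; figures are exported as coordinates only.
* The Wilcoxon normal approximation is used from pooled n = 17 upward;
  for small samples heavy with ties its p-values are approximate (the
  suite bounds the error against the exact distribution at n = 12 + 12).
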