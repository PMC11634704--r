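---
title: "Methods: sparse one-vs-all marker detection and identity-drift analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse one-vs-all marker detection and identity-drift analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerdrift)
```

## The problem

A cell type's operational identity in single-cell RNA-seq is the set of
marker genes it retains under fixed filter criteria: genes significantly
higher-expressed in that type than in all other cells. Tracking how that
marker count changes across donor age groups asks whether immune cell types
keep their transcriptional identity as people age, and -- if identity erodes
-- whether the mechanism is *dispersion* (cells spread out around an intact
type centroid, diluting marker detectability) or *convergence* (type
centroids move toward each other as the type-specific repertoire shrinks).

markerdrift provides the three layers this takes: a sparse one-vs-all-others
Wilcoxon rank-sum engine, the standard marker filters on top of it, and the
age-stratified analytics (deciles, balanced downsampling, trajectories,
PCA distance summaries, aging scores), plus a synthetic atlas generator that
plants each mechanism as ground truth.

## The rank engine

For a gene column with `n` cells and `m` stored (nonzero) values, the
implicit zeros are the smallest values: they occupy ranks `1..n-m` and
collapse to the shared midrank `(n-m+1)/2`. Stored values are ranked once
above the zero block with midrank tie handling. For every class `c` with
`n_c` cells, the rank sum `R_c` accumulates in a single pass over the stored
values (zero cells contribute `n_zero_c * zero_rank` by bookkeeping), so the
cost per gene is `O(m log m + C)` regardless of the number of classes `C`,
and each gene column is sorted exactly once for all classes. Tie-group sizes
`t_j` (including the zero block) give the correction `T = sum(t_j^3 - t_j)`.

The Mann-Whitney statistic and its normal approximation are

    U_c = R_c - n_c (n_c + 1) / 2
    mu = n_c (n - n_c) / 2
    sigma^2 = n_c (n - n_c) / 12 * ((n + 1) - T / (n (n - 1)))
    z = (U_c - mu -/+ 0.5) / sigma        (continuity correction toward mu)
    p = erfc(|z| / sqrt(2))               (two-sided)

Numerical conventions:

* **Continuity correction** is on by default. The classical R implementation
  (`wilcox.test(exact = FALSE, correct = TRUE)`) applies it, and agreement
  with that reference to better than `1.5e-8` is the engine's acceptance
  bar; the flag is exposed for users who want the uncorrected z.
* **Degenerate variance** (`sigma^2 = 0`, all `n` values tied): `p = 1`,
  `z = 0` -- no evidence against the null.
* **Class codes** are dense integers in first-appearance order; the
  "hash table" accumulation contract is satisfied by flat class-indexed
  accumulators filled in one vectorized pass over the stored triplets.
* Rank statistics are invariant under strictly increasing transforms of a
  gene's values (tested with cubing and global `log1p` rescaling). Per-cell
  library normalization is *not* such a transform -- it can reorder a gene's
  values when totals differ -- so tests are run on the log-normalized layer,
  the conventional choice.

## Marker criteria

`find_all_markers()` mirrors the classical cluster-marker workflow on
log-normalized data (`ln(1 + v * 10000 / T)`): for each (class, gene),

* `log_fc`: log2 ratio of de-logged group means with pseudocount 1,
  `log2((mean(expm1 x | class) + 1) / (mean(expm1 x | rest) + 1))`;
* `pct_1`, `pct_2`: detection fractions (nonzero cells) in class and rest;
* `p` from the rank engine, adjusted per class over the full gene panel
  (`m = n_genes`), Bonferroni by default (the convention of the replaced
  implementation), Benjamini-Hochberg available;
* a gene is a marker iff `log_fc > 0.5`, `p_adj < 0.05` and
  `max(pct_1, pct_2) > 0.1` (strict inequalities; defaults from standard
  practice, all exposed in `marker_params()`).

Genes failing the fold-change/detection screen in every class may skip the
rank test (`prefilter = TRUE`); they are still reported with
`is_marker = FALSE`, and pre-filtering provably never changes decisions
(tested). Genes with zero detection everywhere get the neutral record
`log_fc = 0, p = 1`.

## Age deciles, balancing, trajectories

Donors of each sex are split into 10 groups at the empirical 10%..90%
quantiles of *donor* age (donor-level quantiles, so decile boundaries track
the cohort's age pyramid rather than fixed 10-year bins; tied ages stay
together, so populations can be unequal under heavy ties). Marker counts
correlate strongly with per-group cell numbers, so before counting, each
(sex, cell type) unit is downsampled without replacement to its minimum
per-decile count -- every decile then has identical composition and equal
detection power.

`marker_trajectory()` runs the full marker pipeline *within each decile
independently* (each cell type versus all other cells of the same decile;
the alternative decile-versus-ensemble contrast is not implemented), counts
markers per type, and fits OLS of count on the decile midpoint age (mean
donor age in the decile), reporting slope in markers/year, intercept and
r-squared. At desk scale a single (sex, type) trajectory over 10 deciles is
noise-dominated, so the per-atlas summary statistic used in the acceptance
checks is the mean slope across the dispersed (sex, type) units -- the same
aggregation a trajectory figure's panel summarizes.

## Distances in PCA space

`pca_embed()` selects the highest-variance log-normalized genes (default
2000, or all available), centers and unit-scales each, and projects onto the
top principal components (default 20; distance analyses use dims 1..10).
Component signs are fixed by making each component's largest-magnitude
loading positive, so embeddings are reproducible run to run.

Age groups contrast donors younger than 40 with donors older than 79
(configurable). Two summaries are computed per (sex, age group):

* **within-type dispersion** -- mean Euclidean distance of each type's cells
  to the type centroid (`dispersion_to_centroid()`), with `se = sd/sqrt(n)`;
* **convergence distance** -- each cell's distance to the single centroid of
  all the group's cells (`convergence_distance()`), summarized per type and
  overall.

For *regime discrimination* (`regime_signature()`) the between-type summary
is the mean distance of the type centroids to the global centroid, not the
per-cell convergence distance. This is a deliberate design choice: per-cell
distances to the global centroid mix between-type separation with
within-type spread, so a pure increase in within-type dispersion would
mechanically inflate them and masquerade as centroid motion. Centroid-level
separation averages the noise out and isolates the convergence signal. The
dispersion signature is "within-type spread up for every type, between-type
separation stable (within 10%)"; the convergence signature is the reverse.

## Aging scores

Two formulations are in circulation and both are implemented, neither
privileged:

* `z_mean` -- per signature gene, Z-normalize log-normalized expression
  across all cells; per cell, average over signature genes;
* `umi_ratio` -- per cell, the fraction of raw UMIs on signature genes;
  always in `[0, 1]` and invariant to any normalization choice (it uses the
  raw layer only).

## The synthetic atlas generator

Counts are negative binomial (gamma-Poisson): `v ~ NB(mu, size0)` with
`size0 = 2` by default, a typical droplet-data overdispersion. Per-cell
library factors are log-normal (`sigma = 0.3`). Baseline gene means are
log-normal across genes and rescaled once (by solving for the multiplier
that sets the *expected* zero fraction) so empirical sparsity lands within a
few points of the 90% target typical of UMI matrices.

Cell-type identity is carried entirely by planted markers: each type owns a
disjoint block of `markers_per_type` genes whose mean is shifted up by
`marker_log2_shift` log2 units in cells of that type. Markers are planted on
*well-expressed* genes (upper quartile of the baseline profile): real
cell-type markers are expressed genes, and markers planted on
dropout-dominated genes would be undetectable under the stated filters no
matter how large the fold shift. For trajectory studies the shifts are
graded (a vector, e.g. `seq(0.4, 2, length.out = 20)`), so the marker count
responds smoothly to detection power rather than saturating.

Three regimes plant the competing aging mechanisms:

* **null** -- nothing varies with age.
* **dispersion** -- cell-intrinsic heterogeneity grows with age. The law
  `k(age)` (linear between `k_young` and `k_old` over the age range) sets
  `sigma^2 = log(k)` for two log-normal noise sources on the NB means:
  an independent log-median-1 modulation of every (cell, gene) mean, and
  mean-1 per-cell activity factors on three fixed "expression programs"
  (random subsets of non-marker genes shared by all types). The first
  erodes rank-test separability of the markers -- the marker-count decline
  -- while keeping each type's log-expression profile centred; the second
  gives the within-type spread the correlated low-dimensional structure
  that a 10-component PCA actually captures (independent per-gene noise is
  isotropic across hundreds of genes and nearly invisible in a truncated
  embedding), while translating all type centroids identically so
  between-type separation stays flat. Realizations that preserve the
  count-scale mean instead (the textbook `size/k` overdispersion increase)
  were rejected after measurement: under `log1p` at UMI-scale means they
  barely widen log-space spread, and they drag type centroids together
  through asymmetric dropout -- i.e. they plant the wrong signature.
* **convergence** -- marker shifts shrink toward baseline by `s(age)`
  (linear, default 0 to 0.5), collapsing the type-specific repertoire while
  within-type noise stays put.

Donor ages are uniform over 20--90 years by default (or explicit via
`donor_ages`), with each donor's draws on an independent RNG substream
derived from `(seed, sex, donor index)` -- adding donors never perturbs
existing donors' cells.

### What the generator does and does not emulate

It reproduces the features the analyses are sensitive to: ~90% sparsity,
library-size variation, class-specific markers of graded strength,
age-dependent within-type heterogeneity or centroid convergence, and a
donor/sex structure wide enough for per-sex deciles. It does **not** model
batch effects, doublets, ambient RNA, realistic gene-gene correlation beyond
the planted programs, or the gene-level statistics of any real atlas.
Passing tests therefore demonstrate that the pipeline recovers planted
mechanisms under controlled noise -- not that any particular biological
cohort shows them.

## Problem sizes and tolerances used by the test suite

Chosen once as desk-scale study conditions:

* Engine-oracle parity: 5 matrices of 300 genes x 1,000 cells, density 0.10,
  5 classes; max elementwise |dp| must be <= 1.5e-8 (R's default numeric
  tolerance; the observed value is 0).
* Exact invariants (rank conservation, U-sum identity): 10,000 fuzzed
  columns spanning densities 0.02--1.
* Marker recovery: null regime, 2,000 genes, 3 types x ~200 cells,
  10 markers/type at shift 2; >= 95% recovery, at most 1 false marker per
  class, exact agreement with a dense brute-force pipeline.
* Trajectories: dispersion law k: 1 -> 3 (and reversed), 500 genes, 3 types,
  20 graded markers, 20 donors/sex x 250 cells; mean slope sign correct in
  >= 19 of 20 seeds per direction.
* Regime discrimination: 600 genes, 3 types, 40 markers at shift 2,
  ~500 cells per (age group, type); correct signature in >= 19 of 20 seeds
  per regime. Regime fixtures use `base_mean_log_sd = 2` (heavy-tailed
  means), since dispersed expression lives on well-expressed genes.

## Known limitations

* The Wilcoxon test treats each cell as a replicate; with many cells,
  p-values are optimistic about donor-level generalization. Pseudobulk
  replication is out of scope here.
* Only the two-sided alternative and normal approximation are provided; no
  exact permutation p-values, no AUC effect sizes.
* The mitochondrial QC column is supplied (or computed from a gene-name
  prefix), not chosen adaptively per dataset; cohort-specific cutoffs are
  the user's responsibility.
* `assign_age_deciles()` requires >= 10 donors and >= 10 distinct donor ages
  per sex; smaller cohorts need coarser bins, which are not implemented.
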