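# markerdrift

Sparse one-vs-all Wilcoxon marker detection and age-related identity-drift
analytics for single-cell RNA-seq.

## What problem this solves, and for whom

A cell type's operational identity in scRNA-seq is its set of **marker
genes**: genes significantly higher-expressed in that type than in all
other cells, under fixed fold-change, detection and adjusted-p filters.
Finding them means running a Wilcoxon rank-sum test for every (gene, class)
pair — the step that dominates runtime in conventional single-cell
pipelines, because each gene column is re-sorted for every class and sparse
matrices are densified.

markerdrift is for people who study how cell identity changes across donor
groups (here: age) and need the marker machinery to be fast, transparent
and testable:

* a **single-pass sparse rank engine**: each gene column is sorted once,
  zeros collapse to a shared midrank, and per-class rank sums, tie
  corrections and U statistics for *all* classes accumulate in one pass
  over the stored values;
* the standard **marker criteria** on top (log2 fold change of de-logged
  means > 0.5, adjusted p < 0.05, detection > 10% in either group);
* **identity-drift analytics**: per-sex donor age deciles with balanced
  downsampling, marker-count-versus-age trajectories with OLS fits,
  cell-type composition by decile, PCA distance-to-centroid dispersion and
  convergence summaries, and gene-signature aging scores;
* a **synthetic atlas generator** that plants markers and age-dependent
  dispersion/convergence mechanisms as ground truth, so every analysis is
  testable without external data.

## The statistic at the core

For a gene with `n` cells, `n_zero` implicit zeros and class `c` of size
`n_c`, with midrank ties and the zero block ranked lowest
(`zero_rank = (n_zero + 1) / 2`):

```
U_c     = R_c − n_c (n_c + 1) / 2
μ       = n_c (n − n_c) / 2
σ²      = n_c (n − n_c) / 12 · [ (n + 1) − T / (n (n − 1)) ] ,  T = Σ_j (t_j³ − t_j)
z       = (U_c − μ ∓ 0.5) / σ          (continuity correction)
p       = erfc(|z| / √2)               (two-sided)
```

Agreement with the classical dense implementation
(`wilcox.test(exact = FALSE, correct = TRUE)`) is elementwise exact to well
below 1.5e-8 — see *Reproducing the validation figure* below.

## Worked example

```r
library(markerdrift)

atlas <- generate_atlas(atlas_spec(
  n_genes = 1000, n_types = 3, markers_per_type = 10, marker_log2_shift = 2,
  donors_per_sex = 3, cells_per_donor = 100, seed = 42))
atlas$counts
#> SparseCounts: 600 cells x 1000 genes, layer=raw, 60235 stored values (10.0% dense)

ln <- log_normalize(atlas$counts)          # ln(1 + v * 10000 / T)
mk <- find_all_markers(ln, atlas$cells$cell_type)
count_markers(mk)
#> typeC typeB typeA
#>    10    11    10

top <- mk[mk$is_marker & mk$class == "typeA", ]
head(top[order(top$p_adj), c("gene", "log_fc", "pct_1", "pct_2", "p_adj")], 3)
#>     gene log_fc pct_1 pct_2    p_adj
#>    g0003   2.10 0.705 0.334 7.95e-24
#>    g0005   2.00 0.611 0.251 2.45e-19
#>    g0008   2.26 0.453 0.110 4.40e-19

truth <- atlas$truth$markers
found <- mk[mk$is_marker, ]
sum(paste(found$gene, found$class) %in% paste(truth$gene, truth$cell_type))
#> [1] 30    # all 30 planted markers recovered (one spurious call in typeB)
```

The marker table reads like the familiar cluster-marker output: `g0003` is
detected in 70.5% of typeA cells versus 33.4% of the rest, with a 2.1-log2
fold change and a Bonferroni-adjusted p of 8e-24 — a planted typeA marker
recovered with its shift estimated near the true value of 2.

For the aging analyses, `assign_age_deciles()` + `balance_cells()` +
`marker_trajectory()` produce per-decile marker counts and per-(sex, type)
OLS slopes; `pca_embed()` + `dispersion_by_group()` /
`convergence_distance()` + `regime_signature()` summarize within-type
spread versus between-type separation for young (<40) versus old (>79)
donors. The methods vignette
(`vignettes/identity-drift-methods.Rmd`) documents the model behind each
step and the generator's ground-truth regimes.

## Command line

A thin wrapper over the same functions ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/markerdrift.R", package = "markerdrift"))')
Rscript $CLI simulate --seed 4 --out atlas/
Rscript $CLI qc --mtx atlas/matrix.mtx --genes atlas/genes.tsv \
    --cells atlas/barcodes.tsv --annot atlas/annot.tsv --out filtered/
Rscript $CLI find-markers --mtx atlas/matrix.mtx --genes atlas/genes.tsv \
    --cells atlas/barcodes.tsv --annot atlas/annot.tsv --out markers.tsv
Rscript $CLI drift --mtx atlas/matrix.mtx --genes atlas/genes.tsv \
    --cells atlas/barcodes.tsv --annot atlas/annot.tsv --out drift_report/
```

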