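# spotscreen

Spatially aware quality control for spot- and bin-based spatial
transcriptomics (10x Genomics Visium / Visium HD style data).

## Why

Standard QC pipelines threshold per-spot metrics — total UMI counts,
detected genes, mitochondrial percentage — *globally*, flagging any spot
beyond `median ± 3·MAD` over the whole tissue. Tissue is spatially
heterogeneous: large anatomical regions with systematically lower counts
get removed wholesale even though they are coherent, plausibly meaningful
tissue, while small focal defects (micro-tears, edge damage) embedded in
high-count neighbourhoods can slip through. spotscreen scores each spot
against its **k nearest spatial neighbours** instead, within its own
tissue section:

    z_i = 0.6745 · (x_i − median{x_j : j ∈ N(i)}) / MAD{x_j : j ∈ N(i)}

where `N(i)` are the k (default 36) nearest within-sample neighbours of
spot i (self excluded), MAD is the unscaled median absolute deviation, and
0.6745 calibrates the score against a standard z under normality. Spots
are flagged when z crosses a directional cutoff (default: lower tail,
cutoff 3; use `"higher"` for mitochondrial percentage). Count metrics are
log(1+x)-transformed first by default. Degenerate neighbourhoods
(constant, empty) conservatively score 0 and are never flagged.

The package is for analysts of Visium-style data who want QC flags that
respect tissue architecture: it provides the local statistic, the
conventional global `median ± n·MAD` baseline for comparison, readers and
writers for 10x-style matrix directories and h5ad-style annotated
matrices, a synthetic tissue generator with ground-truth artifacts,
spatial QC plots with multipage PDF reports, and a command-line workflow.

## Worked example

Simulate a 40×40 hexagonal tissue carrying a radius-1 micro-tear (counts
cut to 5%) and a large half-intensity region, then run the local sweep on
total counts and compare with the global baseline:

```r
library(spotscreen)

spec <- synthetic_tissue_spec(
  n_rows = 40, n_cols = 40, seed = 11,
  artifacts = list(
    list(kind = "micro_tear", center = c(10, 10), radius = 1, effect = 0.05),
    list(kind = "low_region", center = c(28, 28), radius = 8, effect = 0.5)))
sim <- generate_tissue(spec)

ds <- compute_qc_metrics(sim$dataset)          # sum, detected, mito %
ds <- local_outliers(ds, metric = "sum", direction = "lower",
                     n_neighbors = 36)         # adds sum_z, sum_outliers
sum(ds$obs$sum_outliers & sim$truth$micro_tear)
#> 7                                            # all 7 tear spots recovered

compare_global_local(ds)
#> Global vs local QC outlier comparison
#>                metric direction n_spots global_n global_pct local_n local_pct
#>                   sum     lower    1600      251     15.69%      20     1.25%
#>               sum_log     lower    1600      251     15.69%      21     1.31%
#>              detected     lower    1600       72      4.50%      26     1.62%
#>  subsets_mito_percent    higher    1600      108      6.75%      50     3.12%
#>            any_metric     union    1600      390     24.38%      90     5.62%
#> discrepancy: 309 global-only, 9 local-only spot(s)
```

Reading the table: the global rule flags 24% of all spots — dominated by
the intact-but-dimmer region — while the local sweep flags ~6%,
concentrated on the planted focal defects; the 309 global-only spots are
the region the local method deliberately spares. `plot_qc_metric()` draws
a sample's spots coloured by any metric with outliers ringed in red
(inverted y-axis, equal aspect), and `plot_qc_pdf()` writes one such page
per sample. `write_obs_table()` / `write_annmatrix()` export the
annotations (`{metric}_z`, `{metric}_outliers`, `{metric}_log`) to CSV or
an h5ad-style file readable from the python ecosystem.

The same workflow is scriptable from a shell:

```sh
exec/spotscreen simulate --spec tissue.json --out fixture/
exec/spotscreen qc      --input fixture/ --out qc.h5ad
exec/spotscreen sweep   --input qc.h5ad --out swept.h5ad --metric sum
exec/spotscreen compare --input qc.h5ad --out comparison.csv
exec/spotscreen report  --input swept.h5ad --metric sum --pdf report.pdf
```

Each run writes a JSON manifest (parameters, seed, version, timestamp)
next to its outputs.

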