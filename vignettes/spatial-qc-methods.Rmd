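---
title: "Neighbourhood-aware quality control for spot-based spatial transcriptomics"
author: "spotscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighbourhood-aware quality control for spot-based spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotscreen)
```

## The problem

Spot- and bin-based spatial transcriptomics platforms (10x Genomics Visium,
Visium HD) measure gene expression on a spatial lattice of capture units.
The QC metrics inherited from single-cell pipelines — total UMI counts per
spot, number of detected genes, percentage of mitochondrial counts — are
conventionally thresholded *globally*: a spot is discarded when its metric
falls beyond `median ± n·MAD` computed over the whole tissue.

Tissues, however, are spatially heterogeneous. Entire anatomical regions can
have systematically lower counts while being perfectly healthy tissue; a
global threshold removes them wholesale. Conversely, small focal defects —
micro-tears, bubbles, edge damage — sit inside otherwise high-count
neighbourhoods and may not be globally extreme at all. spotscreen replaces
the tissue-wide reference with each spot's local spatial context.

## The local statistic

For spot $i$ with (optionally log-transformed) QC value $x_i$ and
$\mathcal{N}(i)$ the indices of its $k$ nearest spatial neighbours within
the same tissue section, the robust (modified) z-score is

$$
z_i \;=\; 0.6745 \,\cdot\,
\frac{x_i - \operatorname{median}\{x_j : j \in \mathcal{N}(i)\}}
     {\operatorname{MAD}\{x_j : j \in \mathcal{N}(i)\}},
\qquad
\operatorname{MAD}(S) = \operatorname{median}_{j}\,
\bigl|x_j - \operatorname{median}(S)\bigr|.
$$

The constant $0.6745$ is the normal quantile that makes a MAD-based score
comparable to a standard z-score under normality, so the default cutoff of
3 corresponds to classic "3-sigma" practice. A spot is flagged when
$z_i < -c$ (`direction = "lower"`), $z_i > c$ (`"higher"`), or $|z_i| > c$
(`"both"`), with strict inequalities — a spot exactly at the cutoff is not
an outlier.

Conventions worth making explicit:

* **Self-exclusion.** $\mathcal{N}(i)$ does not contain $i$. The score asks
  "how far is this spot from what its surroundings predict"; including the
  focal spot would shrink $z$ exactly for the genuine outliers the method
  exists to find.
* **Degenerate neighbourhoods.** If the neighbourhood MAD is zero (constant
  neighbours) or non-finite, $z_i$ is conservatively set to 0, as is any
  non-finite $z_i$ and any spot with an empty neighbour list (a section
  with a single spot). Degenerate spots are therefore never flagged. A
  corollary: on an *exactly* constant background even a dead spot scores 0 —
  meaningful detection needs some baseline variability, which real tissue
  always has.
* **Two-sided rule.** `"both"` flags $|z| > c$. A two-sided rule that
  duplicated the upper tail alone would be indistinguishable from
  `"higher"`, which is not a useful reading; the absolute-value form is the
  one under which "either tail is undesirable" makes sense.
* **Log transform.** With `log = TRUE` (default) the metric is transformed
  by natural $\log(1+x)$ before scoring, damping the heavy right tail of
  count metrics. The transformed values are persisted in `"{metric}_log"`;
  an existing column of that name is *never overwritten* — whatever values
  it holds are scored as-is (with a notice), so an upstream preprocessing
  pipeline keeps authority. The z and flag columns are always named from
  the original metric: `"{metric}_z"`, `"{metric}_outliers"`.

## Neighbourhood construction

Neighbours are the $k$ nearest spots by Euclidean distance in the
coordinate frame of the source data (pixels or lattice units — coordinates
are never rescaled), restricted to spots of the same sample: tissue
sections are independent and neighbourhoods must not bridge them. Ties at
equal distance are broken by ascending global spot index, which makes
results exactly reproducible across runs and worker counts; this matters on
lattices, where whole rings of neighbours are equidistant. When $k$ exceeds
a section's size it is clamped to $n-1$ with a warning, so tiny fixtures
and HD-scale bins run the same code.

The search is an exact per-sample all-pairs scan, $O(n^2)$ in section
size. At the scales this package targets (a Visium section is ~4–5k spots;
our test tissues are up to 3,600 spots) this costs seconds; exactness is
what lets the deterministic tie-break be a testable contract. Internally
all indices are 1-based (native R); on-disk formats keep their own
conventions.

**Defaults.** $k = 36$ — three full hexagonal rings ($6+12+18$) on a
Visium-style grid, a neighbourhood large enough to stabilize the median/MAD
and small enough to stay local; the practical range is 24–48 (larger $k$
smooths, smaller $k$ sharpens but adds variance). `cutoff = 3` is
conservative; 2.5 or lower trades confidence for sensitivity in complex
tissue. Default direction is `"lower"` (low counts/genes imply poor
quality); use `"higher"` for mitochondrial percentage.

## The global baseline

`global_mad_outliers()` implements the tissue-wide rule the local score is
compared against: flag values beyond `median ± n_mads · MAD` over all
spots. The MAD here is **unscaled** by default — no 1.4826 normal
consistency constant — matching the `median ± 3 MAD` convention the local
score is benchmarked against (the 0.6745 constant already lives inside the
local z-score); `mad_scaled = TRUE` is exposed for parity with ecosystems
that scale. The centre is the median, not the mean: the point of the rule
is robustness, and a mean-centred variant would defeat it.

A structural property of this baseline, reproduced mechanically by the
tests: for strongly right-skewed non-negative metrics (raw total counts),
`median − 3·MAD` can fall below every observed value, so the lower tail
flags *nothing*. That is precisely why log totals, not raw totals, are the
recommended global QC metric — and why the comparison table carries both as
separate rows (`sum` and an explicit `sum_log` column, so each row keeps
its own `_z`/`_outliers` columns).

`compare_global_local()` runs both methods over the four standard rows
(total counts lower, log total counts lower, detected genes lower,
mitochondrial percentage higher), reports per-metric and any-metric-union
counts and percentages, summarizes the local z-score distributions
stratified by flag status (the numbers behind violin-style plots), and
returns two discrepancy masks: spots flagged *only* globally (typically
large contiguous regions the local method deliberately spares) and *only*
locally (scattered focal defects).

## What the synthetic generator emulates — and what it does not

`generate_tissue()` draws lattices (hexagonal with odd-row offset 0.5 and
row pitch $\sqrt{3}/2$, so Euclidean kNN recovers the 6-neighbour ring
structure; or square) with:

* **Totals:** negative binomial with mean `total_mean` (default 4,000) and
  `total_dispersion` parameterized as the **variance-to-mean ratio** (Fano
  factor; default 2, Poisson at 1), i.e.
  `rnbinom(mu = m, size = m/(d-1))`. Spot totals pool thousands of genes,
  so homogeneous tissue sits near-Poisson with modest inflation; Fano
  factors of order a few are the realistic spot-total regime. Large-scale
  variation in real tissue is *regional structure*, which the generator
  models explicitly as artifacts rather than as baseline noise.
* **Genes:** the total is split binomially into a mitochondrial share (a
  per-spot Beta-distributed fraction, mean 2.5%, over MT-prefixed genes)
  and a remainder allocated multinomially over a per-spot active subset of
  the other genes (each active with probability `detected_fraction`,
  default 0.6) — so mitochondrial percentage and detected-gene counts are
  internally consistent with the counts matrix.
* **Artifacts with ground truth:** `micro_tear` and `low_region` binomially
  thin counts inside a disk to a fraction `effect` of baseline (tears:
  radius 1, effect 0.05; regions: large radius, effect 0.5); `mito_spike`
  raises the target mitochondrial fraction by `effect` percentage points.
  Masks are returned with the dataset; for regions an additional
  `low_region_interior` mask marks spots ≥ 3.5 lattice spacings inside the
  edge — spots whose default 36-neighbourhood lies entirely within the
  region, the right stratum for asking whether the local method spares
  region cores.

The generator does **not** model expression programs, spatial domains, cell
types, platform-specific noise (optics, segmentation, diffusion), or
coordinate errors. Passing tests on these tissues therefore demonstrate the
*statistical contract* of the method — recovery of focal artifacts, sparing
of coherent regions, calibrated null behaviour — not its end-to-end
performance on any particular real dataset.

## Numerical and design choices

* Strict inequalities at the cutoff; boundary spots are kept.
* Zero-total spots get mitochondrial percentage 0 (not NaN), keeping every
  downstream input finite and consistent with the degenerate-z convention.
* Natural log for $\log(1+x)$.
* The per-spot sample identifier is treated as a per-spot label column
  (`obs`-style), looked up by `sample_key` with a fallback to the dataset's
  canonical sample slot; a missing sample column at load time is tolerated
  (metric-only workflows) and only enforced when `local_outliers()` runs.
* Positions files in both wild dialects (headered `tissue_positions.csv`
  and headerless `tissue_positions_list.csv`) are auto-detected; spots
  flagged not-in-tissue are dropped at read time; matrix/positions barcode
  mismatches drop to the intersection with a warning, and disjoint sets are
  an error.
* h5ad-style files are read and written in the anndata HDF5 encoding
  (sparse CSR/CSC or dense `X`, encoded data frames, `obsm` slots) via
  rhdf5, so annotations travel losslessly between the R and python sides;
  doubles round-trip bit-exact.
* Parallelism (`workers`) partitions by sample and is contractually
  output-invariant.

## Problem sizes used in the checks

The test suite and the reproduction script work at desk scale, chosen to
exercise every code path and the stochastic properties with comfortable
margins: oracle-agreement sweeps on 20 random datasets of 200–500 spots
across 1–3 samples; tear-recovery and regional-contrast studies on 60×60
hexagonal tissues (3,600 spots; five radius-1 tears at effect 0.05, or a
~20%-area region at effect 0.5); null-rate estimates on 30×30 tissues
across 3 replicates; the four-metric comparison on a 40×40 tissue carrying
all three artifact kinds. On these conditions the local sweep recovers tear
spots essentially completely with a background false-positive rate well
under 1%, while the global lower-tail rule flags the entire low region that
the local method spares — the package's core qualitative claim, stated as
reproducible numbers by `scripts/acceptance.R`.

## Known limitations

* Accurate coordinates and roughly uniform capture density are assumed;
  stitching errors or irregular lattices bias neighbourhoods and can create
  false positives.
* The exact all-pairs neighbour search is quadratic per section — ample
  for sections up to tens of thousands of spots, not tuned for
  multi-million-bin HD runs.
* Only *local* (focal) outlier detection is implemented; detection of
  broader contiguous artifact regions as a positive call (rather than via
  the global baseline) is out of scope, as are multi-scale neighbourhoods,
  histology-image integration, and interactive visualization.
* Flags are statistical indicators computed from sequencing metrics alone;
  inspecting histology before filtering remains good practice.
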