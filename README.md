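# cycmif

Analysis of **cyclic multiplexed immunofluorescence (mIF)** image stacks:
from raw stain/quench TIFF pairs to aligned images, single-cell
segmentation, marker profiles, immune phenotypes and unsupervised cell
clusters. The package is written for imaging groups running cyclic
staining protocols (stain → image → quench → re-stain) who need the
whole downstream analysis — registration, segmentation, profiling,
clustering — reproducible on ordinary hardware.

## What it does

A cyclic acquisition is indexed by (FOV *i* = 1..M, cycle *j* = 1..N,
channel *c* = 1..C); every slot holds a stain image and a paired quenched
background exposure. `cycmif` implements the full pipeline:

1. **Grouping** — raw TIFFs are collected into a `CyclicDataset` by a
   configurable file-name pattern, with missing stain/quench partners
   reported by triple.
2. **Pre-processing** — per image: quench subtraction (clipped at zero),
   normalization by the image's 25th/99th intensity percentiles, Gaussian
   denoising with mirrored borders.
3. **Registration** — slides are remounted between cycles, offsetting all
   FOVs of a cycle by one rigid translation. Channels are collapsed by
   maximum projection, a mask of cell-sized objects is computed (Otsu +
   opening + area band), images are downsampled two-fold, and the shift is
   the trial-averaged peak of the **masked normalized cross-correlation**
   over random 75% crops, with outlier trials discarded. Low-cellularity
   FOVs fail loudly instead of mis-registering.
4. **Segmentation** — a three-class U-Net (background / cell interior /
   cell boundary — the boundary class keeps touching cells separable)
   with auxiliary cell-count and auto-encoding heads, trained under

   L = L<sub>ce</sub> + α·L<sub>jacc</sub> + λ<sub>c</sub>·L<sub>count</sub> + λ<sub>a</sub>·L<sub>auto</sub> + β·L<sub>reg</sub>

   (weighted cross-entropy; soft per-class Jaccard; squared count error;
   reconstruction MSE; L2; α = 10³, λ<sub>c</sub> = 10³, λ<sub>a</sub> = 0.5,
   β = 10⁻⁴). Interior/boundary pixels weigh 3×, and boundary pixels
   currently predicted as interior a further 2×. The network, backprop and
   Adam are implemented in compiled code inside the package; gradients are
   verified against finite differences in the test suite. Class masks
   become instances by watershed-style expansion of interior seeds.
5. **Profiling** — per-cell mean marker intensities over each instance's
   pixels; MAD-based high-outlier removal; log transform; per-marker
   positivity thresholds (mean − 3 SD, or an Otsu split of the log
   intensities); phenotype calls from an ordered positive/negative marker
   rule table (CD4+/CD8+ T cells, NK, B cells, neutrophils, macrophages,
   dendritic cells, CD45+ fallback).
6. **Clustering** — UMAP embedding (optionally supervised by phenotype
   labels) and HDBSCAN density clustering (implemented in the package)
   with noise labeling, cluster marker profiles and phenotype-by-cluster
   composition tables.

A fully ground-truthed **synthetic-data generator** (`generateDataset()`)
plants shifts, cells, phenotypes and noise so that every stage is testable
end-to-end without external data.

## Worked example

```r
library(cycmif)

# a small fully ground-truthed specimen: 2 FOVs, 4 cycles x 3 channels
cfg <- syntheticConfig(n_cycles = 4, n_fovs = 2, n_channels = 3,
                       image_shape = c(192, 192), n_cells = 25,
                       max_shift = 6, noise_sd = 0.005, seed = 61)
gen <- generateDataset(cfg)
writeDataset(gen, "demo_raw", sample = "demo")

run <- runPipeline(pipelineConfig(
  "demo_raw", "demo_out", use_ground_truth = TRUE,
  registration = registrationConfig(size_band = c(20, 3000), seed = 2),
  mad_k = 100, min_cluster_size = 10, seed = 3))
run
#> Pipeline run: OK
#>   group      completed    0.0s
#>   preprocess completed    0.6s
#>   register   completed    0.4s
#>   segment    completed    0.0s
#>   profile    completed    0.2s
#>   cluster    completed    2.1s
#>   fovs: 2
#>   cycles: 4
#>   failed_cycles: 0
#>   cells_segmented: 50
#>   cells_total: 50
#>   cells_filtered: 0
#>   n_clusters: 1
```

`fovs`/`cycles` confirm the grid that was grouped; `failed_cycles: 0` says
every cycle's translation was recovered (the estimated shifts land within
the downsampling granularity of the planted ones — see
`demo_out/shifts.json`); `cells_total: 50` equals the planted cell count,
recovered through the ground-truth segmentation bypass. `demo_out/`
contains the per-stage artifacts: `shifts.json`, instance label TIFFs,
`cells.csv` (one row per cell with marker means and phenotype), and
`cells_clustered.csv` with UMAP coordinates and HDBSCAN cluster ids.
Re-running the same call skips every stage whose inputs are unchanged.

To train the segmentation network instead of bypassing it:

```r
fit <- trainNetwork(tiles$tiles, tiles$labels, tiles$counts, fov = tiles$fov,
                    config = trainConfig(tile_size = 64, epochs = 30,
                                         batch_size = 16,
                                         learning_rate = 7e-4, seed = 4),
                    depth = 3, base_filters = 8)
```

where `tiles` comes from `makeTrainingTiles()` (see the methods vignette;
on 325 synthetic 64-px tiles this reaches a held-out mean per-class pixel
F1 of ~0.95 in a few CPU-minutes).

A thin command-line wrapper lives at `inst/scripts/cycmif.R`
(`simulate` and `run --config config.yaml` subcommands).

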