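---
title: "Methods: registration, segmentation and profiling of cyclic mIF stacks"
author: "cycmif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: registration, segmentation and profiling of cyclic mIF stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The data model

Cyclic multiplexed immunofluorescence (mIF) images a specimen through
repeated stain/quench rounds: in each cycle a handful of fluorescent
markers are imaged across every field of view (FOV), the signal is
chemically quenched, and a background ("quench") exposure is recorded for
each channel. A full acquisition is therefore indexed by
(FOV $i = 1..M$, cycle $j = 1..N$, channel $c = 1..C$), each slot holding a
stain image and its paired quench image, plus a manifest mapping
(cycle, channel) to a marker name. `CyclicDataset` holds exactly this,
and `groupImages()` builds it from raw TIFF directories via a configurable
file-name pattern (acquisition software naming varies, so the pattern is a
user-supplied regular expression with named groups).

# Pixel pre-processing

Each stain image passes through a fixed three-step pipeline, in this order:

1. **Quench subtraction** — the paired background exposure is subtracted
   pixel-by-pixel and the result clipped at zero. Autofluorescence and
   residual signal from earlier cycles live in the quench image, so this is
   the background correction.
2. **Percentile normalization** — intensities are rescaled by the image's
   own 25th and 99th percentiles to the unit interval,
   $\mathrm{clip}((x - P_{25})/(P_{99} - P_{25}), 0, 1)$. The percentiles
   are computed over the full image including background: most pixels in an
   FNA-style specimen are background, so $P_{25}$ tracks the residual floor
   while $P_{99}$ is a robust bright reference that ignores hot pixels. A
   flat image (both percentiles equal) maps to zero with a warning rather
   than an error, since blank channels occur in practice.
3. **Gaussian denoising** — a separable Gaussian of $\sigma = 1$ px by
   default (the scale of impulse noise; configurable) with mirror-padded
   borders so FOV edges are not darkened and constants are preserved.

# Translation registration

Slides are physically removed and remounted between cycles, which offsets
every FOV of a cycle by a common rigid translation. The estimator exploits
this: shifts are measured once per cycle, on a single designated FOV, and
applied to all FOVs of that cycle — reducing the work from
$N \times M \times C$ images to $N \times C$.

For the designated FOV, the $C$ channel images of each cycle are collapsed
by per-pixel **maximum projection** (cells visible in any channel become
anchors), a foreground mask of *cell-sized* objects is computed (Otsu
threshold, $3\times3$ morphological opening, connected components kept when
their area lies in a configurable band), and both image and mask are
downsampled two-fold by block averaging. On each of $t = 3$ trials a random
crop of 75% per axis is taken — the identical window applied to the image
and its mask, and to the reference and moving sides, so the masked
correlation stays consistent — and the integer-pixel peak of the **masked
normalized cross-correlation** (Padfield's formulation, Fourier-accelerated)
is recorded. Trial shifts farther than 4 px (downsampled) from the
component-wise trial median are discarded; the mean surviving shift is
scaled back to full resolution and rounded to the nearest integer pixel.

Failure modes are explicit rather than silent: fewer cell-sized objects
than `min_objects` (default 5) in either image fails the cycle with
*"low cellularity"*; mutually inconsistent trials fail it with *"unstable
correlation"*. Failed cycles keep their data unshifted and are flagged in
the run report, so a caller can re-estimate from another FOV.

Because correlation happens on the half-resolution grid, recovered shifts
are exact for even translations and within 1 px for odd ones (the trial
mean can restore odd values after the $\times 2$ rescale). The package's
recovery study — 50 synthetic seven-cycle specimens with planted integer
shifts up to 15 px and moderate noise — asks for 95% of cycles within 2 px,
which the masked estimator passes with a wide margin; an optional
full-resolution refinement pass was considered and dropped as unnecessary
at that precision.

# Three-class segmentation network

Touching immune cells are the hard case for instance segmentation from
masks: a two-class (cell/background) network merges neighbors. The package
therefore classifies each pixel as **background, cell interior, or cell
boundary**, and converts class masks to instances afterwards. Ground-truth
class masks are rasterized from instance maps with a 2 px boundary ring
(pixels within 2 px of any differently-labeled pixel); 2 px keeps the ring
a few percent of tile pixels at the default cell sizes while guaranteeing
that interiors of touching cells are never 4-connected.

The model is a U-Net-style encoder–decoder (depth 3, 8 base filters by
default, doubling per level; plain conv+ReLU blocks, nearest-neighbour
upsampling, skip concatenation) with two auxiliary heads sharing the
encoder: a scalar **cell-count regressor** on the globally averaged
bottleneck and an **auto-encoding decoder** reconstructing the input.
Batch normalization was left out deliberately: on percentile-normalized
inputs the small network trains stably without it, and the leaner blocks
keep single-CPU training fast. The implementation (forward, backward,
Adam) is hand-written compiled code, with gradients verified against
central finite differences in the test suite.

Training minimizes

$$L = L_{ce} + \alpha L_{jacc} + \lambda_c L_{count} + \lambda_a L_{auto}
      + \beta L_{reg},$$

with defaults $\alpha = 10^3$, $\lambda_c = 10^3$, $\lambda_a = 0.5$,
$\beta = 10^{-4}$:

* $L_{ce}$ — pixel cross-entropy, weighted 3-fold for interior and
  boundary pixels against the dominant background class, and a further
  2-fold when a true boundary pixel is *currently predicted interior* (the
  error mode that merges neighbors). That last multiplier is recomputed
  from the argmax each forward pass and treated as a constant weight, not
  differentiated through.
* $L_{jacc}$ — soft per-class Jaccard loss with probabilistic
  intersection/union and $\varepsilon = 10^{-7}$ smoothing (differentiable,
  unlike thresholded IoU).
* $L_{count}$ — squared error against the number of distinct instances
  intersecting the tile (the simplest consistent count target).
* $L_{auto}$ — mean squared reconstruction error.
* $L_{reg}$ — the L2 norm of all weights (biases excluded).

Tiles with no labeled cells are removed from the training split to curb
class imbalance; augmentation applies stochastic 90° rotations, flips,
Gaussian noise and mean shifts. Training can restart from several random
initializations, keeping the checkpoint with the best validation pixel
accuracy; the train/validation split is by FOV so held-out tiles come from
held-out scenes. Whole FOVs are predicted by tiling with 20% overlap,
averaging class probabilities over overlaps (deterministic and seam-free),
and taking the per-pixel argmax. Instances are then extracted by seeding
on 4-connected interior components, expanding each seed into adjacent
boundary pixels by geodesic propagation, and dropping instances below
`min_area`.

Full-scale defaults mirror a production run (300 px tiles, batch 16, Adam
at $10^{-5}$, 700 epochs). The packaged studies use scaled-down conditions
chosen once for single-CPU work: 13 FOVs of 256×256 px with ~30 cells each
(30% planted as touching pairs), 64 px tiles (325 tiles), 30 epochs at a
learning rate of $7\times10^{-4}$. Under these conditions the held-out
mean per-class pixel F1 exceeds 0.85 and instance counts are within 10% of
the planted truth.

# Single-cell profiling

Ground-truth or predicted instance masks are applied to the aligned,
pre-processed marker stack; each cell's profile is the mean intensity over
its full pixel set (interior plus claimed boundary), with area and centroid
recorded. `SingleCellTable` extends `SummarizedExperiment` (markers ×
cells) and moves through an explicit transform state machine
(raw → log → z-score) so transforms cannot be applied twice.

High-intensity outliers are removed per marker at
`median + k × MAD` (k = 5 by default, high side only, MAD unscaled and
median-centered — the robust choice, since the deviations are measured
around the very outliers being removed; markers with zero MAD impose no
removals). The rule presumes broadly unimodal marker distributions with
rare bright artifacts, as in real immunofluorescence. On the generator's
sharply bimodal on/off markers the default k would excise entire positive
populations — a property of the rule, not a bug — so the synthetic studies
run with a large k (effectively disabling removal) and exercise the rule's
behavior separately on unimodal columns. Intensities are then natural-log transformed with a $10^{-6}$
pseudocount.

Marker positivity defaults to the threshold *mean − 3 SD* of the marker's
log intensities. That rule presumes a marker-positive population with a
low-end tail — reasonable for a panel gated on segmented CD45+ cells — but
on a mixed panel it calls nearly every cell positive for every marker, so
an alternative data-driven threshold (Otsu split of the log intensities)
is available behind `positivityThresholds(method = "otsu")`. The package's
phenotype-recovery studies use the Otsu switch together with a synthetic
specimen containing a CD45-negative epithelial ("Tumor cells") population,
which makes every gated marker bimodal; this choice is a study condition,
not a change to the default.

One interaction deserves emphasis: because normalization rescales each
image by its own 25th/99th percentiles, a marker expressed in too few
cells (positive pixels below roughly 1% of the image) anchors its upper
limit on background rather than signal, stretching the off-level to the
top of the range — after which no threshold can separate positives. The
phenotype-recovery studies therefore use mixtures in which every gated
marker is expressed by at least ~10% of cells; on real specimens, very
rare markers should be inspected before trusting automatic positivity
calls.

Phenotypes are assigned from an ordered rule table of positive/negative
marker combinations (CD4+ T cells, CD8+ T cells, NK, B cells, neutrophils,
macrophages, dendritic cells, then the generic CD45+ fallback). Rules are
evaluated most-specific-first with first-match-wins, which resolves
overlapping gates (a CD68+CD66b+ cell is a neutrophil); cells failing every
rule — in particular CD45-negative cells — are "unassigned".

# Embedding and cluster discovery

Cells are projected to 2-D by UMAP on the per-marker z-scored log
intensities (`n_neighbors = 15`, `min_dist = 0.1`, Euclidean metric,
seeded and single-threaded for reproducibility); supplying phenotype
labels switches to the supervised projection, which draws predefined
phenotypes together. Clusters are found by HDBSCAN — implemented in the
package: core distances at `min_samples` neighbors define the mutual
reachability distance, its single-linkage hierarchy is condensed at
`min_cluster_size` (default `max(10, 1%)` of cells), and clusters are
selected by excess-of-mass stability, with points falling out early
labeled noise (−1). One deliberate boundary choice: when the condensed
tree has no true split at all, the root is returned as a single cluster
rather than calling everything noise. Cluster profiles are per-cluster
marker means z-scored across clusters, and phenotype-by-cluster
contingency tables summarize how manual gates distribute over unsupervised
structure.

# What the synthetic generator does and does not emulate

`generateDataset()` plants everything downstream stages estimate: integer
per-cycle translations (uniform on $[-s, s]^2$, reference cycle fixed at
zero), disk-shaped cells with 1 px soft edges, nuclear DAPI (55% of the
cell radius), membrane-localized CD45 (an annulus outside the nuclear
zone), phenotype-driven marker means drawn per cell around separated
on/off levels, a constant background, additive Gaussian pixel noise, and
quench exposures sharing the noise model but not the noise realization.
Cells keep a 2 px minimum gap unless a touching fraction is requested for
boundary-class stress tests.

It does **not** model photobleaching kinetics, tissue autofluorescence
texture, optical point-spread blur, rotation/scale misregistration, or
irregular cell morphology. Passing tests therefore demonstrate that the
algorithms are implemented correctly and recover planted structure under
controlled conditions — not that the trained network or the thresholds
transfer to real tissue unchanged. On real data the network should be
retrained and the positivity rule inspected per panel.

# Numerical choices

* Probabilities are clamped at $10^{-7}$ inside logs; Jaccard uses the same
  $\varepsilon$.
* The masked correlation surface is zeroed where the mask overlap is below
  30% of its maximum (unstable normalization at extreme lags).
* Trial means are rounded to integer pixels before shifts are applied;
  `applyShift` zero-fills vacated pixels.
* Conv biases initialize at 0.01 rather than 0 so ReLU units start off the
  zero kink; weights use He initialization.
* All stochastic steps (generator, crops, shuffling, augmentation, UMAP)
  are seeded; end-to-end runs are reproducible.

# Known limitations

* Registration is translation-only by design; rotation or non-rigid
  deformation is out of scope.
* The count head is a regularizer here; reported cell counts come from
  instance extraction, not the count head.
* HDBSCAN is the dense $O(n^2)$ formulation — appropriate for the
  $10^3$–$10^4$ cells of a specimen, not for millions of points.
* The supervised embedding mode follows the standard label-supervised
  UMAP; the package makes no claim that this is the only reading of
  "optimized to minimize distances between predefined phenotypes".
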