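---
title: "Central-pooling CNN segmentation of lung nodules: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Central-pooling CNN segmentation of lung nodules: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfcnn)
```

## The problem and the model

Lung nodules on CT are heterogeneous — juxtapleural nodules share the
pleura's intensity, cavitary nodules contain air, ground-glass nodules are
barely brighter than lung parenchyma — so intensity thresholds and
morphological templates generalise poorly. `cfcnn` treats segmentation as
voxel classification: for every voxel inside a user-supplied bounding box
the network predicts the probability that the voxel belongs to the nodule,
and a slice-propagation stage assembles the per-slice decisions into a 3-D
mask.

The classifier is a two-branch convolutional network. For a target voxel
it receives

* a **tri-slice 3-D patch**: the 35 × 35 axial neighbourhood on the
  current, preceding and subsequent slice, stacked as three channels and
  z-scored jointly, `f(x) = (x − x_mean)/x_std`;
* a **multi-scale 2-D patch**: the 65 × 65 and 35 × 35 axial crops around
  the voxel, the larger one rescaled to 35 × 35 with third-order spline
  interpolation, stacked as two channels.

Each branch stacks three blocks of two 3 × 3 convolutions (batch
normalisation and PReLU after each convolution), with a **central pooling**
stage after the first and second block. Branch outputs feed one fully
connected layer each, are concatenated, pass a fused fully connected layer
and end in a 2-unit softmax. Training minimises cross-entropy with 1-norm
weight regularisation (strength `lambda_l1 = 5e-4`) by momentum SGD
(`mu = 0.9`, batch 128) under the inverse-decay schedule
`alpha_t = alpha_0 (1 + gamma t)^(-p)` with `alpha_0 = 6e-5`,
`gamma = 1e-4`, `p = 0.75`; weights start from Xavier initialisation and
PReLU slopes at 0.25.

## Central pooling

Ordinary max pooling treats all positions of a feature map alike, yet the
network's decision concerns the *centre* voxel of the patch. Central
pooling therefore uses 1-D max-pooling kernels whose size depends on
position: size-1 kernels (no reduction) near the centre, sizes 2 and 3
towards the edge, applied along rows and then columns.

For an axis of length $O$ the kernel counts $(n_1, n_2, n_3)$ solve

$$n_1 + 2n_2 + 3n_3 = O, \qquad n_1 + n_2 + n_3 = O/2, \qquad n_1 + n_3 = n_2,$$

whose exact solution $(O/8,\, O/4,\, O/8)$ is rounded down and the
remainder distributed through a fixed look-up table. We define the
residual as the number of axis positions left uncovered by the base
counts, $r = O - (\lfloor O/8\rfloor + 2\lfloor O/4\rfloor + 3\lfloor
O/8\rfloor) \in [0, 7]$; each table column covers exactly $r$ positions,
which is what makes the tiling constraint hold for every $O$ (for example
$O = 12$). An alternative reading of the residual as the fractional part
of $O/8$ is dimensionally a fraction, cannot index the table, and breaks
the worked 9 × 9 example, so the coverage definition is used. The table
also carries columns $r = 6, 7$ that the base counts never produce
($r \le 5$ for all $O$); they are implemented for completeness.

```{r}
unlist(solve_kernel_counts(9)[c("n1", "n2", "n3")])
build_kernel_order(2, 2, 1)
```

Kernels are laid out symmetrically — larger kernels outermost, the size-1
kernels contiguous in the centre. An odd count of size-3 kernels places
its extra kernel on the low-index side and an odd count of size-2 kernels
on the high-index side; this alternation reproduces the canonical order
`{3, 2, 1, 1, 2}` for a 9 × 9 map and, unlike sending every odd count to
the same side, guarantees for every axis length that the centre of an
odd-length output — the window containing the target voxel — has size 1
whenever any size-1 kernel exists. That guarantee is the point of the
layer: the voxel being classified is never blurred with a neighbour. The default 35 × 35 input pools 35 → 18 → 9. The forward pass
records, per output cell, the input coordinate that supplied the maximum
(ties to the lowest linear index), and the backward pass routes gradients
through exactly those coordinates; because windows never overlap, the
adjoint is exact and finite-difference checks pass through the whole
network. A ceil-mode uniform 2/2 plan (`pooling = "uniform_max"`) swaps in
traditional max pooling with identical map sizes and parameter count, for
ablation comparisons.

## Weighted training-voxel sampling

Nodule voxels are typically under 5% of a CT slice, and randomly drawn
background patches are dominated by easy dark lung field. Sampling is
therefore weighted by segmentation difficulty within an expanded box (the
slice's nodule bounding box grown by 8 voxels per side):

* nodule voxels: $PW_i = \exp(-\min_{j \in N} d(i,j))/Z$ — edge voxels,
  nearest to the background set $N$, get the largest weights;
* background voxels: $NW_i = I_i \exp(-\min_{j \in P} d(i,j))/Z$, where
  $I_i$ is the intensity min–max normalised over the box, suppressing the
  dark lung field in favour of bright nodule-adjacent wall and vessels.

Distances are 2-D within-slice Euclidean distances in voxel units,
computed with an exact separable distance transform. Per slice, 40% of
the nodule voxels and the same number of background voxels are drawn
without replacement with probabilities proportional to these weights, so
class labels are exactly balanced. The 40% fraction is applied per slice
(rather than pooled over the training set) so every nodule contributes
samples; rounding is half-away-from-zero. Intensity normalisation over a
constant-intensity box degenerates; all $I_i$ are then set to 1.

## Slice propagation

The user supplies one 2-D bounding box on a starting slice. After
classifying every voxel in the box (probability ≥ 0.5 is nodule; the
threshold and the inclusive boundary are configurable conventions), the
mask is reduced to a single 8-connected component — the one nearest the box
centre on the starting slice, or nearest the preceding slice's kept
centroid on propagated slices (ties: larger area, then lower first linear
index). The same box is then applied slice by slice in both directions
independently. Propagation in a direction stops when the selected
component is empty, or when its area falls strictly below 30% of the
preceding kept slice's area; the violating slice is excluded. A slice at
exactly 30% continues. The area entering the 30% comparison is the
post-component-selection area, since the stopping rule is about the
nodule, not about noise that component selection removes. Centroids are
unweighted voxel-coordinate means.

## Evaluation

Per case the package reports Dice ($2|G \cap A|/(|G|+|A|)$), Jaccard
overlap ($|G \cap A|/|G \cup A|$), sensitivity, positive predictive value
and the symmetric average surface distance in millimetres. ASD surfaces
are mask voxels with at least one background 6-neighbour (border voxels
count as surface); distances are between voxel centres scaled
anisotropically by the spacing, and the metric is computed on the 3-D
surface rather than per slice because its definition is
dimension-agnostic and results are reported per nodule. Multi-rater
ground truth is fused with a 50% consensus: a voxel is nodule when at
least half the raters mark it, ties included. Cohort summaries use the
sample (n − 1) standard deviation.

## The phantom generator

Real thoracic CT with expert contours cannot ship with a package, so all
tests run on synthetic phantoms: a spherical nodule in a uniform lung
field (−800 HU-like) with additive Gaussian noise (default sd 30), in five
variants mirroring the clinically distinct classes — isolated (solid, 60),
juxtapleural (touching a 250-intensity wall slab), cavitary (an internal
air sphere at lung intensity whose voxels *remain* in the ground-truth
mask, since a cavity belongs to the nodule), calcific (a 500-intensity
core) and ground-glass (nodule/lung contrast scaled by 0.25). An optional
cylinder stands in for an attached vessel. The generator is deterministic
given its config and seed.

These phantoms exercise local intensity structure — which is what a
patch-based voxel classifier consumes — but they are deliberately not
anatomically realistic: no lung texture, no partial-volume or respiratory
artifacts, no irregular margins, no spiculation. Passing tests therefore
demonstrate that the machinery (patch geometry, pooling arithmetic,
gradients, sampling, propagation, metrics) is correct and that the network
can learn an easy, well-posed version of the task; they say nothing about
accuracy on clinical data.

## Numerical choices and conventions

* Coordinates are 0-based with half-open boxes everywhere; arrays are
  indexed (slice, row, col) and the axial plane is (row, col). NIfTI is
  the on-disk format.
* Patch borders reflect (edge-repeating symmetric reflection), on the
  slice axis too.
* A constant patch (zero standard deviation) z-scores to all zeros rather
  than dividing by zero. The 2-D branch channels are z-scored per channel
  by default (`normalize_2d`), keeping the two branches' input scales
  symmetric; the switch exists because normalisation there is a
  convention, not a necessity.
* The 65 → 35 rescale uses natural interpolating cubic splines applied
  separably with endpoints aligned; on a fixed grid this is a
  precomputed linear operator, so it is exact for linear ramps and cheap
  per patch.
* Convolutions are zero-padded "same", so the pooling chain alone
  controls spatial sizes; the filter counts of the deeper blocks and the
  fully connected widths are configuration defaults
  ((36,36)/(72,72)/(108,108), 256/128), since only the first block's 36
  filters are architecturally pinned down.
* Batch normalisation uses batch statistics in training and running
  statistics (momentum 0.1) at prediction time; the 1-norm regulariser
  covers convolutional and fully connected weight matrices only.
* Loss probabilities are clamped at 1e-7; cross-entropy of a perfect
  prediction is therefore ~1e-7, not 0.
* The training-mode forward/backward pass is exact (verified against
  central finite differences end to end, central pooling included); the
  2-D convolution kernel is compiled code with an im2col reference
  implementation kept as an independent check.

## Desk-scale study sizes

The package's end-to-end demonstration trains the `tiny = TRUE` preset
(filters (4,4)/(8,8)/(12,12), fully connected 32/16, ~70k parameters) on
a 30-phantom cohort (18 train / 2 validation / 10 test, radius 4 voxels,
44 × 44 × 20 volumes, noise sd 30, a 40/20/20/10/10 mix of
isolated/juxtapleural/cavitary/ggo/calcific), roughly 4,500 weighted
samples, batch 64, three epochs with epoch-wise validation DSC selecting
the returned weights. At this scale only a few hundred SGD updates happen,
so the published full-scale base rate of 6e-5 would leave the weights
essentially at initialisation; the smoke schedule uses 5e-3 — chosen from
that update-count argument, with momentum, decay and everything else
unchanged — while 6e-5 remains the package default for full-scale use.
The oracle-classifier pipeline (a plug-in classifier that returns the
ground-truth label) isolates the propagation stage and recovers sphere
phantoms exactly.

## Limitations

Single-nodule volumes only; nodule detection is out of scope (the
bounding box is user input). No data augmentation, no multi-view
non-axial patches, no GPU path — the implementation is CPU-oriented and
sized for method verification, not for full-scale clinical training.
DICOM series assembly and HU rescale handling are left to upstream tools;
volumes are consumed as NIfTI with spacing metadata.
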