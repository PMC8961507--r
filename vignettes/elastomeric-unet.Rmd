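---
title: "Elastomeric U-Nets: the model family, its compiler, and the training engine"
author: "eunet package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastomeric U-Nets: the model family, its compiler, and the training engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eunet)
```

## The model family

Encoder–decoder ("U-shaped") convolutional networks dominate biomedical
image segmentation: a contracting path extracts features at successively
halved resolutions, an expansive path restores resolution, and skip
connections concatenate each contracting layer into its equal-resolution
expansive partner. The elastomeric U-Net (EUNet) family generalizes the
single U in two directions:

* **Horizontal extension** cascades several U-structures in sequence,
  producing W-like elevation profiles. The layer where one expansive path
  ends and the next contracting path begins is a *peak*; a *high peak* sits
  at the input height, a *low peak* one level below it. Single, double, and
  three high-peak cascades (SHP/DHP/THP) use two, three, and four
  U-structures.
* **Spatial extension** runs several independently parameterized U-shaped
  branches in parallel. The input is split into the branches, and the
  branches are fused (*convergence*) at the valleys — the deepest,
  lowest-resolution layers — and at the branch output layers. Double and
  triple branch forms are conventionally written U\*UNet and U\*U\*UNet.

A compact notation names every member: `U_i(d-u)` is one U-structure with
`d` descending levels (valley included) and `u` ascending levels (terminal
layer included); `-` cascades segments and `//` joins parallel branches.
`U_1(4-4)-U_2(4-4)` is the single high-peak cascade, `U_1(4-3)-U_2(3-4)`
its low-peak sibling, `U_1(4)//U^1(4)` the double-branch network (a single
integer abbreviates the symmetric pair). Subscripts and superscripts are
opaque branch identifiers with no structural meaning.

Elevation bookkeeping makes the grammar semantic: the input sits at
elevation 0, each segment moves the profile by `u - d`, no peak may rise
above the input, and the cascade must return to elevation 0 so the output
layer sits at the input height. `parseArchitecture()` enforces exactly
these rules, and `formatArchitecture()` round-trips every accepted
architecture.

## From notation to layer graph

`buildLayerGraph()` compiles an architecture into an explicit DAG of layer
blocks whose operation schedule follows the published reference
configuration of the SHP cascade:

* **down block** at elevation $e$: two 3×3 convolutions at
  $f_d \cdot 2^{-e}$ channels, each followed by batch normalization and a
  rectified-linear activation, then a 2×2 max-pool;
* **valley**: the two convolutions, then dropout (rate 0.5, no pool);
* **up block**: 2× nearest-neighbour upsampling, a 2×2 convolution halving
  the channels, channel-axis concatenation with the equal-elevation skip
  partner of the same U-structure, then two 3×3 convolutions;
* **peak**: an up block that additionally ends with the next segment's
  2×2 pool;
* **terminal block**: an up block whose second convolution is 1×1;
* **output head**: a 3×3 convolution to 2 channels and a 1×1 convolution to
  1 channel with a sigmoid.

`inferShapes()` walks the graph and reproduces the reference feature-size
schedule (the 128/64/32/16 progression and the $f_d\times\{1,2,4,8\}$
multipliers) exactly:

```{r}
g <- buildLayerGraph("U_1(4-4)-U_2(4-4)", inputSize = 128, baseFilters = 64)
inferShapes(g)
```

Where the design was genuinely open, the package commits to one reading and
records it here:

* **Up-block operation order.** Architecture tables for this family list
  the 2×2 convolution before the upsampling, but only the reverse order
  (upsample, then 2×2 convolution) makes the listed channel counts and
  feature sizes consistent; the compiler upsamples first.
* **Peak semantics.** Prose descriptions of the peak can be read as adding
  a third convolution group that feeds the output layer. The compiler
  follows the operational schedule of the reference table — the peak block
  ends in the next segment's pool — and additionally exposes
  `peakToOutputConcat` (default `TRUE`), which concatenates the pre-pool
  peak features of every input-height joint into the output head,
  implementing "the output is the cascaded output of the input/output layer
  and peak layer" without contradicting the table. Low peaks sit at half
  resolution and are never concatenated.
* **Batch normalization** follows each 3×3 convolution, before the
  activation (`batchNorm = FALSE` disables it). Hidden activations are
  rectified-linear, the output is a sigmoid; Dice training of binary masks
  requires a (0, 1) output, and no other activation is prescribed by the
  family's description.
* **Branch fusion** is channel concatenation followed by a single 3×3
  convolution restoring the nominal channel count, applied at corresponding
  valleys and at the branch output layers; the fused valley feeds every
  branch's expansive path. This is the minimal information-preserving
  realization of the convergence points shown in the family's branch
  diagrams, which name the fusion locations but not the operator.
* **Cascade joints with unequal branch counts** (legal forms such as
  `U_1(3)//U^1(3)-U_2(5)`) are bridged by the output merge: all branches
  are fused before the next segment begins.
* **Raised segments.** In low-peak cascades such as `U_1(4-3)-U_2(3-4)`,
  the terminal block of the second segment sits above every layer of its
  own contracting path, so no equal-elevation skip partner exists inside
  that U-structure; since different U-structures share no interior
  connections, that block simply has no skip concatenation. All high-peak
  forms are unaffected.
* **Segments ending at their valley** (`u = 1`) cannot cascade into a
  deeper segment: that would force a pool onto a valley. The compiler
  rejects the combination rather than silently bending the valley
  invariant.
* **Input divisibility.** Each image side must be divisible by
  `2^maxDescent(spec)`; violations are configuration errors naming the
  required multiple. Note that divisibility by the full power is the only
  requirement — 48×48 is valid for a five-level U because 48 = 3·16, even
  though intermediate resolutions become odd only after the last pool.
  Odd-sized inputs at prediction time can be reflect-padded reversibly
  (`pad = "reflect"`), never silently cropped.

## The training engine

`realizeModel()` binds a graph to concrete parameters and an execution
plan; `trainModel()` and `predictModel()` run it. The engine is a compact
CPU implementation (im2col convolutions with BLAS matrix products behind
`Rcpp`/`RcppArmadillo`, exact max-pool/upsample adjoints, standard
batch-norm backpropagation) whose gradients are verified against finite
differences in the test suite.

* **Loss** is soft Dice,
  $1 - (2\sum pt + \varepsilon)/(\sum p + \sum t + \varepsilon)$ with
  $\varepsilon = 1$ by default, summed over all pixels of a batch. The
  family's description names the Dice coefficient loss but no formula; this
  is the standard smoothed form, and $\varepsilon$ is configurable.
* **Optimizer** defaults to Adam at learning rate $10^{-3}$ (plain SGD is
  available). No optimizer or schedule is prescribed for the family, so
  everything is exposed in `trainingConfig()`.
* **Initialization** is He-scaled Gaussian, drawn from per-convolution
  seed streams derived from the master seed; parallel branches use
  branch-offset streams, so the branches of a spatial EUNet start from
  different weights under one seed — the reading of "different random seeds
  for convolution" consistent with independent parallel branches — while
  the same (graph, seed) pair always reproduces identical parameters.
* **Determinism.** With `deterministic = TRUE`, dropout masks and batch
  order derive from the configuration seed; a rerun from the same realized
  model is bitwise identical. Batch statistics use the biased variance;
  running statistics (momentum 0.9) serve inference. Max-pool ties resolve
  to the first maximum in scan order.
* **Masks** binarize at the standard 8-bit threshold (pixel value > 127).
  Train/validation splits are explicit file lists, never randomized at
  training time.

## Synthetic phantoms

`generatePhantoms()` provides seeded stand-ins for the two evaluation
regimes the family was designed around:

* **cell mode** emulates small, low-resolution fluorescence microscopy
  images of cells: 3–7 soft-edged ellipses (semi-axes between 1/12 and 1/6
  of the image side) with multiplicative low-frequency texture on a
  textured background, additive Gaussian noise (sd 0.05), and the mask as
  the exact union of the ellipse supports. The 128×128 default matches the
  scale of such datasets; the set-level foreground fraction is asserted to
  stay within a configurable band (default 5–40%).
* **vessel mode** emulates thin bright curvilinear structures: smoothed
  random-walk tracks dilated to widths 1–4 px on a textured background,
  with the mask as the exact track support. Real retinal images are
  ~584×565 RGB; the phantoms default to a scaled-down single-channel
  geometry (the comparison workflows in this package use 64×64) with a
  2–30% prevalence band, bracketing the ~9% vessel density of retinal
  photographs.

Images are quantized to the 8-bit grid at generation, so the PNG
write/read round-trip is pixel-identical. The phantoms reproduce the
*geometry* of the two regimes — blob-like versus curvilinear foreground,
texture, noise — but not the optics of real data: no point-spread blur
model, no illumination falloff or field-of-view border, no RGB fundus
coloration, no inter-patient variability. Passing the package's training
and comparison checks on phantoms therefore demonstrates that the
architectures are built correctly and can be optimized, not that any
variant reaches a particular accuracy on real microscopy or retinal data.

## Problem sizes used by the checks

The test suite exercises the published arithmetic at full size (the
128×128 reference schedule) and everything trainable at toy scale, the
package's choice for fast, deterministic verification: the five named
variants (SHP, DHP, THP, U\*UNet, U\*U\*UNet) at $f_d = 4$ on 32×32
phantoms must each memorize a 4-image set to Dice loss ≤ 0.05 within 500
epochs (one image per optimizer step, Adam at 3·10⁻³), and the comparison
workflow runs U-Net, SHP, and U\*UNet over a 40-image 64×64 vessel set
split 20/20. Benchmark-scale training (90-image microscopy sets, full
retinal images, hundreds of epochs at $f_d = 64$) is supported by the same
code paths but is a GPU-scale undertaking outside the scope of the checks;
the original benchmark tables additionally depend on a private dataset and
unpublished hyperparameters, so they are not reproduction targets.

## Known limitations

* The engine is single-threaded CPU code built for correctness and
  determinism; it is not a performance substitute for a deep-learning
  framework at benchmark scale.
* No data augmentation, no deep supervision, no nested-skip (UNet++-style)
  builder — the latter is a different published design that a comparison
  harness may plug in externally.
* Mean IoU is defined as the two-class mean (foreground and background
  IoU); micro-averaging over pixels is the default for dataset reports.
  Published tables for this family do not state their averaging
  convention, so these definitions are declared rather than inferred.
* The low-peak/high-peak mixing question (whether a cascade may descend
  below elevation −1 through repeated low transitions) is not settled by
  the family's description; the parser accepts any elevation-balanced
  cascade that never rises above the input, without claiming endorsement
  for the exotic forms.
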