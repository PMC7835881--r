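---
title: "One-shot classification and segmentation of cryo-ET subtomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-shot classification and segmentation of cryo-ET subtomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cryo-electron tomography images macromolecular complexes inside intact
cells, but every particle must then be classified into a structural class
and segmented from its 32-cube neighbourhood. Supervised 3D networks do
this well only with large labelled training sets, and must be retrained
whenever a new structural class appears. `tomoshot` implements a one-shot
alternative: a Siamese network is trained to decide whether two
subtomograms show the same structure, so at test time a *single* manually
picked example per candidate class (the support set) suffices to classify
a target subtomogram — including classes the network has never seen — and
the same forward pass yields a voxel-level segmentation.

## Model

Both input streams (support and target) run through one shared parameter
set with three parts:

* **Volume encoder.** Three levels, each two 3×3×3 convolutions with a
  leaky rectifier (negative slope 0.05), a dual squeeze-and-excitation
  block, and 2× max pooling, taking a 32³ cube to a 4³ latent grid.
  Channel widths are configurable (`model_config(channels = ...)`;
  32/64/128 is the reference setting). The leak matters at small
  widths: with two channels in a level, one permanently dead rectifier
  erases half that level's capacity, and plain ReLU training outcomes
  were bimodal across initialization seeds.
* **Volume decoder.** Mirrors the encoder with trilinear upsampling and
  ends in a 1-channel sigmoid convolution: a per-voxel foreground
  probability map. Its Dice loss against the ground-truth masks acts as
  an attention signal that shapes the shared encoder features, and its
  output seeds the final segmentation.
* **Feature encoder.** A reduction of the latent grid
  (`model_config(fe_adapter)`: global average pooling, or the flattened
  grid itself), a linear adapter to 512 dimensions, then a 512×512
  fully connected layer, with the output projected onto the unit
  sphere. An adapter is needed because the fully connected layer is
  defined on a 512-vector while the latent is a channel × space grid;
  pooling gives one value per channel and some built-in pose
  robustness, but at small channel counts it discards the spatial
  structure that distinguishes unseen classes, so the desk-scale
  experiments use the flatten adapter (at channels (2, 4, 8) the
  flattened 4³×8 latent is exactly 512-dimensional). The unit-sphere
  normalization is standard metric-learning practice that keeps the
  initial matching logits on a seed-independent scale — without it,
  some initializations start with saturated pairwise sigmoids and the
  matching loss never escapes the trivial 0.5 fixed point.

Support and target embeddings are compared elementwise,
`F_dis = |F_S2 − F_T2|`, and a final linear head maps the 512-length
distance vector to one logit per support class. The head optionally
carries a monotonicity prior (`model_config(head_monotone = TRUE)`): its
weights on the distance coordinates are initialized nonpositive and kept
nonpositive (projected after every optimizer step), so a match score can
only fall as any embedding coordinate moves further from the support.
The matching output is specified only as "a fully connected layer", and
the unconstrained layer is the default; but a head trained on only a
handful of classes learns sign patterns specific to those classes'
embedding layout and transfers poorly to unseen classes, so the
package's desk-scale experiments enable the prior. (The prior makes
even an untrained model mildly informative — it then scores like
nearest-neighbour on random features — while the unconstrained default
behaves at chance until trained.)

The dual squeeze-and-excitation (DuSE) block recalibrates features along
both axes: the channel branch pools each channel globally, passes the
pooled vector through a bottleneck (`w1 ∈ R^{C/2×C}`, ReLU,
`w2 ∈ R^{C×C/2}`, sigmoid) and rescales channels; the spatial branch
squeezes channels with a 1×1×1 convolution `w3`, applies a sigmoid and
rescales voxels. The two branches are summed elementwise. The bottleneck
ratio is C/2, following the weight shapes above rather than the C/16
common elsewhere.

### The two head modes

The training objective is binary: each of the n² ordered support pairs
carries a match/no-match label and a sigmoid + binary cross-entropy
loss. Inference instead needs one decision across n support classes, so
the same head logits are passed through a softmax over the support set
and the argmax (ties to the lowest index) is the prediction. Both modes
share the head weights; this dual-mode reading is our resolution of the
otherwise conflicting pairwise-label and softmax formulations of the
matching output.

## Training strategy

Each episode draws two n-class single-sample support sets over the same
randomly chosen classes; the n² ordered pairs are labelled by class
match (exactly n positives). The loss is

```
L_tot = L_dsc + L_bce
```

with unit weights: `L_dsc = 2 − mean DSC(set A) − mean DSC(set B)` is a
soft Dice on the decoder probabilities (product intersection, sum
cardinality, ε = 10⁻⁶), and `L_bce` is averaged over the n² pairs so the
1:1 balance does not depend on n. Averaging BCE over pairs, and soft
rather than hard Dice, are our choices — required respectively to keep
the balance n-independent and to make the segmentation term
differentiable. Optimization uses Adam (default learning rate 10⁻³),
fully seeded; the optimizer is not specified by the original description
of the method, so the field default is used and exposed in
`train_config()`.

Because the Dice term only ever sees the *training* support sets'
predictions and masks, segmentation of unseen test classes never touches
their labels: at test time the decoder map of the target is refined by
the CRF without any class supervision.

Episode records are pose-augmented by default
(`train_config(augment_poses = "inplane")`): each sampled record
(volume and mask together) is rotated by a fresh uniform angle about
the beam axis before the forward pass. In-plane rotations are the
natural augmentation group for tomographic data because every
subtomogram — simulated or experimental — carries its missing wedge
along the same beam axis, so rotating about that axis generates valid
new examples without disturbing the artifact geometry, whereas full
SO(3) augmentation (`"so3"`, also available) asks the network to
ignore wedge orientation, a variation the evaluation data never
exhibits. Augmentation emulates a larger pool of particle poses per
class — particularly important when the training split holds only a
few classes.

Weights are He-normal with zero biases, drawn from the configuration
seed; under the monotone head prior the head weights are additionally
initialized nonpositive.

## CRF refinement

The decoder map `P` defines unary potentials `−log P(x_i)`; the pairwise
potential couples every ordered voxel pair `(i, j)` with

```
ψ_p = μ(x_i, x_j) [ w1 exp(−|p_i−p_j|²/2σ_α² − (I_i−I_j)²/2σ_β²)
                  + w2 exp(−|p_i−p_j|²/2σ_γ²) ]
```

where μ is 1 for differing labels and 0 otherwise, `p` are voxel
coordinates and `I` the subtomogram intensities standardized to zero
mean and unit variance (so σ_β is in intensity standard deviations).
Inference is synchronous mean-field with the pairwise messages truncated
to 3σ neighbourhoods; the dense all-pairs evaluator (`crf_energy`, and
an all-pairs mean-field reference) is quadratic in the voxel count and
kept as the test oracle. The five kernel parameters are described as
learnable in the source formulation but no training procedure for them
is given; here they are hyperparameters with defaults
(w1 = w2 = 1, σ_α = 2, σ_β = 0.5, σ_γ = 1, 5 iterations) and a
validation-split grid search (`crf_grid_search`). When the CRF is
disabled the decoder map is thresholded at 0.5.

## The simulator

The synthetic data generator reproduces the standard cryo-ET image
formation chain:

1. **Packing.** Randomly posed copies of the class density maps are
   placed at uniform positions with bounding-sphere rejection sampling
   (max 1000 retries per particle), so particles never overlap.
   Rotations are uniform on SO(3) by the unit-quaternion method.
2. **Projection.** Single-axis tilt geometry; each projection is the
   line integral along the tilted beam. The default tilt scheme is ±60°
   in 2° steps — the canonical missing-wedge condition; range and step
   are configurable because the reference experiments do not state them.
3. **Optical factors.** Each projection is multiplied in the frequency
   domain by the CTF (300 kV, −5 μm defocus, Cs 2 mm, 7% amplitude
   contrast by default) and a Gaussian MTF envelope (cutoff 0.4 Nyquist).
4. **Noise.** Zero-mean Gaussian with variance var(signal)/SNR per
   projection image. SNR = var(signal)/var(noise) on projections is the
   standard subtomogram-simulation convention; the reference SNR levels
   are ∞, 1000 and 0.5.
5. **Reconstruction.** Ramp-filtered (weighted) back-projection; the
   back-projector is the exact adjoint of the projector, which makes
   adjointness testable and leaves the expected missing-wedge artifacts
   when the tilt span is under 180°.
6. **Extraction.** 32³ subtomograms around each in-bounds particle, with
   the ground-truth mask taken as the support of the identically posed
   source map. How ground-truth masks were derived from the known
   structures is not stated in the source description; support of the
   noiseless density (threshold fraction 0, configurable) is our
   stand-in.

Geometric phantoms (sphere, spherical shell, dumbbell, torus, L-shape,
plate, helix, three-rod cross) stand in for macromolecular density maps
so every experiment is reproducible without external files; atomic
models can be rasterized as sums of Gaussians
(σ = resolution/(π√2), a standard resolution convention) when PDB/mmCIF
coordinates are available.

### What the generator does and does not emulate

It reproduces random poses, the missing wedge, CTF/MTF modulation,
projection-space Gaussian noise, and reconstruction artifacts. It does
not simulate dose-dependent or detector-physics noise, tilt-series
misalignment, stage drift, crowding by non-target densities, or
structural heterogeneity within a class. Passing tests on this data
therefore demonstrates the correctness of the pipeline and the learning
dynamics of the model under controlled conditions, not performance on
experimental tomograms.

## Desk-scale experiment sizes

The package's own experiments are sized for a single CPU: a
170×170×110-voxel tomogram packed with 150 requested particles
(bounding-sphere rejection accepts about 106) over 6 phantom classes,
32³ subtomograms, channels (2, 4, 8) with the flatten adapter and the
monotone head, and 2-way-1-shot training of 30 epochs × 20 episodes
with in-plane pose augmentation. The class split holds out the sphere
and the torus: the two test structures are distinguishable without
subtomogram alignment, whereas a hold-out pair of elongated rod
assemblies (L-shape vs three-rod cross) is ambiguous across arbitrary
relative orientations — the same alignment limitation the method's
outlook discusses. The reference-scale setting (600×600×300 tomograms,
10,000 particles, 22 classes, channels 32/64/128) is reachable through
the same configuration objects. Class splits are class-disjoint by
construction: evaluation classes are never sampled during training.

## Numerical choices

* Rotation resampling is trilinear about the geometric grid centre with
  zero outside the grid — the simplest scheme consistent with 32³
  resolution. Phantom solids are centred on an integer voxel so discrete
  voxel counts track analytic volumes.
* Projections keep integer sample points at 0° tilt, so the 0°
  projection equals the beam-axis sum exactly; the ray parameter range
  covers the volume diagonal, conserving projected mass at any angle.
* BCE scores are clipped to [10⁻⁷, 1 − 10⁻⁷]; CRF unaries clip
  probabilities at 10⁻⁸; soft Dice uses ε = 10⁻⁶ and treats an all-zero
  prediction with an all-zero mask as perfect.
* Max-pooling ties resolve to the lowest within-cell index; the argmax
  over support scores resolves ties to the lowest class index.
* All randomness flows from one top-level seed through named sub-streams
  (`substream_seed`), so stages are independently reproducible.

## Known limitations

* No subtomogram alignment: support and target poses differ freely,
  which caps matching accuracy exactly as discussed in the source
  method's outlook; alignment preprocessing is out of scope.
* K > 1 (few-shot) episodes, multi-label CRFs, and end-to-end
  differentiable CRF training are not implemented.
* The hand-written network runs on CPU only; reference-scale training
  is possible but slow.
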