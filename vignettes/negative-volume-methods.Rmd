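---
title: "Negative-volume segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Negative-volume segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the method

Assessing the health of a ball-and-socket joint — the temporomandibular
joint (TMJ) between the mandibular condyle (MC) and the temporal bone (TB)
is the motivating case — requires measuring the *joint space*: the empty
volume between the two bones.  Bones can be segmented and meshed, but the
space between them has no intensity signature of its own and is bounded by
two surfaces that never touch.  `negvol` extracts this space as a solid,
the **negative volume**, by a geometric construction:

1. **Localize** the two joints in the head scan by coarse low-resolution
   segmentation, and crop a volume of interest (VOI) around each.
2. **Segment** the condyle with a volumetric convolutional network (step A)
   and the socket bone with a network heatmap fused with a classical
   image-processing route (steps B + C).
3. **Reconstruct** triangle meshes from the masks (step D).
4. **Inflate** the condyle mesh along its vertex normals, with Laplacian
   regularization, until it is stopped by the socket-bone surface; **clip**
   the mandibular neck with a plane; subtract the original condyle solid
   (step E).  What remains is the negative volume.
5. **Quantify left–right symmetry** of the two negative volumes with the
   Hausdorff cloud-to-cloud distance

   $$H_{LR} = \max\Big\{\sup_{l \in \mathcal L}\inf_{r \in \mathcal R} d(l,r),\;
     \sup_{r \in \mathcal R}\inf_{l \in \mathcal L} d(l,r)\Big\}$$

   and the surface-area ratio

   $$S_{LR} = \frac{\max\{S_L, S_R\}}{\min\{S_L, S_R\}} \ge 1 .$$

Joint-space asymmetry is the clinically interesting signal: a widened or
narrowed space on one side changes both the shape (raising $H_{LR}$) and
the surface area (raising $S_{LR}$) of that side's negative volume.

# The synthetic phantom

Clinical CT cohorts of this anatomy are not openly available, so the
package ships a fully synthetic test substrate with *analytically known*
answers.  A phantom joint is a ball-and-socket caricature of the TMJ:

* a **condyle**: ball of radius $r$ (default 6 mm) on a cylindrical neck;
* a **socket**: hemispherical cavity of radius $r+g$ carved into a slab
  disc, with a short cylindrical lip wrapping below the equatorial plane;
* a **joint space**: the upper hemispherical shell between them, of
  thickness $g$ (default 2 mm), so that

  $$V = \tfrac{2}{3}\pi\big[(r+g)^3 - r^3\big], \qquad
    S = 2\pi (r+g)^2 + 2\pi r^2 + \pi\big[(r+g)^2 - r^2\big].$$

Intensities are three tissue plateaus (bone 0.85, soft tissue 0.35, air in
the joint space 0.05) plus Gaussian noise (default sd 0.03).  A **head**
phantom embeds a left and a right joint mirror-symmetrically about the
mid-sagittal plane; the right-side gap is scaled by an `asymmetry_factor`,
so for a factor $a$ the analytic $S_{LR}$ of the pair is known in closed
form.  With $r = 6$, $g = 2$ mm, factors 1.25–1.35 give analytic
$S_{LR} \approx 1.11$–$1.15$ — deliberately subtle asymmetries.

Three geometric details of the phantom matter and were chosen once:

* the slab must be at least $r + g$ thick so the socket is closed at the
  top (otherwise the inflation escapes and the closed form does not apply);
* a 2 mm lip below the equator confines the joint space laterally, playing
  the role of the articular eminence;
* the slab is a finite disc (socket radius + 3 mm) so the two joints of a
  head remain spatially separate, as real joints are.

What the phantom does **not** emulate: trabecular texture, the articular
disc and other soft tissues, CT physics (beam hardening, HU calibration),
head tilt, or anatomical shape variability.  Passing the phantom study
therefore demonstrates that the geometry pipeline is correct and that the
learning components can be trained and deployed end-to-end — not that the
shipped toy networks would segment clinical scans.

# Networks and training

Three architectures are implemented natively (forward and backward passes,
Adam) as a small static computation graph: **V-Net** (5³ kernels, residual
stages with 1/2/3/3/3 convolutions per level, strided down-convolutions),
**3D U-Net** (two 3³ convolutions per level, max pooling) and an
**attention-gated 3D U-Net** (sigmoid gates on the skip connections).  The
published V-Net design reads two ways — its text halves the channels at
each up-convolution while its figure runs decoder stages at twice the skip
width — so both decoder schedules are available (`vnet_decoder = "halve"` /
`"skip"`).

The loss is the weighted sum of soft Dice (smoothing $\varepsilon=10^{-5}$)
and voxelwise cross-entropy, default weights $(1, 1)$ — a linear
combination with unstated weights in the source method.  Optimization is
Adam ($\beta_1 = 0.9$, $\beta_2 = 0.99$) with additive L2 weight decay.
Augmentation composes left–right flips, 3D rotations, integer translations,
gamma contrast changes, and elastic deformations (smoothed displacement
fields capped at 4 voxels), with the identical geometric transform applied
to image (trilinear) and mask (nearest neighbour).

**Analytic compute cost.**  `count_flops()` walks the same graph the
builder constructs and counts one multiply–accumulate as two FLOPs, plus
bias adds, activations, residual/gating elementwise work, pooling
comparisons and the softmax.  Transposed convolutions are counted by the
*profiler convention* (kernel volume × input channels × output channels ×
output elements), as the widely used network profilers report them, which
makes the counts comparable with published figures; the true dataflow count
for a non-overlapping stride-2, kernel-2 up-convolution is 8× lower and is
available via `transposed = "dataflow"`.  `flops_grid()` tabulates the
standard width/depth/decoder variants at a given patch so a published
compute figure can be attributed to a configuration.  Under this
convention, a half-width V-Net (base 8, depth 5, "halve" decoder) at a
112×144×64 patch counts 320.3 GFLOPs; no standard 3D U-Net configuration
lands near the corresponding published U-Net figure under the same
convention (the nearest, a plain-schedule base-32 depth-5 net, counts
694.6 GFLOPs), which is consistent with that figure having been produced
with a MACs-based (factor-two different) convention.

# Geometry: reconstruction, inflation, Booleans

**Isosurfaces** are extracted by marching tetrahedra on a 6-tetrahedra cube
decomposition whose face diagonals are shared between neighbouring cubes,
so the triangulation is watertight and consistently oriented by
construction.  Binary masks produce staircase surfaces whose vertex normals
are unreliable — fatal for a normal-driven inflation, where near-tangential
normals stall whole regions of the front — so meshes intended for inflation
are extracted from a lightly box-smoothed field
(`mask_to_mesh(smooth_radius = 1)`); the 0.5 level set moves by well under
a voxel.

**Inflation** moves every free vertex by `step` along its area-weighted
vertex normal per iteration, then applies Laplacian smoothing
$v \leftarrow (1-\lambda)v + \lambda\,\overline{N(v)}$ with
$\lambda = 0.2$ by default ($\lambda = 1$ is rejected: it collapses the
mesh towards neighbour means).  Collision with the bounding solid is
tested on a signed-distance field of the socket mesh (ray-parity inside
test + exact Euclidean distance transform, trilinearly sampled); a vertex
whose move would bring it within `collision_tolerance` (default 0.05 mm)
of the surface is frozen at the contact point found by bisection along its
motion segment.  Defaults `step = 0.1` mm and `max_iters = 500` suit
sub-millimetre joint spaces; phantom studies size the iteration budget to
sweep about twice the expected gap, because the region outside the finite
socket is unbounded (it is clipped away afterwards) and letting it balloon
for hundreds of iterations serves nothing.

**Clipping** removes the half-space on the negative side of the neck plane
and caps each cut loop with a triangle fan around its centroid, so
watertight inputs stay watertight; vertices exactly on the plane are nudged
to the kept side so cuts never pass through vertices.  The default neck
plane is a heuristic (minimal cross-section along the mesh's principal
axis); phantoms carry their exact equatorial plane, and the pipeline
accepts an explicit plane in its configuration.

**Booleans** are computed robustly on a voxel grid: both solids are
rasterized by ray parity on a common fine grid (default 160 voxels along
the longest axis), combined voxelwise, and re-meshed.  This trades exact
geometry for unconditional robustness; at the default resolution the
volume of analytic test solids is recovered within 1–2%.  The identity
$\operatorname{vol}(A \setminus B) =
\operatorname{vol}(A) - \operatorname{vol}(A \cap B)$ holds within 1% on
analytic solids and is part of the test suite.

# Symmetry metrics

$H_{LR}$ is computed between point clouds sampled from the two
negative-volume surfaces — mesh vertices by default, optionally
uniform-area surface samples — after the right mesh is reflected across the
mid-sagittal plane and aligned (centroid match by default, optional rigid
ICP; the applied transform is reported).  How left and right are
co-registered before the distance, and which points enter the clouds, are
not specified by the source method; both choices are explicit options
here.  The reported spread of $H_{LR}$ (mean ± sd) is computed over 20
seeded subsamples of 50% of each cloud — an explicit interpretation of the
± convention in per-patient tables of this kind.  $S_{LR}$ uses the exact
mesh surface areas.  A pair is flagged asymmetric when $S_{LR}$ exceeds a
threshold: the package default 1.15 follows the convention of bolding
patients near 1.17–1.21 as unhealthy in the source clinical table and is a
heuristic, not clinical guidance; phantom studies instead derive the
threshold from the cohort's own analytic geometry (midpoint between the
symmetric value 1 and the smallest asymmetric analytic $S_{LR}$), fixed
before any pipeline output is seen.

# The classical enhancement route

The socket bone is the hard segmentation target, so the pipeline
supplements the network heatmap with a deterministic classical route:
slice-wise median denoising, minimum-method histogram thresholding (256
bins smoothed with a 3-bin moving average until exactly two maxima remain;
the threshold is the deepest valley), morphological closing then opening
with true Euclidean ball elements (built on the exact distance transform),
slice-wise Canny edges linked across slices by 3D hysteresis (the package's
realization of "3D Canny"; plain 3D gradient-magnitude thresholding is a
config switch), and hole filling.  Two guards reject volumes without bone
structure, both fixed a priori from the behaviour of the statistics on the
two regimes: a spurious valley in a distribution tail leaves less than
`min_minority_fraction` (2%) of the mass on one side, and a spurious
mid-histogram split of pure noise yields speckle of which less than
`min_solidity` (20%) survives an opening — solid bone retains well over
half.  Fusion with the network heatmap is
`(classical ∩ dilate(heatmap ≥ τ)) ∪ (heatmap ≥ τ_core)` with τ = 0.5,
τ_core = 0.9 and dilation radius 3 — the fusion operator is unspecified in
the source method, so the rule guarantees two checkable bounds
(core ⊆ output ⊆ classical ∪ core) and monotonicity in τ, and every
constant is config-exposed.

# The scaled-down phantom study

`phantom_study()` is the package's end-to-end experiment at desk scale,
with every size chosen once for a single-CPU run:

* cohort of **10 heads** (52×52×56 half-grids, 0.5 mm voxels), 3 of them
  with asymmetry factors drawn from [1.25, 1.35];
* condyle V-Net: base 4 channels, depth 3, trained on the 14 joints of 7
  training patients (**32³ patches**, 30 epochs, Adam 3e-3, batch 2) with
  mild augmentation — integer translations (±3 voxels), flips and gamma
  contrast.  Integer translations and flips transform the target masks
  exactly, adding no boundary label noise, and make the network tolerate
  the few-voxel centring jitter of pipeline VOIs (networks this small,
  trained on 14 examples, otherwise learn absolute patch position);
* localization V-Net of the same size on whole heads at 32³, 14 epochs;
* pipeline VOIs of 48³ voxels centred on each side's coarse-mask mass
  centroid (robust to thin structures missed at coarse resolution, unlike
  the box centre), with the network applied to a centred 32³ sub-crop —
  the layout it was trained on — and the geometry stages run on the full
  VOI so the socket is never truncated;
* inflation step = gap/10, 22 iterations; Boolean grid 112.

On held-out patients the condyle Dice is ~98%; the pipeline's negative
volumes track the analytic shells with a systematic deficit of roughly
15–20% (the predicted condyle boundary sits about half a voxel outside the
plateau edge, and the frozen inflation front stops `collision_tolerance`
short of the socket), which cancels in the left–right ratio: symmetric
pairs score $S_{LR} \approx 1.00$ and the asymmetric phantoms are the ones
flagged.  With ground-truth meshes (isolating the geometry from the
learned segmentation) the recovered volume is within ~4% of the closed
form at 0.5 mm voxels.

# Degenerate inputs and numerical choices

* Min–max normalization of a constant volume returns zeros (no division by
  zero); the operation is idempotent.
* Voxels are half-open cubes; a voxel's centre is `origin + (i-1)*spacing`;
  masks voxelized from meshes use a strict centre-inside parity test with a
  deterministic sub-voxel ray jitter so rays never hit edges exactly.
* "Bicubic" resizing of a 3D stack is implemented as Catmull-Rom in-plane
  plus linear along z (`bicubic-per-slice`), with pure trilinear as the
  isotropic default; both preserve physical extent exactly.
* The minimum-method threshold falls back to 0.5 (with a warning) on
  unimodal probability histograms in localization postprocessing.
* Hausdorff distances use an exact $O(N^2)$ computation with early
  termination; segmentation HD uses surface voxels and the exact Euclidean
  distance transform.  If exactly one mask is empty the distance is
  reported as `Inf`; two empty masks are an error.
* Meshes are checked for watertightness combinatorially (every directed
  edge once, every undirected edge twice); enclosed volume uses the signed
  tetrahedron sum and is only defined for watertight meshes.

# Known limitations

* The voxel-based Boolean and the SDF collision test are resolution-bound;
  sub-voxel features of the negative volume are smoothed at the default
  grids.
* Inflation has no self-intersection repair; heavily non-convex sockets
  may fold the advancing front (the trace's frozen fraction and volume
  monotonicity are the practical diagnostics).
* The DICOM reader covers exactly the uncompressed explicit-VR
  little-endian axial series the package writes; it is a testing aid, not
  a general DICOM implementation — use NIfTI for real data.
* The shipped networks are deliberately tiny; segmenting clinical CT would
  require training at realistic size and resolution, which is outside the
  scope of a CPU-bound package.
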