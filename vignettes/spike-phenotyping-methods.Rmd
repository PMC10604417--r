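---
title: "Virtual spike phenotyping from micro-CT slices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual spike phenotyping from micro-CT slices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeCT)
```

## The problem

X-ray micro-CT lets a cereal spike be measured without threshing it: a
dried spike fixed upright in a plastic holder is scanned at 75--95 µm per
pixel, reconstructed into a stack of 8-bit transaxial slices, and every
grain can then be counted and measured in place, including its position
along the rachis. Two image-analysis obstacles stand between the slice
stack and those traits. First, each slice mixes grain tissue with the
rachis, awns, dust, and the bright cross-section of the holder, so grain
pixels must be isolated per slice. Second, the stacked binary volume — the
*virtual spike* — is a single connected-looking cloud of foreground voxels
that must be split into individual grains before any per-grain measurement
is possible.

spikeCT implements the full chain: holder removal, per-slice semantic
segmentation by a small UNet followed by mask-assisted Otsu thresholding,
stacking into a NIfTI volume, density-based clustering of the voxel point
cloud into grains, and per-grain morphometry (volume, alpha-shape surface
area, oriented-box length/width/thickness, bottom-up position), plus the
validation statistics used to compare virtual against manual measurements.

Because real scans are large and scanner-specific, the package carries a
*phantom generator* that renders synthetic spikes with exact voxel-level
ground truth. Every stage of the pipeline is tested against phantoms, and
all numbers quoted in this vignette are produced by the test suite or the
acceptance script, not copied from elsewhere.

## The phantom: what it emulates and what it does not

`phantom_spec()` / `generate_phantom()` render, at a chosen pixel size
\(P\) (default 85 µm):

* ellipsoidal grains attached in two-row or six-row arrangement along a
  vertical rachis cylinder, long axis pointing radially outward with a
  random tilt (default up to 8°) from the horizontal;
* a bright holder ring on every slice (the plastic holder's cross
  section);
* optional thin awn/dust impurity segments;
* i.i.d. additive Gaussian noise (default sd 12 grey levels), clipped to
  0..255.

A voxel belongs to a shape iff its centre satisfies the analytic
inequality. This rule has an exact enumeration oracle, so rasterized grain
voxel counts can be checked against \(\tfrac43\pi abc\) (they agree within
a fraction of a percent for the default sizes) and every truth label can
be verified independently.

Deliberate simplifications: grains are homogeneous ellipsoids (no
embryo/endosperm contrast, no crease), noise is white (no beam hardening,
ring artifacts or scatter), and grain surfaces are smooth. Passing tests
on phantoms therefore demonstrates the correctness of the geometry,
clustering and measurement code and the learnability of the segmentation
task — not robustness to every artifact a physical scanner produces.

Two geometric defaults deserve a note:

* **Clearance.** Default axial spacing keeps at least ~9 voxels between
  grain surfaces, one more than the largest clustering radius in use
  (eps ≤ 7), so the clustering ground truth is unambiguous. Touching-grain
  stress phantoms can be built by shrinking `axial_spacing`; no recovery
  guarantee is made for them.
* **Minimum grain size.** Box extents measured on a voxel set carry a
  worst-case half-voxel error at each end (see the OBB convention below),
  i.e. a relative error up to \(1/(2c)\) on the smallest dimension. The
  default semi-axes (smallest ≥ 10.2 voxels) keep that bound under 5%,
  which is what makes 5%-level parameter-recovery checks meaningful at
  all. Grains much smaller than ~20 voxels across cannot be measured to
  that accuracy at any algorithmic skill, only scanned at finer pixel
  size.

## Per-slice segmentation

**Holder removal.** The holder appears as a bright circle surrounding the
spike. `remove_holder()` zeroes everything at and beyond a circular ROI;
`detect_holder()` estimates the ring radius from the radial intensity
profile of a slice and backs off 3 px. The operation is idempotent.

**UNet.** `build_unet()` is a classic encoder–decoder with skip
connections: per level two 3×3 convolutions + ReLU, 2×2 max pooling,
channel width doubling from `base_channels`; nearest-neighbour upsampling
and skip concatenation on the way up; a 1×1 convolution to one logit
channel. Training (`train_unet()`) minimises binary cross-entropy on
logits with Adam (defaults: lr 1e-3, β 0.9/0.999, batch 4, 40 epochs at
full scale), shuffles each epoch, and keeps the checkpoint with the lowest
epoch loss rather than the last. The paper-scale protocol (512×512 input)
is config; the tested, scaled-down study condition is 64×64 slices, depth
4, base 16, 200 phantom slices, 10 epochs, one CPU, which reaches held-out
foreground IoU ≈ 0.99 against phantom truth (the acceptance bound is
0.85). All randomness flows from one seed; forward/backward passes are
plain BLAS chains, so a rerun reproduces the loss history bit for bit.

**Mask-assisted Otsu.** The network's mask is not the final answer: its
blobs can bleed past grain boundaries. `assisted_segment()` zeroes the
original image outside the prediction and applies Otsu's criterion to the
masked image — the zeroed background included in the histogram — keeping
only in-mask pixels above the threshold. The output is therefore always a
subset of the prediction, and false-positive blobs lying below the
threshold vanish. Including the zeros is essential: restricting the
histogram to in-mask pixels only would, for an *accurate* mask whose
interior is pure grain tissue, make Otsu split the grain intensity class
against itself and silently halve grain volumes (this failure mode was
caught by the end-to-end phantom check during development). A constant
masked image is flagged degenerate and the prediction returned unchanged.
Otsu's threshold itself (`otsu_threshold()`) maximises between-class
variance over the 256-bin histogram, ties broken toward the smaller
threshold, and is tested for exact equality against an exhaustive search.

**Metrics.** `seg_metrics()` reports precision, recall, per-class IoU,
and overall pixel accuracy from pixel confusion counts. In this binary
setting the class means (mIoU, mPA) are taken over the two categories,
grain and background; a category absent from both masks scores 1. The
implementation is tested for exact equality against brute-force per-pixel
counting.

## From binary volume to grains

**Point cloud.** Each foreground voxel contributes one point at its
centre, in `(z, y, x)` voxel coordinates; z is the slice index with the
spike base at small z (a `flip` flag covers base-up scans).

**Clustering.** `cluster_grains()` is DBSCAN with a closed-ball core rule:
a point whose eps-ball (default eps = 4 voxels; scans in the source
protocol used 3–7) holds at least `min_points` (default 10) points is a
core point; clusters are maximal density-connected sets, grown in
ascending point order so border-point assignment is deterministic.
Clusters below `min_cluster_voxels` (default 50) are set aside as debris —
dust and awn fragments that survive segmentation. The implementation is
checked for exact partition equality against an O(n²) BFS oracle.

**Volume and surface (the two unit formulas).** With \(n\) voxels at
pixel size \(P\) µm,
\[ V = nP^3/10^9 \ \mathrm{mm}^3, \qquad S = mP^2/10^6 \ \mathrm{mm}^2, \]
where \(m\) is the mesh area (in voxel²) of the reconstructed surface.

**Surface reconstruction.** The mesh is the alpha shape (default
alpha = 12 voxels) over the grain's contour shell — the voxels with at
least one 6-connected background neighbour. Implementation: for
`alpha` at least the point-set diameter the alpha shape is the convex
hull, computed directly by quickhull (this branch is exact: the hull of a
10³ voxel cube's points has area exactly \(6\cdot 9^2\) voxel²).
Otherwise boundary triangles are found by the alpha-exposure criterion —
a triangle with circumradius ≤ alpha is on the boundary iff one of its two
alpha-balls is empty — restricted to candidate edges up to the lattice
chord \(2\sqrt{2\alpha}\), the span of a ball of radius alpha resting
across unit voxel steps. Two properties of this definition matter for
interpretation:

* the alpha shape of a one-voxel-thick shell is a thin *slab*; where the
  ball fits on both sides the mesh has an outer and an inner face and
  \(m\) approaches twice the one-sided geometric area (hollow-sphere
  phantoms give a ratio of 1.96–2.00). This is intrinsic to alpha-shape
  reconstruction over contour point clouds, not a defect;
* for small convex grains whose interior cannot host the ball the mesh is
  single-sided and numerically equals the hull.

**Boxes and ordering.** `grain_obb()` fits a principal-axes box (axes =
covariance eigenvectors), extents = max − min projection **+ 1 voxel** —
the voxel is a cube, not a point, and the +1 makes an axis-aligned solid
box of 50 × 20 × 10 voxels measure exactly 5 × 2 × 1 mm at P = 100 µm.
Minimum-volume box search was rejected as slower and non-deterministic
under ties; on ellipsoids the principal axes are the box axes exactly.
Extents are reported sorted, length ≥ width ≥ thickness. The spike axis is
the leading eigenvector of the whole cloud; grains are ranked bottom-up by
centroid projection (`order_grains()`), ties broken by `(y, x)` order.
`spike_traits()`/`extract_grains()` assemble the per-grain table,
per-spike totals, and spike length (the cloud's longest box extent);
`positional_profile()` averages any per-grain trait per position and group
across spikes, the along-spike distribution that shows mid-spike grains
running larger (the phantom generator's `size_profile = "mid-peak"` mode
reproduces that pattern with a ~0.8→1.25→0.8 size factor).

## Validation statistics

`correlate()` is the squared Pearson correlation (unit-free, so virtual
volume can be validated against manual spike weight);
`compare_groups()` runs pairwise two-sample t-tests — Welch's
unequal-variance test by default, pooled on request, the choice made
because group variances of different germplasm types cannot be assumed
equal — with the significance legend Ns / * / ** / *** at 0.05 / 0.01 /
0.001. Identical zero-variance samples are a defined degenerate case
(t = 0, p = 1). Both are tested against independent direct-formula
oracles.

## Numerical choices and degenerate inputs

* Otsu on a constant region: degenerate flag, never a guessed threshold.
* Alpha shape/hull on < 4 points, collinear or coplanar points: error
  ("degenerate grain geometry").
* Clustering yielding no cluster above the debris size: error advising an
  eps change, never an empty success.
* Voxel inclusion ties (centre exactly on a surface): the inequality is
  ≤, fixed and documented; alpha-shape cosphericity degeneracies of the
  integer lattice are broken by a deterministic 1e-4-voxel jitter.
* NIfTI spacing is stored in float32 by the format; `load_volume()`
  recovers P to 7 significant digits.
* Phantom overlap (two grains claiming a voxel) or out-of-bounds grains
  are errors, not warnings: ground truth must stay unambiguous.

## Study sizes used by tests and the acceptance script

Chosen so the whole suite runs comfortably on one CPU: phantoms with
10–30 grains at ~100×500 voxel volumes for clustering and morphometry;
64×64-slice phantoms (19 grains, 200 training slices, 10 epochs) for
network training and the end-to-end run; oracle equivalence on 16×16 masks
(100 pairs) and ≤ 2000-point clouds (20 trials). The end-to-end check —
render slices to disk, read back, segment with the phantom-trained
network, cluster, measure — recovers the grain count exactly, total grain
volume within 5%, and spike length within 3% of the constructed truth.

## Known limitations

* Phantom realism as listed above; no claim is made about scanner
  artifacts or about accessions whose grains touch (eps has no
  universally correct value there; in practice it is tuned per variety,
  and the config here exposes it per scan).
* The finite-alpha surface counts both faces of thin shells; comparing S
  across methods requires knowing which convention a method uses.
* Training at full 512×512 scale is supported but takes hours on one CPU;
  the package's verified operating point is the scaled-down condition
  stated above.
* Spike length is defined on the segmented grain cloud; awn or stalk
  remnants removed by segmentation do not contribute.
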