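---
title: "ratcine: models and methods for rat bi-ventricular cine-MR analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ratcine: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ratcine` implements an automated analysis chain for rodent short-axis cine
cardiac MR: per-slice 5-class segmentation of the thick-slice cine stack by
a fully convolutional network (FCN), refinement to a high-resolution (HR)
3-D label by multi-atlas fusion, surface meshing with template-based vertex
correspondence between end-diastole (ED) and end-systole (ES), and
decomposition of systolic wall motion into longitudinal, radial and
circumferential components summarized on a 28-segment bi-ventricular model
(17 LV + 11 RV segments). Because suitable rat scans are rarely public, the
package ships a seeded synthetic phantom whose ED-to-ES deformation is known
in closed form; every stage can therefore be validated against analytic
ground truth. This vignette records the models, the tunable parameters, and
the design decisions taken where the problem was genuinely open.

## The synthetic rat-heart phantom

The two ventricles are modelled as implicit surfaces on a 3-D grid whose
slices run base to apex:

* **LV**: two coaxial prolate ellipsoids (endocardium and epicardium). The
  interventricular septum carries the LV-wall label, and the cavity label
  stands for the blood pool with trabeculae and papillary muscles included,
  matching the usual small-animal segmentation protocol.
* **RV**: the cavity is the crescent between the LV epicardial shell and a
  copy of it offset along +x, restricted to an angular sector
  (`rv_crescent_extent`, default 150 degrees), with a thin free wall grown
  outward. This reproduces the crescent-shaped RV of short-axis views with
  a minimal parameter set.
* The base is truncated by a plane perpendicular to the long axis
  (`base_truncation_frac`).

Anatomical defaults -- 3 mm LV endocardial radius, 1.5 mm LV wall, 12 mm
long axis, 0.8 mm RV free wall, 2 mm RV offset -- are plausible magnitudes
for an adult rat, chosen once; they are **not** measured values and phantom
volumes should not be read as physiological claims. Acquisition geometry
follows small-animal protocols: 0.2 mm in-plane resolution, 0.34 mm HR
slices, and cine slices exactly 4 HR slices thick (1.36 mm, under the
1.5 mm ceiling typical of rodent cine stacks). The in-plane grid is padded
to a multiple of 32 so the 5-level FCN divides it evenly.

Images are rendered by assigning each class its mean intensity
(bright blood, mid-grey myocardium, dark background; all five class means
separated by at least twice the default noise SD), averaging the HR
sub-slices spanned by each thick cine voxel (the partial-volume effect that
motivates HR refinement), then adding seeded Gaussian noise and clipping to
[0, 1]. Noise is additive Gaussian only -- no Rician floor, bias field,
flow artefact or trabeculation. Passing tests on phantoms therefore
demonstrates the machinery is correct, not that the network would reach the
same accuracy on scanner data.

### The analytic deformation

The ED-to-ES map composes three closed-form motions in the cylindrical
frame of the long axis (apex fixed): base-toward-apex shortening
`h -> (1 - f_l) h` of the height above the apex, radial contraction
`r -> (1 - f_r) r`, and a twist about the axis with angle proportional to
height (right-handed about the apex-to-base direction). Each composant maps
onto exactly one reported motion component, so the decomposition can be
tested for cross-talk mode by mode. The map is invertible in closed form
whenever `f_l, f_r < 1` (enforced, and spot-checked numerically), and ES
labels are produced by nearest-neighbour resampling through the inverse.
Defaults (15% shortening, 20% radial contraction, 1 degree/mm twist) give
label-derived ejection fractions around 45%, a plausible healthy-rat
magnitude. Cine frames follow a cosine ED-ES-ED profile; frame 1 is ED and
only ED/ES are consumed downstream.

## Preprocessing and augmentation

Intensities are clipped to the per-scan 1st/99th percentiles (computed over
the whole 3-D stack, so subjects become comparable) and rescaled to [0, 1];
a constant image maps to zeros. The percentile rule is read as
clip-then-rescale rather than discarding voxels from the statistics; on its
own output the operation is idempotent up to the interpolation of the
saturated tails. Training augmentation draws, per image and per batch, an
intensity scale (+-10%), an in-plane rotation (+-10 degrees; the network is
2-D, so rotation about the slice normal is the natural reading) and a shift
of up to 10 pixels along exactly one randomly chosen axis. The identical
spatial transform is applied to image (bilinear) and label
(nearest-neighbour). ES is selected as the frame with the smallest LV
blood-pool area at the mid-ventricular level -- the middle slice among
slices containing LV cavity -- with ties to the earliest frame.

## The segmentation network

A 2-D encoder-decoder FCN with 14 3x3 encoder convolutions, each followed
by batch normalization and ReLU, five of them stride-2 downsampling layers
that double the feature width (16, 32, ..., 512 at the default
`base_features = 16`). The layout is two stem convolutions, then
(downsample, refine) pairs per level, then two bottleneck convolutions.
The decoder uses 2x2 stride-2 transposed convolutions with encoder skip
concatenation, and the decoder features of every scale are upsampled to
full resolution and concatenated before a 1x1 classifier (implemented
per-scale before upsampling, which is algebraically identical and much
cheaper). Training minimizes mean per-pixel cross-entropy with Adam
(learning rate 0.001, batch size 2, 200 epochs by default), shuffling
slices within subject-wise splits; classes are unweighted by default.
Argmax ties break to the lowest class index for determinism. All layer
primitives are exact (the backward pass matches finite differences to
numerical precision, which the test suite checks on a reduced
architecture).

## Multi-atlas HR refinement

Six landmarks -- the LV and RV cavity centroids of the basal, middle and
apical slices containing each cavity -- initialize a least-squares
(Kabsch) rigid alignment. Atlas ranking uses "label consistency" scored as
the mean foreground Dice after landmark-rigid alignment; the top 5 (ED) or
3 (ES) atlases are refined with affine then B-spline free-form deformation
(FFD) registration and fused by per-voxel majority vote, with ties broken
by the highest-ranked atlas's vote (implemented as a rank-decreasing
epsilon weight that cannot overturn a strict majority).

All registration here is label-driven: the objective is the mean squared
difference of Gaussian-smoothed (sigma = 1 voxel) one-hot label channels, a
differentiable surrogate for multi-class overlap. Optimization is plain
gradient descent with a backtracking line search (accepted steps only, so
the objective trace is non-increasing), two resolution levels (half
resolution, then full resolution with strided sampling), at most 200
iterations per level and relative tolerance 1e-6 by default. Coordinates
are centred on the fixed-image domain and the linear block preconditioned
by the squared domain radius so rotation-like and translation-like
parameters move on comparable scales. The FFD lattice spacing defaults to
8 HR voxels per axis with control displacements capped at twice the
spacing (diffeomorphism-friendly); points mapped outside the moving volume
sample the background prior. Whether the rigid stage should refine beyond
the landmark fit is ambiguous in common practice; both are provided
(`register_rigid`), and template alignment defaults to landmark
initialization plus overlap refinement, rigid-only so no shape distortion
enters inter-subject comparison.

The average bi-ventricular template is built by co-registering all atlases
(ED and ES together) rigidly to the first atlas in library order, fusing by
majority vote, and repeating against the fused average for two iterations
-- deterministic given library order; sensitivity to the reference choice
is covered by the degenerate-library tests.

## Meshing and correspondence

Surfaces are extracted from the binary structure mask (endocardium =
cavity; epicardium = cavity + wall) as the zero level of its signed
Euclidean distance field, triangulated by marching tetrahedra on a 6-tet
cube decomposition whose shared main diagonal makes neighbouring cells
agree on face diagonals -- a case-table-free member of the marching-cubes
family that yields closed, consistently outward-oriented 2-manifold
meshes. The distance field is smoothed with a 0.7-voxel Gaussian first:
this removes the half-voxel corrugation of the digital distance transform
(which would inflate surface area by well over 10%) at the cost of a small
curvature-dependent inward bias. At the default setting a digital sphere of
radius 10 voxels reproduces the closed-form area and volume to better than
1% and 3% respectively, both improving with resolution.

The fixed template mesh is extracted once from the template label on a
uniformly rescaled sampling grid bisected until the vertex count is within
5% of the configured budget (defaults 14,440 for LV and 18,312 for RV
surfaces, typical operating sizes for bi-ventricular meshes; reduced
budgets are used in the test suite). Correspondence propagates this
template: its vertices are warped by the phase-specific fitted transforms
(rigid, affine, FFD) and projected to the nearest point of that phase's
isosurface, so vertex *i* denotes the same material point at ED and ES. If
more than 5% of projections land farther than 1 mm the subject is flagged
and excluded from group tables -- the same screening role as visual
quality control of failed segmentations.

The centreline is a total-least-squares 3-D line through the per-slice
centroids of septal voxels (LV-wall voxels within 2 voxels of RV cavity) at
ED, oriented apex to base, and held fixed for both phases so the motion
components are functions of vertex displacement only, not axis motion.
Without a septum it falls back to LV-cavity centroids and flags the result.

## Motion decomposition

For ED position `p` and ES position `q` in the cylindrical frame of the
centreline: longitudinal = `z(p) - z(q)` along the apex-to-base direction
(positive = systolic descent), radial = `r(p) - r(q)` (positive = inward),
circumferential = `r(p) * dtheta` with the signed angular change wrapped to
(-pi, pi] and the radius taken at ED (the choice among ED/ES/mean radius is
immaterial at physiological twists but must be fixed). A vertex on the axis
has zero circumferential motion by definition. The motion magnitude is the
Euclidean norm of the three orthogonal components; the literal
root-mean-square reading (divide by sqrt(3)) is available as
`magnitude = "rms"` and only rescales every magnitude by the same factor.
The decomposition is exactly invariant under a shared rigid motion of both
phases and the axis.

Point-wise percentage change against a control mean excludes vertices whose
control value is under 0.01 mm (near-zero baselines produce arbitrarily
large percentages) and reports the exclusion count. Group differences are
`100 (mean(group) - mean(baseline)) / mean(baseline)` with the group spread
mapped to the percentage scale and a delta-method standard error that
includes baseline-mean uncertainty.

## The 28-segment model

The apical cap -- the most apical 5% of the axial extent (the tip fraction
is not standardized; 5% isolates the true apex without starving the apical
third) -- forms the apex segment. The rest splits into equal basal/mid/
apical thirds along the axis. Angles are measured from the anterior RV
insertion point, detected as the counterclockwise end of the RV cavity's
angular span at the basal third's mid-level, in 60-degree sectors named
anterior, anterolateral, inferolateral, inferior, inferoseptal,
anteroseptal. LV: 6 + 6 sectors at basal and mid, 4 merged 90-degree
sectors at apical, apex = 17 (the standard 17-segment layout). RV: the
four non-septal sectors at basal (1-4) and mid (5-8), two merged apical
sectors (9-10), apex = 11. A uniform reading of "4 sectors x 3 levels +
apex" gives 13, not 11; the merged-apical layout is the package's
resolution of that ambiguity, kept in one table (`segment_layout`) so an
alternative convention is a one-place change, and it should not be
attributed to any external source. Per-subject regional statistics are
segment medians (robust to projection outliers); group statistics are the
mean and SD of per-subject medians; the apex can be excluded from line
summaries.

## Evaluation metrics

Dice is `2|A n B| / (|A| + |B|)` per label; the empty-empty 0/0 case is
defined as 1 and flagged so evaluation tables can drop it. Slice-wise Dice
omits slices empty in both volumes and counts them. Cardiac indices follow
the standard formulas -- `SV = EDV - ESV`, `EF = SV/EDV x 100`,
`CO = HR x SV / 1000`, myocardial mass = 1.05 g/mL x ED wall volume, Meeh
body-surface-area `BSA = 10 W^(2/3) / 10000` m^2 with W in grams -- and
BSA-indexed variants. Note the CO formula is implemented exactly as
conventionally printed: bpm x uL / 1000 yields mL/min, not L/min; the
discrepancy is surfaced in the documentation rather than silently
corrected. Method agreement reports the Bland-Altman bias, SD of
differences, bias +- 1.96 SD limits of agreement, and Pearson r;
interobserver comparisons reuse the same functions on two manual label
sets.

## Numerical and testing choices

Voxel indices are 0-based in physical mapping (`origin + index * spacing`
at voxel centres); slice order is normalized base-to-apex at load when a
NIfTI affine indicates apex-first. Label resampling is always
nearest-neighbour; image interpolation trilinear/bilinear. Determinism is a
contract: every generator, the network (seeded initialization and
shuffling), registration and fusion reproduce bit-identical label outputs
under identical seeds on a fixed platform.

The test suite exercises the full pipeline at two scales chosen as package
defaults: unit tests use a coarse phantom (0.4 mm in-plane, 0.68 mm
slices) for speed, while the end-to-end property tests run the study-scale
phantom (0.2 mm / 0.34 mm), a 20-subject cohort with a 16/4 subject-wise
split for network training, 10 phantoms for motion recovery, 10 random
pairs for registration monotonicity, an 8-atlas library with the standard
top-5 selection for super-resolution, and two 10-subject cohorts for the
group-difference closure with a prescribed 37.7% RV motion reduction.

## Known limitations

* Phantom realism: no trabeculation, papillary muscles, flow or motion
  artefacts, edema, or pathological remodelling; intensity statistics are
  far cleaner than scanner data, so network accuracies on phantoms are an
  upper bound.
* Registration is label-driven only; it cannot be used on grey-scale
  images without segmentations.
* Motion is ED-to-ES only, as in standard two-phase analyses; no
  frame-by-frame tracking and no strain tensors.
* The RV 11-segment layout and the 5% apical cap are package conventions
  where the field has no fixed standard; results by segment should cite
  the layout table.
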