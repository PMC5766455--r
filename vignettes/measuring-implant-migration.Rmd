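---
title: "Measuring implant migration from low-field MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring implant migration from low-field MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mmri)
```

## The measurement problem

Early migration of a joint implant relative to its host bone predicts later
aseptic loosening. The clinical reference method, marker-based roentgen
stereophotogrammetric analysis (RSA), reaches about 0.05–0.5 mm in
translation and 0.15–1.15° in rotation (95 % CI), but requires tantalum
beads implanted at surgery, calibration cages and stereo X-ray
infrastructure. Low-field MRI (≈ 0.25 T) suffers far less from metal
artifacts than high-field MRI and images bone, implant outline and soft
tissue without radiation, making it a candidate marker-free alternative.

`mmri` implements the full analysis chain for assessing that candidate:
semi-automatic segmentation of bone and implant from repeated 3D
acquisitions, rigid registration of reference models into every
acquisition, six-degree-of-freedom (6-DOF) decomposition of the
implant-in-bone pose differences, and *precision-of-zero-motion*
statistics. Because a scanner and phantom cannot be shipped in a package,
a synthetic phantom generator reproduces the experiment's conditions with
exact ground truth, so every stage is testable end to end.

## The zero-motion experiment

The experimental design the package emulates: a tibial tray is implanted
in a porcine tibia, embedded in 2 % gelatin (soft-tissue-like relaxation
and elasticity), and scanned 12 times with a transverse 2D metal-artifact
reduction (MARS) protocol — 180 mm field of view, 224 × 224 matrix
(0.8036 mm in-plane), 3 mm slices. Between acquisitions the phantom is
relocated by up to ±25° roll about the scanner's longitudinal axis. The
implant cannot move relative to the bone, so any measured migration is
measurement error; the per-DOF mean μ and standard deviation σ over the 12
cyclic acquisition pairs (1 vs 2, 2 vs 3, …, 12 vs 1) define the precision
of zero motion, reported with 95 % CI as μ ± 1.96 σ and compared against
the golden-standard bands 0.5 mm / 1.15°.

Three registration strategies are implemented, mirroring the experiment:

* **MMRI-M** (manual surrogate): bone automatically, implant by matching
  named landmarks (posterior edge, distal notch, plate corners) followed
  by an ICP polish;
* **MMRI-A** (automatic, model-based): both structures by principal-axes
  global alignment + ICP against reference models;
* **MMRI-W** (automatic, model-free): as MMRI-A, but acquisition 1's own
  segmentations serve as the reference models.

The packaged table `phantom_study_pairs()` carries the published per-pair
zero-motion migrations of that experiment for all three methods;
`zero_motion_precision()` reproduces its μ(σ) summary rows, and
`compare_to_golden()` the golden-standard comparison.

## Geometry core

Rigid transforms are stored as a rotation matrix plus translation and
validated on construction (orthonormality and det +1 within 1e-9; no
reflection or scaling can leak in). The rigid Procrustes fit is the
Kabsch/Umeyama construction — SVD of the cross-covariance with a
determinant correction — and is exact (RMS < 1e-9) on noiselessly
transformed point sets.

The 6-DOF decomposition reports translations of the *implant midpoint*
(the reference-mesh centroid) on the anatomical axes, and fixed-axis Euler
angles in the sequence ML → DP → PA (`R = R_pa R_dp R_ml`), in degrees.
The underlying experiment does not state its Euler convention; at the
magnitudes involved (≤ 7.4°) the sequence choice shifts components by less
than 0.05°, so one convention was fixed and is written into every output
file header. Signs follow a right-handed frame with `ml × dp = pa`
(medial, proximal, anterior positive); flip frame axes to change sign
conventions. Gimbal lock (|DP rotation| → 90°) raises an explicit error —
it cannot occur at migration magnitudes.

## The synthetic phantom

`phantom_spec()` describes the phantom parametrically; all defaults are a
plausible adult-knee scale, chosen once at design time:

| parameter | default | rationale |
|---|---|---|
| tibia shaft | 110 mm long, outer radius 32→16 mm, 5 mm cortex | proximal tibia segment |
| fibula | solid cortical cylinder r 6 mm, 45 mm lateral | breaks the bone's rotational symmetry, as in vivo |
| tray plate | 70 × 45 × 4 mm trapezoid (posterior/anterior width 0.75) with a 10 × 6 mm posterior notch | tibial trays narrow posteriorly; the notch is the landmarking feature |
| stem | 40 mm, radius 6→4 mm | cemented-style stem |
| implant pose | 5° posterior slope about ML | standard surgical alignment |
| gelatin | cylinder r 75 mm, 140 mm tall | fits the 180 mm field of view |
| intensities | gelatin 200, trabecular 120, cortical 50, metal 0 | PD-weighted-like ordering |
| artifact halo | 2 mm signal void beyond metal | residual MARS artifact |
| noise | Rician, σ = 2 % of gelatin mean | magnitude-MRI noise model |

Acquisitions sample the relocated phantom on the preset grid with linear
partial-volume mixing (sub-voxel supersampling, finer through-plane) and
deterministic, seed-derived Rician noise. Relocations draw the dominant
roll uniformly within ±25°, plus ±5° tilt about the two transverse axes
and ±5 mm translation, pivoting about the phantom's own center — manual
repositioning never preserves exact supine orientation, and a perfectly
axis-aligned phantom would make the through-plane direction artificially
degenerate. The zero-motion guarantee is structural: the implant-in-bone
pose object is reused unchanged across acquisitions unless a migration is
injected, in which case the stated per-pair transform (about the posed
implant midpoint) is composed between consecutive acquisitions and
recorded in the manifest.

What the simulator does *not* model: MR physics (Bloch equations,
susceptibility fields, B0/B1 inhomogeneity), geometric distortion,
gelatin relaxometry and temperature effects, anatomical shape variation,
and operator variability. Passing synthetic tests therefore demonstrates
correctness of the measurement chain under the stated image-formation
model, not clinical performance.

## Segmentation

The six-step semi-automatic workflow is reproduced as deterministic
operations: profile-line window thresholding (Otsu on the sampled
profile, tie plateaus resolved to their midpoint), 26-connected region
growing from seed points (multiple seeds union tibia and fibula),
scripted erase/fill edits standing in for the manual steps, per-slice
morphological closing (disk, radius 1 voxel by default; a 3D ball is
available), and iso-surface extraction.

Iso-surfaces use marching tetrahedra — the tetrahedral variant of
marching cubes on the conforming six-tetrahedron cube split — at level
0.5 of the σ = 0.5-voxel Gaussian-smoothed mask, followed by 10 Taubin
(shrink-free) smoothing passes to remove tetrahedral faceting. The result
is watertight by construction; a digital ball of radius 10 voxels comes
out within 5 % of the analytic sphere area.

Two additional reconstruction steps matter for anisotropic voxels
(0.8 mm in-plane vs 3 mm slices):

* **Sub-voxel boundary refinement** (`refine_surface_subvoxel`): window
  thresholding binarizes the partial-volume ramp at the window edge, not
  at the tissue interface, so the binarized boundary is displaced by up
  to half a slice thickness, direction-dependently. Each vertex is moved
  along its normal to the nearest crossing of the half-way intensity
  between its local inside and outside values — the interface position
  under linear mixing. The search stays within ±1 directional voxel
  footprint (enough to undo the quantization staircase, short enough not
  to jump across thin structures) and runs for three passes by default,
  since normals improve as the surface settles.
* **Artifact-void compensation**: the metal appears as a signal void one
  halo radius larger than the implant; the implant surface is offset
  inward along vertex normals by that radius
  (`config$implant_offset_mm`), and bone-mask voxels inside the
  artifact shell are erased by the scripted manual-edit step. In a real
  study the offset radius would be calibrated once per sequence; for
  synthetics it equals the generator's halo.

## Registration

Global alignment matches area-weighted centroids and principal axes
(area weighting so that mesh vertex density cannot bias the fit), scoring
the four proper-rotation sign assignments by subsampled nearest-neighbour
RMS; two principal moments within 1 % raise an explicit
ambiguous-alignment error (a sphere cannot be oriented). ICP is classic
point-to-point: seeded uniform subsampling of the moving vertices,
nearest-neighbour correspondences into the fixed vertex set (uniform-grid
buckets, exact), rigid Procrustes update, stop when the RMS change drops
below 1e-4 mm or at 100 iterations; the correspondence RMS is provably
non-increasing and is asserted in tests. An optional trimming flag drops
the worst 10 % of correspondences; the pipeline enables it because the
artifact-erased bone segmentation is locally incomplete.

The pipeline subsamples 6000 points per registration rather than a more
customary 2000: with 3 mm slices the through-plane information is sparse,
and the larger sample measurably reduces subsample noise in the weak
(distal-proximal) direction at negligible cost.

Reference models are parametric meshes refined by midpoint subdivision to
roughly uniform vertex density — coarsely triangulated flat caps would
otherwise be nearly invisible to vertex-subsampled alignment, leaving the
in-plane orientation unconstrained.

## Migration computation and statistics

Per acquisition, `implant_in_bone = invert(bone) ∘ implant`; any global
relocation of the acquisition cancels algebraically, which is the reason
the method needs no scanner-frame calibration. Cyclic pairs (1,2) … (n,1)
yield migrations `M = pose_b ∘ invert(pose_a)`, decomposed about the
implant midpoint. The ordered composition of all cyclic migrations is the
identity by construction; the test suite asserts this as a software
integrity check. Precision statistics use the sample standard deviation
(n−1) — recomputing the published table confirms that convention (the n
denominator would give 0.559 instead of the printed 0.584 for the first
entry). The CI multiplier defaults to 1.96 (the experiment's text states
μ ± 1.96 σ; a figure caption says μ ± 2σ — the text was taken as
authoritative and the multiplier is configurable). Presentation rounding
is half-away-from-zero at 3 decimals, matching the published table.

A note on that table: 34 of its 36 μ/σ entries are reproduced exactly at
printed precision from the printed per-pair values; two MMRI-W σ entries
differ by one unit in the last digit because the original summary was
evidently computed from unrounded per-pair values, which are not
published. The acceptance test asserts exact agreement where attainable
and half-an-input-ulp agreement for the rest.

The golden-standard flagging deserves one caveat: under the stated rule
(the whole 95 % CI inside ±0.5 mm / ±1.15°) *every* DOF of every method
is outside the band — including the one rotation DOF the experiment's
narrative describes as within range. The arithmetic is unambiguous
(μ 0.152, σ 0.884 gives a CI of ±1.88°), so the package follows the rule,
not the narrative.

## Problem sizes and numerical choices

The packaged validation experiments run at the study's acquisition
geometry: 12 acquisitions at 224 × 224 × ~3 mm for the noise-free
zero-motion run, a 112-matrix grid for the noisy repeat, and 6
acquisitions for known-motion recovery (per-pair injections accumulate,
and 11 × 2° would drive the stem through the cortex; 6 acquisitions keep
the cumulative motion surgically meaningful while still giving 5
consecutive recovery pairs plus a wrap-around check). Voxelization uses
2 × 2 × 4 sub-voxel samples (finer through-plane, where the footprint is
largest). Tie-breaks are deterministic throughout: global-alignment
candidates by lowest RMS then candidate order, Otsu plateaus by midpoint,
ICP subsampling by a fixed seed.

Known limitations: the intensity model is piecewise-constant with linear
mixing, so segmentation operates under idealized contrast; the halo is a
perfect offset surface, making the inward compensation exact in a way a
real artifact never is; the landmark surrogate for manual registration
places landmarks with ground-truth accuracy, so MMRI-M's real-world
observer variability is not represented; and precision estimates from 12
pairs carry the same small-sample uncertainty as the original experiment.
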