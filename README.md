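# mmri — marker-free measurement of implant migration from low-field MRI

`mmri` measures rigid-body migration of a joint implant relative to its
host bone from repeated 3D MRI acquisitions, without implanted markers.
Early implant migration predicts aseptic loosening; the clinical standard
for measuring it, marker-based roentgen stereophotogrammetric analysis
(RSA), needs tantalum beads implanted at surgery and stereo X-ray
infrastructure. Low-field MRI (~0.25 T) images the implant-in-bone
situation with modest metal artifacts and no radiation; this package
provides the complete analysis chain to quantify how precisely such images
can measure migration, plus a synthetic phantom generator so the whole
method runs with known ground truth.

The package is aimed at imaging methodologists and orthopaedic-research
groups evaluating marker-free migration measurement.

## Method

For each acquisition *i* the bone and implant are segmented
(profile-line window thresholding → region growing → scripted edits →
morphological closing → marching-tetrahedra surfaces with sub-voxel
boundary refinement) and registered to reference models by one of three
strategies: landmark-guided ("manual", MMRI-M), automatic model-based
(MMRI-A), or automatic using acquisition 1's segmentations as the models
(MMRI-W). Registration gives rigid transforms `B_i` (bone) and `P_i`
(implant); the implant-in-bone pose is

    T_i = B_i⁻¹ ∘ P_i

and the migration between paired acquisitions (cyclically: 1–2, 2–3, …,
n–1) is

    M_ij = T_j ∘ T_i⁻¹,

decomposed into three translations (medial-lateral, distal-proximal,
posterior-anterior, mm) and three rotations (flexion-extension,
external-internal, varus-valgus, degrees) about the implant midpoint,
using the fixed-axis Euler sequence ML → DP → PA. With true zero motion,
the per-DOF mean μ and sample standard deviation σ (n−1) of the `M_ij`
define the *precision of zero motion* (95 % CI: μ ± 1.96 σ), compared
against the RSA golden-standard bands of 0.5 mm and 1.15°.

Rigid fits use orthogonal Procrustes superimposition (cross-covariance
SVD with determinant correction — rotation + translation, never scaling
or reflection); surface registration is principal-axes global alignment
followed by point-to-point ICP.

## Worked example

Simulate the zero-motion experiment (12 relocated acquisitions of a
tibial tray in a porcine-tibia phantom, MARS-like sampling), run the
automatic model-based pipeline, and summarize precision:

```r
library(mmri)

spec   <- phantom_spec(noise_sigma = 0)          # noise-free phantom
series <- generate_series(spec, mars_preset(),   # 180 mm / 224 x 224 / 3 mm
                          n_acq = 12, max_rotation_deg = 25, seed = 1)
res    <- run_synthetic_series(series, "mmri-a")

head(round(res$records, 3), 3)
#>   acquisition reference_acquisition   t_ml   t_dp  t_pa   r_fe   r_ei  r_vv
#> 1           1                     2 -0.017 -0.273 0.065 -0.345 -0.062 0.003
#> 2           2                     3  0.015  0.040 -0.022  0.009 -0.099 0.154
#> 3           3                     4 -0.039  0.110 -0.028  0.125  0.011 0.069
```

Every entry would be zero for a perfect measurement; the residuals (all
below 0.28 mm / 0.41° here) are the measurement error of the chain under
0.8036 mm in-plane / 3 mm slice sampling. The published phantom-study
table ships with the package and reproduces its summary statistics:

```r
tab  <- phantom_study_pairs("MMRI-M")
summ <- zero_motion_precision(tab, method = "MMRI-M")
round(summ$mu, 3)
#> [1]  0.128  0.022 -0.118  0.050  0.152  0.006
round(summ$sigma, 3)
#> [1] 0.584 0.931 0.593 1.630 0.884 1.147

compare_to_golden(summ)$within     # CI containment in 0.5 mm / 1.15 deg
#> [1] FALSE FALSE FALSE FALSE FALSE FALSE
```

`write_report()` produces the migration table CSV (per-pair rows plus the
μ(σ) row), per-DOF boxplots with the golden-standard bands, and a
distance-map mesh (per-vertex displacement in mm on the implant surface).
A thin command-line front end is installed at `inst/cli/mmri`
(subcommands `simulate`, `segment`, `migrate`, `precision`, `run-all`).

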