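# soleusshape

Statistical shape modelling of elongated skeletal muscles — in particular the
soleus — from triangulated surface meshes.

Muscles segmented from MRI arrive as unstructured triangle meshes: every
specimen has its own vertex count, ordering and pose, so their geometry cannot
be compared vertex by vertex. `soleusshape` turns such a cohort into a
point-distribution model:

1. **Correspondence** — a reference mesh is non-rigidly warped onto every
   specimen with a radial-basis-function (thin-plate) deformation driven by
   farthest-point-sampled control points and an affine point-to-plane ICP
   initialization; the reference is then iteratively re-fitted against the
   evolving mean shape. After this step every specimen is described by the
   same vertices in the same order.
2. **Alignment** — each corresponded mesh is moved to a canonical pose by its
   centre of mass and the principal axes of its vertex covariance (long axis
   to *z*, second axis to *x*), with axis signs fixed by third-order asymmetry
   statistics so the pose is a deterministic function of the geometry alone.
3. **Decomposition** — principal component analysis of the aligned shape
   vectors yields a mean shape plus orthogonal deformation modes:
   `S_i ≈ S̄ + P b_i`. The *morphological* model keeps size in the data; the
   *appearance* model is built after least-squares size normalization, so its
   modes describe shape proper.
4. **Validation and comparison** — leave-one-out reconstruction RMS measures
   model generality; cohort means are compared through per-vertex difference
   maps with Hausdorff summaries; per-component weights of two cohorts are
   compared with a gated battery (Shapiro–Wilk and Levene checks routing each
   component to a pooled t-test with Holm–Bonferroni correction, or to
   Kruskal–Wallis when the gates fail).

Because real MRI cohorts are rarely shareable, the package ships a synthetic
generator of soleus-like meshes with five known ground-truth deformation
modes (overall size, length–width aspect, medial margin shift, proximal
girth, peak-width position). It drives the test suite and makes every
pipeline claim checkable against known answers.

## Worked example

Generate a 12-specimen cohort with two active modes, re-tessellated per
specimen so correspondence genuinely has to be established, then build and
validate a 4-mode model:

```r
library(soleusshape)

cfg <- generator_config(n_subjects = 12, mode_sds = c(size = 1, aspect = 1),
                        noise_sd = 0.3, resolution = 10, seed = 42,
                        shuffle_topology = TRUE)
cohort <- generate_cohort(cfg)
cohort$meshes[[1]]
#> <surface_mesh: 202 vertices, 400 faces>
#>   extent (mm): x 94.0  y 47.8  z 307.9
#>   frame: x:medial-lateral y:anterior-posterior z:proximal-distal, right limb

fit <- build_model(cohort$meshes, k = 4,
                   settings = registration_settings(n_control = 120))
fit$model
#> <shape_model: morphological, 4 modes from 12 specimens, 202 vertices>
#>   cumulative variance of retained modes: 99.6%

tidy(fit$model)
#> # A tibble: 4 × 4
#>    mode variance prop_variance cum_variance
#>   <int>    <dbl>         <dbl>        <dbl>
#> 1     1   24995.        0.874         0.874
#> 2     2    2282.        0.0798        0.954
#> 3     3     714.        0.0250        0.979
#> 4     4     497.        0.0174        0.996
```

The two planted modes dominate the spectrum (mode 1 ≈ size, mode 2 ≈
aspect). Registration lands around 1 mm per specimen
(`fit$rms_report$rms_mm` ranges 0.87–1.27 here, against 0.3 mm planted
vertex noise), and leave-one-out generality:

```r
leave_one_out_rms(fit$shape_vectors, k = 4)
#> <loo_report: projection method, k = 4, mean RMS 1.2206 mm over 12 folds>
```

`autoplot(fit$model)` draws the scree curve, `autoplot(mean_difference_map(a, b))`
a flattened difference map; `tidy()`/`glance()` methods return tibbles
throughout. A full two-group study — generation or mesh input via
`manifest.csv` (left-side specimens are reflected sagittally on load), six
models, leave-one-out, difference maps and the statistical battery, all
written as deterministic plain-text artifacts — runs through
`run_study(study_config(...), out_dir)`.

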