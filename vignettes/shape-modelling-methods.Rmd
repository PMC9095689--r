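---
title: "Shape-modelling methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-modelling methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `soleusshape`, the
assumptions it makes, the meaning and rationale of every tunable parameter,
and the design decisions that are not visible from the API alone.

## The point-distribution model

A cohort of `m` corresponded, rigidly aligned surface meshes is flattened
into shape vectors `S_i` (vertex-major: `x1, y1, z1, x2, ...`). The model is

```
S_i  ≈  S̄ + P b_i
```

where `S̄` is the coordinate-wise mean, the columns of `P` are the leading
eigenvectors of the sample covariance (divisor `m − 1`) of the deviations,
and `b_i = Pᵀ(S_i − S̄)` are the specimen's *weights* (scores). Because
`3n ≫ m`, the decomposition goes through the `m × m` Gram matrix: if
`D = [S_1 − S̄, ...]` and `G = DᵀD = VΛVᵀ`, then the j-th mode is
`D v_j / √λ_j` with variance `λ_j / (m − 1)`. This dual route is
algebraically identical to decomposing the `3n × 3n` covariance (the test
suite checks the equivalence to 1e−8) at a tiny fraction of the cost. At most
`m − 1` eigenvalues are nonzero; "explained variance" fractions always use
the sum of all `m − 1` of them, not only the retained `k`.

Mode signs are fixed by convention (largest-magnitude entry positive) so
that models are reproducible run to run.

Two models are built from each cohort:

* **morphological** — PCA on the raw aligned shape vectors; size differences
  stay in the data and typically dominate the first mode;
* **appearance** — each shape is first scaled by the closed-form
  least-squares factor `s_i = ⟨S_i, S_ref⟩ / ⟨S_i, S_i⟩` toward the cohort
  mean. Only uniform scale is removed; the inputs are assumed already
  rigidly aligned.

### Assumptions

* Shapes are adequately described by a linear subspace around the mean —
  reasonable for one anatomical structure, not for mixed populations.
* Correspondence is trustworthy: PCA inherits any registration bias.
* Specimens are independent draws from one population per cohort.

## Correspondence and alignment

`rbf_fit()` warps a reference mesh onto a target in two stages:

1. **Affine point-to-plane ICP** — 12-parameter affine transform estimated by
   iteratively minimizing the distance of reference vertices to the target's
   tangent planes. Point-to-plane, rather than point-to-point, is essential
   for elongated shapes: tangential stretch (a longer muscle) is invisible to
   point-to-point correspondences, which stall far from the optimum.
2. **One RBF solve** — with correspondences fixed, a thin-plate deformation
   (`φ(r) = r` in 3D, the polyharmonic spline) plus affine term is solved on
   control points chosen by farthest-point sampling. Regularization `λ` is
   added to the kernel diagonal; `λ = 0` interpolates the control points
   exactly.

`rigid_align()` then maps each fitted mesh to a canonical pose from its
centre of mass and vertex-covariance eigenvectors (largest axis to `z`,
second to `x`, third — their cross product — to `y`). Axis signs are fixed by
requiring a non-negative third-order asymmetry statistic per axis: whichever
of the coordinate skewness and the axial-versus-squared-radial-spread
covariance is larger in magnitude. The second statistic matters in practice:
a muscle sampled in evenly spaced rings has near-zero coordinate skewness
along its long axis, and an unstable sign flips specimens head-to-tail,
collapsing the cohort mean. Near-equal eigenvalues (relative gap below
1e−9, e.g. a cube) are refused as degenerate rather than silently resolved.

`iterative_refit()` repeats fit → mean → refit against the evolving mean.
Point-to-surface RMS is not monotone across the switch from the clean
reference to the (smoother) mean reference; among the mean-referenced
iterations it decreases in practice.

### Registration parameters (`registration_settings()`)

| parameter | default | why |
|---|---|---|
| `kernel` | `"thin_plate"` | standard smooth interpolant in 3D; a Gaussian kernel (`kernel_scale` defaulting to 1/10 of the bounding-box diagonal) is offered for locality |
| `n_control` | 200 | enough to carry the five synthetic modes on ~1500-vertex meshes; farthest-point sampling keeps controls well spread at any budget |
| `regularization` | 0 | exact interpolation at controls; raise for noisy targets |
| `icp_iters` | 10 | the affine point-to-plane stage converges in a handful of iterations on smooth shapes |
| `max_iter` | 5 | refit iterations; the mean stabilizes in 2–3 |
| `tol_mm` | 0.01 | stop refitting when the mean RMS improves by less than this — far below MRI voxel size |

## Validation, comparison, statistics

*Generality* is leave-one-out reconstruction: a `k`-mode model fitted on
`m − 1` shapes reconstructs the left-out one, reported as per-vertex RMS in
mm (root-mean-square over vertices, arithmetic mean over folds). Projection
(`S̄ + PPᵀ(S − S̄)`) is the default; a partial-least-squares variant
(NIPALS PLS2 regressing shape on fold scores) is offered because it is a
named alternative whose exact setup is a declared interpretation.

*Difference maps* report both readings of "distance between corresponding
nodes": the per-corresponding-vertex Euclidean distance (drives a colour
map, exported as a PLY `quality` scalar) and the true symmetric
point-to-surface Hausdorff distance as a single summary. In the study
pipeline both cohort means are taken from the *combined* build, so they share
one registration frame and one normalization reference; per-cohort
normalization would silently retain the between-group size difference in the
appearance map.

*Two-group testing* runs per principal component of the combined model:
outliers beyond 1.5×IQR fences are excluded (recorded per PC), each group is
checked for normality (Shapiro–Wilk) and the pair for variance equality
(Levene on absolute deviations from group means); if all three gate p-values
exceed 0.05 a pooled two-sample t-test is used, otherwise Kruskal–Wallis.
Raw p-values are Holm–Bonferroni-adjusted within each branch family. Two
caveats are documented rather than hidden: trimming outliers before a t-test
inflates its size (measured ≈ 0.08 at nominal 0.05 for n ≈ 18), and at
`n = 19/17` the battery has only moderate power for sub-SD effects — both
are properties of the specified procedure, not of its implementation.

## The synthetic generator

`base_soleus_template()` builds a closed, tapered, slightly curved mesh
(length 300 mm, width 80 mm, thickness 40 mm — soleus-like proportions) from
`resolution` rings of `2 × resolution` vertices plus two poles. The width
profile peaks 40% along the length and a sinusoidal medial offset curves the
belly. Five deformation modes with exact analytic vertex maps are defined:
`size`, `aspect` (volume-preserving elongation), `margin_side`,
`proximal_width`, `broad_shift`.

`generate_cohort()` draws per-mode weights `w_i ~ N(offset, sd)` and forms

```
v_i = v_0 + Σ_j w_ij U_j(v_0) + ε,   ε ~ N(0, noise_sd² I)
```

where `U_j` is mode `j`'s unit-amplitude displacement field at the template.
**Linear superposition is deliberate**: composing the nonlinear maps in
sequence would make the population only approximately low-rank, whereas the
linear form makes it *exactly* rank-`k`, so subspace-recovery and
leave-one-out claims can be tested against machine-precision expectations.
The nonlinear maps themselves are still exercised directly (`size` scales
all pairwise distances by `1 + 0.1a`; `aspect` preserves volume to 0.5%).

`shuffle_topology = TRUE` re-tessellates each specimen with a rotated
circumferential seam: identical geometry, permuted vertex order — so
pipeline tests cannot accidentally rely on pre-existing correspondence.

Scope: the generator produces plausible *soleus-like* geometry for method
verification. It is not a biomechanical or anatomical model; its noise is
iid Gaussian per coordinate (real segmentation noise is spatially
correlated), and its modes are chosen for identifiability, not anatomy.

## Problem sizes and numerical choices

The reference study (19 + 17 specimens, resolution 27 → 1460 vertices,
0.5 mm noise, shuffled topology) is the package's own choice of a
desk-scale stand-in for an MRI cohort: large enough that registration,
rank-9 models and the test battery are all non-trivial, small enough to run
end to end in well under a minute. Other sizes used in tests (resolutions
4–12, cohorts of 5–200) are similarly cost-driven choices, not claims about
data.

Numerical choices worth knowing:

* closest-point-on-triangle queries (ICP, RMS, Hausdorff) run in C++ with
  per-face centroid/radius pruning;
* the TPS system is solved densely with `λ` on the kernel diagonal only;
* covariance eigen-decompositions use `eigen(symmetric = TRUE)`; negative
  round-off eigenvalues are clamped to zero;
* all artifacts (STL/PLY, CSV, JSON, model archives) are plain text written
  with shortest-round-trip number formatting and no timestamps, so a rerun
  under the same seed is byte-identical.

## Known limitations

* Rigid alignment needs three well-separated inertia eigenvalues; highly
  symmetric shapes are rejected.
* The sign-disambiguation statistics can both be near zero for shapes with
  genuine fore–aft symmetry; such cohorts would need a landmark-based
  convention instead.
* Registration quality is reported (per-specimen RMS, 1 mm flags) but not
  guaranteed; badly undersampled control budgets degrade gracefully rather
  than erroring.
* The statistical battery implements the specified gate-and-branch
  procedure faithfully, including its documented size inflation under
  outlier trimming; it reproduces that protocol as stated, not as a
  statistical recommendation.
* Only ASCII PLY and ASCII/binary STL are supported; no quad meshes.
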