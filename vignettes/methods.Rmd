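---
title: "Methods and design rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htoplan)
```

This vignette documents how each stage of the automatic Miniaci planning
pipeline works and, more importantly, *why* it works the way it does —
every place where the implementation had to make a non-obvious choice is
recorded here with its rationale.

## 1. Coordinate conventions

Images are numeric matrices `img[y, x]` in `[0, 1]`, origin at the top-left,
x growing rightward and y growing downward. All landmark points are
`c(x, y)` in this frame. `EBImage` stores images x-major, so every
conversion goes through `as_ebimage()`/`from_ebimage()` (a transpose), and
non-symmetric convolution kernels are transposed once at the call site.

## 2. Miniaci geometry

Given the five landmarks (femoral head centre, medial and lateral plateau
edges, two talus border points) the construction is closed-form:

```{r geometry}
lm <- leg_landmarks(
  femoral_head_center = pt(140, 65),
  medial_plateau_edge = pt(186, 432), lateral_plateau_edge = pt(74, 428),
  talus_inner = pt(180, 700), talus_outer = pt(120, 700),
  laterality = "right")
correction_angle(lm)
```

Design choices:

* **Fujisawa point at 62.5 %** of the knee width from the medial edge,
  interpolated *along the plateau segment* (not along the x axis), so a
  tilted plateau keeps the point on the joint line.
* **Hinge point** at 14 % of the knee width inside the lateral edge and
  18 % below it, measured along and perpendicular to the plateau segment
  for the same reason.
* **Ground level** defaults to the ankle centre's y. The construction
  needs the row where the correction axis is intersected; on a standing
  radiograph the floor is not imaged, and the ankle centre row is the
  reproducible proxy. `correction_angle(..., ground_level_y =)` overrides
  it when the acquisition defines a true ground row.
* **Sign**: positive = varus deformity (ankle medial of the correction
  axis), the case treated by an opening wedge; negative = valgus. The
  magnitude is reported separately so downstream consumers never have to
  re-derive the convention.

A property worth stating: the phantom generator inverts this construction
analytically (`solve_ankle_position()`), so `correction_angle()` applied to
phantom ground truth must return the requested angle to numerical
precision. This round trip is asserted to 1e-6° on 100 phantoms in the
acceptance suite.

## 3. Femoral head: circular Hough transform

Edges come from a Canny-style detector (Gaussian smoothing, Sobel
gradients, non-maximum suppression, hysteresis). Each edge pixel votes for
every centre at rounded distance `r`; the best-supported `(centre, radius)`
is disambiguated by the gradient-direction score of Gerig and Klein
(border gradients of a bright disk point radially).

Implementation notes that were learned the hard way:

* `EBImage`'s convolutions are FFT-based. On a constant image the response
  is not exactly zero but ~1e-15 numerical noise; purely *relative*
  thresholds then amplify it into a dense random edge mask. Both the edge
  detector and the talus segmenter therefore apply an **absolute response
  floor** (1e-8 — far below any real edge on a `[0, 1]` image, far above
  FFT noise).
* `EBImage::gblur` uses circular (wrap-around) boundaries, which blurs the
  left border into the right and fabricates border edges whenever the two
  sides differ. Smoothing is done with an explicit Gaussian kernel through
  `filter2(..., boundary = "replicate")` instead.
* Non-maximum suppression quantizes the gradient direction into four
  sectors; where a circle crosses the diagonals this keeps a short 2–3 px
  halo. It does not affect centre recovery (sub-pixel on clean disks) and
  is left as-is rather than post-filtered.
* The default radius search spans 50–100 % of the ROI half-extent; the
  vote floor rejects hypotheses supported by less than a quarter of their
  circumference, turning "no head here" into a structured detection error
  instead of a garbage answer.

Correctness is not argued but *measured*: the accumulator is asserted
vote-for-vote identical to an O(N·|edges|) brute force on every fixture up
to 64×64.

## 4. Statistical shape models

### Procrustes and PCA

`procrustes_align()` is a standard generalized Procrustes analysis:
centre, scale to unit centroid size, iteratively rotate each shape onto
the evolving mean. It is tested against an independent naive alternating
minimization written without complex arithmetic.

One subtlety deserves its own paragraph. `project_to_shape_space()` maps
image points into the model frame by inverting the least-squares
similarity fit of the mean onto the points. Algebraically this is the
Kendall **tangent-space projection** (the projected shape always satisfies
⟨shape, mean⟩ = |mean|²), and it is *not* the same scaling as the GPA's
unit-centroid-size normalization — the two differ by a per-shape factor
along the mean direction, which no PCA mode can represent. If the PCA is
trained on the raw GPA alignments, a full-variance model misses its own
training shapes by that factor (~1e-2 px here). `train_shape_model()`
therefore re-expresses the aligned shapes by the same tangent-space
projection, iterating the mean to its fixed point; exact training-shape
reconstruction (to ~1e-13) then holds by construction, and so does exact
pose recovery of a similarity-transformed mean.

### Active Shape Model

Per landmark, the model stores the mean and inverse covariance of
normalized first-derivative intensity profiles (length 2k+1) sampled along
the contour normal. Fitting alternates a Mahalanobis-best profile search
along each normal with a projection onto the shape space (modes clamped at
±3σ).

* **Stopping rule.** Plain Cootes iteration on these images contracts
  geometrically (~0.8× per iteration). A commonly quoted stop —
  "mean movement < 0.5 px" — halts that contraction at ~2.5 px RMS from a
  5 px-perturbed start, which makes the standard recovery example
  unreachable. The defaults are therefore `move_tol = 0.15` px and
  `max_iter = 60`; both remain arguments.
* **Convergence flag.** `converged = TRUE` requires both the movement stop
  *and* that some profile signal was found; a blank image reports
  `converged = FALSE` instead of pretending success.
* **Containment.** Landmarks are clamped to the ROI (or the init's
  bounding box) expanded by 10 %, so a diverging search cannot wander into
  a neighbouring structure.

### Active Appearance Model

Texture is sampled in the mean-shape reference frame through a
piecewise-affine warp over a Delaunay triangulation (Bowyer–Watson, own
implementation), normalized to zero mean/unit variance, and modelled by
PCA via the Gram matrix. Fitting drives a project-out texture residual
through a linear parameter-update matrix learned by regressing known
perturbations against induced residuals, with a `(1, 0.5, 0.25, 0.125)`
step-halving line search.

Two decisions here are load-bearing:

* **Multiplicative pose updates.** The similarity pose is stored as raw
  coefficients `(a, b)` whose magnitude is the pose scale (~100 px).
  Training perturbations of ±3 %/±6 % only make sense as *relative* scale
  and rotation changes; applied additively to `(a, b)` they are invisible
  and the regression learns noise for those columns. Updates therefore
  compose multiplicatively: `a' = a(1+ds) − b·dr`, `b' = b(1+ds) + a·dr`;
  translations stay additive pixels.
* **Rank-truncated update regression.** With ~560 training residuals in a
  ~2000-dimensional texture space, the unregularized pseudo-inverse
  interpolates the training pairs exactly and extrapolates wildly
  off-grid (the fit froze or diverged). The pseudo-inverse keeps only the
  top `4 · n_params` singular directions — a ridge-like regularization of
  the same regression. A sweep over ranks 7–112 was flat (0.19–0.29 px
  recovery), so the constant is not tuned to a test threshold.

`converged = TRUE` only when the relative residual-improvement stop fires;
exhausting `max_iter` or failing three consecutive line searches reports
`FALSE`.

In the validation suite the AAM beats the ASM in aggregate recovery error
(as expected: it uses the whole texture, not 1-D profiles), and both meet
the fixed-point (≤ 0.5 px) and recovery (≤ 1.5 px RMS) criteria on 20
seeds each.

## 5. Talus border points

The tibiotalar joint space appears as a dark horizontal band. The
segmenter takes the absolute horizontal-Sobel response, Otsu-thresholds
it, then applies **closing before opening**. The order matters: the Sobel
response to a sharp band edge is two pixels thick, so a 3×3 opening
applied first erases the signal entirely; closing first (7×7, enough to
bridge the ~6 px band between the paired edge responses) merges them into
one solid component, and the opening then strips protrusions and specks.
Small components are removed, and the largest near-horizontal component is
selected; a band tilted beyond 15° triggers a warning (rotated ankle,
detection unreliable). The band's row-extreme endpoints are the talus
border points; laterality maps them to medial/inner and lateral/outer.
Every operator is recorded in a provenance log on the returned object.

## 6. Phantom generator

`render_phantom()` draws a stylized long-leg radiograph (femoral head
disk, femur/tibia shafts, condyle block, plateau contour through the two
characteristic corners, ankle block with a dark tibiotalar band) whose
geometry is *derived from the requested correction angle* by inverting the
Miniaci construction. Ground truth — landmarks, boxes, angle — is
therefore exact by construction, not annotated. `sample_specs()` draws
angles from a right-skewed skew-normal (most mass 4–18°, matching the
clinical distribution of planned corrections) and varies knee width,
plateau tilt/bow and head radius. The generator's realism limits are
stated in the README: uniform intensities, no soft tissue, no implants —
accuracy on phantoms is a best case.

## 7. Evaluation statistics

* **ICC.** `icc()` computes the two-way mean squares explicitly and
  returns ICC(2,1) (absolute agreement; rater offsets count) by default —
  the right form when asking whether an algorithm can replace a human
  reader — with ICC(3,1) (consistency) available. Confidence intervals
  use the Shrout–Fleiss F method (Satterthwaite df for ICC(2,1)). The
  estimates are asserted equal to `stats::aov` mean-square oracles to
  1e-10 on 50 random tables, and point estimates/CIs/p-values are frozen
  against an independent reference implementation on a fixed table.
* **Bland–Altman** limits use z = 1.96 with no small-sample correction
  (documented); `bland_altman(a, a)` returns exact zeros.
* **Skew-normal** density/sampling/ML fit are implemented directly
  (Azzalini's representation for sampling; Nelder–Mead then BFGS for the
  fit, moment-based start). Parameter recovery is asserted at n = 5000,
  and fitting near-normal data drives the shape toward zero.

## 8. Pipeline and configuration

`hto_config()` validates every override against a typed schema and
**rejects unknown keys with their dotted path** — a misspelled tuning knob
fails loudly instead of silently using the default. The configuration hash
(FNV-1a over the canonical JSON) is stamped on every result, so a plan is
traceable to the exact settings that produced it.

`run_hto_pipeline()` runs per leg: Hough head centre → shape-model knee
points → talus border points → geometry. Each stage is timed; a failure
marks that leg with the failing stage and never aborts the other leg.
Box input is a list, a darknet sidecar path, or `NULL` (built-in phantom
detector). Legs are split at the image midline (patient right appears on
the image left); a **single-leg image** (no box class appears twice) skips
the midline rule — which would label a leg by which half of the image it
happens to occupy — and instead infers laterality from the medial offset
of the femoral head relative to the knee box: the head sits medially of
the shaft axis, whereas the ankle shifts with the deformity itself and is
not a reliable reference.

Everything is deterministic: no stage uses randomness at fit time, and all
phantom randomness flows from explicit seeds.
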