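---
title: "Methods: 3D choroidal vessel models and their morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D choroidal vessel models and their morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

`choroid3d` treats the choroidal vasculature as the set of dark tubular
silhouettes inside a segmented choroid of a structural OCT volume. Three
binary models are derived per scan:

* the **vessel volume model** — voxels whose multiscale Hessian tubularity
  response, converted to 8-bit grayscale, reaches a fixed threshold inside
  the choroid mask;
* the **surface model** — volume-model voxels with at least one background
  face-neighbour *inside* the scan domain (voxels exposed only at the scan
  border are excluded, so a model clipped by the field of view does not
  accrue spurious surface);
* the **line model** — one voxel per detected vessel cross-section: local
  intensity maxima of the masked response found independently in every
  fixed-x (y,z) slice and every fixed-z (x,y) B-scan, then combined by
  union and intersected with the volume model.

The morphometric layer converts voxel counts N to physical quantities with
the voxel volume `v = dx·dy·dz`: volumes scale by `v`, surfaces by
`v^(2/3)`, line lengths by `v^(1/3)`. Intensive parameters (MCT, CVI,
VLDI, VL–S, S–V, VDI) for pooled regions are always recomputed from pooled
counts; they are never means of per-region ratios, which keeps the
centre + parafovea rows exactly consistent with the whole-circle totals.

Assumptions worth stating explicitly:

* the choroid mask is an *input* (from any segmentation pipeline); its
  anatomical definition (sub-RPE to choroid/sclera border, including
  posterior stroma) is inherited, not re-decided here;
* vessels are resolvable dark structures — the filter needs roughly two
  voxels of radius to respond reliably;
* the line model is a per-slice point cloud, not a topological centerline:
  crossings and bifurcations are not resolved, and a vessel running inside
  a scan plane contributes a short chain of in-plane maxima rather than a
  single point (see *Known limitations*).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| voxel spacing | (0.012, 0.01172, 0.012) | mm | 500×256×500 voxels spanning 6×3×6 mm; the depth constant is the printed rounded value so worked arithmetic matches published tables digit for digit (`oct_default_spacing(exact_dy = TRUE)` gives 3/256) |
| scales σ | 0.024, 0.048, 0.096, 0.144 | mm | 2–12 voxels laterally, bracketing medium/large choroidal vessels; the source protocol does not record its values |
| α, β | 0.5, 0.5 | — | classic Frangi plate/blob discriminators |
| c | half the max Frobenius norm, per scale | — | classic structureness cutoff; adapts to the volume's contrast |
| threshold | 40 | 8-bit | fixed-value binarization of the 0–255 response; unrecoverable from the source, exposed in config |
| prominence | 10 | 8-bit | *Find Maxima* noise tolerance for the line model; suppresses speckle maxima while keeping faint vessels |
| normalization percentiles | 0, 100 | % | plain min–max; see *Numerical choices* |
| C/S smoothing λ | 0 (off) | — | cubic smoothing-spline penalty for the choroid/sclera border, applied separably along each en-face axis and averaged |

## The synthetic phantom

`default_phantom()` builds the validation world: a slab choroid (flat or
ramped boundary depth maps in mm) containing straight tubes of radii 3, 5
and 8 lateral voxels at separated slow-scan positions, drawn dark
(contrast 1) on a bright stromal background (0.85) in acquired polarity so
the inversion step is exercised, with additive Gaussian noise of σ = 0.05
on the [0, 1] intensity scale — a mild stand-in for speckle chosen to
stress peak detection without modelling OCT physics (a multiplicative
variant is available behind the `speckle` flag). Each tube carries
analytic truth: arc length (closed form for helices), volume πr²L,
lateral surface 2πrL, diameter 2r.

A voxel belongs to a tube iff its centre lies within the radius of the
centreline polyline. That rule generates a *capsule* (cylinder plus
hemispherical end caps), so convergence of voxel counts is tested against
the capsule volume πr²L + 4/3πr³; against the bare cylinder the cap term
adds a relative error growing like r/L that is not a discretization
artefact.

What the phantom does **not** emulate: real speckle statistics, retinal
layers and their shadows, RPE reflectivity, vessel curvature/branching,
and segmentation error in the choroid mask. A green phantom test therefore
establishes that the *pipeline machinery* (inversion, filtering, models,
counting, scaling) is correct and deterministic — not that the fixed
defaults are clinically optimal for any particular scanner.

## Numerical choices

* **Normalization** is per-volume min–max by default. Percentile clipping
  (e.g. 1–99%) is available for real scans with outliers, but is a poor
  default: when vessels occupy less than the clipped tail fraction of the
  voxels, both percentiles land on the stromal background, the
  normalization window collapses, and background noise is amplified into
  the filter. Per-slice normalization was rejected to keep the response
  comparable across B-scans.
* **Derivative kernels** are sampled Gaussian derivatives per axis in
  physical units (σ in mm divided by the axis spacing), truncated at 3σ,
  with the second-derivative kernel mean-subtracted so constants map to
  exactly zero. Boundaries mirror with edge repeat. Axis lengths shorter
  than the kernel are tolerated but distort the largest scale — depth
  extents of at least ~6.2 σ_max/dy voxels (75 at the defaults) are
  recommended.
* **Eigenvalues** come from the closed-form symmetric 3×3 solution; the
  response matches scikit-image's `frangi` to ~10⁻³ on identical input.
* **8-bit conversion** maps [0, max response] to 0–255, rounding half up;
  an all-zero response stays zero. A zero threshold therefore selects
  exactly the nonzero-response voxels in the mask, and threshold 255
  isolates the argmax only when it is more than one quantum clear.
* **Prominence semantics**: a maximum is reported iff no path to a higher
  pixel exists without descending more than the tolerance; the global
  maximum is measured against the slice minimum (a constant slice has no
  maxima). Plateaus report one point at their centroid, halves rounded
  toward the smaller index; a centroid outside its plateau falls back to
  the nearest plateau pixel (smaller linear index on ties). Detection is
  8-connected in-plane and implemented with a descending-order union-find;
  the test suite checks it against an independent maximum-spanning-tree
  prominence oracle.
* **Depth convention** for surface-built masks is half-open
  (`upper ≤ y < lower`), so stacked structures never double-count a layer.
* **ROI geometry** uses pixel-centre inclusion with no anti-aliasing.
  Pixels exactly on a dividing line join the quadrant with the smaller
  label under the right-eye labelling; left-eye maps are the mirrored
  relabelling, which makes switching laterality an exact label swap
  (2↔5, 3↔4) including boundary pixels.
* **Line-model input** is the 8-bit response (not the binary volume):
  maxima of a binary image are degenerate plateaus, while the response
  retains the cross-section peak the construction is meant to find. Maxima
  are masked to the binarized vessels afterwards so line ⊆ volume always
  holds, which VDI and VLDI implicitly assume.
* **Undefined ratios** (zero denominators) are explicit `NA`s with reason
  strings, never silent zeros.

## Design decisions on open points

* **Variable clustering** substitutes seeded k-means (50 restarts) on
  *absolute* correlation profiles for the proprietary PCA-splitting
  procedure used by commercial statistics software; absolute values make
  the grouping sign-invariant, which the published two-cluster structure
  requires (a surface-to-volume ratio belongs with the volume measures it
  is negatively correlated with). "R² with own cluster" is the squared
  correlation with the cluster's first principal component. Variables are
  sorted by name internally, so column order cannot change the result.
* **Scale selection behaviour**: under σ²-normalization the per-scale
  response of a top-hat tube of radius r peaks at the scale nearest its
  equivalent Gaussian width r/√2, not nearest r; the tests freeze the
  oracle-derived value.
* **SFCT** is the single foveal A-scan by definition; a 3×3 median option
  exists but is off by default.

## Known limitations

* With the fixed default scale set and threshold, the binarized vessel
  volume of tubes of radius ≥ 5 voxels is over-estimated by roughly
  50–80%: the largest scale (σ = 0.144 mm) sees such a tube as a smoothed
  blob whose normalized response stays above 40/255 of the volume maximum
  out to ~1.4–1.6× the true radius. This is a property of the
  max-over-scales Frangi construction itself (the package's response
  matches an independent reference implementation), not of this
  implementation; radius-3 tubes are recovered within a few percent. The
  acceptance suite reports these recovery errors honestly rather than
  retuning the defaults.
* The line model inflates length estimates for vessels running inside a
  scan plane: the orthogonal pass contributes ~2r extra maxima per tube
  plus end-cap bumps whose prominence exceeds the default tolerance.
  Relative inflation shrinks as vessels lengthen (it is ~10% at ~180
  voxels of length for thin tubes) but is intrinsic to the two-axis union
  rule.
* Printed-units quirks are reproduced, not resolved: VLDI and VL–S are
  defined in mm⁻² (some published tables print mm⁻¹), and the aggregate
  VLDI printed in the source tables is inconsistent with its own formula
  applied to the printed totals; the formulas as defined are implemented.
* No DICOM/proprietary-export ingestion, no GPU, no learned vesselness,
  no per-layer (Sattler/Haller) analysis, no automatic fovea detection.
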