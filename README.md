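# choroid3d

Three-dimensional choroidal vessel models and morphometrics from
swept-source OCT volume scans.

## The problem

The choroid is the vascular layer between the retina and the sclera; its
vessels appear as *dark silhouettes* in structural OCT volumes. Classical
biomarkers (subfoveal choroidal thickness, the 2D choroidal vascularity
index) compress this 3D vasculature into a slice or a ratio. `choroid3d`
reconstructs three binary 3D models of the choroidal vessels from a volume
scan and a choroid segmentation, and derives eleven regional morphometric
biomarkers from them. It is aimed at ophthalmic image-analysis researchers
who have structural OCT volumes and a choroid mask (however obtained) and
want reproducible vessel-geometry measurements plus the synthetic phantoms
to validate them.

## Models and parameters

From an acquired-polarity volume the pipeline runs:

1. **Inversion + normalization** — intensities mapped to [0, 1] and
   inverted so vessels become bright tubes.
2. **3D multiscale Hessian enhancement** — a Frangi-type tubularity filter:
   per scale σ the Gaussian-derivative Hessian (computed in physical mm,
   honouring anisotropic voxel spacing) is σ²-normalized; with eigenvalues
   |λ₁| ≤ |λ₂| ≤ |λ₃| the response is

   V(σ) = (1 − e^{−R_A²/2α²}) · e^{−R_B²/2β²} · (1 − e^{−S²/2c²}),

   R_A = |λ₂|/|λ₃|, R_B = |λ₁|/√(|λ₂λ₃|), S = ‖H‖_F, zero wherever
   λ₂ > 0 or λ₃ > 0; the final response is the voxelwise maximum over
   scales.
3. **Vessel volume model** — the response converted to 8-bit grayscale,
   thresholded at a fixed value, and masked to the choroid.
4. **Surface model** — foreground voxels with a background 6-neighbour
   inside the scan (scan-border exposure does not count).
5. **Line model** — per-slice intensity maxima (topographic prominence, as
   in Fiji's *Find Maxima*) in every fixed-x and every fixed-z slice,
   combined by union and masked to the volume model.

With `v = dx·dy·dz` the voxel volume (default
`12×10⁻³ · 12×10⁻³ · 11.72×10⁻³ mm³`), counts N scale as:

| parameter | formula | units |
|---|---|---|
| CVolume | N_choroid · v | mm³ |
| MCT | CVolume / ROI area | mm |
| VVolume | N_vessel · v | mm³ |
| VSurface | N_surface · v^(2/3) | mm² |
| VLI | N_line · v^(1/3) | mm |
| CVI | VVolume / CVolume | — |
| VLDI | VLI / VVolume | mm⁻² |
| VL–S ratio | VLI / (CVolume − VVolume) | mm⁻² |
| S–V ratio | VSurface / VVolume | mm⁻¹ |
| VDI | √(VVolume / VLI) | mm (reported in µm) |

SFCT (mm) is the sub-RPE to choroid/sclera distance at the foveal A-scan.
All parameters are evaluated on a fovea-centred ROI: a 1-mm-diameter centre
circle plus the four quadrants of a 4.5-mm circle (the parafovea), split by
horizontal and vertical lines through the fovea.

**Axis conventions.** Arrays are indexed `[x, y, z]` = (fast scan, depth,
slow scan), 0-based coordinates in the API; the en-face plane is `(x, z)`.
Superior is at smaller `z`; for a right eye the temporal side is at smaller
`x` (flipped for a left eye). TIFF stacks store one fixed-z B-scan per
page.

## Worked example

The parameter layer reproduces in-print regional arithmetic exactly. Using
the published centre/parafovea voxel counts pooled over the whole 4.5-mm
circle on the standard 500×500 en-face grid:

```r
library(choroid3d)
spacing <- oct_default_spacing()           # (0.012, 0.01172, 0.012) mm
roi <- build_roi(c(500L, 500L), spacing, fovea_xz = c(249.5, 249.5))
morphometrics_from_counts(
  n_cho = 3240543, n_ves = 1328451, n_surf = 1116202, n_line = 68882,
  area_mm2 = region_area(roi, 1:5), spacing = spacing)
#> morphometric_record [total]
#>   SFCT_mm            NA
#>   CVolume_mm3        5.469
#>   MCT_mm             0.34403
#>   VVolume_mm3        2.242
#>   VSurface_mm2       158.22
#>   VLI_mm             820.1
#>   CVI                0.40995
#>   VLDI_mm2inv        365.79
#>   VLS_ratio_mm2inv   254.14
#>   SV_ratio_mminv     70.572
#>   VDI_um             52.286
```

CVolume 5.469 mm³ over the rasterized 15.897 mm² circle gives MCT
0.344 mm; CVI ≈ 0.41 means 41% of the choroidal volume is vessel lumen;
VDI ≈ 52 µm is the effective vessel calibre (√π·r for an ideal cylinder).

End-to-end on synthetic data:

```r
ph <- default_phantom()                    # 256x128x256, three tubes
norm <- invert_and_normalize(ph$volume$grid)
resp <- hessian_vesselness(norm, vesselness_params())
models <- build_vessel_models(resp, ph$mask)
ph$volume$truth                            # analytic ground truth per tube
```

## Command line

```sh
Rscript inst/cli/choroid3d.R phantom --shape 256,128,256 --out ph/
Rscript inst/cli/choroid3d.R run --volume ph/phantom.tif \
    --mask ph/choroid_mask.tif --fovea 128,128 --out results/
Rscript inst/cli/choroid3d.R cohort --input eyes.csv --out stats/
```

Subcommands: `phantom`, `enhance`, `model`, `measure`, `cohort`, `run`
(full chain). A YAML config (`--config`) supplies defaults; flags win.
Every run writes a provenance JSON (config, package version, input
checksums); identical config + inputs reproduce byte-identical CSVs.

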