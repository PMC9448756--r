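# The eleven morphometric parameters. Scaling uses the published voxel
# constants: with v = dx*dy*dz (mm^3), volumes scale by v, surface areas by
# v^(2/3) and line lengths by v^(1/3). Intensive parameters for pooled
# regions are always recomputed from pooled voxel counts, never averaged.

#' Count model voxels whose en-face position lies in an ROI region
#'
#' @param model logical 3D array or logical [voxel_grid()].
#' @param roi a [build_roi()] grid, or `NULL` to count the whole volume.
#' @param region region id(s) in 0..5.
#' @return integer voxel count.
#' @export
count_in_region <- function(model, roi = NULL, region = 1:5) {
  if (inherits(model, "voxel_grid")) model <- model$data
  stopifnot(is.logical(model), length(dim(model)) == 3L)
  if (is.null(roi)) return(sum(model))
  stopifnot(inherits(roi, "roi_grid"))
  region <- check_region_ids(region)
  d <- dim(model)
  if (!identical(as.integer(dim(roi$labels)), c(d[1], d[3]))) {
    stop("ROI labels (", paste(dim(roi$labels), collapse = "x"),
         ") do not match the volume's en-face shape (", d[1], "x", d[3], ")")
  }
  col_counts <- colSums(aperm(model, c(2L, 1L, 3L)))   # (nx, nz) counts
  sum(col_counts[roi$labels %in% region])
}

#' Morphometric record from voxel counts
#'
#' Computes the parameter set from raw counts: `CVolume = n_cho * v`,
#' `VVolume = n_ves * v`, `VSurface = n_surf * v^(2/3)`,
#' `VLI = n_line * v^(1/3)` with `v = dx*dy*dz`; then
#' `MCT = CVolume / area`, `CVI = VVolume / CVolume`,
#' `VLDI = VLI / VVolume`, `VLS_ratio = VLI / (CVolume - VVolume)`,
#' `SV_ratio = VSurface / VVolume`, `VDI = sqrt(VVolume / VLI)` (reported
#' both in mm and in µm). Undefined ratios (zero denominators) are `NA`
#' with the reason recorded in the `undefined` field, never silent zeros.
#'
#' @param n_cho,n_ves,n_surf,n_line voxel counts in the choroid mask, vessel
#'   volume model, surface model and line model (fractional counts are
#'   accepted so printed physical values can be used as inputs).
#' @param area_mm2 en-face region area in mm^2.
#' @param spacing a [voxel_spacing()].
#' @param region region label carried through to the output.
#' @param sfct_mm optional subfoveal choroidal thickness (whole-eye only).
#' @return an object of class `morphometric_record` (a named list).
#' @export
morphometrics_from_counts <- function(n_cho, n_ves, n_surf, n_line, area_mm2,
                                      spacing, region = "total",
                                      sfct_mm = NA_real_) {
  stopifnot(inherits(spacing, "voxel_spacing"))
  if (any(c(n_cho, n_ves, n_surf, n_line) < 0)) {
    stop("voxel counts must be nonnegative")
  }
  v <- voxel_volume(spacing)
  cvol <- n_cho * v
  vvol <- n_ves * v
  vsurf <- n_surf * v^(2 / 3)
  vli <- n_line * v^(1 / 3)
  undefined <- character()
  na <- NA_real_
  if (cvol > 0) {
    mct <- if (area_mm2 > 0) cvol / area_mm2 else na
    cvi <- vvol / cvol
  } else {
    mct <- na; cvi <- na
    undefined <- c(undefined, "MCT: CVolume is zero", "CVI: CVolume is zero")
  }
  if (vvol > 0) {
    vldi <- vli / vvol
    sv_ratio <- vsurf / vvol
    vdi <- if (vli > 0) sqrt(vvol / vli) else {
      undefined <- c(undefined, "VDI: VLI is zero"); na
    }
  } else {
    vldi <- na; sv_ratio <- na; vdi <- na
    undefined <- c(undefined, "VLDI: VVolume is zero",
                   "SV_ratio: VVolume is zero", "VDI: VVolume is zero")
  }
  stroma <- cvol - vvol
  if (stroma > 0) {
    vls_ratio <- vli / stroma
  } else {
    vls_ratio <- na
    undefined <- c(undefined, "VLS_ratio: stromal volume is zero")
  }
  structure(list(
    region = region,
    SFCT_mm = sfct_mm,
    CVolume_mm3 = cvol,
    MCT_mm = mct,
    VVolume_mm3 = vvol,
    VSurface_mm2 = vsurf,
    VLI_mm = vli,
    CVI = cvi,
    VLDI_mm2inv = vldi,
    VLS_ratio_mm2inv = vls_ratio,
    SV_ratio_mminv = sv_ratio,
    VDI_mm = vdi,
    VDI_um = vdi * 1000,
    area_mm2 = area_mm2,
    counts = c(n_cho = n_cho, n_ves = n_ves, n_surf = n_surf,
               n_line = n_line),
    undefined = undefined
  ), class = "morphometric_record")
}

#' @export
print.morphometric_record <- function(x, ...) {
  cat("morphometric_record [", x$region, "]\n", sep = "")
  flds <- c("SFCT_mm", "CVolume_mm3", "MCT_mm", "VVolume_mm3", "VSurface_mm2",
            "VLI_mm", "CVI", "VLDI_mm2inv", "VLS_ratio_mm2inv",
            "SV_ratio_mminv", "VDI_um")
  for (f in flds) cat(sprintf("  %-18s %s\n", f, format(x[[f]], digits = 5)))
  if (length(x$undefined)) {
    cat("  undefined:", paste(x$undefined, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.morphometric_record <- function(x, ...) {
  data.frame(region = x$region, SFCT_mm = x$SFCT_mm,
             CVolume_mm3 = x$CVolume_mm3, MCT_mm = x$MCT_mm,
             VVolume_mm3 = x$VVolume_mm3, VSurface_mm2 = x$VSurface_mm2,
             VLI_mm = x$VLI_mm, CVI = x$CVI, VLDI_mm2inv = x$VLDI_mm2inv,
             VLS_ratio_mm2inv = x$VLS_ratio_mm2inv,
             SV_ratio_mminv = x$SV_ratio_mminv, VDI_mm = x$VDI_mm,
             VDI_um = x$VDI_um, area_mm2 = x$area_mm2,
             stringsAsFactors = FALSE)
}

#' Morphometrics of one ROI region
#'
#' Counts the choroid mask and the three vessel models in the region and
#' derives the full parameter set.
#'
#' @param mask a [choroid_mask()].
#' @param models a [vessel_model_set()].
#' @param roi a [build_roi()] grid.
#' @param region region id(s) in 0..5.
#' @param sfct_mm optional precomputed SFCT (see [compute_sfct()]).
#' @return a [morphometrics_from_counts()] record.
#' @export
compute_parameters <- function(mask, models, roi, region,
                               sfct_mm = NA_real_) {
  stopifnot(inherits(mask, "choroid_mask"),
            inherits(models, "vessel_model_set"))
  check_same_geometry(mask$mask, models$volume_model$data,
                      "mask and vessel models")
  region_label <- paste(region, collapse = "+")
  morphometrics_from_counts(
    n_cho = count_in_region(mask$mask, roi, region),
    n_ves = count_in_region(models$volume_model, roi, region),
    n_surf = count_in_region(models$surface_model, roi, region),
    n_line = count_in_region(models$line_model, roi, region),
    area_mm2 = region_area(roi, region),
    spacing = mask$spacing, region = region_label, sfct_mm = sfct_mm)
}

#' Pool per-region counts into the standard summary rows
#'
#' Given a per-region count table (regions 1..5), emits records for each
#' region plus `center` (region 1), `parafovea` (regions 2-5 pooled) and
#' `total` (regions 1-5 pooled). Extensive parameters are additive by
#' construction; intensive parameters are recomputed from the pooled counts.
#'
#' @param counts data frame with columns `region` (1..5), `n_cho`, `n_ves`,
#'   `n_surf`, `n_line`, `area_mm2`.
#' @param spacing a [voxel_spacing()].
#' @param sfct_mm optional SFCT attached to the pooled rows.
#' @return data frame of records (one row per region/summary row).
#' @export
summarize_counts <- function(counts, spacing, sfct_mm = NA_real_) {
  need <- c("region", "n_cho", "n_ves", "n_surf", "n_line", "area_mm2")
  if (!all(need %in% names(counts))) {
    stop("counts table must have columns ", paste(need, collapse = ", "))
  }
  if (!all(1:5 %in% counts$region)) {
    stop("counts table must cover regions 1..5; missing: ",
         paste(setdiff(1:5, counts$region), collapse = ", "))
  }
  pool <- function(ids, label) {
    sub <- counts[counts$region %in% ids, , drop = FALSE]
    morphometrics_from_counts(sum(sub$n_cho), sum(sub$n_ves),
                              sum(sub$n_surf), sum(sub$n_line),
                              sum(sub$area_mm2), spacing, region = label,
                              sfct_mm = sfct_mm)
  }
  region_names <- c("center", "upper_temporal", "lower_temporal",
                    "lower_nasal", "upper_nasal")
  recs <- lapply(1:5, function(r) pool(r, region_names[r]))
  recs <- c(recs, list(pool(2:5, "parafovea"), pool(1:5, "total")))
  do.call(rbind, lapply(recs, as.data.frame))
}

#' Full per-eye summary table from volumes
#'
#' @param mask a [choroid_mask()].
#' @param models a [vessel_model_set()].
#' @param roi a [build_roi()] grid.
#' @param sfct_mm optional SFCT in mm.
#' @return data frame with rows center, the four quadrants, parafovea, total.
#' @export
summarize_eye <- function(mask, models, roi, sfct_mm = NA_real_) {
  counts <- do.call(rbind, lapply(1:5, function(r) {
    data.frame(region = r,
               n_cho = count_in_region(mask$mask, roi, r),
               n_ves = count_in_region(models$volume_model, roi, r),
               n_surf = count_in_region(models$surface_model, roi, r),
               n_line = count_in_region(models$line_model, roi, r),
               area_mm2 = region_area(roi, r))
  }))
  summarize_counts(counts, mask$spacing, sfct_mm = sfct_mm)
}
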