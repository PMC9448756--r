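sp <- oct_default_spacing()
v <- voxel_volume(sp)

test_that("count_in_region counts by en-face position", {
  s <- voxel_spacing(0.05, 0.05, 0.05)
  roi <- build_roi(c(100L, 100L), s, c(49.5, 49.5))
  model <- array(FALSE, dim = c(100L, 20L, 100L))
  expect_equal(count_in_region(model, roi, 1:5), 0)
  model[] <- TRUE
  expect_equal(count_in_region(model, roi, 1), sum(roi$labels == 1) * 20)
  per <- vapply(1:5, function(r) count_in_region(model, roi, r), numeric(1))
  expect_equal(sum(per), count_in_region(model, roi, 1:5))
  bad <- array(TRUE, dim = c(50L, 20L, 100L))
  expect_error(count_in_region(bad, roi, 1), "en-face")
})

test_that("parameter formulas follow the published voxel scalings", {
  rec <- morphometrics_from_counts(n_cho = 1e6, n_ves = 4e5, n_surf = 2e5,
                                   n_line = 5e4, area_mm2 = 10, spacing = sp)
  expect_equal(rec$CVolume_mm3, 1e6 * v)
  expect_equal(rec$VVolume_mm3, 4e5 * v)
  expect_equal(rec$VSurface_mm2, 2e5 * v^(2 / 3))
  expect_equal(rec$VLI_mm, 5e4 * v^(1 / 3))
  expect_equal(rec$MCT_mm, rec$CVolume_mm3 / 10)
  expect_equal(rec$CVI, 0.4)
  expect_equal(rec$VLDI_mm2inv, rec$VLI_mm / rec$VVolume_mm3)
  expect_equal(rec$VLS_ratio_mm2inv,
               rec$VLI_mm / (rec$CVolume_mm3 - rec$VVolume_mm3))
  expect_equal(rec$SV_ratio_mminv, rec$VSurface_mm2 / rec$VVolume_mm3)
  expect_equal(rec$VDI_mm, sqrt(rec$VVolume_mm3 / rec$VLI_mm))
  expect_equal(rec$VDI_um, rec$VDI_mm * 1000)
  # CVI * CVolume recovers VVolume to 1e-9 relative
  expect_equal(rec$CVI * rec$CVolume_mm3, rec$VVolume_mm3,
               tolerance = 1e-9)
})

test_that("a fully vascular choroid has CVI 1; bounds always hold", {
  rec <- morphometrics_from_counts(5000, 5000, 800, 100, 2, sp)
  expect_equal(rec$CVI, 1)
  expect_true(is.na(rec$VLS_ratio_mm2inv))      # stroma volume is zero
  expect_match(paste(rec$undefined, collapse = " "), "stromal")
})

test_that("undefined ratios are explicit missing values with reasons", {
  rec0 <- morphometrics_from_counts(0, 0, 0, 0, 1, sp)
  expect_true(is.na(rec0$CVI) && is.na(rec0$MCT_mm) && is.na(rec0$VLDI_mm2inv))
  expect_match(paste(rec0$undefined, collapse = " "), "CVolume is zero")
  recv <- morphometrics_from_counts(1000, 0, 0, 0, 1, sp)
  expect_equal(recv$CVI, 0)
  expect_true(is.na(recv$VLDI_mm2inv) && is.na(recv$SV_ratio_mminv) &&
                is.na(recv$VDI_mm))
  expect_error(morphometrics_from_counts(-1, 0, 0, 0, 1, sp), "nonnegative")
})

test_that("VDI on an ideal cylinder model equals sqrt(pi) * r", {
  # r = 0.05 mm, length 4 mm: VVolume/VLI = pi r^2 so VDI ~ 88.6 um
  r_mm <- 0.05; len <- 4
  n_ves <- pi * r_mm^2 * len / v            # ideal voxel count
  n_line <- len / sp$dx                     # one voxel per slice
  rec <- morphometrics_from_counts(2 * n_ves, n_ves, 1, n_line,
                                   area_mm2 = 1, spacing = sp)
  expect_equal(rec$VDI_um, sqrt(pi) * r_mm * 1000, tolerance = 0.01)
  expect_equal(rec$VDI_um, 88.6, tolerance = 0.01)
})

test_that("published regional rows pool into the published totals", {
  roi <- build_roi(c(500L, 500L), sp, c(249.5, 249.5))
  area_center <- region_area(roi, 1)
  area_para <- region_area(roi, 2:5)
  # Table-style inputs: printed center and parafovea values, as voxel counts
  printed <- list(
    center = c(cvol = 0.286, vvol = 0.122, vsurf = 8.423, vli = 42.9),
    para = c(cvol = 5.183, vvol = 2.120, vsurf = 149.8, vli = 777.2))
  to_counts <- function(p, area, region) {
    data.frame(region = region, n_cho = p[["cvol"]] / v,
               n_ves = p[["vvol"]] / v, n_surf = p[["vsurf"]] / v^(2 / 3),
               n_line = p[["vli"]] / v^(1 / 3), area_mm2 = area)
  }
  counts <- rbind(
    to_counts(printed$center, area_center, 1),
    do.call(rbind, lapply(2:5, function(q)
      to_counts(printed$para / 4, area_para / 4, q))))
  tab <- summarize_counts(counts, sp)
  total <- tab[tab$region == "total", ]
  para <- tab[tab$region == "parafovea", ]
  expect_equal(total$CVolume_mm3, 5.469, tolerance = 1e-6)   # 0.286 + 5.183
  expect_equal(total$VVolume_mm3, 2.242, tolerance = 1e-6)   # 0.122 + 2.120
  expect_equal(total$VSurface_mm2, 158.223, tolerance = 1e-6)
  expect_equal(total$VLI_mm, 820.1, tolerance = 1e-6)        # 42.9 + 777.2
  # MCT: published worked numbers at printed precision
  expect_equal(round(total$MCT_mm, 3), 0.344)                # 5.469 / 15.904
  expect_equal(round(para$MCT_mm, 3), 0.343)                 # 5.183 / 15.119
  ctr <- tab[tab$region == "center", ]
  expect_equal(round(ctr$MCT_mm, 3), 0.364)                  # 0.286 / 0.785
})

test_that("pooled intensive parameters come from pooled counts, not means", {
  counts <- data.frame(region = 1:5,
                       n_cho = c(1000, 4000, 4000, 4000, 4000),
                       n_ves = c(900, 400, 400, 400, 400),
                       n_surf = rep(100, 5), n_line = rep(10, 5),
                       area_mm2 = rep(1, 5))
  tab <- summarize_counts(counts, sp)
  total <- tab[tab$region == "total", ]
  expect_equal(total$CVI, (900 + 4 * 400) / (1000 + 4 * 4000))
  mean_of_ratios <- mean(counts$n_ves / counts$n_cho)
  expect_false(isTRUE(all.equal(total$CVI, mean_of_ratios)))
  expect_error(summarize_counts(counts[-2, ], sp), "missing")
})

test_that("dimensional audit: spacing doubling scales each parameter right", {
  rec1 <- morphometrics_from_counts(1e5, 3e4, 1e4, 3e3, 4, sp)
  sp2 <- voxel_spacing(2 * sp$dx, 2 * sp$dy, 2 * sp$dz)
  rec2 <- morphometrics_from_counts(1e5, 3e4, 1e4, 3e3, 4, sp2)
  expect_equal(rec2$CVolume_mm3 / rec1$CVolume_mm3, 8)
  expect_equal(rec2$VSurface_mm2 / rec1$VSurface_mm2, 4)
  expect_equal(rec2$VLI_mm / rec1$VLI_mm, 2)
  expect_equal(rec2$VDI_mm / rec1$VDI_mm, 2)
  expect_equal(rec2$CVI, rec1$CVI)
})

test_that("summarize_eye ties volumes, models and ROI together", {
  s <- voxel_spacing(0.05, 0.05, 0.05)
  shape <- c(100L, 40L, 100L)
  mask <- make_slab_choroid(shape, s, upper_depth = 0.25, thickness = 1.0)
  set.seed(21)
  ves <- mask$mask & array(runif(prod(shape)) < 0.4, shape)
  vg <- voxel_grid(ves, s, "uint8")
  surf <- voxel_grid(build_surface_model(ves), s, "uint8")
  lg <- voxel_grid(ves & array(runif(prod(shape)) < 0.05, shape), s, "uint8")
  models <- vessel_model_set(vg, surf, lg)
  roi <- build_roi(c(100L, 100L), s, c(49.5, 49.5))
  tab <- summarize_eye(mask, models, roi, sfct_mm = 0.31)
  expect_equal(nrow(tab), 7)
  expect_true(all(tab$CVI >= 0 & tab$CVI <= 1))
  expect_true(all(tab$VVolume_mm3 <= tab$CVolume_mm3))
  expect_equal(tab$CVI * tab$CVolume_mm3, tab$VVolume_mm3, tolerance = 1e-9)
  # extensive additivity across the partition
  regs <- tab[tab$region %in% c("center", "upper_temporal", "lower_temporal",
                                "lower_nasal", "upper_nasal"), ]
  expect_equal(sum(regs$CVolume_mm3), tab$CVolume_mm3[tab$region == "total"])
  expect_equal(sum(regs$VLI_mm), tab$VLI_mm[tab$region == "total"])
})
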