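# Run configuration and the end-to-end pipeline:
# volume + choroid mask -> enhance -> models -> ROI -> per-region table.

#' Pipeline run configuration
#'
#' A fully serializable record of every tunable: given the same config and
#' inputs, a run reproduces its outputs bit for bit.
#'
#' @param spacing a [voxel_spacing()] (used when inputs carry no metadata).
#' @param vesselness a [vesselness_params()].
#' @param prominence line-model descent tolerance (8-bit scale).
#' @param fovea_xz 0-based en-face fovea coordinate, or `NULL` for the scan
#'   centre.
#' @param laterality `"right"` or `"left"`.
#' @param low_pct,high_pct normalization percentiles.
#' @param cs_smoothing cubic-smoothing-spline penalty applied to the C/S
#'   border when the mask carries boundary surfaces (0 = off).
#' @param seed integer seed recorded for provenance (the measurement chain
#'   itself is deterministic).
#' @return an object of class `run_config`.
#' @export
run_config <- function(spacing = oct_default_spacing(),
                       vesselness = vesselness_params(),
                       prominence = 10, fovea_xz = NULL,
                       laterality = "right", low_pct = 0, high_pct = 100,
                       cs_smoothing = 0, seed = 1L) {
  structure(list(spacing = spacing, vesselness = vesselness,
                 prominence = prominence, fovea_xz = fovea_xz,
                 laterality = laterality, low_pct = low_pct,
                 high_pct = high_pct, cs_smoothing = cs_smoothing,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_to_list <- function(config) {
  list(spacing = c(config$spacing$dx, config$spacing$dy, config$spacing$dz),
       scales = config$vesselness$scales,
       alpha = config$vesselness$alpha, beta = config$vesselness$beta,
       c_frac = config$vesselness$c_frac,
       threshold_8bit = config$vesselness$threshold_8bit,
       prominence = config$prominence,
       fovea_xz = config$fovea_xz, laterality = config$laterality,
       low_pct = config$low_pct, high_pct = config$high_pct,
       cs_smoothing = config$cs_smoothing, seed = config$seed)
}

#' Read a run configuration from YAML
#' @param path YAML file; missing keys fall back to defaults.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- run_config()
  sp <- if (!is.null(y$spacing)) {
    s <- as.numeric(y$spacing); voxel_spacing(s[1], s[2], s[3])
  } else defaults$spacing
  vp <- vesselness_params(
    scales = if (!is.null(y$scales)) as.numeric(y$scales)
             else defaults$vesselness$scales,
    alpha = y$alpha %||% defaults$vesselness$alpha,
    beta = y$beta %||% defaults$vesselness$beta,
    c_frac = y$c_frac %||% defaults$vesselness$c_frac,
    threshold_8bit = y$threshold_8bit %||% defaults$vesselness$threshold_8bit)
  run_config(spacing = sp, vesselness = vp,
             prominence = y$prominence %||% defaults$prominence,
             fovea_xz = y$fovea_xz %||% NULL,
             laterality = y$laterality %||% defaults$laterality,
             low_pct = y$low_pct %||% defaults$low_pct,
             high_pct = y$high_pct %||% defaults$high_pct,
             cs_smoothing = y$cs_smoothing %||% defaults$cs_smoothing,
             seed = y$seed %||% defaults$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration to YAML
#' @param config a [run_config()].
#' @param path destination file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' Run the full measurement pipeline
#'
#' Reads a volume and a choroid mask, optionally smooths the C/S border,
#' enhances and binarizes the vessels, builds the surface and line models,
#' rasterizes the fovea-centred ROI, and writes per-region morphometrics
#' (tidy and wide CSV), the three model volumes (TIFF), the ROI label map,
#' and a provenance JSON (config, package version, input checksums).
#'
#' @param config a [run_config()].
#' @param volume path to the acquired volume (TIFF or raw + sidecar).
#' @param mask path to the choroid mask volume, or a [choroid_mask()].
#' @param out_dir output directory (created if needed).
#' @param write_volumes write the model TIFF stacks (default TRUE).
#' @return invisibly, a list with the summary table and the output paths.
#' @export
run_pipeline <- function(config, volume, mask, out_dir,
                         write_volumes = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(volume)) stop("volume file not found: ", volume)
  grid <- read_volume(volume, quiet = TRUE)
  if (inherits(mask, "choroid_mask")) {
    cmask <- mask
    mask_path <- NA_character_
  } else {
    if (!file.exists(mask)) stop("mask file not found: ", mask)
    mask_path <- mask
    mgrid <- read_volume(mask, mask = TRUE, quiet = TRUE)
    check_same_geometry(grid, mgrid, "volume and mask")
    cmask <- choroid_mask(mgrid$data, grid$spacing)
  }
  if (config$cs_smoothing > 0 && !is.null(cmask$lower)) {
    lower <- smooth_cs_border(cmask$lower, config$cs_smoothing,
                              depth_range = c(0, dim(grid)[2]))
    cmask <- choroid_mask_from_surfaces(dim(grid), grid$spacing,
                                        cmask$upper, lower)
  }
  d <- dim(grid)
  fovea <- config$fovea_xz %||% c((d[1] - 1) / 2, (d[3] - 1) / 2)
  roi <- build_roi(c(d[1], d[3]), grid$spacing, fovea, config$laterality)

  norm <- invert_and_normalize(grid, config$low_pct, config$high_pct)
  response <- hessian_vesselness(norm, config$vesselness)
  models <- build_vessel_models(response, cmask, config$vesselness,
                                config$prominence)
  sfct <- if (!is.null(cmask$upper) && !is.null(cmask$lower)) {
    compute_sfct(cmask, round(fovea))
  } else NA_real_
  summary <- summarize_eye(cmask, models, roi, sfct_mm = sfct)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wide_csv <- file.path(out_dir, "morphometrics_wide.csv")
  utils::write.csv(summary, wide_csv, row.names = FALSE)
  tidy <- stats::reshape(summary, direction = "long",
                         varying = setdiff(names(summary), "region"),
                         v.names = "value",
                         times = setdiff(names(summary), "region"),
                         timevar = "parameter", idvar = "region")
  tidy <- tidy[order(tidy$region, tidy$parameter), c("region", "parameter",
                                                     "value")]
  tidy_csv <- file.path(out_dir, "morphometrics_tidy.csv")
  utils::write.csv(tidy, tidy_csv, row.names = FALSE)

  paths <- list(wide = wide_csv, tidy = tidy_csv)
  if (write_volumes) {
    for (nm in c("volume_model", "surface_model", "line_model")) {
      p <- file.path(out_dir, paste0(nm, ".tif"))
      write_volume(models[[nm]], p)
      paths[[nm]] <- p
    }
    roi_grid_out <- voxel_grid(array(roi$labels,
                                     dim = c(d[1], 1L, d[3])),
                               grid$spacing, "uint8")
    paths$roi <- file.path(out_dir, "roi_labels.tif")
    write_volume(roi_grid_out, paths$roi)
  }
  prov <- list(config = config_to_list(config),
               package_version = as.character(utils::packageVersion("choroid3d")),
               inputs = list(volume = volume, mask = mask_path),
               checksums = as.list(tools::md5sum(
                 stats::na.omit(c(volume, mask_path)))))
  paths$provenance <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(summary = summary, models = models, roi = roi,
                 paths = paths))
}
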