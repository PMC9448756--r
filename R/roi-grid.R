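# Fovea-centred ROI grid on the en-face plane: a 1-mm-diameter centre circle
# (region 1) and the four quadrants of the 4.5-mm-diameter circle outside it
# (2 upper-temporal, 3 lower-temporal, 4 lower-nasal, 5 upper-nasal; 0
# outside). "Upper" (superior) is at smaller z; the temporal side depends on
# laterality: smaller x for a right eye, larger x for a left eye.

ROI_REGION_NAMES <- c(outside = 0, center = 1, upper_temporal = 2,
                      lower_temporal = 3, lower_nasal = 4, upper_nasal = 5)

#' Build the fovea-centred ROI label grid
#'
#' A pixel belongs to the centre iff its centre point lies within 0.5 mm of
#' the fovea pixel centre; to quadrant q iff within 2.25 mm, outside the
#' centre, and on the corresponding side of the horizontal and vertical
#' lines through the fovea. Pixels exactly on a dividing line go to the
#' quadrant with the smaller label under the right-eye labelling; left-eye
#' labels are the mirrored relabelling (2<->5, 3<->4), so switching
#' laterality swaps quadrant labels exactly.
#'
#' @param shape_xz en-face shape `c(nx, nz)`.
#' @param spacing a [voxel_spacing()] (only `dx`, `dz` used).
#' @param fovea_xz 0-based en-face voxel coordinate `c(x, z)` of the fovea.
#' @param laterality `"right"` or `"left"`.
#' @return an object of class `roi_grid` with fields `labels` (nx x nz
#'   integer matrix), `areas_mm2` (named per-region areas), `fovea_xz`,
#'   `spacing`, `laterality`, and `truncated` (TRUE when the 4.5-mm circle
#'   does not fit inside the scan).
#' @export
build_roi <- function(shape_xz, spacing, fovea_xz,
                      laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  stopifnot(inherits(spacing, "voxel_spacing"))
  nx <- as.integer(shape_xz[1]); nz <- as.integer(shape_xz[2])
  fx <- fovea_xz[1]; fz <- fovea_xz[2]
  if (fx < 0 || fx > nx - 1 || fz < 0 || fz > nz - 1) {
    stop("fovea coordinate (", fx, ", ", fz, ") outside en-face bounds ",
         nx, "x", nz)
  }
  dx <- spacing$dx; dz <- spacing$dz
  sx <- ((0:(nx - 1)) - fx) * dx          # signed offsets of pixel centres, mm
  sz <- ((0:(nz - 1)) - fz) * dz
  SX <- matrix(sx, nx, nz)
  SZ <- matrix(sz, nx, nz, byrow = TRUE)
  dist <- sqrt(SX^2 + SZ^2)
  labels <- matrix(0L, nx, nz)
  in45 <- dist <= 2.25
  # right-eye quadrants in absolute geometry; min label wins on dividing lines
  q <- matrix(NA_integer_, nx, nz)
  q[in45] <- 5L                                     # sx >= 0 & sz <= 0 default
  q[in45 & SX >= 0 & SZ >= 0] <- 4L
  q[in45 & SX <= 0 & SZ >= 0] <- 3L
  q[in45 & SX <= 0 & SZ <= 0] <- 2L
  labels[in45] <- q[in45]
  labels[dist <= 0.5] <- 1L
  if (laterality == "left") {
    swap <- c(`2` = 5L, `3` = 4L, `4` = 3L, `5` = 2L)
    idx <- labels %in% 2:5
    labels[idx] <- swap[as.character(labels[idx])]
  }
  truncated <- (fx + 0.5) * dx < 2.25 || (nx - 0.5 - fx) * dx < 2.25 ||
               (fz + 0.5) * dz < 2.25 || (nz - 0.5 - fz) * dz < 2.25
  if (truncated) {
    warning("the 4.5-mm circle does not fit inside the scan; ",
            "region areas are truncated")
  }
  pixel_area <- dx * dz
  areas <- vapply(ROI_REGION_NAMES, function(code) {
    sum(labels == code) * pixel_area
  }, numeric(1))
  structure(list(labels = labels, areas_mm2 = areas,
                 fovea_xz = c(fx, fz), spacing = spacing,
                 laterality = laterality, truncated = truncated),
            class = "roi_grid")
}

#' @export
print.roi_grid <- function(x, ...) {
  cat(sprintf("roi_grid %dx%d, fovea (%g, %g), %s eye%s\n",
              nrow(x$labels), ncol(x$labels), x$fovea_xz[1], x$fovea_xz[2],
              x$laterality, if (x$truncated) " [truncated]" else ""))
  print(round(x$areas_mm2, 4))
  invisible(x)
}

#' Physical area of an ROI region
#'
#' @param roi a [build_roi()] grid.
#' @param region region id in 0..5 or a vector of ids (e.g. `2:5` for the
#'   parafovea).
#' @return pixel count times `dx * dz`, in mm^2.
#' @export
region_area <- function(roi, region) {
  stopifnot(inherits(roi, "roi_grid"))
  region <- check_region_ids(region)
  sum(roi$labels %in% region) * roi$spacing$dx * roi$spacing$dz
}

check_region_ids <- function(region) {
  region <- as.integer(region)
  if (!length(region) || any(is.na(region)) || any(!region %in% 0:5)) {
    stop("unknown region id(s): valid ids are 0 (outside), 1 (center), ",
         "2-5 (quadrants)")
  }
  region
}
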