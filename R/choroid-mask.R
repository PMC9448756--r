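#' Segmented choroid
#'
#' Binary occupancy volume of the choroid (between the sub-RPE surface and
#' the choroid/sclera border), optionally with the two en-face boundary depth
#' maps from which it was built. Depth maps hold fractional 0-based voxel
#' y-indices; where both are present the mask is true exactly for integer
#' depths `y` with `upper <= y < lower` (half-open, so stacked structures
#' never double-count a voxel layer).
#'
#' @param mask logical 3D array `[x, y, z]`.
#' @param spacing a [voxel_spacing()].
#' @param upper,lower optional en-face matrices (`nx` x `nz`) of boundary
#'   depths in voxel y-index units.
#' @return an object of class `choroid_mask`.
#' @export
choroid_mask <- function(mask, spacing, upper = NULL, lower = NULL) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask))
  stopifnot(inherits(spacing, "voxel_spacing"))
  d <- dim(mask)
  for (srf in list(upper, lower)) {
    if (!is.null(srf) && !identical(as.integer(dim(srf)), c(d[1], d[3]))) {
      stop("boundary surface must be an en-face ", d[1], "x", d[3], " matrix")
    }
  }
  if (!is.null(upper) && !is.null(lower) && any(upper > lower)) {
    stop("upper surface must lie above (<=) the lower surface everywhere")
  }
  structure(list(mask = mask, spacing = spacing,
                 upper = upper, lower = lower),
            class = "choroid_mask")
}

#' @export
print.choroid_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "choroid_mask %dx%dx%d, %d voxels (CVolume %.4f mm^3), surfaces: %s\n",
    d[1], d[2], d[3], sum(x$mask), sum(x$mask) * voxel_volume(x$spacing),
    if (is.null(x$upper)) "absent" else "present"))
  invisible(x)
}

#' Build a choroid mask from two boundary depth maps
#'
#' @param shape integer triple (nx, ny, nz).
#' @param spacing a [voxel_spacing()].
#' @param upper,lower en-face matrices (or scalars, recycled) of boundary
#'   depths in voxel y-index units; the mask is true for `upper <= y < lower`
#'   with `y` a 0-based integer depth index.
#' @return a `choroid_mask` with both surfaces recorded.
#' @export
choroid_mask_from_surfaces <- function(shape, spacing, upper, lower) {
  shape <- as.integer(shape)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  as_surf <- function(s) {
    if (length(s) == 1L) matrix(as.numeric(s), nx, nz)
    else matrix(as.numeric(s), nx, nz)
  }
  upper <- as_surf(upper); lower <- as_surf(lower)
  if (any(upper > lower)) stop("upper surface below lower surface somewhere")
  # y in [upper, lower) for 0-based integer y
  y <- 0:(ny - 1)
  mask <- array(FALSE, dim = shape)
  for (yi in y) {
    mask[, yi + 1L, ] <- (upper <= yi) & (yi < lower)
  }
  choroid_mask(mask, spacing, upper, lower)
}

#' Smooth the choroid/sclera border with a cubic smoothing spline
#'
#' Applies a cubic smoothing spline separably along each en-face axis of the
#' lower-boundary depth map and averages the two fits. `smoothing` is the
#' spline penalty (`lambda` of [stats::smooth.spline()], on the unit-scaled
#' abscissa); `0` returns the input unchanged. Linear trends are reproduced
#' exactly (they span the penalty null space).
#'
#' @param lower_surface en-face numeric matrix of depths (voxel y-index).
#' @param smoothing nonnegative penalty; larger smooths more.
#' @param depth_range optional `c(min, max)` clamp applied to the output,
#'   e.g. `c(0, ny - 1)`.
#' @return smoothed matrix of the same shape.
#' @export
smooth_cs_border <- function(lower_surface, smoothing, depth_range = NULL) {
  if (!is.numeric(smoothing) || length(smoothing) != 1 || smoothing < 0) {
    stop("'smoothing' must be a single nonnegative number")
  }
  if (any(!is.finite(lower_surface))) {
    stop("lower surface must be finite everywhere")
  }
  srf <- as.matrix(lower_surface)
  if (smoothing == 0) return(srf)
  fit_profile <- function(yv) {
    n <- length(yv)
    if (n < 4L || stats::sd(yv) == 0) return(yv)
    stats::predict(stats::smooth.spline(seq_len(n), yv, lambda = smoothing,
                                        all.knots = TRUE),
                   seq_len(n))$y
  }
  along_x <- apply(srf, 2, fit_profile)                 # each column: x profile
  along_z <- t(apply(srf, 1, fit_profile))              # each row: z profile
  out <- (along_x + along_z) / 2
  if (!is.null(depth_range)) {
    out <- pmin(pmax(out, depth_range[1]), depth_range[2])
  }
  out
}

#' Choroidal volume in a region of interest
#'
#' Counts choroid voxels whose en-face position falls in the given ROI
#' region(s) and scales by the physical voxel volume.
#'
#' @param mask a [choroid_mask()].
#' @param roi a [build_roi()] grid (or `NULL` for the whole volume).
#' @param region region id or vector of ids (0 outside, 1 centre, 2-5
#'   quadrants); e.g. `2:5` for the parafovea, `1:5` for the full circle.
#' @return volume in mm^3.
#' @export
compute_cvolume <- function(mask, roi = NULL, region = 1:5) {
  stopifnot(inherits(mask, "choroid_mask"))
  n <- count_in_region(mask$mask, roi, region)
  n * voxel_volume(mask$spacing)
}

#' Subfoveal choroidal thickness
#'
#' Distance from the sub-RPE surface to the choroid/sclera border at the
#' foveal A-scan, in mm. Uses the single A-scan column at the fovea by
#' default; `median3x3 = TRUE` takes the median over the 3x3 neighbourhood.
#'
#' @param mask a [choroid_mask()] carrying both boundary surfaces.
#' @param fovea_xz 0-based en-face voxel coordinate `c(x, z)` of the fovea.
#' @param median3x3 median-filter option (off by default).
#' @return thickness in mm.
#' @export
compute_sfct <- function(mask, fovea_xz, median3x3 = FALSE) {
  stopifnot(inherits(mask, "choroid_mask"))
  d <- dim(mask$mask)
  fx <- as.integer(fovea_xz[1]); fz <- as.integer(fovea_xz[2])
  if (fx < 0 || fx >= d[1] || fz < 0 || fz >= d[3]) {
    stop("fovea coordinate (", fx, ", ", fz, ") outside en-face bounds")
  }
  if (is.null(mask$upper) || is.null(mask$lower)) {
    stop("boundary surfaces undefined at the fovea; provide surfaces or ",
         "derive thickness from the mask (contiguous run length of the ",
         "foveal A-scan column times dy)")
  }
  if (median3x3) {
    xs <- pmax(1L, pmin(d[1], fx + (0:2)))   # fx+1 +/- 1 in 1-based indexing
    zs <- pmax(1L, pmin(d[3], fz + (0:2)))
    thick <- stats::median(mask$lower[xs, zs] - mask$upper[xs, zs])
  } else {
    thick <- mask$lower[fx + 1L, fz + 1L] - mask$upper[fx + 1L, fz + 1L]
  }
  if (!is.finite(thick)) {
    stop("boundary surfaces undefined at the fovea; provide surfaces or ",
         "derive thickness from the mask run length at that A-scan")
  }
  thick * mask$spacing$dy
}
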