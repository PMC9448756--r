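# Synthetic OCT-like phantoms: a slab "choroid" containing dark tubes on a
# bright stromal background, with analytic ground truth for tube length,
# volume, lateral surface and diameter. Phantoms are generated in acquired
# polarity (vessels dark) so the pipeline's inversion step is exercised.

#' Specify a synthetic tube
#'
#' @param centerline n x 3 matrix of points (mm, in `(x, y, z)` physical
#'   coordinates) defining a polyline; or the output of [helix_centerline()].
#' @param radius tube radius in mm.
#' @param contrast intensity contrast in (0, 1]: 1 makes the tube interior
#'   fully dark against the stromal background.
#' @return an object of class `tube_spec` carrying analytic truth
#'   (arc length, volume, lateral surface, diameter).
#' @export
tube_spec <- function(centerline, radius, contrast = 1) {
  centerline <- as.matrix(centerline)
  stopifnot(ncol(centerline) == 3, nrow(centerline) >= 2)
  if (!(radius > 0)) stop("tube radius must be positive")
  if (!(contrast > 0 && contrast <= 1)) stop("contrast must be in (0, 1]")
  len <- attr(centerline, "arc_length")
  if (is.null(len)) len <- polyline_length(centerline)
  structure(list(centerline = centerline, radius = radius,
                 contrast = contrast, length = len,
                 volume = pi * radius^2 * len,
                 lateral_surface = 2 * pi * radius * len,
                 cap_area = 2 * pi * radius^2,
                 diameter = 2 * radius),
            class = "tube_spec")
}

#' Arc length of a 3D polyline
#' @param pts n x 3 matrix of points in mm.
#' @return total length in mm.
#' @export
polyline_length <- function(pts) {
  d <- diff(pts)
  sum(sqrt(rowSums(d^2)))
}

#' Helical centerline with analytic arc length
#'
#' Generates a polyline sampling of a circular helix around an axis parallel
#' to x, and attaches the closed-form arc length
#' `2*pi*coils*sqrt(r^2 + (pitch/(2*pi))^2)` as an attribute so tube truth is
#' exact rather than chord-approximated.
#'
#' @param center `c(x, y, z)` mm of the helix start-axis point.
#' @param helix_radius radius of the helix (mm).
#' @param pitch axial rise per full turn (mm).
#' @param coils number of full turns (may be fractional).
#' @param n number of polyline vertices.
#' @return n x 3 matrix with attribute `arc_length`.
#' @export
helix_centerline <- function(center, helix_radius, pitch, coils, n = 400L) {
  t <- seq(0, 2 * pi * coils, length.out = n)
  pts <- cbind(center[1] + pitch * t / (2 * pi),
               center[2] + helix_radius * sin(t),
               center[3] + helix_radius * cos(t))
  attr(pts, "arc_length") <-
    2 * pi * coils * sqrt(helix_radius^2 + (pitch / (2 * pi))^2)
  pts
}

#' Slab choroid phantom
#'
#' Builds a flat or sloped slab choroid mask: at each en-face position the
#' choroid occupies depths from `upper_depth` to `upper_depth + thickness`
#' (both in mm, converted to fractional voxel y-indices and rasterized with
#' the half-open convention of [choroid_mask_from_surfaces()]).
#'
#' @param shape voxel triple (nx, ny, nz).
#' @param spacing a [voxel_spacing()].
#' @param upper_depth scalar or en-face matrix, depth of the sub-RPE surface
#'   in mm.
#' @param thickness scalar or en-face matrix, slab thickness in mm; must be
#'   strictly positive everywhere.
#' @return a [choroid_mask()].
#' @export
make_slab_choroid <- function(shape, spacing, upper_depth, thickness) {
  shape <- as.integer(shape)
  if (any(thickness <= 0)) stop("slab thickness must be strictly positive")
  dy <- spacing$dy
  up <- upper_depth / dy
  lo <- (upper_depth + thickness) / dy
  if (any(lo > shape[2])) {
    stop("upper_depth + thickness exceeds the volume depth (",
         shape[2] * dy, " mm)")
  }
  choroid_mask_from_surfaces(shape, spacing, up, lo)
}

# minimum distance from points (m x 3) to segment a-b
dist_to_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(sqrt(rowSums(sweep(pts, 2, a)^2)))
  }
  ap <- sweep(pts, 2, a)
  t <- pmin(1, pmax(0, (ap %*% ab)[, 1] / len2))
  proj <- outer(t, ab)
  sqrt(rowSums((ap - proj)^2))
}

# logical volume of voxels whose center lies within `radius` of the polyline
voxelize_tube <- function(tube, shape, spacing) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  sp <- c(spacing$dx, spacing$dy, spacing$dz)
  out <- array(FALSE, dim = shape)
  cl <- tube$centerline
  r <- tube$radius
  for (s in seq_len(nrow(cl) - 1)) {
    a <- cl[s, ]; b <- cl[s + 1, ]
    lohi <- rbind(pmin(a, b) - r, pmax(a, b) + r)
    # voxel index ranges whose centers (i + 0.5) * sp may be in range
    i0 <- pmax(0L, floor(lohi[1, ] / sp - 0.5))
    i1 <- pmin(c(nx, ny, nz) - 1L, ceiling(lohi[2, ] / sp - 0.5))
    if (any(i0 > i1)) next
    xs <- i0[1]:i1[1]; ys <- i0[2]:i1[2]; zs <- i0[3]:i1[3]
    ctr <- as.matrix(expand.grid(x = (xs + 0.5) * sp[1],
                                 y = (ys + 0.5) * sp[2],
                                 z = (zs + 0.5) * sp[3]))
    inside <- dist_to_segment(ctr, a, b) <= r
    if (any(inside)) {
      sub <- out[xs + 1L, ys + 1L, zs + 1L, drop = FALSE]
      out[xs + 1L, ys + 1L, zs + 1L] <-
        sub | array(inside, dim = c(length(xs), length(ys), length(zs)))
    }
  }
  out
}

#' Render a tube phantom volume
#'
#' Draws dark tubes on a bright stromal background inside a slab choroid,
#' adds voxelwise Gaussian noise, and returns the volume together with the
#' analytic ground truth for each tube. The volume is float in [0, 1],
#' acquired polarity (vessels dark). Deterministic for a fixed seed.
#'
#' @param tubes list of [tube_spec()] objects.
#' @param mask a [choroid_mask()] defining geometry and the slab.
#' @param noise_sigma standard deviation of additive Gaussian noise on the
#'   [0, 1] intensity scale (default 0.05, a mild speckle stand-in).
#' @param seed integer RNG seed.
#' @param background stromal intensity (default 0.85).
#' @param speckle if `TRUE`, use multiplicative (speckle-like) noise
#'   `I * (1 + sigma * N)` instead of additive.
#' @return a list with `grid` (a [voxel_grid()]) and `truth` (a data frame,
#'   one row per tube plus a `total` row; attribute `overlap` flags voxels
#'   claimed by more than one tube, in which case the volume/surface totals
#'   are not guaranteed additive).
#' @export
render_tubes <- function(tubes, mask, noise_sigma = 0.05, seed = 1L,
                         background = 0.85, speckle = FALSE) {
  stopifnot(inherits(mask, "choroid_mask"))
  shape <- dim(mask$mask)
  spacing <- mask$spacing
  extent <- shape * c(spacing$dx, spacing$dy, spacing$dz)
  vol <- array(background, dim = shape)
  occupancy <- array(0L, dim = shape)
  rows <- list()
  for (i in seq_along(tubes)) {
    tube <- tubes[[i]]
    stopifnot(inherits(tube, "tube_spec"))
    cl <- tube$centerline
    if (any(sweep(cl, 2, extent) > -tube$radius + 1e-12) ||
        any(cl < tube$radius - 1e-12)) {
      stop("tube ", i, " escapes the volume bounds (",
           paste(signif(extent, 4), collapse = " x "), " mm)")
    }
    tv <- voxelize_tube(tube, shape, spacing)
    occupancy <- occupancy + tv
    vol[tv] <- pmin(vol[tv], background * (1 - tube$contrast))
    rows[[i]] <- data.frame(
      tube = i, length_mm = tube$length, volume_mm3 = tube$volume,
      lateral_surface_mm2 = tube$lateral_surface,
      diameter_mm = tube$diameter,
      voxels = sum(tv))
  }
  truth <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(tube = integer(), length_mm = numeric(),
               volume_mm3 = numeric(), lateral_surface_mm2 = numeric(),
               diameter_mm = numeric(), voxels = integer())
  }
  total <- data.frame(tube = NA_integer_,
                      length_mm = sum(truth$length_mm),
                      volume_mm3 = sum(truth$volume_mm3),
                      lateral_surface_mm2 = sum(truth$lateral_surface_mm2),
                      diameter_mm = NA_real_,
                      voxels = sum(occupancy > 0L))
  truth <- rbind(truth, total)
  attr(truth, "overlap") <- any(occupancy > 1L)
  attr(truth, "slab_volume_mm3") <- sum(mask$mask) * voxel_volume(spacing)
  if (!is.null(mask$upper) && !is.null(mask$lower)) {
    attr(truth, "thickness_map_mm") <- (mask$lower - mask$upper) * spacing$dy
  }
  if (noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    })
    set.seed(as.integer(seed))
    noise <- array(stats::rnorm(prod(shape), sd = noise_sigma), dim = shape)
    vol <- if (speckle) vol * (1 + noise) else vol + noise
    vol <- pmin(pmax(vol, 0), 1)
  }
  list(grid = voxel_grid(vol, spacing, "float"), truth = truth)
}
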