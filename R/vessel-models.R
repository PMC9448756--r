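# The three vessel models: volume (binarized vessels), surface (boundary
# voxels by 6-neighbourhood, scan border excluded) and line (per-slice
# intensity maxima along the x and z scan axes, combined).

#' Bundle the three vessel models
#'
#' @param volume_model,surface_model,line_model logical [voxel_grid()]s of
#'   identical geometry; surface and line models must be subsets of the
#'   volume model.
#' @param provenance named list of the settings used (recorded verbatim).
#' @return an object of class `vessel_model_set`.
#' @export
vessel_model_set <- function(volume_model, surface_model, line_model,
                             provenance = list()) {
  for (g in list(volume_model, surface_model, line_model)) {
    stopifnot(inherits(g, "voxel_grid"), is.logical(g$data))
  }
  check_same_geometry(volume_model, surface_model)
  check_same_geometry(volume_model, line_model)
  if (any(surface_model$data & !volume_model$data)) {
    stop("surface model must be a subset of the volume model")
  }
  if (any(line_model$data & !volume_model$data)) {
    stop("line model must be a subset of the volume model")
  }
  structure(list(volume_model = volume_model, surface_model = surface_model,
                 line_model = line_model, params_provenance = provenance),
            class = "vessel_model_set")
}

#' @export
print.vessel_model_set <- function(x, ...) {
  cat(sprintf("vessel_model_set: volume %d, surface %d, line %d voxels\n",
              sum(x$volume_model$data), sum(x$surface_model$data),
              sum(x$line_model$data)))
  invisible(x)
}

#' Surface model: 6-direction boundary voxels
#'
#' A voxel belongs to the surface model iff it is foreground and at least
#' one of its six face neighbours *inside the scan domain* is background.
#' Exposure at the scan border alone does not count, so a volume that is
#' entirely foreground has an empty surface model.
#'
#' @param volume_model logical [voxel_grid()] (or plain logical 3D array).
#' @return logical volume of the same type as the input.
#' @export
build_surface_model <- function(volume_model) {
  if (inherits(volume_model, "voxel_grid")) {
    arr <- volume_model$data
    out <- cpp_surface6(arr, as.integer(dim(arr)))
    return(grid_like(volume_model, array(out, dim = dim(arr))))
  }
  stopifnot(is.logical(volume_model), length(dim(volume_model)) == 3L)
  array(cpp_surface6(volume_model, as.integer(dim(volume_model))),
        dim = dim(volume_model))
}

#' Per-slice maxima by topographic prominence
#'
#' Finds local intensity maxima of a 2D image in the manner of Fiji's
#' "Find Maxima": a maximum is reported iff no path to a higher pixel exists
#' without descending more than `prominence` below it (the global maximum is
#' measured against the image minimum), using 8-connectivity. One point is
#' reported per plateau, at the plateau centroid with half-values rounded
#' toward the smaller index. A constant image yields no maxima.
#'
#' @param slice2d numeric matrix.
#' @param prominence nonnegative descent tolerance (Fiji's noise tolerance).
#' @return integer matrix with one row per maximum and columns `i`, `j`
#'   (1-based row/column indices into `slice2d`).
#' @export
find_slice_maxima <- function(slice2d, prominence) {
  stopifnot(is.matrix(slice2d), prominence >= 0)
  mask <- cpp_prominence_maxima(slice2d, prominence)
  pts <- which(mask, arr.ind = TRUE)
  colnames(pts) <- c("i", "j")
  pts
}

#' Line model: combined per-slice maxima along the x and z axes
#'
#' Runs [find_slice_maxima()] on the vessel-masked response in every fixed-x
#' `(y, z)` slice and every fixed-z `(x, y)` slice, marks the maxima voxels,
#' takes the union of the two passes, and intersects with the vessel volume
#' model so that the line model is always a subset of the binarized vessels.
#'
#' @param response [voxel_grid()], the (8-bit or float) vesselness response.
#' @param volume_model logical [voxel_grid()] of binarized vessels.
#' @param prominence descent tolerance; the default 10 is calibrated to the
#'   0-255 8-bit response scale.
#' @return logical [voxel_grid()] line model.
#' @export
build_line_model <- function(response, volume_model, prominence = 10) {
  stopifnot(inherits(response, "voxel_grid"),
            inherits(volume_model, "voxel_grid"),
            is.logical(volume_model$data))
  check_same_geometry(response, volume_model, "response and volume model")
  d <- dim(response$data)
  masked <- response$data * volume_model$data
  line <- array(FALSE, dim = d)
  for (x in seq_len(d[1])) {                      # fixed-x (y, z) slices
    img <- masked[x, , ]
    if (all(img == 0)) next
    line[x, , ] <- line[x, , ] | cpp_prominence_maxima(img, prominence)
  }
  for (z in seq_len(d[3])) {                      # fixed-z (x, y) slices
    img <- masked[, , z]
    if (all(img == 0)) next
    line[, , z] <- line[, , z] | cpp_prominence_maxima(img, prominence)
  }
  grid_like(volume_model, line & volume_model$data)
}

#' Build all three vessel models from a response and a choroid mask
#'
#' Convenience wrapper: binarize, surface, line, bundled with provenance.
#'
#' @param response float [voxel_grid()] vesselness response.
#' @param mask a [choroid_mask()].
#' @param params a [vesselness_params()] (threshold taken from it).
#' @param prominence line-model descent tolerance on the 8-bit scale.
#' @return a [vessel_model_set()].
#' @export
build_vessel_models <- function(response, mask, params = vesselness_params(),
                                prominence = 10) {
  volume_model <- binarize_vessels(response, mask, params$threshold_8bit)
  surface_model <- build_surface_model(volume_model)
  response8 <- rescale_to_8bit(response)
  line_model <- build_line_model(response8, volume_model, prominence)
  vessel_model_set(volume_model, surface_model, line_model,
                   provenance = list(scales = params$scales,
                                     alpha = params$alpha, beta = params$beta,
                                     c_frac = params$c_frac,
                                     threshold_8bit = params$threshold_8bit,
                                     prominence = prominence))
}
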