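#' Attenuation volume
#'
#' Container for a 3D chest CT attenuation grid. Voxels are integer Hounsfield
#' units (HU) and the grid axis order is fixed as `(z, y, x)`: the first array
#' index runs along the scanner axis (slices), the last along the patient's
#' left-right axis. `spacing` gives the voxel edge lengths in millimetres in
#' the same `(z, y, x)` order.
#'
#' @param voxels 3D integer array of HU values, axis order `(z, y, x)`.
#'   All values must lie in the CT representable range \[-1024, 3071\].
#' @param spacing numeric length-3, voxel spacing in mm per axis `(z, y, x)`;
#'   all entries must be positive.
#' @param origin numeric length-3 offset in mm (informational only).
#'
#' @return An object of class `attenuation_volume` with fields `voxels`,
#'   `spacing`, `origin`.
#' @export
#' @examples
#' vol <- attenuation_volume(array(-800L, c(8, 8, 8)), spacing = c(2, 2, 2))
#' voxel_volume_mm3(vol)
attenuation_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    stop_pedct("`voxels` must be a 3D array", "pedct_bad_volume")
  if (anyNA(voxels))
    stop_pedct("`voxels` must not contain NA", "pedct_bad_volume")
  rng <- range(voxels)
  if (rng[1] < -1024 || rng[2] > 3071)
    stop_pedct("HU values must lie in [-1024, 3071]", "pedct_bad_volume")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_pedct("`spacing` must be 3 positive values (mm)", "pedct_bad_volume")
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "attenuation_volume")
}

#' @export
print.attenuation_volume <- function(x, ...) {
  cat("<attenuation_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels (z,y,x), spacing ", paste(x$spacing, collapse = " x "),
      " mm, HU range [", min(x$voxels), ", ", max(x$voxels), "]\n", sep = "")
  invisible(x)
}

#' @rdname attenuation_volume
#' @param volume an `attenuation_volume`.
#' @export
voxel_volume_mm3 <- function(volume) prod(volume$spacing)

#' Lung mask
#'
#' Boolean grid congruent with its source [attenuation_volume()], marking the
#' voxels retained as lung parenchyma plus central airways.
#'
#' @param voxels 3D logical array, same shape as the source volume.
#' @param component_count number of connected components retained.
#'
#' @return An object of class `lung_mask`.
#' @export
lung_mask <- function(voxels, component_count = NA_integer_) {
  if (length(dim(voxels)) != 3L)
    stop_pedct("mask must be a 3D array", "pedct_bad_mask")
  storage.mode(voxels) <- "logical"
  structure(list(voxels = voxels,
                 component_count = as.integer(component_count)),
            class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  cat("<lung_mask> ", sum(x$voxels), " of ", length(x$voxels),
      " voxels, ", x$component_count, " component(s)\n", sep = "")
  invisible(x)
}

check_congruent <- function(volume, mask) {
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    stop_pedct("mask and volume shapes differ", "pedct_incongruent")
  invisible(TRUE)
}
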