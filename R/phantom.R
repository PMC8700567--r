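#' Synthetic chest phantom specification
#'
#' Describes a digital chest phantom: a soft-tissue body modelled as an
#' elliptical cylinder spanning the full z extent of the grid (so exterior
#' air surrounds it laterally, as on a real scan where cranial/caudal slices
#' truncate the anatomy), containing one or more lung ellipsoids whose voxels
#' are drawn from a calibrated [parenchyma_distribution()]. Optional extra
#' air pockets at exterior-air HU emulate non-pulmonary air (the
#' gastric-bubble situation) that segmentation must reject.
#'
#' @param grid_shape integer length-3 voxel counts `(z, y, x)`, all >= 8.
#' @param spacing voxel spacing in mm `(z, y, x)`, all > 0.
#' @param distribution a [parenchyma_distribution()] for lung voxels.
#' @param lung_ellipsoids list of ellipsoids, each `list(center=, semiaxes=)`
#'   in 1-based voxel units `(z, y, x)`. Defaults to two lungs scaled to the
#'   grid.
#' @param body_hu soft-tissue HU (default 40).
#' @param outside_hu exterior-air HU (default -1000).
#' @param body_semiaxes_frac fractions of the `(y, x)` grid extents used as
#'   body cylinder semi-axes (default 0.46).
#' @param extra_air_pockets list of ellipsoids (same structure as
#'   `lung_ellipsoids`) carved at `outside_hu`; must not intersect the lungs.
#'
#' @return Object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(grid_shape = c(48, 48, 48), spacing = c(2, 2, 2),
#'                      distribution = calibrate_distribution(-803, 147.3,
#'                                                            0.0053, 0.102))
phantom_spec <- function(grid_shape = c(96, 96, 96),
                         spacing = c(2, 2, 2),
                         distribution,
                         lung_ellipsoids = NULL,
                         body_hu = 40,
                         outside_hu = -1000,
                         body_semiaxes_frac = c(0.46, 0.46),
                         extra_air_pockets = list()) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop_pedct("grid_shape must be 3 values, all >= 8", "pedct_bad_spec")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_pedct("spacing must be 3 positive values", "pedct_bad_spec")
  stopifnot(inherits(distribution, "parenchyma_distribution"))
  if (is.null(lung_ellipsoids))
    lung_ellipsoids <- default_lung_ellipsoids(grid_shape)
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 distribution = distribution,
                 lung_ellipsoids = lung_ellipsoids,
                 body_hu = as.integer(body_hu),
                 outside_hu = as.integer(outside_hu),
                 body_semiaxes_frac = body_semiaxes_frac,
                 extra_air_pockets = extra_air_pockets),
            class = "phantom_spec")
}

# Two lung ellipsoids placed symmetrically about the midline, sized relative
# to the grid so they sit strictly inside the body cylinder.
default_lung_ellipsoids <- function(grid_shape) {
  nz <- grid_shape[1]; ny <- grid_shape[2]; nx <- grid_shape[3]
  semi <- c(0.42 * nz, 0.30 * ny, 0.17 * nx)
  ctr_z <- (nz + 1) / 2; ctr_y <- (ny + 1) / 2
  offset <- 0.20 * nx
  list(list(center = c(ctr_z, ctr_y, (nx + 1) / 2 - offset), semiaxes = semi),
       list(center = c(ctr_z, ctr_y, (nx + 1) / 2 + offset), semiaxes = semi))
}

# Logical array of voxels inside an ellipsoid, on a (z,y,x) grid.
ellipsoid_mask <- function(grid_shape, center, semiaxes) {
  d2 <- lapply(1:3, function(a)
    ((seq_len(grid_shape[a]) - center[a]) / semiaxes[a])^2)
  outer(outer(d2[[1]], d2[[2]], "+"), d2[[3]], "+") <= 1
}

body_mask_for <- function(spec) {
  ny <- spec$grid_shape[2]; nx <- spec$grid_shape[3]
  dy2 <- ((seq_len(ny) - (ny + 1) / 2) / (spec$body_semiaxes_frac[1] * ny))^2
  dx2 <- ((seq_len(nx) - (nx + 1) / 2) / (spec$body_semiaxes_frac[2] * nx))^2
  in_yx <- outer(dy2, dx2, "+") <= 1
  array(rep(in_yx, each = spec$grid_shape[1]), dim = spec$grid_shape)
}

#' Generate a synthetic chest phantom
#'
#' Renders a [phantom_spec()] into an [attenuation_volume()]: exterior voxels
#' and extra air pockets get `outside_hu`, body voxels `body_hu`, and lung
#' voxels independent integer-HU draws from the spec's parenchymal
#' distribution. The ground-truth lung mask and its volume are returned
#' alongside, so segmentation and densitometry can be validated against a
#' known answer.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; the same spec and seed give bit-identical output.
#'
#' @return A list with elements `volume` ([attenuation_volume()]),
#'   `ground_truth_mask` ([lung_mask()]) and `ground_truth_volume_mL`.
#' @export
generate_phantom <- function(spec, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  body <- body_mask_for(spec)

  lung <- array(FALSE, dim = spec$grid_shape)
  for (e in spec$lung_ellipsoids)
    lung <- lung | ellipsoid_mask(spec$grid_shape, e$center, e$semiaxes)
  if (any(lung & !body))
    stop_pedct("lung ellipsoid extends outside the body region",
               "pedct_bad_spec")

  pockets <- array(FALSE, dim = spec$grid_shape)
  for (e in spec$extra_air_pockets)
    pockets <- pockets | ellipsoid_mask(spec$grid_shape, e$center, e$semiaxes)
  if (any(pockets & lung))
    stop_pedct("extra air pocket intersects a lung ellipsoid",
               "pedct_bad_spec")

  vox <- array(spec$outside_hu, dim = spec$grid_shape)
  vox[body] <- spec$body_hu
  vox[pockets] <- spec$outside_hu
  n_lung <- sum(lung)
  vox[lung] <- sample_parenchyma(spec$distribution, n_lung, seed)

  volume <- attenuation_volume(vox, spec$spacing)
  list(volume = volume,
       ground_truth_mask = lung_mask(lung, component_count =
                                       length(spec$lung_ellipsoids)),
       ground_truth_volume_mL = n_lung * prod(spec$spacing) / 1000)
}
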