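#' Select voxels inside an attenuation window
#'
#' First segmentation stage: marks every voxel whose HU lies in
#' `[lower, upper]` (inclusive at both ends). On a chest CT this captures
#' aerated lung, airway air and exterior air while excluding soft tissue and
#' bone; the default window (-1024, -200) HU brackets aerated parenchyma
#' generously. The result still contains exterior air — see
#' [remove_external_air()].
#'
#' @param volume an [attenuation_volume()].
#' @param lower,upper window bounds in HU, `lower < upper`.
#' @return A candidate [lung_mask()] (`component_count` not yet set).
#' @export
select_attenuation_window <- function(volume, lower = -1024, upper = -200) {
  stopifnot(inherits(volume, "attenuation_volume"))
  if (!(lower < upper))
    stop_pedct("window requires lower < upper", "pedct_bad_window")
  m <- volume$voxels >= lower & volume$voxels <= upper
  if (!any(m))
    stop_pedct("attenuation window selects no voxels", "pedct_empty_window")
  lung_mask(m)
}

# Strides of the three axes in R's column-major linear indexing of a (z,y,x)
# array: moving one step along z changes the linear index by 1, along y by
# nz, along x by nz*ny.
axis_strides <- function(d) c(1L, d[1], d[1] * d[2])

# 6-connected component labels of a logical 3D array. Returns a list with
# `membership` (integer label per TRUE voxel), `voxel_index` (their linear
# indices) and `n_components`. Edges between face-adjacent TRUE voxels are
# built vectorised per axis and handed to igraph.
label_components_6 <- function(m) {
  d <- dim(m)
  voxel_index <- which(m)
  k <- length(voxel_index)
  if (k == 0) return(list(membership = integer(0),
                          voxel_index = integer(0), n_components = 0L))
  vertex_of <- integer(length(m))
  vertex_of[voxel_index] <- seq_len(k)
  strides <- axis_strides(d)
  edges <- vector("list", 3L)
  for (ax in 1:3) {
    shifted <- array(FALSE, d)
    n <- d[ax]
    src <- switch(ax, m[-1, , , drop = FALSE], m[, -1, , drop = FALSE],
                  m[, , -1, drop = FALSE])
    switch(ax,
           shifted[-n, , ] <- src,
           shifted[, -n, ] <- src,
           shifted[, , -n] <- src)
    i <- which(m & shifted)
    edges[[ax]] <- rbind(vertex_of[i], vertex_of[i + strides[ax]])
  }
  g <- igraph::make_graph(edges = as.vector(do.call(cbind, edges)),
                          n = k, directed = FALSE)
  comp <- igraph::components(g)
  list(membership = comp$membership, voxel_index = voxel_index,
       n_components = comp$no)
}

#' Remove exterior air and sub-minimum components from a candidate mask
#'
#' Algorithmic replacement for the manual clean-up step of interactive
#' densitometry software, where air outside the chest and incidental
#' non-pulmonary air (gastric bubble and the like) are erased by hand. The
#' candidate mask is split into 6-connected components; a component is
#' discarded when it touches a lateral (`x` or `y`) face of the grid
#' (exterior air — the `z` faces are exempt because cranial/caudal slices
#' may legitimately truncate lung) or when it is smaller than
#' `min_component_mL` (stray air pockets). Everything that remains — lung
#' parenchyma plus enclosed central airways — is returned.
#'
#' @param candidate_mask a nonempty [lung_mask()], e.g. from
#'   [select_attenuation_window()].
#' @param volume the congruent [attenuation_volume()] (supplies spacing).
#' @param min_component_mL minimum component volume kept, in mL (default 5).
#' @return A [lung_mask()] with `component_count` set to the number of
#'   retained components. Idempotent: applying it to its own output changes
#'   nothing.
#' @export
remove_external_air <- function(candidate_mask, volume,
                                min_component_mL = 5) {
  stopifnot(inherits(candidate_mask, "lung_mask"))
  check_congruent(volume, candidate_mask)
  m <- candidate_mask$voxels
  if (!any(m))
    stop_pedct("candidate mask is empty", "pedct_empty_mask")
  lab <- label_components_6(m)
  d <- dim(m)

  pos <- arrayInd(lab$voxel_index, d)
  on_lateral_face <- pos[, 2] == 1L | pos[, 2] == d[2] |
    pos[, 3] == 1L | pos[, 3] == d[3]
  touches_face <- logical(lab$n_components)
  touches_face[unique(lab$membership[on_lateral_face])] <- TRUE

  vox_ml <- voxel_volume_mm3(volume) / 1000
  comp_ml <- tabulate(lab$membership, lab$n_components) * vox_ml
  keep <- !touches_face & comp_ml >= min_component_mL
  if (!any(keep))
    stop_pedct("segmentation failed: no component survives exterior-air and minimum-volume filtering",
               "pedct_segmentation_failure")

  out <- array(FALSE, d)
  out[lab$voxel_index[keep[lab$membership]]] <- TRUE
  lung_mask(out, component_count = sum(keep))
}

#' Volume of a mask in millilitres
#'
#' @param mask a [lung_mask()].
#' @param volume the congruent [attenuation_volume()] whose spacing defines
#'   the voxel volume.
#' @return Voxel count times voxel volume, in mL.
#' @export
mask_volume_mL <- function(mask, volume) {
  stopifnot(inherits(mask, "lung_mask"))
  check_congruent(volume, mask)
  sum(mask$voxels) * voxel_volume_mm3(volume) / 1000
}

#' Full lung segmentation pipeline
#'
#' Attenuation window followed by exterior-air/minimum-volume filtering:
#' the deterministic equivalent of the interactive workflow (set window
#' visually, erase exterior air by hand).
#'
#' @inheritParams select_attenuation_window
#' @inheritParams remove_external_air
#' @param window_low,window_high attenuation window in HU.
#' @return A [lung_mask()].
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
#'   distribution = calibrate_distribution(-803, 147.3, 0.0053, 0.102)),
#'   seed = 1)
#' mask <- segment_lungs(ph$volume)
#' mask_volume_mL(mask, ph$volume) / ph$ground_truth_volume_mL
segment_lungs <- function(volume, window_low = -1024, window_high = -200,
                          min_component_mL = 5) {
  cand <- select_attenuation_window(volume, window_low, window_high)
  remove_external_air(cand, volume, min_component_mL)
}
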