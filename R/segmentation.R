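#' Segmentation parameters
#'
#' Two-threshold scheme in Hounsfield units: bone is taken between
#' `bone_threshold` and `metal_threshold`, metal (screws) at or above
#' `metal_threshold`, so screw voxels never enter the bone mask. The
#' defaults (226 HU, a widely used cortical-bone preset, and 2000 HU) are
#' explicit, configurable numbers; every chosen threshold should be echoed
#' into reports.
#'
#' @param bone_threshold Lower bone threshold (HU).
#' @param metal_threshold Metal threshold (HU); must exceed `bone_threshold`.
#' @param min_component_voxels Connected components smaller than this are
#'   discarded (>= 1).
#' @param closing_radius Morphological closing ball radius (mm).
#' @param marching_level Iso-level in (0,1) for surface extraction from a
#'   binary mask; 0.5 places the surface midway between in/out voxels.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(bone_threshold = 226, metal_threshold = 2000,
                                min_component_voxels = 100,
                                closing_radius = 0.8, marching_level = 0.5) {
  if (metal_threshold <= bone_threshold)
    stop("metal_threshold must exceed bone_threshold", call. = FALSE)
  if (min_component_voxels < 1) stop("min_component_voxels must be >= 1",
                                     call. = FALSE)
  if (marching_level <= 0 || marching_level >= 1)
    stop("marching_level must lie in (0, 1)", call. = FALSE)
  structure(list(bone_threshold = bone_threshold,
                 metal_threshold = metal_threshold,
                 min_component_voxels = min_component_voxels,
                 closing_radius = closing_radius,
                 marching_level = marching_level),
            class = "segmentation_params")
}

#' Segment bone from a CT volume
#'
#' Bone is `bone_threshold <= intensity < metal_threshold`, with a one-voxel
#' dilation of the metal mask additionally subtracted to suppress
#' partial-volume blooming around screws, morphological closing with a ball
#' of `closing_radius`, and removal of components below
#' `min_component_voxels`. Deterministic, and disjoint from
#' [segment_metal()] by construction.
#'
#' @param volume A [ct_volume()].
#' @param params [segmentation_params()].
#' @return A [binary_mask()].
#' @export
segment_bone <- function(volume, params = segmentation_params()) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$data)
  mask <- volume$data >= params$bone_threshold &
    volume$data < params$metal_threshold
  metal <- volume$data >= params$metal_threshold
  if (any(metal)) {
    dil <- cpp_ball_morph(metal, as.integer(d), volume$spacing,
                          max(volume$spacing) * 1.01, 1L)
    mask <- mask & !dil
  }
  raw <- array(mask, d)   # pre-closing mask: the volumetric reference
  if (params$closing_radius > 0) {
    mask <- cpp_ball_morph(mask, as.integer(d), volume$spacing,
                           params$closing_radius, 1L)
    mask <- cpp_ball_morph(mask, as.integer(d), volume$spacing,
                           params$closing_radius, 0L)
    if (any(metal)) mask <- mask & !dil
  }
  mask <- array(mask, d)
  if (!any(mask))
    stop("empty bone segmentation (thresholds ", params$bone_threshold,
         "..", params$metal_threshold, " HU)", call. = FALSE)
  lab <- cpp_label3d(mask, as.integer(d))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= params$min_component_voxels)
  if (length(keep) == 0)
    stop("empty bone segmentation after component filtering (thresholds ",
         params$bone_threshold, "..", params$metal_threshold, " HU)",
         call. = FALSE)
  mask <- array(lab %in% keep, d)
  out <- binary_mask(mask, volume$spacing, volume$origin, volume$direction)
  # closing stabilizes topology for surfaces and connectivity; volumes are
  # counted on the raw thresholded voxels to avoid closing-induced bias
  attr(out, "raw") <- raw
  out
}

#' Segment metal (screws) from a CT volume
#'
#' Metal is `intensity >= metal_threshold`, split into connected components
#' with components below `min_component_voxels` dropped. Two components are
#' expected in a standard follow-up scan (two screws); zero components
#' (e.g. a pre-operative scan) and more than two both warn rather than
#' fail. Equal-size components are all kept; the screws are never reduced
#' to "the largest".
#'
#' @param volume A [ct_volume()].
#' @param params [segmentation_params()].
#' @return A [binary_mask()] with attribute `n_components`.
#' @export
segment_metal <- function(volume, params = segmentation_params()) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$data)
  mask <- array(volume$data >= params$metal_threshold, d)
  if (!any(mask)) {
    warning("no metal voxels at threshold ", params$metal_threshold,
            " HU (screws may be absent, e.g. a pre-operative scan)",
            call. = FALSE)
    out <- binary_mask(mask, volume$spacing, volume$origin, volume$direction)
    attr(out, "n_components") <- 0L
    return(out)
  }
  lab <- cpp_label3d(mask, as.integer(d))
  sizes <- tabulate(lab[lab > 0])
  # never let the size floor wipe out genuine screws on coarse grids
  floor_vox <- min(params$min_component_voxels, ceiling(max(sizes) / 4))
  keep <- which(sizes >= floor_vox)
  mask <- array(lab %in% keep, d)
  if (length(keep) > 2)
    warning("expected 2 screw components, found ", length(keep),
            " (sizes: ", paste(sizes[keep], collapse = ", "), " voxels)",
            call. = FALSE)
  out <- binary_mask(mask, volume$spacing, volume$origin, volume$direction)
  attr(out, "n_components") <- length(keep)
  out
}

#' Extract a watertight surface from a binary mask
#'
#' Marching tetrahedra at iso-level `marching_level` on the padded mask, in
#' physical millimetres. The enclosed volume tracks the voxel-count volume
#' within a few percent for blobs at least ~10 voxels across. A
#' non-watertight result is attempted to be repaired once by re-extraction
#' on the filled mask, then is a hard error.
#'
#' @param mask A nonempty [binary_mask()].
#' @param params [segmentation_params()].
#' @return A [triangle_mesh()].
#' @export
extract_surface <- function(mask, params = segmentation_params()) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop("cannot extract a surface from an empty mask",
                            call. = FALSE)
  d <- dim(mask$data)
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(mask$data)
  origin <- mask$origin - as.vector(mask$direction %*% mask$spacing)
  res <- cpp_marching_tets(as.numeric(padded), as.integer(d + 2L),
                           mask$spacing, origin, mask$direction,
                           params$marching_level)
  mesh <- triangle_mesh(res$vertices, res$faces + 1L)
  a <- cpp_edge_audit(mesh$faces - 1L, nrow(mesh$vertices))
  if (a$boundary_edges > 0 || a$nonmanifold_edges > 0)
    stop("surface extraction produced a non-watertight mesh (",
         a$boundary_edges, " boundary edges)", call. = FALSE)
  mesh
}
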