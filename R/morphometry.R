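#' Osteotomy plane
#'
#' The plane of the coracoid osteotomy, given by a point on the plane and a
#' unit normal pointing towards the retained scapula side. The graft is the
#' material on the negative-normal side.
#'
#' @param point Length-3 point on the plane (mm).
#' @param normal Length-3 normal; normalized internally.
#' @return An object of class `osteotomy_plane`.
#' @export
osteotomy_plane <- function(point, normal) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  l <- sqrt(sum(normal^2))
  if (!is.finite(l) || l == 0) stop("plane normal must be nonzero", call. = FALSE)
  structure(list(point = point, normal = normal / l),
            class = "osteotomy_plane")
}

#' Fit an osteotomy plane to marked landmarks
#'
#' Least-squares plane through three or more user-marked points (the
#' osteotomy site is marked manually on the pre-operative scan); the normal
#' is oriented with `orient_towards` (a point on the retained scapula side),
#' when given.
#'
#' @param points N x 3 matrix of landmark coordinates (N >= 3).
#' @param orient_towards Optional point on the retained-scapula side.
#' @return An [osteotomy_plane()].
#' @export
fit_plane <- function(points, orient_towards = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 3) stop("need at least 3 landmarks", call. = FALSE)
  ctr <- colMeans(points)
  e <- eigen(crossprod(sweep(points, 2, ctr)), symmetric = TRUE)
  n <- e$vectors[, 3]
  if (!is.null(orient_towards) && sum((orient_towards - ctr) * n) < 0) n <- -n
  osteotomy_plane(ctr, n)
}

#' Transform an osteotomy plane by a rigid transform
#' @param plane An [osteotomy_plane()].
#' @param transform A [rigid_transform()].
#' @return The transformed [osteotomy_plane()].
#' @export
transform_plane <- function(plane, transform) {
  osteotomy_plane(as.vector(transform$rotation %*% plane$point) +
                    transform$translation,
                  as.vector(transform$rotation %*% plane$normal))
}

#' Virtual osteotomy: cut a watertight mesh with a plane
#'
#' Both outputs are watertight (the cut faces are capped with a planar lid
#' triangulated identically on both sides), so
#' `volume(graft) + volume(remainder) == volume(mesh)` within 1e-6 relative.
#' The graft is the material on the negative-normal side. If the cut leaves
#' more than one graft-side component, the component containing
#' `tip_landmark` (or the largest, if none is given) is kept with a message.
#'
#' @param mesh A watertight [triangle_mesh()].
#' @param plane An [osteotomy_plane()].
#' @param tip_landmark Optional point (mm) marking the coracoid tip, used to
#'   select among multiple graft-side components.
#' @return List with `graft` and `remainder` [triangle_mesh()]es.
#' @export
cut_mesh <- function(mesh, plane, tip_landmark = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(plane, "osteotomy_plane"))
  if (!is_watertight(mesh))
    stop("cut_mesh requires a watertight mesh", call. = FALSE)
  res <- cpp_plane_cut(mesh$vertices, mesh$faces - 1L, plane$point, plane$normal)
  graft <- .cut_piece(res$vertices, res$faces_neg, mesh$provenance)
  remainder <- .cut_piece(res$vertices, res$faces_pos, mesh$provenance)
  if (is_empty_mesh(graft) || is_empty_mesh(remainder)) {
    warning("osteotomy plane does not intersect the mesh", call. = FALSE)
    return(list(graft = .empty_mesh("graft"), remainder = mesh))
  }
  comps <- mesh_components(graft)
  if (length(comps) > 1) {
    pick <- 1L
    if (!is.null(tip_landmark)) {
      dmin <- vapply(comps, function(m)
        min(sqrt(rowSums(sweep(m$vertices, 2, tip_landmark)^2))), numeric(1))
      pick <- which.min(dmin)
    }
    message("cut produced ", length(comps), " graft-side components; keeping ",
            if (is.null(tip_landmark)) "the largest" else "the one at the tip landmark",
        " (volumes: ",
        paste(signif(vapply(comps, mesh_volume, numeric(1)), 4), collapse = ", "),
        " mm^3)")
    graft <- comps[[pick]]
  }
  graft$provenance <- "graft"
  list(graft = graft, remainder = remainder)
}

.cut_piece <- function(V, F0, provenance) {
  if (nrow(F0) == 0) return(.empty_mesh(provenance))
  used <- sort(unique(as.vector(F0)))
  remap <- integer(nrow(V))
  remap[used + 1L] <- seq_along(used)
  triangle_mesh(V[used + 1L, , drop = FALSE],
                matrix(remap[F0 + 1L], ncol = 3), provenance = provenance)
}

#' Place the modeled graft on the glenoid
#'
#' Rigidly aligns the virtually osteotomised graft to the remodelled
#' follow-up graft, using the inferior third along the superior-inferior
#' axis as the registration region: the inferior graft is known to be
#' resorption-spared, so it anchors the timepoint-zero pose even under
#' marked superior osteolysis. Falls back to whole-graft alignment with a
#' warning when the inferior reference surface is below `min_area_mm2`.
#'
#' @param graft The modeled graft from [cut_mesh()].
#' @param preop_scapula The registered pre-op scapula (the placed graft
#'   united with it models the immediate post-operative geometry); not used
#'   in the fit itself.
#' @param followup_graft_reference The isolated follow-up graft mesh.
#' @param superior_axis Unit vector of the superior direction in the
#'   follow-up frame.
#' @param inferior_fraction Fraction of the axis range treated as inferior.
#' @param min_area_mm2 Minimum inferior reference surface area.
#' @return The transformed graft (`triangle_mesh`) with attributes
#'   `transform` (the placement [rigid_transform()]) and `rms` (mm).
#' @export
place_graft <- function(graft, preop_scapula = NULL, followup_graft_reference,
                        superior_axis = c(0, 0, 1), inferior_fraction = 1 / 3,
                        min_area_mm2 = 50) {
  stopifnot(inherits(graft, "triangle_mesh"),
            inherits(followup_graft_reference, "triangle_mesh"))
  if (is_empty_mesh(followup_graft_reference))
    stop("follow-up graft reference is empty", call. = FALSE)
  ax <- superior_axis / sqrt(sum(superior_axis^2))
  ref <- followup_graft_reference
  proj_ref <- as.vector(ref$vertices %*% ax)
  ref_range <- diff(range(proj_ref))
  # at least ~6 mm of anchoring band, or rotation is ill-constrained when
  # osteolysis has consumed most of the graft
  band_h <- max(ref_range * inferior_fraction, min(ref_range, 6))
  thr <- min(proj_ref) + band_h
  fc <- (proj_ref[ref$faces[, 1]] + proj_ref[ref$faces[, 2]] +
           proj_ref[ref$faces[, 3]]) / 3
  sub_faces <- which(fc <= thr)
  use_whole <- FALSE
  if (length(sub_faces) == 0 || .faces_area(ref, sub_faces) < min_area_mm2) {
    warning("inferior reference surface below ", min_area_mm2,
            " mm^2; falling back to whole-graft alignment", call. = FALSE)
    use_whole <- TRUE
  }
  fixed_region <- if (use_whole) ref else {
    f <- ref$faces[sub_faces, , drop = FALSE]
    structure(list(vertices = ref$vertices, faces = f, provenance = "graft"),
              class = "triangle_mesh")
  }

  # inferior slab of the reference anchors the translation: osteolysis may
  # have consumed the superior graft, so centroid matching is biased, but
  # the inferior end is resorption-spared by assumption
  ref_bot_thr <- min(proj_ref) + diff(range(proj_ref)) * 0.2
  ref_bot_ctr <- colMeans(ref$vertices[proj_ref <= ref_bot_thr, , drop = FALSE])
  bottom_align <- function(R) {
    P <- graft$vertices %*% t(R)
    pj <- as.vector(P %*% ax)
    bot <- pj <= min(pj) + diff(range(pj)) * 0.2
    bc <- colMeans(P[bot, , drop = FALSE])
    # match the inferior-slab centroid in-plane and the inferior extreme
    # along the superior axis
    t_perp <- (ref_bot_ctr - bc) - sum((ref_bot_ctr - bc) * ax) * ax
    t_ax <- (min(proj_ref) - min(pj)) * ax
    rigid_transform(R, t_perp + t_ax)
  }
  Rinit <- initialize_alignment(graft, ref)$rotation
  inits <- list(bottom_align(Rinit))
  # the near-conical graft is almost symmetric end-for-end; try the flip
  Rf <- .rotation_pi_about(.any_perpendicular(ax))
  inits[[2]] <- bottom_align(Rf %*% Rinit)

  fit_one <- function(tf0) {
    Pg <- transform_points(graft$vertices, tf0)
    sel <- if (use_whole) seq_len(nrow(Pg)) else {
      pj <- as.vector(Pg %*% ax)
      which(pj <= thr)          # the reference's inferior band
    }
    if (length(sel) < 10) sel <- seq_len(nrow(Pg))
    grid <- cpp_trigrid_new(fixed_region$vertices, fixed_region$faces - 1L)
    tf <- tf0
    P0 <- graft$vertices[sel, , drop = FALSE]
    prev <- Inf; rms <- Inf
    for (it in 1:60) {
      P <- transform_points(P0, tf)
      cc <- cpp_trigrid_closest(grid, P)
      keep <- cc$dist <= quantile(cc$dist, 0.9, names = FALSE)
      rms <- sqrt(mean(cc$dist[keep]^2))
      if (abs(prev - rms) < 1e-5) break
      prev <- rms
      tf <- .fit_rigid(P0[keep, , drop = FALSE], cc$points[keep, , drop = FALSE])
    }
    list(tf = tf, rms = rms)
  }

  fits <- lapply(inits, fit_one)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rms"))]]
  out <- apply_transform(graft, best$tf)
  out$provenance <- "modeled-postop"
  attr(out, "transform") <- best$tf
  attr(out, "rms") <- best$rms
  out
}

.faces_area <- function(mesh, face_idx) {
  f <- mesh$faces[face_idx, , drop = FALSE]
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  c <- mesh$vertices[f[, 3], , drop = FALSE]
  u <- b - a; v <- c - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

.any_perpendicular <- function(a) {
  p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- p - sum(p * a) * a
  v / sqrt(sum(v^2))
}

.rotation_pi_about <- function(v) {
  K <- .skew(v / sqrt(sum(v^2)))
  diag(3) + 2 * K %*% K
}

#' Isolate the remodelled follow-up graft
#'
#' Removes from the follow-up bone mask every voxel inside the registered
#' pre-operative scapula (native bone), every voxel within one voxel of the
#' metal mask, and the fitted screw geometry (screw heads must not
#' contribute to the graft volume). The remaining voxels are restricted to
#' the largest connected component lying within `adjacency_mm` of the
#' registered scapula surface (the graft sits on the anterior glenoid rim).
#'
#' @param followup_bone A [binary_mask()] of follow-up bone.
#' @param preop_scapula_registered The pre-op scapula [triangle_mesh()]
#'   already mapped into the follow-up frame.
#' @param screws Optional [binary_mask()] of metal.
#' @param screw_models Optional list of [screw_model()]s whose geometry
#'   (plus `screw_margin_mm`) is carved out.
#' @param adjacency_mm Maximum distance from the graft component to the
#'   registered scapula surface.
#' @param screw_margin_mm Margin added around fitted screw geometry.
#' @param params [segmentation_params()] (for the minimum component size and
#'   marching level of the extracted surface).
#' @return A [triangle_mesh()] of the isolated graft with attributes
#'   `voxel_volume_mm3` (voxel-count volume), `mask` (the graft
#'   [binary_mask()]) and `grade3_candidate` (TRUE when nothing remains
#'   near the glenoid; then the mesh is empty).
#' @export
isolate_followup_graft <- function(followup_bone, preop_scapula_registered,
                                   screws = NULL, screw_models = NULL,
                                   adjacency_mm = 2, screw_margin_mm = 0,
                                   params = segmentation_params()) {
  stopifnot(inherits(followup_bone, "binary_mask"),
            inherits(preop_scapula_registered, "triangle_mesh"))
  mask <- followup_bone$data
  d <- dim(mask)
  # native bone: voxels inside the registered pre-op scapula
  inside <- .voxelize_mesh(preop_scapula_registered, followup_bone)
  mask <- mask & !inside
  if (!is.null(screws)) {
    dil <- array(cpp_ball_morph(screws$data, as.integer(d),
                                followup_bone$spacing,
                                max(followup_bone$spacing) * 1.01, 1L), d)
    mask <- mask & !dil
  }
  if (length(screw_models)) {
    ctr <- voxel_centers(followup_bone, which = mask)
    keep_idx <- which(mask)
    inside_screw <- rep(FALSE, length(keep_idx))
    for (sm in screw_models)
      if (!is.null(sm))
        inside_screw <- inside_screw | .in_screw(ctr, sm, screw_margin_mm)
    mask[keep_idx[inside_screw]] <- FALSE
  }
  vol <- voxel_volume(followup_bone)
  empty_result <- function() {
    out <- .empty_mesh("graft")
    attr(out, "voxel_volume_mm3") <- 0
    attr(out, "mask") <- binary_mask(array(FALSE, d), followup_bone$spacing,
                                     followup_bone$origin, followup_bone$direction)
    attr(out, "grade3_candidate") <- TRUE
    out
  }
  if (!any(mask)) return(empty_result())
  lab <- array(cpp_label3d(mask, as.integer(d)), d)
  ncomp <- attr(cpp_label3d(mask, as.integer(d)), "n_components") %||% max(lab)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  cand <- which(sizes >= params$min_component_voxels)
  if (length(cand) == 0) return(empty_result())
  sg <- cpp_trigrid_new(preop_scapula_registered$vertices,
                        preop_scapula_registered$faces - 1L)
  near <- logical(length(cand))
  for (i in seq_along(cand)) {
    idx <- which(lab == cand[i])
    if (length(idx) > 400) idx <- idx[unique(round(seq(1, length(idx), length.out = 400)))]
    ctr <- voxel_centers(followup_bone, which = idx)
    near[i] <- min(cpp_trigrid_closest(sg, ctr)$dist) <= adjacency_mm
  }
  cand <- cand[near]
  if (length(cand) == 0) return(empty_result())
  # a residual graft is a solid body; one-voxel-thick sheets are
  # registration slivers on the native bone surface, not graft
  solid <- vapply(cand, function(k) {
    cm <- lab == k
    max(cpp_peel_layers(cm, as.integer(d))) >= 2
  }, logical(1))
  cand <- cand[solid]
  if (length(cand) == 0) return(empty_result())
  pick <- cand[which.max(sizes[cand])]
  gmask <- lab == pick
  bm <- binary_mask(gmask, followup_bone$spacing, followup_bone$origin,
                    followup_bone$direction)
  out <- extract_surface(bm, params)
  out$provenance <- "graft"
  # volume from raw thresholded voxels when available (closing is kept for
  # topology only, not volumetry)
  raw <- attr(followup_bone, "raw")
  nvox <- if (is.null(raw)) sum(gmask) else sum(gmask & raw)
  attr(out, "voxel_volume_mm3") <- nvox * vol
  attr(out, "mask") <- bm
  attr(out, "grade3_candidate") <- FALSE
  out
}

# voxelize a mesh onto the grid of a mask/volume (identity-direction grids)
.voxelize_mesh <- function(mesh, grid_ref) {
  d <- dim(grid_ref$data)
  if (is_empty_mesh(mesh)) return(array(FALSE, d))
  if (max(abs(grid_ref$direction - diag(3))) > 1e-9)
    stop("voxelization requires an axis-aligned grid", call. = FALSE)
  g <- cpp_trigrid_new(mesh$vertices, mesh$faces - 1L)
  array(cpp_trigrid_voxelize(g, as.integer(d), grid_ref$spacing,
                             grid_ref$origin), d)
}

.in_screw <- function(points, sm, margin = 0) {
  rel <- sweep(points, 2, sm$head_center)
  t <- as.vector(rel %*% sm$axis)                 # axis points head -> tip
  rad2 <- rowSums(rel^2) - t^2
  hl <- sm$head_length %||% 3
  in_head <- t >= -hl / 2 - margin & t <= hl / 2 + margin &
    rad2 <= (sm$head_radius + margin)^2
  in_shaft <- t > hl / 2 - margin & t <= sm$length + margin &
    rad2 <= (sm$shaft_radius + margin)^2
  in_head | in_shaft
}

#' Resorption metrics from timepoint-zero and follow-up volumes
#'
#' Positive percentages denote loss; negative values are allowed and mean
#' apparent graft growth. Reports are printed in both sign conventions.
#'
#' @param volume_t0 Modeled timepoint-zero graft volume (mm^3, > 0).
#' @param volume_followup Follow-up graft volume (mm^3, >= 0).
#' @param graft_t0,graft_followup Optional meshes stored alongside.
#' @return An object of class `graft_pair` with `volume_t0`,
#'   `volume_followup`, `resorption_mm3` and `resorption_pct`.
#' @export
compute_resorption <- function(volume_t0, volume_followup,
                               graft_t0 = NULL, graft_followup = NULL) {
  if (!is.finite(volume_t0) || volume_t0 < 0 || !is.finite(volume_followup) ||
      volume_followup < 0)
    stop("volumes must be finite and non-negative", call. = FALSE)
  if (volume_t0 == 0)
    stop("resorption percentage undefined: timepoint-zero volume is 0",
         call. = FALSE)
  structure(list(graft_t0 = graft_t0, graft_followup = graft_followup,
                 volume_t0 = volume_t0, volume_followup = volume_followup,
                 resorption_mm3 = volume_t0 - volume_followup,
                 resorption_pct = 100 * (volume_t0 - volume_followup) / volume_t0),
            class = "graft_pair")
}

#' @export
print.graft_pair <- function(x, ...) {
  cat(sprintf(paste0("graft_pair: V0 = %.1f mm^3, Vf = %.1f mm^3\n",
                     "  resorption %.1f mm^3 (loss-positive %.1f%%; ",
                     "signed convention %.1f%%)\n"),
              x$volume_t0, x$volume_followup, x$resorption_mm3,
              x$resorption_pct, -x$resorption_pct))
  invisible(x)
}

#' Regional resorption map
#'
#' Voxelizes the timepoint-zero graft at `resolution` mm, splits it into
#' half-spaces at the midplanes of its bounding box along the three
#' anatomical axes, and reports the percentage of timepoint-zero material in
#' each half that is no longer inside the follow-up graft. This is the 3D
#' localization capability (superior/inferior, medial/lateral,
#' superficial/deep) that 2D methods cannot provide.
#'
#' @param graft_t0 Placed timepoint-zero graft mesh.
#' @param graft_followup Follow-up graft mesh (same frame).
#' @param axis_frame 3x3 matrix whose rows are unit vectors: superior,
#'   medial, superficial.
#' @param resolution Voxel size for the comparison (mm).
#' @return Named numeric vector of percentages for the six regions.
#' @export
regional_resorption <- function(graft_t0, graft_followup,
                                axis_frame = diag(3), resolution = 0.5) {
  stopifnot(inherits(graft_t0, "triangle_mesh"))
  if (is_empty_mesh(graft_t0)) stop("empty timepoint-zero graft", call. = FALSE)
  axis_frame <- matrix(as.numeric(axis_frame), 3, 3)
  axis_frame <- axis_frame / sqrt(rowSums(axis_frame^2))
  lo <- apply(graft_t0$vertices, 2, min) - 2 * resolution
  hi <- apply(graft_t0$vertices, 2, max) + 2 * resolution
  d <- as.integer(ceiling((hi - lo) / resolution)) + 1L
  ref <- binary_mask(array(FALSE, d), rep(resolution, 3), lo)
  t0_in <- .voxelize_mesh(graft_t0, ref)
  idx <- which(t0_in)
  if (length(idx) == 0) stop("timepoint-zero graft voxelized to nothing",
                             call. = FALSE)
  ctr <- voxel_centers(ref, which = idx)
  lost <- if (is.null(graft_followup) || is_empty_mesh(graft_followup)) {
    rep(TRUE, length(idx))
  } else {
    g <- cpp_trigrid_new(graft_followup$vertices, graft_followup$faces - 1L)
    !cpp_trigrid_inside(g, ctr)
  }
  region_names <- rbind(c("superior", "inferior"), c("medial", "lateral"),
                        c("superficial", "deep"))
  out <- numeric(0)
  for (a in 1:3) {
    pj <- as.vector(ctr %*% axis_frame[a, ])
    mid <- (min(pj) + max(pj)) / 2
    for (side in 1:2) {
      inreg <- if (side == 1) pj > mid else pj <= mid
      pct <- if (any(inreg)) 100 * sum(lost & inreg) / sum(inreg) else NA_real_
      out[region_names[a, side]] <- pct
    }
  }
  out
}

#' Screw model
#'
#' Idealized screw geometry: a cylindrical head and shaft along a common
#' axis. `axis` points from the head towards the tip.
#'
#' @param axis Unit axis vector (head to tip).
#' @param head_center Center of the head cylinder (mm).
#' @param head_radius,shaft_radius Radii (mm); `head_radius >= shaft_radius > 0`.
#' @param length Distance from the head center to the tip (mm).
#' @param head_length Axial length of the head (mm).
#' @param mesh Optional mesh of the segmented screw.
#' @return An object of class `screw_model`.
#' @export
screw_model <- function(axis, head_center, head_radius, shaft_radius, length,
                        head_length = 3, mesh = NULL) {
  axis <- as.numeric(axis); axis <- axis / sqrt(sum(axis^2))
  if (!(head_radius >= shaft_radius && shaft_radius > 0))
    stop("need head_radius >= shaft_radius > 0", call. = FALSE)
  if (length <= 0) stop("screw length must be > 0", call. = FALSE)
  structure(list(axis = axis, head_center = as.numeric(head_center),
                 head_radius = head_radius, shaft_radius = shaft_radius,
                 length = length, head_length = head_length, mesh = mesh),
            class = "screw_model")
}

#' Fit screw models to a metal mask
#'
#' Each connected metal component is modeled as an axis (principal direction
#' of its voxels) with per-station radius estimates; the head is the end
#' whose radius exceeds 1.25x the median shaft radius. Components that
#' cannot be fit yield `NULL` (ungradable).
#'
#' @param metal A [binary_mask()] from [segment_metal()].
#' @param min_voxels Minimum component size to attempt a fit.
#' @return List of [screw_model()]s (possibly empty).
#' @export
fit_screw_models <- function(metal, min_voxels = 50) {
  stopifnot(inherits(metal, "binary_mask"))
  d <- dim(metal$data)
  lab <- cpp_label3d(metal$data, as.integer(d))
  n <- attr(lab, "n_components")
  lab <- array(lab, d)
  out <- list()
  for (k in seq_len(n)) {
    idx <- which(lab == k)
    if (length(idx) < min_voxels) next
    ctr <- voxel_centers(metal, which = idx)
    m <- colMeans(ctr)
    e <- eigen(crossprod(sweep(ctr, 2, m)) / nrow(ctr), symmetric = TRUE)
    u <- e$vectors[, 1]
    profile <- function(t) {
      stations <- seq(min(t), max(t), by = 1)
      prof <- vapply(stations, function(s) {
        sel <- t >= s - 0.75 & t <= s + 0.75
        if (sum(sel) < 3) return(NA_real_)
        quantile(r[sel], 0.95, names = FALSE)
      }, numeric(1))
      list(stations = stations, prof = prof)
    }
    t <- as.vector(sweep(ctr, 2, m) %*% u)
    r <- sqrt(pmax(0, rowSums(sweep(ctr, 2, m)^2) - t^2))
    pr <- profile(t)
    ok <- which(!is.na(pr$prof))
    if (length(ok) < 4) { out[length(out) + 1] <- list(NULL); next }
    shaft_r <- median(pr$prof[ok])
    is_head <- pr$prof > 1.25 * shaft_r & !is.na(pr$prof)
    # orient axis from the head end towards the tip
    if (any(is_head) && mean(pr$stations[is_head]) > mean(pr$stations[ok])) {
      u <- -u
      t <- -t
      pr <- profile(t)
      is_head <- pr$prof > 1.25 * shaft_r & !is.na(pr$prof)
    }
    head_sel <- if (any(is_head)) t <= max(pr$stations[is_head]) + 0.75
                else t <= min(t) + 3
    hc <- colMeans(ctr[head_sel, , drop = FALSE])
    hr <- if (any(is_head)) max(pr$prof[is_head], na.rm = TRUE) else shaft_r
    hl <- if (any(is_head)) max(1.5, diff(range(pr$stations[is_head])) + 1.5)
          else 3
    shaft_r_est <- if (sum(!head_sel) > 10)
      quantile(r[!head_sel], 0.95, names = FALSE) else shaft_r
    len <- max(t) - as.vector((hc - m) %*% u)
    out[[length(out) + 1]] <- screw_model(
      axis = u, head_center = hc, head_radius = max(hr, shaft_r_est + 1e-6),
      shaft_radius = shaft_r_est, length = max(len, 1), head_length = hl)
  }
  out
}

#' Geometric Zhu grade
#'
#' A geometric surrogate of the radiologist's axial-CT call: points are
#' sampled on the screw-head surface and on the extra-osseous shaft, and
#' their coverage by the follow-up graft decides the grade. Grade 0: the
#' head remains buried (>= `coverage` of head samples inside the graft);
#' grade 1: only the head is exposed (shaft still covered); grade 2: shaft
#' partly exposed but graft material remains within `proximity_mm` of the
#' shaft; grade 3: no graft remains near the screw (or the graft is empty).
#' A patient's overall grade is the maximum over the two screws.
#'
#' @param graft_followup Follow-up graft [triangle_mesh()] (may be empty).
#' @param screws List of [screw_model()]s (typically two); `NULL` entries
#'   are ungradable.
#' @param graft_t0 Optional timepoint-zero graft mesh used to clip the shaft
#'   to its extra-osseous, graft-covered course.
#' @param coverage Fraction of samples that must be inside to count as
#'   covered.
#' @param proximity_mm Distance defining "graft remains on the glenoid neck".
#' @param cover_tolerance_mm A sample point within this distance of the
#'   graft surface counts as covered: segmented grafts carry a one-voxel
#'   clearance around metal, so points on the screw surface are never
#'   strictly inside.
#' @return An object of class `zhu_grade`: list with `per_screw` (integer
#'   vector, `NA` = ungradable) and `overall`.
#' @export
zhu_grade <- function(graft_followup, screws, graft_t0 = NULL,
                      coverage = 0.95, proximity_mm = 2,
                      cover_tolerance_mm = 1.5) {
  if (inherits(screws, "screw_model")) screws <- list(screws)
  per <- vapply(screws, function(sm) {
    if (is.null(sm)) return(NA_integer_)
    .grade_one_screw(graft_followup, sm, graft_t0, coverage, proximity_mm,
                     cover_tolerance_mm)
  }, integer(1))
  structure(list(per_screw = per,
                 overall = if (all(is.na(per))) NA_integer_
                           else max(per, na.rm = TRUE)),
            class = "zhu_grade")
}

#' @export
print.zhu_grade <- function(x, ...) {
  cat("zhu_grade: per screw [", paste(x$per_screw, collapse = ", "),
      "], overall", x$overall, "\n")
  invisible(x)
}

.grade_one_screw <- function(graft, sm, graft_t0, coverage, proximity,
                             cover_tol = 1.5) {
  empty <- is.null(graft) || is_empty_mesh(graft)
  hs <- .screw_head_samples(sm)
  ss <- .screw_shaft_samples(sm)
  if (!is.null(graft_t0) && !is_empty_mesh(graft_t0)) {
    gt <- cpp_trigrid_new(graft_t0$vertices, graft_t0$faces - 1L)
    keep <- cpp_trigrid_inside(gt, ss)
    if (sum(keep) >= 10) ss <- ss[keep, , drop = FALSE]
    else {
      t <- as.vector(sweep(ss, 2, sm$head_center) %*% sm$axis)
      ss <- ss[t <= quantile(t, 0.5), , drop = FALSE]
    }
  }
  if (empty) return(3L)
  g <- cpp_trigrid_new(graft$vertices, graft$faces - 1L)
  covered <- function(p) {
    inside <- cpp_trigrid_inside(g, p)
    if (all(inside)) return(inside)
    inside | cpp_trigrid_closest(g, p)$dist <= cover_tol
  }
  if (mean(covered(hs)) >= coverage) return(0L)
  if (mean(covered(ss)) >= coverage) return(1L)
  near <- min(cpp_trigrid_closest(g, ss)$dist)
  if (near <= proximity) return(2L)
  3L
}

# deterministic samples on the head surface: outer disc, rim, inner annulus
.screw_head_samples <- function(sm) {
  b1 <- .any_perpendicular(sm$axis)
  b2 <- c(sm$axis[2] * b1[3] - sm$axis[3] * b1[2],
          sm$axis[3] * b1[1] - sm$axis[1] * b1[3],
          sm$axis[1] * b1[2] - sm$axis[2] * b1[1])
  hl <- sm$head_length %||% 3
  golden <- pi * (3 - sqrt(5))
  disc <- function(center, r, n = 60) {
    i <- seq_len(n)
    rad <- r * sqrt(i / n)
    th <- i * golden
    t(vapply(seq_len(n), function(j)
      center + rad[j] * (cos(th[j]) * b1 + sin(th[j]) * b2), numeric(3)))
  }
  ring <- function(z, r, n = 36) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    ctr <- sm$head_center + z * sm$axis
    t(vapply(th, function(a) ctr + r * (cos(a) * b1 + sin(a) * b2), numeric(3)))
  }
  outer_ctr <- sm$head_center - (hl / 2) * sm$axis
  rbind(disc(outer_ctr, sm$head_radius * 0.95),
        ring(-hl / 2, sm$head_radius), ring(0, sm$head_radius),
        ring(hl / 2, sm$head_radius))
}

# samples on the shaft surface from the head's inner face towards the tip
.screw_shaft_samples <- function(sm, n_axial = 40, n_phi = 12) {
  hl <- sm$head_length %||% 3
  b1 <- .any_perpendicular(sm$axis)
  b2 <- c(sm$axis[2] * b1[3] - sm$axis[3] * b1[2],
          sm$axis[3] * b1[1] - sm$axis[1] * b1[3],
          sm$axis[1] * b1[2] - sm$axis[2] * b1[1])
  ts <- seq(hl / 2 + 0.25, sm$length, length.out = n_axial)
  th <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  out <- matrix(0, n_axial * n_phi, 3)
  r <- sm$shaft_radius
  k <- 1
  for (t in ts) for (a in th) {
    out[k, ] <- sm$head_center + t * sm$axis + r * (cos(a) * b1 + sin(a) * b2)
    k <- k + 1
  }
  out
}
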