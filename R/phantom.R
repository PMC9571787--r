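#' Phantom specification
#'
#' Parameters of a synthetic pre-/follow-up CT pair with exact ground truth.
#' The geometry is deliberately schematic — an ellipsoidal scapula body with
#' a tapering cylindrical coracoid, a plane osteotomy, a graft frustum placed
#' tangent to the anterior glenoid, and two cylindrical screws — because
#' validation needs exactly known volumes, not anatomical realism. Axes of
#' the scene frame: +x anterior (deep to superficial), +y medial, +z
#' superior. The follow-up scan is the post-osteotomy scene moved by a rigid
#' inter-scan transform, with graded osteolysis applied to the graft and
#' Gaussian noise added.
#'
#' @param voxel_spacing Isotropic voxel size (mm); the study's slice
#'   thickness, 0.75 mm, by default.
#' @param bone_hu,metal_hu,background_hu Intensities (HU).
#' @param noise_sigma Gaussian noise SD (HU).
#' @param body_semiaxes Ellipsoid semi-axes (mm).
#' @param coracoid_base,coracoid_dir Base point and direction of the
#'   coracoid tube.
#' @param coracoid_length Total coracoid length (mm).
#' @param coracoid_radius_base Radius at the base (mm).
#' @param coracoid_taper Radius decrease per mm along the tube.
#' @param osteotomy_offset Distance from the base to the osteotomy plane (mm).
#' @param graft_base,graft_axis Base point and axis of the placed graft.
#' @param screws List of two screw descriptions (`head_outer`, `axis`,
#'   `head_radius`, `head_length`, `shaft_radius`, `total_length`).
#' @param interscan_rotation_deg,interscan_axis,interscan_translation The
#'   rigid transform between the two acquisitions.
#' @param resorption_fraction Target resorbed fraction of the graft in
#'   `[0, 1]` (realized within one voxel).
#' @param gradient_axis,gradient_weight Direction and strength (0-1) of the
#'   osteolysis gradient; the default superior weighting mirrors where graft
#'   resorption concentrates clinically, and the complementary weight
#'   removes superficial material before deep material.
#' @param margin Padding around the anatomy (mm).
#' @param seed Integer seed for the image noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(voxel_spacing = 0.75,
                         bone_hu = 700, metal_hu = 3000, background_hu = 0,
                         noise_sigma = 20,
                         body_semiaxes = c(18, 12, 26),
                         coracoid_base = c(8, 0, 20),
                         coracoid_dir = c(1, 0, 0.45),
                         coracoid_length = 30,
                         coracoid_radius_base = 7.4,
                         coracoid_taper = 0.05,
                         osteotomy_offset = 8,
                         graft_base = c(24.5, 0, -4),
                         graft_axis = c(0, 0, 1),
                         screws = NULL,
                         interscan_rotation_deg = 7,
                         interscan_axis = c(0.3, 1, 0.2),
                         interscan_translation = c(4, -3, 2),
                         resorption_fraction = 0,
                         gradient_axis = c(0, 0, 1),
                         gradient_weight = 0.7,
                         margin = 6, seed = 1) {
  if (resorption_fraction < 0 || resorption_fraction > 1)
    stop("resorption_fraction must lie in [0, 1]", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (is.null(screws))
    screws <- list(
      list(head_outer = c(29, 0, 2), axis = c(-1, 0, 0), head_radius = 3.2,
           head_length = 3, shaft_radius = 2.25, total_length = 33),
      list(head_outer = c(28, 0, 12), axis = c(-1, 0, 0), head_radius = 3.2,
           head_length = 3, shaft_radius = 2.25, total_length = 33))
  spec <- list(voxel_spacing = voxel_spacing, bone_hu = bone_hu,
               metal_hu = metal_hu, background_hu = background_hu,
               noise_sigma = noise_sigma, body_semiaxes = body_semiaxes,
               coracoid_base = coracoid_base,
               coracoid_dir = coracoid_dir / sqrt(sum(coracoid_dir^2)),
               coracoid_length = coracoid_length,
               coracoid_radius_base = coracoid_radius_base,
               coracoid_taper = coracoid_taper,
               osteotomy_offset = osteotomy_offset,
               graft_base = graft_base,
               graft_axis = graft_axis / sqrt(sum(graft_axis^2)),
               screws = screws,
               interscan_rotation_deg = interscan_rotation_deg,
               interscan_axis = interscan_axis / sqrt(sum(interscan_axis^2)),
               interscan_translation = interscan_translation,
               resorption_fraction = resorption_fraction,
               gradient_axis = gradient_axis / sqrt(sum(gradient_axis^2)),
               gradient_weight = gradient_weight,
               margin = margin, seed = seed)
  class(spec) <- "phantom_spec"
  spec
}

# rotation matrix from axis-angle
.axis_angle <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  K <- .skew(axis / sqrt(sum(axis^2)))
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Inter-scan transform of a phantom spec
#' @param spec A [phantom_spec()].
#' @return The [rigid_transform()] mapping the scene (pre-op) frame into the
#'   follow-up frame.
#' @export
phantom_interscan_transform <- function(spec) {
  rigid_transform(.axis_angle(spec$interscan_axis, spec$interscan_rotation_deg),
                  spec$interscan_translation)
}

#' Ground-truth osteotomy plane of a phantom (pre-op frame)
#' @param spec A [phantom_spec()].
#' @return An [osteotomy_plane()] with the normal towards the retained side.
#' @export
phantom_osteotomy_plane <- function(spec) {
  osteotomy_plane(spec$coracoid_base + spec$osteotomy_offset * spec$coracoid_dir,
                  -spec$coracoid_dir)
}

# ---- analytic solid predicates (scene frame, pts is N x 3) ----

.ph_in_body <- function(pts, spec) {
  rowSums(sweep(pts, 2, spec$body_semiaxes, `/`)^2) <= 1
}

.ph_cor_t <- function(pts, spec) {
  as.vector(sweep(pts, 2, spec$coracoid_base) %*% spec$coracoid_dir)
}

.ph_in_coracoid <- function(pts, spec, t_min = 0, t_max = NULL) {
  t_max <- t_max %||% spec$coracoid_length
  t <- .ph_cor_t(pts, spec)
  rel <- sweep(pts, 2, spec$coracoid_base)
  rad2 <- rowSums(rel^2) - t^2
  r <- spec$coracoid_radius_base - spec$coracoid_taper * t
  t >= t_min & t <= t_max & rad2 <= r^2
}

.ph_in_graft <- function(pts, spec) {
  L <- spec$coracoid_length - spec$osteotomy_offset
  s <- as.vector(sweep(pts, 2, spec$graft_base) %*% spec$graft_axis)
  rel <- sweep(pts, 2, spec$graft_base)
  rad2 <- rowSums(rel^2) - s^2
  r <- spec$coracoid_radius_base - spec$coracoid_taper * (spec$osteotomy_offset + s)
  s >= 0 & s <= L & rad2 <= r^2
}

.ph_in_screws <- function(pts, spec) {
  hit <- rep(FALSE, nrow(pts))
  for (sc in spec$screws) {
    a <- sc$axis / sqrt(sum(sc$axis^2))
    rel <- sweep(pts, 2, sc$head_outer)
    t <- as.vector(rel %*% a)
    rad2 <- rowSums(rel^2) - t^2
    head <- t >= 0 & t <= sc$head_length & rad2 <= sc$head_radius^2
    shaft <- t > sc$head_length & t <= sc$total_length & rad2 <= sc$shaft_radius^2
    hit <- hit | head | shaft
  }
  hit
}

# scene bounding box (pre-op frame) over all primitives
.ph_scene_bbox <- function(spec, include_distal_coracoid = TRUE) {
  pts <- rbind(-spec$body_semiaxes, spec$body_semiaxes)
  rb <- spec$coracoid_radius_base
  tip <- spec$coracoid_base + spec$coracoid_length * spec$coracoid_dir
  pts <- rbind(pts, spec$coracoid_base - rb, spec$coracoid_base + rb)
  if (include_distal_coracoid) pts <- rbind(pts, tip - rb, tip + rb)
  gL <- spec$coracoid_length - spec$osteotomy_offset
  gtop <- spec$graft_base + gL * spec$graft_axis
  pts <- rbind(pts, spec$graft_base - rb, spec$graft_base + rb,
               gtop - rb, gtop + rb)
  for (sc in spec$screws) {
    a <- sc$axis / sqrt(sum(sc$axis^2))
    tip_s <- sc$head_outer + sc$total_length * a
    pts <- rbind(pts, sc$head_outer - sc$head_radius,
                 sc$head_outer + sc$head_radius,
                 tip_s - sc$head_radius, tip_s + sc$head_radius)
  }
  list(lo = apply(pts, 2, min), hi = apply(pts, 2, max))
}

.ph_grid <- function(lo, hi, spacing) {
  d <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  list(dims = d, origin = lo, spacing = rep(spacing, 3))
}

.ph_centers <- function(grid) {
  d <- grid$dims
  ijk <- arrayInd(seq_len(prod(d)), d) - 1L
  sweep(ijk * rep(grid$spacing, each = nrow(ijk)), 2, grid$origin, `+`)
}

#' Generate a synthetic pre-/follow-up CT pair with ground truth
#'
#' Builds the pre-operative scan (body + intact coracoid) and the follow-up
#' scan (coracoid truncated at the osteotomy plane, graft on the anterior
#' glenoid, two screws, graded osteolysis, rigid inter-scan motion, Gaussian
#' noise). All ground-truth volumes are exact voxel counts recorded before
#' noise is added; noise never changes the truth.
#'
#' @param spec A [phantom_spec()].
#' @return List with `preop` and `followup` ([ct_volume()]s) and `truth`, a
#'   list carrying exact graft volumes at both timepoints (mm^3), the
#'   realized resorbed fraction, per-region resorbed fractions, the expected
#'   geometric Zhu grade per screw, the inter-scan transform, the osteotomy
#'   plane (pre-op frame), the anatomical axes in the follow-up frame, the
#'   follow-up-frame screw models, and the graft masks.
#' @export
generate_phantom_pair <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$voxel_spacing

  # ---- pre-operative scan (scene frame) ----
  bb <- .ph_scene_bbox(spec, include_distal_coracoid = TRUE)
  gr_pre <- .ph_grid(bb$lo - spec$margin, bb$hi + spec$margin, sp)
  ctr <- .ph_centers(gr_pre)
  bone_pre <- .ph_in_body(ctr, spec) | .ph_in_coracoid(ctr, spec)
  bone_pre <- array(bone_pre, gr_pre$dims)

  # ---- follow-up scan (scene moved by the inter-scan transform) ----
  tis <- phantom_interscan_transform(spec)
  corners <- as.matrix(expand.grid(x = c(bb$lo[1] - spec$margin, bb$hi[1] + spec$margin),
                                   y = c(bb$lo[2] - spec$margin, bb$hi[2] + spec$margin),
                                   z = c(bb$lo[3] - spec$margin, bb$hi[3] + spec$margin)))
  tc <- transform_points(corners, tis)
  gr_fu <- .ph_grid(apply(tc, 2, min), apply(tc, 2, max), sp)
  yc <- .ph_centers(gr_fu)
  pc <- transform_points(yc, invert_transform(tis))   # back to scene frame
  in_body <- .ph_in_body(pc, spec)
  in_cor <- .ph_in_coracoid(pc, spec, t_max = spec$osteotomy_offset)
  in_scr <- .ph_in_screws(pc, spec)
  in_gr_full <- .ph_in_graft(pc, spec)
  overlap <- sum(in_gr_full & (in_body | in_cor)) / max(sum(in_gr_full), 1)
  if (overlap > 0.2)
    stop("invalid phantom spec: graft pose overlaps the scapula by ",
         round(100 * overlap), "% of the graft volume (> 20%)", call. = FALSE)
  in_gr <- in_gr_full & !in_body & !in_cor & !in_scr
  graft_t0 <- array(in_gr, gr_fu$dims)

  # graded osteolysis: remove the highest-scoring voxels until the target
  # fraction is reached (superior- and surface-weighted, deterministic)
  idx <- which(graft_t0)
  n_remove <- round(spec$resorption_fraction * length(idx))
  removed <- rep(FALSE, length(idx))
  if (n_remove > 0) {
    gax <- as.vector(tis$rotation %*% spec$gradient_axis)
    tproj <- yc[idx, , drop = FALSE] %*% gax
    tnorm <- (tproj - min(tproj)) / max(diff(range(tproj)), 1e-9)
    layer <- cpp_peel_layers(graft_t0, as.integer(gr_fu$dims))[idx]
    dnorm <- (layer - 1) / max(max(layer) - 1, 1)
    score <- spec$gradient_weight * tnorm - (1 - spec$gradient_weight) * dnorm
    ord <- order(score, seq_along(score), decreasing = TRUE)
    removed[ord[seq_len(n_remove)]] <- TRUE
  }
  graft_fu <- graft_t0
  graft_fu[idx[removed]] <- FALSE

  bone_fu <- array(in_body | in_cor, gr_fu$dims) | graft_fu
  metal_fu <- array(in_scr, gr_fu$dims)

  # ---- intensities + seeded noise (truth is fixed before this) ----
  set.seed(spec$seed)
  vol_pre <- spec$background_hu + spec$bone_hu * as.numeric(bone_pre)
  vol_pre <- vol_pre + if (spec$noise_sigma > 0)
    rnorm(length(vol_pre), 0, spec$noise_sigma) else 0
  vol_fu <- spec$background_hu + spec$bone_hu * as.numeric(bone_fu)
  vol_fu[as.vector(metal_fu)] <- spec$metal_hu
  vol_fu <- vol_fu + if (spec$noise_sigma > 0)
    rnorm(length(vol_fu), 0, spec$noise_sigma) else 0

  preop <- ct_volume(array(vol_pre, gr_pre$dims), gr_pre$spacing, gr_pre$origin)
  followup <- ct_volume(array(vol_fu, gr_fu$dims), gr_fu$spacing, gr_fu$origin)

  # ---- ground truth ----
  voxvol <- sp^3
  axes_fu <- t(tis$rotation %*% t(rbind(superior = c(0, 0, 1),
                                        medial = c(0, 1, 0),
                                        superficial = c(1, 0, 0))))
  rownames(axes_fu) <- c("superior", "medial", "superficial")
  per_region <- .ph_regional_truth(yc[idx, , drop = FALSE], removed, axes_fu)
  screws_fu <- lapply(spec$screws, function(sc) {
    a <- sc$axis / sqrt(sum(sc$axis^2))
    hc_scene <- sc$head_outer + (sc$head_length / 2) * a
    screw_model(axis = as.vector(tis$rotation %*% a),
                head_center = transform_points(matrix(hc_scene, 1), tis)[1, ],
                head_radius = sc$head_radius, shaft_radius = sc$shaft_radius,
                length = sc$total_length - sc$head_length / 2,
                head_length = sc$head_length)
  })
  mask_t0 <- binary_mask(graft_t0, gr_fu$spacing, gr_fu$origin)
  mask_fu <- binary_mask(graft_fu, gr_fu$spacing, gr_fu$origin)
  zhu_true <- vapply(screws_fu, function(sm)
    .ph_zhu_truth(sm, mask_fu, mask_t0), integer(1))
  truth <- list(
    graft_volume_t0 = length(idx) * voxvol,
    graft_volume_followup = sum(graft_fu) * voxvol,
    resorbed_fraction = if (length(idx)) n_remove / length(idx) else NA_real_,
    per_region = per_region,
    expected_zhu_per_screw = zhu_true,
    expected_zhu_grade = max(zhu_true),
    osteotomy_plane = phantom_osteotomy_plane(spec),
    interscan_transform = tis,
    axes_followup = axes_fu,
    screws_followup = screws_fu,
    graft_mask_t0 = mask_t0,
    graft_mask_followup = mask_fu,
    seed = spec$seed)
  list(preop = preop, followup = followup, truth = truth)
}

# fraction of timepoint-zero graft voxels removed per half-space
.ph_regional_truth <- function(centers, removed, axes_fu) {
  region_names <- rbind(c("superior", "inferior"), c("medial", "lateral"),
                        c("superficial", "deep"))
  out <- numeric(0)
  for (a in 1:3) {
    pj <- as.vector(centers %*% axes_fu[a, ])
    mid <- (min(pj) + max(pj)) / 2
    for (side in 1:2) {
      inreg <- if (side == 1) pj > mid else pj <= mid
      out[region_names[a, side]] <-
        if (any(inreg)) sum(removed & inreg) / sum(inreg) else NA_real_
    }
  }
  out
}

# truth Zhu grade from voxel masks, mirroring the geometric surrogate
.ph_zhu_truth <- function(sm, mask_fu, mask_t0, coverage = 0.95,
                          proximity = 2) {
  inside_vox <- function(mask, pts, lenient = TRUE) {
    d <- dim(mask$data)
    ijk <- round(sweep(pts, 2, mask$origin) / rep(mask$spacing, each = nrow(pts)))
    ok <- logical(nrow(pts))
    for (r in seq_len(nrow(pts))) {
      i <- ijk[r, 1]; j <- ijk[r, 2]; k <- ijk[r, 3]
      hit <- FALSE
      offs <- if (lenient) rbind(c(0,0,0), c(1,0,0), c(-1,0,0), c(0,1,0),
                                 c(0,-1,0), c(0,0,1), c(0,0,-1))
              else rbind(c(0,0,0))
      for (o in seq_len(nrow(offs))) {
        ii <- i + offs[o,1]; jj <- j + offs[o,2]; kk <- k + offs[o,3]
        if (ii >= 0 && ii < d[1] && jj >= 0 && jj < d[2] && kk >= 0 && kk < d[3] &&
            mask$data[ii + 1, jj + 1, kk + 1]) { hit <- TRUE; break }
      }
      ok[r] <- hit
    }
    ok
  }
  if (!any(mask_fu$data)) return(3L)
  hs <- .screw_head_samples(sm)
  ss <- .screw_shaft_samples(sm)
  keep <- inside_vox(mask_t0, ss)
  if (sum(keep) >= 10) ss <- ss[keep, , drop = FALSE]
  if (mean(inside_vox(mask_fu, hs)) >= coverage) return(0L)
  if (mean(inside_vox(mask_fu, ss)) >= coverage) return(1L)
  # any remaining graft voxel within `proximity` of a shaft sample?
  gctr <- voxel_centers(mask_fu, which = mask_fu$data)
  near <- FALSE
  for (r in seq_len(nrow(ss))) {
    d2 <- rowSums(sweep(gctr, 2, ss[r, ])^2)
    if (min(d2) <= proximity^2) { near <- TRUE; break }
  }
  if (near) return(2L)
  3L
}

#' Generate a phantom validation cohort
#'
#' Draws per-phantom resorption fractions from per-grade strata (seeded)
#' whose means mirror the published per-grade resorption pattern, together
#' with randomized inter-scan transforms, and returns the phantom specs,
#' their ground truth and a rating table built from the truth volumes.
#' Images themselves are regenerated on demand from the specs (they are
#' large); pass `keep_images = TRUE` to retain them.
#'
#' @param n_per_grade Phantoms per Zhu stratum (grades I, II, III).
#' @param frac_mean,frac_sd Per-stratum resorption-fraction distributions.
#' @param max_rotation_deg,max_translation_mm Ranges of the randomized
#'   inter-scan transforms.
#' @param voxel_spacing Voxel size passed to every phantom (mm).
#' @param seed Master seed; every phantom derives its own sub-seed.
#' @param keep_images Keep the generated `ct_volume` pairs.
#' @param out_dir Optional directory: writes `truth.csv` and, with
#'   `keep_images`, NIfTI pairs.
#' @return List with `specs`, `truths`, and `table` (a rating data frame
#'   with truth volumes and expected grades).
#' @export
generate_cohort <- function(n_per_grade = c(8, 18, 5),
                            frac_mean = c(0.123, 0.315, 0.583),
                            frac_sd = c(0.05, 0.06, 0.08),
                            max_rotation_deg = 15, max_translation_mm = 8,
                            voxel_spacing = 0.75, seed = 1,
                            keep_images = FALSE, out_dir = NULL) {
  stopifnot(length(n_per_grade) == 3)
  draws <- .with_seed(seed, {
    lapply(seq_len(sum(n_per_grade)), function(i) {
      g <- rep(1:3, n_per_grade)[i]
      list(grade = g,
           frac = min(0.9, max(0.01, rnorm(1, frac_mean[g], frac_sd[g]))),
           rot = runif(1, 2, max_rotation_deg),
           axis = rnorm(3),
           trans = runif(3, -max_translation_mm, max_translation_mm),
           sub_seed = sample.int(1e6, 1))
    })
  })
  specs <- lapply(draws, function(d)
    phantom_spec(voxel_spacing = voxel_spacing,
                 resorption_fraction = d$frac,
                 interscan_rotation_deg = d$rot,
                 interscan_axis = d$axis,
                 interscan_translation = d$trans,
                 seed = d$sub_seed))
  truths <- vector("list", length(specs))
  rows <- vector("list", length(specs))
  images <- if (keep_images) vector("list", length(specs)) else NULL
  for (i in seq_along(specs)) {
    ph <- generate_phantom_pair(specs[[i]])
    truths[[i]] <- ph$truth
    rows[[i]] <- data.frame(
      patient_id = sprintf("PH%02d", i),
      zhu_grade = ph$truth$expected_zhu_grade,
      stratum = draws[[i]]$grade,
      rater = "truth", session = "S1",
      volume_t0_mm3 = ph$truth$graft_volume_t0,
      volume_followup_mm3 = ph$truth$graft_volume_followup,
      resorption_pct = 100 * ph$truth$resorbed_fraction)
    if (keep_images) images[[i]] <- ph[c("preop", "followup")]
    if (!is.null(out_dir) && keep_images) {
      write_volume(ph$preop, file.path(out_dir, sprintf("ph%02d_preop.nii.gz", i)))
      write_volume(ph$followup, file.path(out_dir, sprintf("ph%02d_followup.nii.gz", i)))
    }
  }
  table <- do.call(rbind, rows)
  if (!is.null(out_dir))
    write.csv(table, file.path(out_dir, "truth.csv"), row.names = FALSE)
  out <- list(specs = specs, truths = truths, table = table)
  if (keep_images) out$images <- images
  out
}
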