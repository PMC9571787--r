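#' Measure graft resorption from a registered CT pair
#'
#' Runs the full morphometric chain on a pre-operative and a follow-up CT
#' volume: bone/metal segmentation, surface reconstruction, trimmed-ICP
#' registration of the pre-op scapula onto the follow-up scapula, virtual
#' osteotomy at the marked plane (given in the pre-op frame and mapped
#' through the estimated registration), isolation of the remodelled graft,
#' placement of the modeled graft on the glenoid anchored by its inferior
#' region, volumetry, regional resorption and geometric Zhu grading.
#'
#' Volumes are compared in voxel space on the follow-up grid with the fitted
#' screw geometry carved out of *both* grafts ("virtual drilling"), since
#' the follow-up graft segmented from CT necessarily excludes
#' metal-occupied voxels; the raw mesh volumes are reported alongside.
#'
#' @param preop,followup [ct_volume()]s.
#' @param plane [osteotomy_plane()] in the pre-op frame (or >= 3 landmark
#'   points to fit one).
#' @param axes 3x3 matrix, rows = superior / medial / superficial unit
#'   vectors in the follow-up frame.
#' @param params [segmentation_params()].
#' @param adjacency_mm Graft-to-glenoid adjacency threshold (mm).
#' @param tip_landmark Optional coracoid-tip point (pre-op frame).
#' @return A `graft_report` list: `volumes`, `resorption`, `regional`,
#'   `zhu`, `registration`, `meshes`, `provenance`.
#' @export
measure_graft_pair <- function(preop, followup, plane, axes = diag(3),
                               params = segmentation_params(),
                               adjacency_mm = 2, tip_landmark = NULL) {
  stopifnot(inherits(preop, "ct_volume"), inherits(followup, "ct_volume"))
  if (is.matrix(plane)) plane <- fit_plane(plane)
  stopifnot(inherits(plane, "osteotomy_plane"))
  axes <- matrix(as.numeric(axes), 3, 3)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  bone_pre <- stage("segment-preop", segment_bone(preop, params))
  mesh_pre <- stage("surface-preop", extract_surface(bone_pre, params))
  mesh_pre$provenance <- "pre-op"
  bone_fu <- stage("segment-followup", segment_bone(followup, params))
  mesh_fu <- stage("surface-followup", extract_surface(bone_fu, params))
  mesh_fu$provenance <- "follow-up"
  metal_fu <- stage("segment-metal", segment_metal(followup, params))

  reg <- stage("register", register_scapula_pair(mesh_pre, mesh_fu,
                                                 plane = plane))
  pre_reg <- apply_transform(mesh_pre, reg$transform)
  plane_fu <- transform_plane(plane, reg$transform)
  tip_fu <- if (!is.null(tip_landmark))
    transform_points(matrix(tip_landmark, 1), reg$transform)[1, ] else NULL

  cut <- stage("osteotomy", cut_mesh(pre_reg, plane_fu, tip_landmark = tip_fu))
  if (is_empty_mesh(cut$graft))
    stop("pipeline stage 'osteotomy' failed: plane does not cut the scapula",
         call. = FALSE)
  screw_models <- stage("screw-fit", fit_screw_models(metal_fu))
  fu_graft <- stage("isolate", isolate_followup_graft(
    bone_fu, pre_reg, screws = metal_fu, screw_models = screw_models,
    adjacency_mm = adjacency_mm, params = params))
  grade3 <- isTRUE(attr(fu_graft, "grade3_candidate"))

  if (!grade3) {
    placed <- stage("place", place_graft(cut$graft, pre_reg, fu_graft,
                                         superior_axis = axes[1, ]))
  } else {
    placed <- cut$graft  # nothing to anchor to; keep the osteotomised pose
  }

  # voxel-space volumes on the follow-up grid, symmetric exclusions
  excl <- array(FALSE, dim(bone_fu$data))
  if (any(metal_fu$data))
    excl <- excl | array(cpp_ball_morph(metal_fu$data,
                                        as.integer(dim(metal_fu$data)),
                                        metal_fu$spacing,
                                        max(metal_fu$spacing) * 1.01, 1L),
                         dim(metal_fu$data))
  v0_set <- if (grade3) {
    # nothing to anchor to: the modeled graft stays at the harvest site,
    # which lies inside the pre-op scapula, so only metal is carved out
    .voxelize_mesh(placed, bone_fu) & !excl
  } else {
    .voxelize_mesh(placed, bone_fu) & !.voxelize_mesh(pre_reg, bone_fu) & !excl
  }
  if (length(screw_models)) {
    idx <- which(v0_set)
    if (length(idx)) {
      ctr <- voxel_centers(bone_fu, which = idx)
      drop <- rep(FALSE, length(idx))
      for (sm in screw_models)
        if (!is.null(sm)) drop <- drop | .in_screw(ctr, sm, 0.3)
      v0_set[idx[drop]] <- FALSE
    }
  }
  v0 <- sum(v0_set) * voxel_volume(bone_fu)
  vf <- attr(fu_graft, "voxel_volume_mm3") %||% 0
  res <- compute_resorption(v0, vf, graft_t0 = placed, graft_followup = fu_graft)

  regional <- if (!grade3)
    regional_resorption(placed, fu_graft, axes) else
    setNames(rep(100, 6), c("superior", "inferior", "medial", "lateral",
                            "superficial", "deep"))
  zhu <- stage("grade", zhu_grade(fu_graft, screw_models, graft_t0 = placed))

  structure(list(
    volumes = list(t0_mm3 = v0, followup_mm3 = vf,
                   t0_mesh_mm3 = mesh_volume(placed),
                   followup_mesh_mm3 = if (is_empty_mesh(fu_graft)) 0
                                       else mesh_volume(fu_graft)),
    resorption = list(mm3 = res$resorption_mm3,
                      pct = res$resorption_pct,
                      signed_pct = -res$resorption_pct),
    regional = as.list(regional),
    zhu = list(per_screw = zhu$per_screw, overall = zhu$overall),
    registration = list(rms_residual = reg$rms_residual,
                        iterations = reg$iterations,
                        converged = reg$converged,
                        transform = reg$transform),
    meshes = list(preop = mesh_pre, followup = mesh_fu,
                  preop_registered = pre_reg, modeled_graft = placed,
                  followup_graft = fu_graft, remainder = cut$remainder),
    provenance = list(
      params = unclass(params), adjacency_mm = adjacency_mm,
      plane_followup_frame = unclass(plane_fu),
      n_screws = length(screw_models),
      grade3_candidate = grade3,
      version = as.character(utils::packageVersion("graftmorph")))),
    class = "graft_report")
}

#' @export
print.graft_report <- function(x, ...) {
  cat("graft_report\n")
  cat(sprintf("  V0 %.0f mm^3, Vf %.0f mm^3 -> resorption %.1f mm^3 (%.1f%% loss)\n",
              x$volumes$t0_mm3, x$volumes$followup_mm3, x$resorption$mm3,
              x$resorption$pct))
  cat("  Zhu grade:", x$zhu$overall, "(per screw:",
      paste(x$zhu$per_screw, collapse = ", "), ")\n")
  cat(sprintf("  registration RMS %.3f mm (%d iterations)\n",
              x$registration$rms_residual, x$registration$iterations))
  invisible(x)
}

#' Run the full pipeline from a configuration
#'
#' Validates the configuration, executes the measurement chain, writes every
#' intermediate mesh (STL), the estimated transform (JSON) and a
#' machine-readable report (JSON) into `out_dir`, and returns the report.
#' Reruns with identical inputs produce identical numbers.
#'
#' @param config Named list (or path to a JSON file) with fields `preop`,
#'   `followup` (paths or `ct_volume`s), `plane` (list with `point`,
#'   `normal`, or a landmark matrix under `landmarks`), optional `axes`,
#'   `params` (passed to [segmentation_params()]), `adjacency_mm`,
#'   `tip_landmark`, `out_dir`, `seed`.
#' @return The `graft_report`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  for (f in c("preop", "followup")) {
    if (is.null(config[[f]])) stop("config lacks '", f, "'", call. = FALSE)
    if (is.character(config[[f]]) && !file.exists(config[[f]]))
      stop("config: '", f, "' file does not exist: ", config[[f]],
           call. = FALSE)
  }
  preop <- if (is.character(config$preop)) read_volume(config$preop)
           else config$preop
  followup <- if (is.character(config$followup)) read_volume(config$followup)
              else config$followup
  plane <- if (!is.null(config$plane$landmarks))
    fit_plane(matrix(unlist(config$plane$landmarks), ncol = 3, byrow = TRUE),
              orient_towards = config$plane$orient_towards)
  else osteotomy_plane(unlist(config$plane$point), unlist(config$plane$normal))
  axes <- if (is.null(config$axes)) diag(3)
          else if (is.matrix(config$axes)) config$axes
          else matrix(unlist(config$axes), 3, 3, byrow = TRUE)
  params <- do.call(segmentation_params, config$params %||% list())
  report <- measure_graft_pair(preop, followup, plane, axes = axes,
                               params = params,
                               adjacency_mm = config$adjacency_mm %||% 2,
                               tip_landmark = config$tip_landmark)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    mm <- report$meshes
    for (nm in names(mm))
      if (!is_empty_mesh(mm[[nm]]))
        write_mesh(mm[[nm]], file.path(config$out_dir, paste0(nm, ".stl")))
    write_transform(report$registration$transform,
                    file.path(config$out_dir, "transform.json"),
                    metadata = list(rms_residual = report$registration$rms_residual,
                                    iterations = report$registration$iterations,
                                    converged = report$registration$converged))
    rep_json <- report
    rep_json$meshes <- NULL
    rep_json$registration$transform <-
      as.vector(t(rbind(cbind(report$registration$transform$rotation,
                              report$registration$transform$translation),
                        c(0, 0, 0, 1))))
    jsonlite::write_json(rep_json, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(report)
}
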