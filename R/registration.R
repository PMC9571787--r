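#' Rigid transform (rotation + translation)
#'
#' A 6-DOF map `x -> R x + t` in mm. Rotations must be proper (no
#' reflection): `det(R) = +1` within 1e-6.
#'
#' @param rotation 3x3 orthonormal rotation matrix.
#' @param translation Length-3 translation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be orthonormal with det = +1 (no reflection)",
         call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x)
  cat("rigid_transform: rotation", signif(ang, 4), "deg, translation (",
      paste(signif(x$translation, 4), collapse = ", "), ") mm\n")
  invisible(x)
}

#' Rotation angle of a rigid transform in degrees
#' @param transform A [rigid_transform()].
#' @return Angle in degrees in `[0, 180]`.
#' @export
rotation_angle_deg <- function(transform) {
  tr <- sum(diag(transform$rotation))
  acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
}

#' Compose two rigid transforms
#' @param a,b [rigid_transform()]s; the result applies `b` first, then `a`.
#' @return A [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @return A [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.vector(Rt %*% transform$translation))
}

#' Apply a rigid transform to points or a mesh
#'
#' Volume is preserved exactly up to floating error (rigidity).
#'
#' @param mesh A [triangle_mesh()] or an N x 3 point matrix.
#' @param transform A [rigid_transform()].
#' @return Transformed mesh or points.
#' @export
apply_transform <- function(mesh, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(mesh, "triangle_mesh")) {
    out <- mesh
    out$vertices <- transform_points(mesh$vertices, transform)
    return(out)
  }
  transform_points(mesh, transform)
}

#' @rdname apply_transform
#' @param points N x 3 matrix.
#' @export
transform_points <- function(points, transform) {
  sweep(points %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Serialize / read a rigid transform as JSON (4x4 homogeneous, row-major)
#' @param transform A [rigid_transform()].
#' @param path JSON file path.
#' @param metadata Optional named list stored alongside the matrix.
#' @return `write_transform` invisibly returns `path`; `read_transform`
#'   returns a [rigid_transform()].
#' @export
write_transform <- function(transform, path, metadata = NULL) {
  M <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  obj <- list(matrix = as.vector(t(M)), order = "row-major")
  if (!is.null(metadata)) obj$metadata <- metadata
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  M <- matrix(obj$matrix, 4, 4, byrow = TRUE)
  rigid_transform(M[1:3, 1:3], M[1:3, 4])
}

# least-squares rigid fit mapping P onto Q (Kabsch, reflection-guarded)
.fit_rigid <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, cq - as.vector(R %*% cp))
}

#' Initial rigid alignment by moments
#'
#' Aligns centroids and principal axes, disambiguating axis signs by the
#' third central moments. For axisymmetric shapes (two equal minor
#' eigenvalues) only the principal axis is aligned, via the minimal rotation;
#' a fully degenerate inertia tensor falls back to centroid-only alignment
#' with a warning.
#'
#' @param moving,fixed Nonempty [triangle_mesh()]es.
#' @return A [rigid_transform()] mapping `moving` towards `fixed`.
#' @export
initialize_alignment <- function(moving, fixed) {
  if (is_empty_mesh(moving) || is_empty_mesh(fixed))
    stop("initialize_alignment needs nonempty meshes", call. = FALSE)
  fm <- .mesh_frame(moving)
  ff <- .mesh_frame(fixed)
  if (fm$degenerate || ff$degenerate) {
    warning("degenerate inertia tensor; falling back to centroid-only alignment",
            call. = FALSE)
    return(rigid_transform(diag(3), ff$centroid - fm$centroid))
  }
  if (fm$axisymmetric || ff$axisymmetric) {
    R <- .rotation_between(fm$axes[, 1], ff$axes[, 1])
  } else {
    R <- ff$axes %*% t(fm$axes)
    if (det(R) < 0) {  # guard: should not occur with right-handed frames
      fm$axes[, 3] <- -fm$axes[, 3]
      R <- ff$axes %*% t(fm$axes)
    }
  }
  rigid_transform(R, ff$centroid - as.vector(R %*% fm$centroid))
}

# principal frame of a mesh: centroid, right-handed axes (columns, by
# decreasing eigenvalue, signs from third moments), degeneracy flags
.mesh_frame <- function(mesh) {
  V <- mesh$vertices
  ctr <- colMeans(V)
  Vc <- sweep(V, 2, ctr)
  C <- crossprod(Vc) / nrow(Vc)
  e <- eigen(C, symmetric = TRUE)
  ev <- e$values
  scale2 <- max(ev, 1e-30)
  degenerate <- (ev[1] - ev[3]) / scale2 < 1e-9
  axisymmetric <- !degenerate && (ev[2] - ev[3]) / scale2 < 1e-6
  axes <- e$vectors
  for (a in 1:2) {
    sk <- mean((Vc %*% axes[, a])^3)
    if (sk < 0) axes[, a] <- -axes[, a]
  }
  axes[, 3] <- c(axes[2, 1] * axes[3, 2] - axes[3, 1] * axes[2, 2],
                 axes[3, 1] * axes[1, 2] - axes[1, 1] * axes[3, 2],
                 axes[1, 1] * axes[2, 2] - axes[2, 1] * axes[1, 2])
  list(centroid = ctr, axes = axes, values = ev,
       degenerate = degenerate, axisymmetric = axisymmetric)
}

# minimal rotation taking unit vector a to unit vector b (Rodrigues)
.rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {
    # opposite vectors: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    v <- v / sqrt(sum(v^2))
    K <- .skew(v)
    return(diag(3) + 2 * K %*% K)
  }
  K <- .skew(v)
  diag(3) + K + K %*% K / (1 + cth)
}

.skew <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

#' Trimmed point-to-surface ICP registration
#'
#' Iterative closest point with point-to-triangle correspondences and
#' trimming: the worst fraction of correspondences by distance is discarded
#' each iteration, which keeps the fit unbiased when the two bones genuinely
#' differ (harvested coracoid on the pre-op side, graft on the follow-up
#' side). Deterministic: moving points are a fixed-stride vertex subsample.
#'
#' @param moving,fixed [triangle_mesh()]es; the result maps `moving` into the
#'   physical frame of `fixed`.
#' @param init Initial [rigid_transform()]; defaults to
#'   [initialize_alignment()].
#' @param max_iterations Iteration cap.
#' @param tolerance Convergence threshold on the change in trimmed RMS
#'   residual (mm).
#' @param trim Fraction of worst correspondences discarded per iteration.
#' @param n_samples Number of moving vertices used.
#' @param exclude_moving Optional integer vertex indices of `moving` to
#'   ignore (e.g. a region known to differ).
#' @param multi_start Also try 180-degree flips of the initialization about
#'   the fixed mesh's principal axes and keep the best trimmed fit. Bones
#'   whose bodies are close to symmetric (and whose asymmetric appendages
#'   genuinely differ between timepoints, so trimming discounts them) can
#'   otherwise trap ICP in a flipped pose.
#' @return A `registration_result`: list with `transform`, `rms_residual`
#'   (mm), `iterations`, `converged`.
#' @export
icp_register <- function(moving, fixed, init = NULL, max_iterations = 100,
                         tolerance = 1e-4, trim = 0.2, n_samples = 1500,
                         exclude_moving = NULL, multi_start = TRUE) {
  stopifnot(inherits(moving, "triangle_mesh"), inherits(fixed, "triangle_mesh"))
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  if (is.null(init)) init <- initialize_alignment(moving, fixed)
  stopifnot(inherits(init, "rigid_transform"))
  cand <- seq_len(nrow(moving$vertices))
  if (!is.null(exclude_moving)) cand <- setdiff(cand, exclude_moving)
  if (length(cand) > n_samples)
    cand <- cand[unique(round(seq(1, length(cand), length.out = n_samples)))]
  P0 <- moving$vertices[cand, , drop = FALSE]
  grid <- cpp_trigrid_new(fixed$vertices, fixed$faces - 1L)

  run_icp <- function(tf, iter_cap) {
    prev_rms <- Inf
    rms <- Inf
    converged <- FALSE
    it <- 0
    while (it < iter_cap) {
      it <- it + 1
      P <- transform_points(P0, tf)
      cc <- cpp_trigrid_closest(grid, P)
      keep <- cc$dist <= quantile(cc$dist, 1 - trim, names = FALSE)
      rms <- sqrt(mean(cc$dist[keep]^2))
      new_tf <- .fit_rigid(P0[keep, , drop = FALSE],
                           cc$points[keep, , drop = FALSE])
      # the RMS plateaus long before the pose settles in noisy, flat
      # residual valleys: require the pose update itself to be negligible,
      # measured as the largest sample-point displacement it causes
      move <- max(sqrt(rowSums((transform_points(P0, new_tf) - P)^2)))
      if (abs(prev_rms - rms) < tolerance && move < 5e-3) {
        converged <- TRUE
        break
      }
      prev_rms <- rms
      tf <- new_tf
    }
    list(tf = tf, rms = rms, it = it, converged = converged)
  }

  inits <- list(init)
  if (multi_start) {
    ff <- .mesh_frame(fixed)
    for (a in 1:3) {
      Rf <- .rotation_pi_about(ff$axes[, a])
      flip <- rigid_transform(Rf, ff$centroid - as.vector(Rf %*% ff$centroid))
      inits[[length(inits) + 1]] <- compose_transform(flip, init)
    }
    # short probe runs, then refine the most promising pose
    probes <- lapply(inits, run_icp, iter_cap = min(12, max_iterations))
    best_i <- which.min(vapply(probes, `[[`, numeric(1), "rms"))
    best <- run_icp(probes[[best_i]]$tf, max_iterations)
    best$it <- best$it + probes[[best_i]]$it
  } else {
    best <- run_icp(init, max_iterations)
  }
  if (!best$converged)
    warning("ICP did not converge within ", max_iterations, " iterations ",
            "(last trimmed RMS ", signif(best$rms, 4), " mm)", call. = FALSE)
  structure(list(transform = best$tf, rms_residual = best$rms,
                 iterations = best$it, converged = best$converged),
            class = "registration_result")
}

#' Two-pass scapula registration with coracoid exclusion
#'
#' The pre-operative scapula still carries the full coracoid while the
#' follow-up scapula does not; a single trimmed fit can settle a few
#' degrees off, trading coracoid mismatch against body alignment. When the
#' osteotomy plane is known (it is marked on the pre-operative scan), a
#' second pass re-registers with the graft-side vertices excluded, which
#' removes that bias.
#'
#' @param moving Pre-operative scapula [triangle_mesh()].
#' @param fixed Follow-up scapula [triangle_mesh()].
#' @param plane Optional [osteotomy_plane()] in the frame of `moving`;
#'   vertices within `margin_mm` of the graft side are excluded on the
#'   refinement pass.
#' @param margin_mm Exclusion margin around the plane (mm).
#' @param refine_iterations,refine_samples Budget of the refinement pass;
#'   progress through the flat residual valley left by the first pass is
#'   slow, so it gets more iterations and samples than the default fit.
#' @param ... Passed to [icp_register()] (first pass).
#' @return A `registration_result`.
#' @export
register_scapula_pair <- function(moving, fixed, plane = NULL, margin_mm = 3,
                                  refine_iterations = 300,
                                  refine_samples = 3000, ...) {
  first <- icp_register(moving, fixed, ...)
  if (is.null(plane)) return(first)
  d <- as.vector(sweep(moving$vertices, 2, plane$point) %*% plane$normal)
  excl <- which(d < margin_mm)
  if (length(excl) == 0 || length(excl) >= nrow(moving$vertices) - 100)
    return(first)
  icp_register(moving, fixed, init = first$transform, exclude_moving = excl,
               multi_start = FALSE, max_iterations = refine_iterations,
               n_samples = refine_samples)
}

#' @export
print.registration_result <- function(x, ...) {
  cat("registration_result:", if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "iterations, trimmed RMS",
      signif(x$rms_residual, 4), "mm\n")
  print(x$transform)
  invisible(x)
}
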