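# Shared fixtures, built in code and cached across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# a coarse, fast phantom pair (still fully featured)
coarse_spec <- function(frac = 0, seed = 7, ...) {
  phantom_spec(voxel_spacing = 1.2, resorption_fraction = frac, seed = seed,
               ...)
}

coarse_phantom <- function(frac = 0, seed = 7, ...) {
  key <- paste0("ph_", frac, "_", seed, "_", paste(c(...), collapse = "_"))
  cached(key, generate_phantom_pair(coarse_spec(frac, seed, ...)))
}

# pre-op scapula mesh of the coarse phantom (bone segmented + surface)
coarse_preop_mesh <- function() {
  cached("preop_mesh", {
    ph <- coarse_phantom()
    extract_surface(segment_bone(ph$preop, segmentation_params()),
                    segmentation_params())
  })
}

# digital sphere volume on a 1 mm grid
digital_sphere_volume <- function(radius, spacing = 1, value = 700) {
  n <- ceiling(2 * (radius + 3) / spacing)
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  g <- expand.grid(x = ax, y = ax, z = ax)
  inside <- g$x^2 + g$y^2 + g$z^2 <= radius^2
  ct_volume(array(inside * value, c(n, n, n)), rep(spacing, 3),
            origin = c(ax[1], ax[1], ax[1]))
}

expect_close <- function(actual, expected, tol, label = NULL) {
  expect_lt(abs(actual - expected), tol, label = label)
}

# full-resolution measured sweep used by the recovery and grading checks;
# computed once, reused across acceptance blocks
measured_sweep <- function(fractions = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                           seed = 11) {
  cached(paste0("sweep_", seed), {
    lapply(fractions, function(f) {
      ph <- generate_phantom_pair(phantom_spec(resorption_fraction = f,
                                               seed = seed))
      rep <- measure_graft_pair(ph$preop, ph$followup,
                                ph$truth$osteotomy_plane,
                                axes = ph$truth$axes_followup)
      list(fraction = f, truth = ph$truth, report = rep)
    })
  })
}
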