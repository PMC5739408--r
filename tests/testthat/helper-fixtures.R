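# Shared small fixtures, built in code.  Expensive objects are cached for
# the duration of the test run.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache))
    assign(key, expr, envir = fixture_cache)
  get(key, envir = fixture_cache)
}

# 32^3 water cylinder at 4 mm voxels
tiny_vol <- function(mu = 0.02, r = 50, hz = 60, supersample = 1L) {
  make_phantom(
    phantom_spec(phantom_primitive("cylinder", c(0, 0, 0), c(r, r, hz), mu)),
    dims = c(32, 32, 32), voxel_size = 4, supersample = supersample)
}

tiny_geom <- function(n_views = 8, det = 32, pitch = 4) {
  scan_geometry(n_views = n_views, det_rows = det, det_cols = det,
                pixel_pitch = pitch)
}

tiny_traj <- function(geom, width = 16, gap = 16, amplitude = 80,
                      period = 10, penumbra = 1, cover = c(-Inf, Inf)) {
  blocker_trajectory(width, gap, geom$n_views, amplitude = amplitude,
                     period = period, penumbra_margin = penumbra,
                     cover = cover)
}

# A small noise-free moving-blocker acquisition with ground truth.
tiny_stack <- function(spr = 1, noise = FALSE, seed = 99) {
  vol <- tiny_vol()
  geom <- tiny_geom()
  traj <- tiny_traj(geom)
  acquire(vol, geom, traj, i0 = 1e5, spr = spr, blur_sigma = 40,
          apply_poisson = noise, noise_seed = if (noise) seed else NULL)
}

# Hand-built stack wrapper for detection tests: supply intensity matrices.
manual_stack <- function(intensities, geom, traj = NULL, i0 = 1e5) {
  structure(list(intensities = intensities, i0 = i0, geometry = geom,
                 trajectory = traj, masks = NULL, ground_truth = NULL),
            class = "projection_stack")
}

expect_close <- function(object, expected, tol = 1e-8) {
  expect_lt(max(abs(object - expected)), tol)
}
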