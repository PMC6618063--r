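# Shared fixtures: a desk-scale protocol and phantom, plus a memoized
# simulated acquisition so expensive stages run once per test session.

small_params <- function(...) {
  sequence_params(matrix = 32, fov = 32 * 2.8, n_slices_recon = 4,
                  slice_oversampling = 0.27, n_interleaves = 6,
                  readout_duration = 5, ...)
}

small_spec <- function(...) {
  args <- utils::modifyList(
    list(loop_radius = 18, tube_radius = 6, mouth_y = 10,
         tube_length = 22, stroke_volume = 8, rr_sd = 30,
         body_semiaxes = c(34, 40), resp_amplitude = 0, noise_sd = 0),
    list(...))
  do.call(phantom_spec, args)
}

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

small_trajectory <- function() {
  memo("traj", design_spiral_interleaf(small_params()))
}

# noise-free dynamic acquisition of the small phantom, fully accepted
small_acquisition <- function() {
  memo("acq", {
    f <- make_phantom(small_spec())
    rr <- sample_rr_intervals(900, 30, 200, seed = 301)
    simulate_acquisition(f, small_trajectory(), small_params(), rr,
                         nav = NULL, resp = NULL, seed = 302)
  })
}

small_recon_series <- function() {
  memo("series", {
    b <- suppressMessages(bin_samples(small_acquisition(),
                                      gating_config(n_frames = 8, t_sys = 360)))
    phase_difference_velocity(grid_reconstruct(b, small_trajectory(),
                                               gridding_config()))
  })
}

# uniform rigid-rotation velocity series (steady): v = omega x r in-plane
rotation_series <- function(omega = 2 * pi / 600, n = 32, vox = 2.8,
                            n_sl = 8, nf = 2, frame_duration = 300) {
  xs <- axis_coords_t(n, vox)
  gg <- expand.grid(x = xs, y = xs, z = axis_coords_t(n_sl, vox))
  vx <- array(-omega * gg$y, dim = c(n, n, n_sl))
  vy <- array(omega * gg$x, dim = c(n, n, n_sl))
  v <- array(0, dim = c(n, n, n_sl, nf, 3))
  for (f in seq_len(nf)) {
    v[, , , f, 1] <- vx
    v[, , , f, 2] <- vy
  }
  velocity_series(array(1, dim = c(n, n, n_sl, nf)), v,
                  voxel_size = rep(vox, 3), frame_duration = frame_duration,
                  venc = 120)
}

# voxel-center coordinates, re-derived here so tests do not depend on the
# package's internal helper
axis_coords_t <- function(n, delta) ((seq_len(n) - 1) + 0.5) * delta - n * delta / 2

# uniform-velocity steady series
uniform_series <- function(vvec, n = 16, vox = 2.8, n_sl = 4, nf = 2) {
  v <- array(0, dim = c(n, n, n_sl, nf, 3))
  for (ci in 1:3) v[, , , , ci] <- vvec[ci]
  velocity_series(array(1, dim = c(n, n, n_sl, nf)), v,
                  voxel_size = rep(vox, 3), frame_duration = 100, venc = 120)
}
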