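#' Scanner gradient system limits
#'
#' Hardware constraints that bound the spiral readout design: peak gradient
#' amplitude, peak slew rate, and the gradient raster time.
#'
#' @param max_gradient Peak gradient amplitude in mT/m.
#' @param max_slew Peak slew rate in T/m/s (equivalently mT/m/ms).
#' @param raster_time Gradient raster time in microseconds.
#' @return An object of class `gradient_limits`.
#' @examples
#' gradient_limits(33, 180)
#' @export
gradient_limits <- function(max_gradient = 33, max_slew = 180, raster_time = 10) {
  assert_that(max_gradient > 0 && max_slew > 0 && raster_time > 0,
              "gradient limits must all be strictly positive")
  structure(list(max_gradient = max_gradient, max_slew = max_slew,
                 raster_time = raster_time), class = "gradient_limits")
}

#' Sequence parameters for a velocity-encoded stack-of-spirals acquisition
#'
#' Holds the acquisition parameters of a retrospectively gated 4D flow
#' protocol: timing (TR/TE), velocity encoding strength, spiral interleaving,
#' geometry, and the flow-segment structure (one reference segment plus three
#' velocity-encoded segments acquired in succession within a heart phase).
#'
#' @param tr Repetition time, ms.
#' @param te Echo time, ms.
#' @param venc Velocity encoding, cm/s (velocity mapping to a phase of pi).
#' @param n_interleaves Number of spiral interleaves per slice-encode
#'   partition.
#' @param readout_duration Maximum spiral readout length, ms.
#' @param fov In-plane field of view, mm (square).
#' @param matrix In-plane matrix size (isotropic).
#' @param n_slices_recon Number of reconstructed slices.
#' @param slice_oversampling Slice oversampling fraction (extra slice encodes
#'   acquired to avoid foldover; e.g. 0.27 for 27%).
#' @param slice_thickness Slice thickness, mm.
#' @param flip_angle Excitation flip angle, degrees.
#' @param segmentation_factor k-space lines acquired per heart phase.
#' @param n_flow_segments Flow segments per line (reference + 3 encoded = 4).
#' @return An object of class `sequence_params`.
#' @examples
#' sequence_params()                      # spiral protocol defaults
#' sequence_params(tr = 5.8, segmentation_factor = 2)  # Cartesian-style timing
#' @export
sequence_params <- function(tr = 12, te = 3.7, venc = 120, n_interleaves = 10,
                            readout_duration = 5, fov = 280, matrix = 100,
                            n_slices_recon = 36, slice_oversampling = 0.27,
                            slice_thickness = 2.8, flip_angle = 8,
                            segmentation_factor = 1, n_flow_segments = 4) {
  assert_that(fov > 0 && matrix >= 2, "fov and matrix must be positive")
  assert_that(n_flow_segments == 4,
              "four-point velocity encoding requires n_flow_segments = 4")
  assert_that(n_interleaves >= 1, "n_interleaves must be >= 1")
  assert_that(slice_oversampling >= 0, "slice_oversampling must be >= 0")
  assert_that(tr > 0 && venc > 0 && readout_duration > 0 &&
                n_slices_recon >= 1 && slice_thickness > 0 &&
                segmentation_factor >= 1,
              "timing and geometry parameters must be positive")
  p <- list(tr = tr, te = te, venc = venc, n_interleaves = n_interleaves,
            readout_duration = readout_duration, fov = fov, matrix = matrix,
            n_slices_recon = n_slices_recon,
            slice_oversampling = slice_oversampling,
            slice_thickness = slice_thickness, flip_angle = flip_angle,
            segmentation_factor = segmentation_factor,
            n_flow_segments = n_flow_segments)
  p$voxel <- fov / matrix       # isotropic in-plane voxel, mm
  p$kmax <- 1 / (2 * p$voxel)   # cycles/mm
  structure(p, class = "sequence_params")
}

#' Variable-density profile for the spiral readout
#'
#' Two-zone radial density law: the core of k-space (out to
#' `core_fraction * kmax`) is sampled at the Nyquist spacing for the full
#' FOV; beyond it the adjacent-turn spacing widens linearly until it is
#' `taper_to` times Nyquist at the k-space edge. `taper_to = 1` is a fully
#' sampled (uniform-density) spiral.
#'
#' @param core_fraction Fraction of kmax that is fully sampled.
#' @param taper_to Undersampling factor reached at the k-space edge (>= 1).
#' @return An object of class `density_profile`.
#' @export
density_profile <- function(core_fraction = 0.2, taper_to = 1.0) {
  assert_that(core_fraction > 0 && core_fraction <= 1,
              "core_fraction must be in (0, 1]")
  assert_that(taper_to >= 1, "taper_to must be >= 1 (1 = fully sampled)")
  structure(list(core_fraction = core_fraction, taper_to = taper_to),
            class = "density_profile")
}

# local spacing multiplier d(r) and its radial derivative
density_mult <- function(r, kmax, dens) {
  rc <- dens$core_fraction * kmax
  if (rc >= kmax) return(list(d = rep(1, length(r)), dd = rep(0, length(r))))
  d <- ifelse(r <= rc, 1,
              1 + (dens$taper_to - 1) * (r - rc) / (kmax - rc))
  dd <- ifelse(r <= rc, 0, (dens$taper_to - 1) / (kmax - rc))
  list(d = d, dd = dd)
}

# One evaluation of the controlled spiral dynamics.
# State: theta (rad), omega = dtheta/dt (rad/ms), r (cycles/mm).
# The radius law is dr/dtheta = c * d(r), c = n_interleaves / (2*pi*FOV),
# so that the combined interleaf set meets Nyquist in the core. At each
# instant the angular acceleration is the largest value keeping |d2k/dt2|
# within the slew limit; once |dk/dt| reaches the gradient limit the design
# switches to the amplitude-limited regime (constant speed along the curve).
spiral_derivs <- function(state, cc, kmax, dens, vmax, amax) {
  theta <- state[1]; omega <- state[2]; r <- state[3]
  dm <- density_mult(r, kmax, dens)
  rp <- cc * dm$d                       # dr/dtheta
  rpp <- cc * dm$dd * rp                # d2r/dtheta2
  # acceleration components in the rotating frame:
  a_re <- (rpp - r) * omega^2
  a_im <- 2 * rp * omega^2
  b_re <- rp; b_im <- r
  b2 <- b_re^2 + b_im^2
  ab <- a_re * b_re + a_im * b_im
  disc <- ab^2 - b2 * ((a_re^2 + a_im^2) - amax^2)
  tdd_slew <- if (disc <= 0) -ab / b2 else (-ab + sqrt(disc)) / b2
  ff <- sqrt(rp^2 + r^2)                # |dk/dtheta|
  speed <- omega * ff
  if (speed >= vmax) {
    # hold |dk/dt| = vmax: d(omega*F)/dt = 0
    dff <- (rp * rpp + r * rp) / ff
    tdd_amp <- -omega^2 * dff / ff
    tdd <- min(tdd_slew, tdd_amp)
  } else tdd <- tdd_slew
  c(omega, tdd, rp * omega)
}

#' Design one variable-density spiral interleaf (and its rotations)
#'
#' Numerically integrates the slew-limited Archimedean spiral dynamics on a
#' fine internal raster, switching to the gradient-amplitude-limited regime
#' when the readout speed saturates, and stops when the k-space radius
#' reaches `kmax = 1/(2 * voxel)`. The remaining interleaves are exact
#' rotations of the base interleaf by `2*pi*m/n_interleaves`
#' (counter-clockwise, interleaf 0 along +kx).
#'
#' @param params A [sequence_params()] object.
#' @param limits A [gradient_limits()] object.
#' @param density A [density_profile()] object.
#' @return An object of class `spiral_trajectory` with elements `k`
#'   (`n_samples x 2 x n_interleaves` array, cycles/mm), `g` (gradient
#'   waveforms, mT/m, same shape), `angles` (rad), `kmax`, `n_samples`,
#'   `raster_time` (us), `kz` (slice-encode values, cycles/mm), `n_kz`,
#'   `readout_time` (ms) and the generating `params`.
#' @seealso [cartesian_trajectory()] for the Cartesian reference.
#' @export
design_spiral_interleaf <- function(params, limits = gradient_limits(),
                                    density = density_profile()) {
  stopifnot(inherits(params, "sequence_params"),
            inherits(limits, "gradient_limits"))
  kmax <- params$kmax
  n_int <- params$n_interleaves
  cc <- n_int / (2 * pi * params$fov)
  raster_ms <- limits$raster_time / 1000
  safety <- 0.995
  vmax <- safety * GAMMA_BAR * limits$max_gradient     # cycles/mm/ms
  amax <- safety * GAMMA_BAR * limits$max_slew         # cycles/mm/ms^2
  sub <- 10                                            # internal substeps
  dt <- raster_ms / sub
  max_steps <- ceiling(params$readout_duration / dt) + sub
  state <- c(0, 0, 0)
  theta_r <- numeric(max_steps %/% sub + 2)  # state at raster points
  rr <- numeric(length(theta_r))
  theta_r[1] <- 0; rr[1] <- 0
  nrec <- 1
  reached <- FALSE
  for (i in seq_len(max_steps)) {
    # RK4 on the controlled system
    k1 <- spiral_derivs(state, cc, kmax, dens = density, vmax, amax)
    k2 <- spiral_derivs(state + dt / 2 * k1, cc, kmax, density, vmax, amax)
    k3 <- spiral_derivs(state + dt / 2 * k2, cc, kmax, density, vmax, amax)
    k4 <- spiral_derivs(state + dt * k3, cc, kmax, density, vmax, amax)
    state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i %% sub == 0) {
      nrec <- nrec + 1
      theta_r[nrec] <- state[1]; rr[nrec] <- state[3]
      if (state[3] >= kmax) { reached <- TRUE; break }
      if (i * dt > params$readout_duration)
        stop_ctx("spiral cannot reach kmax = ", signif(kmax, 4),
                 " /mm within readout_duration = ", params$readout_duration,
                 " ms under the given gradient limits",
                 class = "spiral4d_infeasible_readout")
    }
  }
  if (!reached)
    stop_ctx("spiral design did not converge within readout_duration",
             class = "spiral4d_infeasible_readout")
  theta_r <- theta_r[1:nrec]; rr <- rr[1:nrec]
  n_samp <- nrec
  base <- cbind(rr * cos(theta_r), rr * sin(theta_r))
  angles <- 2 * pi * (seq_len(n_int) - 1) / n_int
  k <- array(0, dim = c(n_samp, 2, n_int))
  g <- array(0, dim = c(n_samp, 2, n_int))
  for (m in seq_len(n_int)) {
    ca <- cos(angles[m]); sa <- sin(angles[m])
    k[, 1, m] <- ca * base[, 1] - sa * base[, 2]
    k[, 2, m] <- sa * base[, 1] + ca * base[, 2]
    g[, , m] <- rbind(k[1, , m], diff(k[, , m])) / (GAMMA_BAR * raster_ms)
  }
  n_kz <- slice_encode_count(params)
  fovz <- n_kz * params$slice_thickness
  kz <- (seq_len(n_kz) - 1 - floor(n_kz / 2)) / fovz
  structure(list(k = k, g = g, angles = angles, kmax = kmax,
                 n_samples = n_samp, raster_time = limits$raster_time,
                 kz = kz, n_kz = n_kz, fovz = fovz,
                 readout_time = (n_samp - 1) * raster_ms,
                 density = density, params = params, limits = limits),
            class = "spiral_trajectory")
}

# Number of acquired slice encodes: reconstructed slices inflated by the
# slice oversampling factor, rounded to the nearest integer; parity matched
# to n_slices_recon so the recon crop lands on coincident voxel centers.
slice_encode_count <- function(params) {
  n <- round(params$n_slices_recon * (1 + params$slice_oversampling))
  if ((n - params$n_slices_recon) %% 2 != 0) n <- n + 1
  n
}

#' @exportS3Method print spiral_trajectory
print.spiral_trajectory <- function(x, ...) {
  cat("Stack-of-spirals trajectory\n",
      "  interleaves: ", dim(x$k)[3], ", samples/interleaf: ", x$n_samples,
      " @ ", x$raster_time, " us\n",
      "  kmax: ", signif(x$kmax, 4), " /mm, readout ",
      signif(x$readout_time, 3), " ms, ", x$n_kz, " slice encodes\n",
      sep = "")
  invisible(x)
}

#' Nominal temporal resolution of the sequence
#'
#' One k-space line needs `n_flow_segments` TRs per heart phase, repeated for
#' every line in a segment: the nominal frame spacing is
#' `segmentation_factor * n_flow_segments * TR`.
#'
#' @param params A [sequence_params()] object.
#' @return Temporal resolution in ms.
#' @examples
#' nominal_temporal_resolution(sequence_params(tr = 12))               # 48
#' nominal_temporal_resolution(sequence_params(tr = 5.8,
#'                                             segmentation_factor = 2)) # 46.4
#' @export
nominal_temporal_resolution <- function(params) {
  stopifnot(inherits(params, "sequence_params"))
  params$segmentation_factor * params$n_flow_segments * params$tr
}

#' Nominal scan time in cardiac cycles
#'
#' With one k-space line (all flow segments, all heart phases) completed per
#' cardiac cycle and segmentation unit, the scan needs
#' `n_interleaves * round(n_slices_recon * (1 + slice_oversampling)) /
#' segmentation_factor` heartbeats.
#'
#' @param params A [sequence_params()] object.
#' @return Number of RR intervals (heartbeats).
#' @examples
#' nominal_scan_time(sequence_params(n_slices_recon = 36))  # 460
#' nominal_scan_time(sequence_params(n_slices_recon = 40))  # 510
#' @export
nominal_scan_time <- function(params) {
  stopifnot(inherits(params, "sequence_params"))
  n_enc <- round(params$n_slices_recon * (1 + params$slice_oversampling))
  params$n_interleaves * n_enc / params$segmentation_factor
}

#' Cartesian reference trajectory
#'
#' Enumerates the phase-encode lines of a fully sampled Cartesian acquisition
#' on the stated matrix; used as the reference acquisition in comparison
#' experiments.
#'
#' @param params A [sequence_params()] object.
#' @param ordering `"linear"` (bottom-to-top) or `"low_high"` (center-out:
#'   lines ordered by increasing |ky|).
#' @return An object of class `cartesian_trajectory` with `k`
#'   (`matrix x 2 x n_lines`), the line `order` used, and slice encodes as in
#'   the spiral case.
#' @export
cartesian_trajectory <- function(params, ordering = c("low_high", "linear")) {
  stopifnot(inherits(params, "sequence_params"))
  ordering <- match.arg(ordering)
  n <- params$matrix
  dk <- 1 / params$fov
  idx <- seq_len(n) - 1 - floor(n / 2)      # DFT frequencies
  kx <- idx * dk
  line_order <- if (ordering == "linear") order(idx) else order(abs(idx), idx)
  k <- array(0, dim = c(n, 2, n))
  for (j in seq_len(n)) {
    ky <- idx[line_order[j]] * dk
    k[, 1, j] <- kx
    k[, 2, j] <- ky
  }
  n_kz <- slice_encode_count(params)
  fovz <- n_kz * params$slice_thickness
  kz <- (seq_len(n_kz) - 1 - floor(n_kz / 2)) / fovz
  structure(list(k = k, order = idx[line_order], ordering = ordering,
                 kmax = params$kmax, n_samples = n, kz = kz, n_kz = n_kz,
                 fovz = fovz, params = params),
            class = "cartesian_trajectory")
}
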