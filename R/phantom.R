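#' Specification of the analytic beating-flow phantom
#'
#' The phantom is a rigid U-bend channel standing in for a cardiac chamber
#' with an inflow and an outflow vessel: two straight tubes (the limbs, along
#' +y) joined by a half-torus bend (the chamber) in the x-y plane, embedded
#' in a static-tissue body. The velocity field is purely azimuthal in the
#' bend and axial in the limbs with a smooth quartic cross-sectional profile,
#' which makes it exactly divergence-free, and is modulated in time by a
#' pulsatile waveform with a systolic ejection lobe and biphasic diastolic
#' filling (E and A waves, the A wave in the final part of the cycle).
#' Because the channel is rigid the instantaneous flux is equal everywhere
#' along it; the waveform therefore splits the per-cycle volume evenly
#' between systole and diastole so that pathline-based inflow and outflow
#' are both half the cycle volume.
#'
#' @param loop_radius Radius of the bend centerline, mm.
#' @param tube_radius Channel (lumen) radius, mm.
#' @param mouth_y y-coordinate of the chamber mouth plane, mm: the bend
#'   occupies y < mouth_y, the straight limbs y >= mouth_y.
#' @param tube_length Length of the straight limbs beyond the mouth, mm.
#' @param stroke_volume Volume through the channel per cardiac cycle, ml.
#' @param systolic_duration Duration of systole, ms.
#' @param e_fraction Fraction of the diastolic volume carried by the E wave
#'   (the rest is the late-diastolic A wave).
#' @param a_wave_fraction Fraction of the cycle, at its very end, occupied by
#'   the A wave.
#' @param rr_mean,rr_sd Mean and SD of the RR interval, ms.
#' @param magnitude_fluid,magnitude_static,magnitude_background Signal
#'   levels (a.u.) of fluid, static tissue and air background.
#' @param body_semiaxes Semi-axes (x, y) of the elliptic-cylinder "body"
#'   whose non-fluid interior is static tissue, mm.
#' @param noise_sd Complex k-space noise SD per sample, in units of the
#'   signal of one fluid-magnitude voxel.
#' @param resp_amplitude,resp_period Respiratory (navigator) motion:
#'   sinusoid amplitude mm and period ms.
#' @param background_poly Optional list with components `vx`, `vy`, `vz`:
#'   coefficient vectors (degree-4 spatial basis, 35 terms, coordinates
#'   normalized to \[-1, 1\]) of a background velocity offset in m/s.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(loop_radius = 40, tube_radius = 9, mouth_y = 25,
                         tube_length = 55, stroke_volume = 25,
                         systolic_duration = 360, e_fraction = 0.7,
                         a_wave_fraction = 0.15, rr_mean = 900, rr_sd = 50,
                         magnitude_fluid = 1, magnitude_static = 0.6,
                         magnitude_background = 0.02,
                         body_semiaxes = c(68, 82), noise_sd = 3,
                         resp_amplitude = 5, resp_period = 4000,
                         background_poly = NULL) {
  assert_that(stroke_volume >= 0, "stroke_volume must be >= 0")
  assert_that(systolic_duration > 0 && systolic_duration < rr_mean,
              "systolic_duration must lie inside the mean cardiac cycle")
  assert_that(e_fraction >= 0 && e_fraction <= 1, "e_fraction must be in [0,1]")
  assert_that(a_wave_fraction > 0 && a_wave_fraction < 0.5,
              "a_wave_fraction must be in (0, 0.5)")
  assert_that(rr_sd >= 0 && rr_mean > 0, "RR distribution must be valid")
  if (tube_radius >= loop_radius)
    stop_ctx("tube_radius >= loop_radius: the limbs do not attach to ",
             "distinct mouths of the bend", class = "spiral4d_geometry")
  structure(as.list(environment()), class = "phantom_spec")
}

# Raised-cosine bump of unit peak on [t0, t0 + dur], zero elsewhere.
rc_bump <- function(t, t0, dur) {
  inside <- t >= t0 & t <= t0 + dur
  out <- numeric(length(t))
  out[inside] <- 0.5 * (1 - cos(2 * pi * (t[inside] - t0) / dur))
  out
}

#' Construct the analytic time-varying flow field of a phantom
#'
#' Returns an evaluation object: closed-form velocity (m/s) and signal
#' magnitude at arbitrary positions and times, region indicators, the flux
#' waveform, and the closed-form instantaneous volume flux. The spatial field
#' carries unit flux (1 ml/s through any channel cross-section), so the flux
#' waveform in ml/s multiplies it directly; beat-to-beat variation stretches
#' the diastolic part of the waveform while systole keeps its duration, the
#' same model the retrospective gating assumes.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `flow_field` with function elements
#'   `velocity(x, y, z, t, rr)`, `unit_velocity(x, y, z)`,
#'   `magnitude(x, y, z)`, `fluid(x, y, z)`, `static_region(x, y, z)`,
#'   `chamber(x, y, z)`, `waveform(t_norm)` (ml/s on the mean cycle),
#'   `flux(t, rr)` (ml/s) and scalars `peak_speed` (m/s) and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  Rc <- spec$loop_radius; a <- spec$tube_radius
  y0 <- spec$mouth_y; ytop <- spec$mouth_y + spec$tube_length
  sv_mm3 <- spec$stroke_volume * 1000
  tsys <- spec$systolic_duration; rrm <- spec$rr_mean
  a_dur <- spec$a_wave_fraction * rrm
  dia <- rrm - tsys
  e_gap <- 0.08 * dia                       # isovolumic-like pause after systole
  e_dur <- max(min(0.55 * dia, dia - a_dur - 2 * e_gap), 1e-6)
  # peak fluxes (mm^3/ms = ml/s); each lobe is a raised cosine: volume = peak*dur/2
  q_sys <- sv_mm3 / tsys                               # systolic half-volume
  q_e <- if (spec$stroke_volume > 0) sv_mm3 * spec$e_fraction / e_dur else 0
  q_a <- if (spec$stroke_volume > 0)
    sv_mm3 * (1 - spec$e_fraction) / a_dur else 0
  waveform <- function(t_norm) {
    t_norm <- t_norm %% rrm
    q_sys * rc_bump(t_norm, 0, tsys) +
      q_e * rc_bump(t_norm, tsys + e_gap, e_dur) +
      q_a * rc_bump(t_norm, rrm - a_dur, a_dur)
  }
  prof_scale <- 3 / (pi * a^2)   # unit-flux quartic profile: peak speed factor
  unit_velocity <- function(x, y, z) {
    n <- length(x)
    v <- matrix(0, n, 3)
    if (sv_mm3 >= 0) {
      bend <- y <= y0
      if (any(bend)) {
        eta <- y0 - y[bend]
        s <- sqrt(x[bend]^2 + eta^2)
        rho <- sqrt((s - Rc)^2 + z[bend]^2)
        p <- ifelse(rho < a & s > 1e-9, (1 - (rho / a)^2)^2, 0)
        v[bend, 1] <- -prof_scale * p * eta / pmax(s, 1e-9)
        v[bend, 2] <- -prof_scale * p * x[bend] / pmax(s, 1e-9)
      }
      limb <- y > y0 & y <= ytop
      if (any(limb)) {
        xl <- x[limb]; zl <- z[limb]
        rin <- sqrt((xl - Rc)^2 + zl^2)
        rout <- sqrt((xl + Rc)^2 + zl^2)
        pin <- ifelse(rin < a, (1 - (rin / a)^2)^2, 0)
        pout <- ifelse(rout < a, (1 - (rout / a)^2)^2, 0)
        v[limb, 2] <- prof_scale * (pout - pin)
      }
    }
    v
  }
  fluid <- function(x, y, z) {
    bend <- y <= y0
    eta <- ifelse(bend, y0 - y, 0)
    s <- sqrt(x^2 + eta^2)
    in_bend <- bend & sqrt((s - Rc)^2 + z^2) < a
    in_limb <- y > y0 & y <= ytop &
      (sqrt((x - Rc)^2 + z^2) < a | sqrt((x + Rc)^2 + z^2) < a)
    in_bend | in_limb
  }
  chamber <- function(x, y, z) fluid(x, y, z) & y <= y0
  body <- function(x, y, z)
    (x / spec$body_semiaxes[1])^2 + (y / spec$body_semiaxes[2])^2 <= 1
  static_region <- function(x, y, z) body(x, y, z) & !fluid(x, y, z)
  magnitude <- function(x, y, z) {
    ifelse(fluid(x, y, z), spec$magnitude_fluid,
           ifelse(body(x, y, z), spec$magnitude_static,
                  spec$magnitude_background))
  }
  # map beat time onto the mean cycle: systole kept, diastole stretched
  norm_time <- function(t, rr) {
    ifelse(t <= tsys | rr <= tsys, pmin(t, rr),
           tsys + (t - tsys) * (rrm - tsys) / (rr - tsys))
  }
  velocity <- function(x, y, z, t, rr = rrm) {
    q <- waveform(norm_time(t, rr))          # scalar flux, mm^3/ms
    unit_velocity(x, y, z) * q               # mm/ms == m/s
  }
  flux <- function(t, rr = rrm) waveform(norm_time(t, rr))
  peak_speed <- max(q_sys, q_e, q_a) * prof_scale
  structure(list(velocity = velocity, unit_velocity = unit_velocity,
                 magnitude = magnitude, fluid = fluid, chamber = chamber,
                 static_region = static_region, waveform = waveform,
                 flux = flux, norm_time = norm_time,
                 peak_speed = peak_speed, spec = spec),
            class = "flow_field")
}

#' @exportS3Method print flow_field
print.flow_field <- function(x, ...) {
  cat("Analytic flow phantom: U-bend chamber, loop radius ",
      x$spec$loop_radius, " mm, lumen radius ", x$spec$tube_radius,
      " mm\n  stroke volume ", x$spec$stroke_volume, " ml, peak speed ",
      signif(x$peak_speed, 3), " m/s, RR ", x$spec$rr_mean, " +/- ",
      x$spec$rr_sd, " ms\n", sep = "")
  invisible(x)
}

#' Sample a sequence of RR intervals
#'
#' Gaussian beat-to-beat variability, truncated at 3.5 SD to keep intervals
#' physiological.
#'
#' @param mean Mean RR interval, ms.
#' @param sd SD of the RR interval, ms.
#' @param n Number of beats.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return Numeric vector of `n` RR intervals in ms.
#' @export
sample_rr_intervals <- function(mean, sd, n, seed = NULL) {
  assert_that(sd >= 0 && mean > 0 && n >= 1, "invalid RR distribution")
  with_seed(seed, {
    rr <- stats::rnorm(n, mean, sd)
    pmin(pmax(rr, mean - 3.5 * sd), mean + 3.5 * sd)
  })
}

#' Add a polynomial background velocity offset to a series
#'
#' Voxel-wise addition of a degree-<=4 spatial polynomial (the eddy-current
#' model the correction stage removes) to every frame of each velocity
#' component. Coordinates are normalized to \[-1, 1\] over the volume before
#' the basis is evaluated, matching [fit_background()].
#'
#' @param series A [velocity_series()].
#' @param coefficients List with components `vx`, `vy`, `vz`: coefficient
#'   vectors on the degree-4 basis of [poly4_design()] (35 terms; shorter
#'   vectors are zero-padded). Units m/s.
#' @return The series with offsets added.
#' @export
apply_background_offset <- function(series, coefficients) {
  stopifnot(inherits(series, "velocity_series"))
  d <- dim(series$magnitude)
  basis <- poly4_design(series)
  for (ci in 1:3) {
    comp <- c("vx", "vy", "vz")[ci]
    beta <- coefficients[[comp]] %||% numeric(0)
    assert_that(length(beta) <= ncol(basis),
                "background polynomial degree exceeds 4 (35 terms)")
    if (!length(beta)) next
    beta <- c(beta, numeric(ncol(basis) - length(beta)))
    off <- array(basis %*% beta, dim = d[1:3])
    for (f in seq_len(d[4])) series$v[, , , f, ci] <- series$v[, , , f, ci] + off
  }
  series
}

#' Rasterize the analytic phantom onto a voxel grid
#'
#' Evaluates the ground-truth field at voxel centers and frame-center times
#' of the mean cardiac cycle; this is the reference every reconstruction is
#' judged against, and the input for analysis-only experiments.
#'
#' @param field A [make_phantom()] object.
#' @param matrix In-plane matrix size.
#' @param voxel Isotropic in-plane voxel size, mm.
#' @param n_slices Number of slices (z).
#' @param slice_thickness Slice thickness, mm (defaults to `voxel`).
#' @param n_frames Cardiac frames.
#' @param velocity_noise_sd Optional zero-mean Gaussian velocity noise, m/s.
#' @param seed Seed for the noise.
#' @return A [velocity_series()] of the ground truth.
#' @export
rasterize_phantom <- function(field, matrix = 64, voxel = 2.8, n_slices = 8,
                              slice_thickness = voxel, n_frames = 20,
                              velocity_noise_sd = 0, seed = NULL) {
  stopifnot(inherits(field, "flow_field"))
  rrm <- field$spec$rr_mean
  xs <- axis_coords(matrix, voxel); ys <- xs
  zs <- axis_coords(n_slices, slice_thickness)
  gg <- expand.grid(x = xs, y = ys, z = zs)
  uv <- field$unit_velocity(gg$x, gg$y, gg$z)
  mag3 <- array(field$magnitude(gg$x, gg$y, gg$z),
                dim = c(matrix, matrix, n_slices))
  tf <- (seq_len(n_frames) - 0.5) * rrm / n_frames
  q <- field$waveform(tf)
  magnitude <- array(rep(mag3, n_frames), dim = c(matrix, matrix, n_slices, n_frames))
  v <- array(0, dim = c(matrix, matrix, n_slices, n_frames, 3))
  for (f in seq_len(n_frames))
    for (ci in 1:3)
      v[, , , f, ci] <- array(uv[, ci] * q[f], dim = c(matrix, matrix, n_slices))
  if (velocity_noise_sd > 0) {
    v <- v + with_seed(seed, array(stats::rnorm(length(v), 0, velocity_noise_sd),
                                   dim = dim(v)))
  }
  velocity_series(magnitude, v, voxel_size = c(voxel, voxel, slice_thickness),
                  frame_duration = rrm / n_frames, venc = 120)
}

#' Region masks of a phantom on a voxel grid
#'
#' Fluid, strict-fluid (one-voxel safety margin inside the lumen, the ROI
#' used for velocity-error metrics so that wall partial-volume voxels are
#' excluded), static tissue, chamber, and mouth-plane inlet/outlet labels.
#'
#' @inheritParams rasterize_phantom
#' @return List of logical 3D arrays: `fluid`, `fluid_strict`, `static`,
#'   `chamber`, `inlet_mouth`, `outlet_mouth`.
#' @export
phantom_masks <- function(field, matrix = 64, voxel = 2.8, n_slices = 8,
                          slice_thickness = voxel) {
  stopifnot(inherits(field, "flow_field"))
  xs <- axis_coords(matrix, voxel); ys <- xs
  zs <- axis_coords(n_slices, slice_thickness)
  gg <- expand.grid(x = xs, y = ys, z = zs)
  dims <- c(matrix, matrix, n_slices)
  shape <- function(v) array(v, dim = dims)
  spec <- field$spec
  fl <- field$fluid(gg$x, gg$y, gg$z)
  # strict fluid: shrink the lumen radius by one in-plane voxel
  shrink <- phantom_spec_shrunk(spec, voxel)
  fls <- make_phantom(shrink)$fluid(gg$x, gg$y, gg$z)
  ch <- field$chamber(gg$x, gg$y, gg$z)
  st <- field$static_region(gg$x, gg$y, gg$z)
  near_mouth <- abs(gg$y - spec$mouth_y) <= max(voxel, slice_thickness)
  inlet <- fl & near_mouth & gg$x > 0
  outlet <- fl & near_mouth & gg$x < 0
  list(fluid = shape(fl), fluid_strict = shape(fls), static = shape(st),
       chamber = shape(ch), inlet_mouth = shape(inlet),
       outlet_mouth = shape(outlet))
}

phantom_spec_shrunk <- function(spec, voxel) {
  s <- unclass(spec)
  s$tube_radius <- max(spec$tube_radius - voxel, 0.5)
  s$background_poly <- NULL
  do.call(phantom_spec, s[names(s) %in% names(formals(phantom_spec))])
}
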